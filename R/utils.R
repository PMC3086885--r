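#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the {A,C,G,T,N} alphabet (uppercase).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Random DNA sequence with i.i.d. uniform composition
#'
#' @param n sequence length in nt.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators are reproducible without side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 1299709) %% 2147483647
}

check_dna <- function(x, what = "sequence") {
  if (any(!nzchar(x))) stop(what, " must be non-empty")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop(what, " contains characters outside {A,C,G,T,N}")
  invisible(x)
}
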