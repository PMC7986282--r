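# Internal helpers shared across modules.

#' Reverse complement of DNA character strings
#'
#' @param x character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @keywords internal
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Run `expr` under a fixed RNG state without clobbering the caller's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Random DNA string(s).
.randomDna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Clamp numeric vector to [lo, hi].
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
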