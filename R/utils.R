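# Internal sequence helpers. All sequences are plain uppercase character
# vectors over {A,C,G,T,N}; coordinates are 0-based half-open internally
# and 1-based only in exported tables.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Translate nucleotide strings to amino acids
#'
#' Translates in frame 0 using the standard genetic code; a trailing
#' partial codon is dropped. Stop codons are rendered as `*`.
#'
#' @param x character vector of nucleotide sequences (A/C/G/T/N).
#' @return character vector of amino acid sequences.
#' @export
translate_nt <- function(x) {
  x <- toupper(as.character(x))
  out <- character(length(x))
  if (!length(x)) return(out)
  empty <- is.na(x) | nchar(x) < 3
  out[empty & !is.na(x)] <- ""
  out[is.na(x)] <- NA_character_
  idx <- which(!empty)
  if (length(idx)) {
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(substr(x[idx], 1L, nchar(x[idx]) %/% 3L * 3L)),
      if.fuzzy.codon = "X"
    )
    out[idx] <- as.character(aa)
  }
  out
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Every stochastic operation in the package
# goes through this, so identical seeds give bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# random bases; `not` optionally forbids, per position, the reference base
# (used for substitution alts)
random_bases <- function(n, not = NULL) {
  if (is.null(not)) return(sample(DNA_BASES, n, replace = TRUE))
  vapply(not, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
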