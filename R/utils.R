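# Internal sequence utilities shared across modules.
# All genome coordinates inside the package are 0-based half-open; conversion
# to/from 1-based inclusive (GFF3) happens only at I/O boundaries.

NUCS <- c("A", "C", "G", "T")

ALL_CODONS <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))

GENETIC_CODE_VEC <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

STOP_CODONS <- names(GENETIC_CODE_VEC)[GENETIC_CODE_VEC == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_VEC), STOP_CODONS)

AMINO_ACIDS <- sort(unique(GENETIC_CODE_VEC[SENSE_CODONS]))

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to protein
#'
#' Standard genetic code; stop codons render as `*`; any codon containing an
#' ambiguity (N) renders as `X`. Trailing bases that do not complete a codon
#' are ignored.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of peptide sequences.
#' @export
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  x <- substr(x, 1L, n)
  out <- character(length(x))
  nz <- n > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(x[nz]),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
  }
  out
}

# split a DNA string into codon triplets (drops incomplete tail)
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# random DNA with a target G+C fraction
random_dna <- function(n, gc = 0.5) {
  paste(sample(NUCS, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deterministic small-integer substream derived from a master seed and a key
derive_seed <- function(seed, key) {
  ints <- utf8ToInt(as.character(key))
  h <- sum(ints * seq_along(ints))
  as.integer((as.numeric(seed) * 48271 + h * 977) %% 2147480000)
}

# interval helpers (0-based half-open tibbles with start/end columns)
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- integer(0); oute <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(outs, ms), end = c(oute, me))
}

# length of overlap between one interval and a set of intervals
overlap_len <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(pmax(0L, pmin(e, ends) - pmax(s, starts)))
}
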