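#' @useDynLib betle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
ESP3I_PLUS <- "CGTCTC"
ESP3I_MINUS <- "GAGACG"

#' Create a sequence record
#'
#' A lightweight container for a named DNA (or protein) sequence, the unit
#' all readers and simulators work with.
#'
#' @param id Record identifier.
#' @param seq Sequence string.
#' @param description Optional free-text description.
#' @return A list of class `seq_record` with fields `id`, `seq`,
#'   `description`.
#' @export
seq_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L, nzchar(seq))
  structure(list(id = id, seq = toupper(seq), description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt)%s\n", x$id, nchar(x$seq),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Check that sequences use the DNA alphabet
#'
#' @param x Character vector of sequences.
#' @param allow_n Permit `N` (read data); reference constructs must be
#'   strictly A/C/G/T.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; stops with an alphabet error otherwise.
#' @export
check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("alphabet error: %s %d contains characters outside {A,C,G,T%s}",
                 what, which(bad)[1L], if (allow_n) ",N" else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (N allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a coding sequence
#'
#' Standard genetic code; stops render as `*`. Trailing partial codons are
#' an error.
#'
#' @param cds DNA string with length a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  check_dna(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3", call. = FALSE)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Generate a random DNA sequence
#'
#' Uniform over A/C/G/T; used by the simulators and tests.
#'
#' @param n Length in nucleotides.
#' @return DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all triplet substrings (sliding window) of a sequence
sliding_triplets <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  substring(seq, 1:(n - 2L), 3:n)
}
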