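# Small sequence helpers shared by all modules. Sequences travel through the
# package as named character vectors (one element per record, names = ids);
# Biostrings containers are accepted at every entry point.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Coerce a sequence collection to a named character vector
#'
#' Accepts a `Biostrings::DNAStringSet` or a named character vector and returns
#' an upper-case named character vector. Ids must be unique and sequences
#' non-empty over the alphabet `A/C/G/T/N`.
#'
#' @param x A `DNAStringSet` or named character vector of DNA sequences.
#' @param what Label used in error messages.
#' @return Named character vector of upper-case sequences.
#' @export
as_seq_set <- function(x, what = "sequence set") {
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x) || length(x) == 0L) {
    stop(what, " must be a non-empty named character vector or DNAStringSet")
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop(what, ": every record needs an id (names attribute)")
  }
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop(what, ": duplicated ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  x <- toupper(x)
  if (any(nchar(x) == 0L)) stop(what, ": empty sequence for id ",
                                names(x)[which(nchar(x) == 0L)[1]])
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stop(what, ": non-ACGTN characters in record ",
                     names(x)[which(bad)[1]])
  x
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar DNA sequence.
#' @return Character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence
#'
#' Thin wrapper over [Biostrings::translate()] returning a character scalar.
#' Trailing stop codons are kept as `*`.
#'
#' @param x Character scalar nucleotide CDS (length divisible by 3).
#' @return Character scalar amino-acid sequence.
#' @export
translate_cds <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) %% 3 == 0)
  as.character(Biostrings::translate(Biostrings::DNAString(x)))
}

# Random DNA with a target GC content, under the caller's RNG state.
random_dna <- function(n, gc = 0.38) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Modal value of an integer vector; ties broken toward the smaller value.
modal_int <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

# Substring by 0-based half-open coordinates (vectorized over coordinates).
substr0 <- function(seq, start0, end0) substring(seq, start0 + 1L, end0)
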