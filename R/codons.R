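## Codon machinery shared by the scanner, the usage estimator and the
## frame-shift chains.  Nucleotides are coded A=0, C=1, G=2, T=3; a codon
## (a,b,c) gets the 1-based index 16a + 4b + c + 1, so CODONS[i] is the
## string form of index i.

NUCS <- c("A", "C", "G", "T")

# lexicographic order: first position slowest, third fastest
CODONS <- paste0(rep(NUCS, each = 16), rep(rep(NUCS, each = 4), 4), rep(NUCS, 16))

DEFAULT_STARTS <- c("ATG", "GTG", "TTG", "CTG")
DEFAULT_STOPS <- c("TAA", "TAG", "TGA")
MOLLICUTE_STOPS <- c("TAA", "TAG")

# lookup table from ASCII byte to nucleotide code (NA for anything else)
.nuc_code <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L
  tab
})

#' Convert an A/C/G/T string to integer nucleotide codes
#'
#' Internal workhorse: A, C, G, T map to 0, 1, 2, 3.
#'
#' @param sequence character scalar over \{A,C,G,T\}.
#' @return integer vector of the same length as the sequence.
#' @keywords internal
seq_to_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  codes <- .nuc_code[utf8ToInt(sequence) + 1L]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("non-ACGT character '", substr(sequence, bad, bad),
         "' at position ", bad)
  }
  codes
}

codes_to_seq <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

# reverse complement on the integer coding (A<->T is 0<->3, C<->G is 1<->2)
revcomp_codes <- function(codes) rev(3L - codes)

#' Reverse complement of a codon or sequence string
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# codon index vector (1..64) for reading frame offset `offset` (0, 1 or 2)
frame_codon_index <- function(codes, offset = 0L) {
  n <- length(codes)
  ncod <- (n - offset) %/% 3L
  if (ncod < 1L) return(integer(0))
  i <- seq.int(offset + 1L, by = 3L, length.out = ncod)
  16L * codes[i] + 4L * codes[i + 1L] + codes[i + 2L] + 1L
}

codon_index <- function(codon) {
  idx <- match(codon, CODONS)
  if (anyNA(idx)) stop("not a codon: ", paste(codon[is.na(idx)], collapse = ", "))
  idx
}

# index permutation sending each codon to its reverse complement
.rc_perm <- local({
  a <- (seq_len(64) - 1L) %/% 16L
  b <- ((seq_len(64) - 1L) %/% 4L) %% 4L
  c <- (seq_len(64) - 1L) %% 4L
  16L * (3L - c) + 4L * (3L - b) + (3L - a) + 1L
})

# evaluate `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
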