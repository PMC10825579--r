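# Shared sequence helpers.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

# codon -> amino acid lookup (standard code)
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Split a nucleotide sequence into codons
#'
#' @param seq Nucleotide string whose length is a multiple of 3.
#' @return Character vector of 3-mers.
#' @keywords internal
codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

#' Test whether in-frame translation is stop-free
#'
#' Frame 1 is used throughout: the amplicon primers anchor the reading
#' frame at codon boundaries.
#'
#' @param seq Nucleotide string, length a multiple of 3.
#' @return Logical.
#' @keywords internal
has_stop_codon <- function(seq) {
  any(codons(seq) %in% STOP_CODONS)
}

#' Reverse-complement a nucleotide string
#' @param seq Nucleotide string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Equal-length strings.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  .hamming_to_ref(a, b)[1L]
}

# Positions (and replacement bases) at which `seq` differs from `ref`.
# Encoded as "pos:base" strings so that pattern-subset tests are plain
# set operations.
diff_pattern <- function(ref, seq) {
  ra <- utf8ToInt(ref)
  sa <- utf8ToInt(seq)
  idx <- which(ra != sa)
  if (length(idx) == 0L) return(character(0))
  paste0(idx, ":", substring(seq, idx, idx))
}

# Random stop-free coding sequence of `n_codons` codons.
random_coding_sequence <- function(n_codons) {
  tab <- .codon_table()
  pool <- names(tab)[tab != "*"]
  paste0(sample(pool, n_codons, replace = TRUE), collapse = "")
}

#' Apply amino-acid-changing codon mutations
#'
#' Replaces `m` distinct codons (within the first `region_len`
#' nucleotides) with random codons encoding a *different* amino acid,
#' never a stop. This is the package's model of one nonsynonymous
#' ("amino acid") mutation: a codon swap typically alters 1-3
#' nucleotides.
#'
#' @param seq Nucleotide string, length a multiple of 3.
#' @param m Number of codons to mutate.
#' @param region_len Restrict mutated codons to the first `region_len`
#'   nucleotides (default: whole sequence). Must be a multiple of 3.
#' @return Mutated nucleotide string.
#' @export
mutate_codons <- function(seq, m, region_len = nchar(seq)) {
  if (m == 0L) return(seq)
  tab <- .codon_table()
  n_codon <- region_len %/% 3L
  if (m > n_codon) stop("more mutations than codons in region")
  picks <- sample.int(n_codon, m)
  cods <- codons(seq)
  for (i in picks) {
    aa <- tab[[cods[i]]]
    if (is.null(aa) || is.na(aa)) aa <- ""
    pool <- names(tab)[tab != "*" & tab != aa]
    cods[i] <- sample(pool, 1L)
  }
  paste0(cods, collapse = "")
}
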