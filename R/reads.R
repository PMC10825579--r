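# Paired-end amplicon preprocessing: quality trimming, overlap merging,
# constant-region trimming, VHH validity filtering and unique-sequence
# tabulation. One sample = one (week, isotype) pair of FASTQ mates, or a
# pre-merged FASTA / sequence-frequency TSV that bypasses this module.

#' Quality-trim a read by cumulative error probability (modified Mott)
#'
#' Converts per-base Phred scores to error probabilities and keeps the
#' contiguous segment maximizing the running sum of `limit - p_err`
#' (the modified-Mott criterion used by common read trimmers). A read
#' whose best segment has non-positive score is discarded.
#'
#' @param seq Nucleotide string.
#' @param qual Integer vector of Phred quality scores, one per base.
#' @param limit Error-probability threshold, default 0.01.
#' @return A list with `seq`, `qual`, and logical `discarded`.
#' @export
trim_quality <- function(seq, qual, limit = 0.01) {
  stopifnot(limit > 0, limit < 1, nchar(seq) == length(qual))
  p_err <- 10^(-qual / 10)
  score <- limit - p_err
  # Kadane scan for the maximal-sum segment; on ties the earliest,
  # shortest segment wins (a strictly negative prefix is dropped, a
  # zero-score prefix is kept)
  best <- 0
  best_start <- 0L
  best_end <- -1L
  cur <- 0
  cur_start <- 1L
  for (i in seq_along(score)) {
    if (cur < 0) {
      cur <- 0
      cur_start <- i
    }
    cur <- cur + score[i]
    if (cur > best) {
      best <- cur
      best_start <- cur_start
      best_end <- i
    }
  }
  if (best_end < best_start || best <= 0) {
    return(list(seq = "", qual = integer(0), discarded = TRUE))
  }
  list(seq = substr(seq, best_start, best_end),
       qual = qual[best_start:best_end],
       discarded = FALSE)
}

#' Merge a read pair by overlap alignment
#'
#' The reverse mate is reverse-complemented and slid along the forward
#' mate; each gapless overlap is scored as
#' `matches - mismatch_cost * mismatches` and the best-scoring overlap
#' is accepted when its score reaches `min_score`. At overlap
#' mismatches the base with the higher Phred quality wins; ties go to
#' the forward mate. Amplicon mate overlaps are effectively never
#' gapped, so the overlap search is gapless; `gap_cost` documents the
#' scoring contract (a gap column would cost `gap_cost`) and is part of
#' the stored parameters.
#'
#' @param fwd,rev Nucleotide strings for forward and reverse mates.
#' @param fwd_qual,rev_qual Integer Phred vectors.
#' @param mismatch_cost Penalty per overlap mismatch (default 2).
#' @param gap_cost Penalty per gap column (default 3; see Details).
#' @param min_score Minimum acceptable overlap score (default 8).
#' @return Merged nucleotide string, or `NULL` when no overlap reaches
#'   `min_score`.
#' @export
merge_read_pair <- function(fwd, rev, fwd_qual, rev_qual,
                            mismatch_cost = 2L, gap_cost = 3L,
                            min_score = 8L) {
  rc <- revcomp(rev)
  rcq <- rev(rev_qual)
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rc, "")[[1]]
  nf <- length(f)
  nr <- length(r)
  best <- list(score = -Inf, shift = NA_integer_, ovl = 0L)
  # shift s: position of r[1] relative to f[1] (0 = aligned starts);
  # negative shifts let the reverse mate overhang on the left.
  for (s in seq(-(nr - 1L), nf - 1L)) {
    lo <- max(1L, s + 1L)            # overlap start in f coords
    hi <- min(nf, s + nr)            # overlap end in f coords
    ovl <- hi - lo + 1L
    if (ovl < 1L) next
    fi <- lo:hi
    ri <- fi - s
    m <- sum(f[fi] == r[ri])
    sc <- m - mismatch_cost * (ovl - m)
    if (sc > best$score || (sc == best$score && ovl > best$ovl)) {
      best <- list(score = sc, shift = s, ovl = ovl)
    }
  }
  if (!is.finite(best$score) || best$score < min_score) return(NULL)
  s <- best$shift
  lo <- max(1L, s + 1L)
  hi <- min(nf, s + nr)
  fi <- lo:hi
  ri <- fi - s
  cons <- f[fi]
  mism <- which(f[fi] != r[ri])
  for (k in mism) {
    if (rcq[ri[k]] > fwd_qual[fi[k]]) cons[k] <- r[ri[k]]
  }
  left <- if (s >= 0L) f[seq_len(lo - 1L)] else r[seq_len(-s)]
  right <- if (s + nr > nf) r[(nf - s + 1L):nr] else f[hi + seq_len(nf - hi)]
  paste0(c(left, cons, right), collapse = "")
}

#' Trim the constant-region tail of a merged read
#'
#' Removes the isotype-specific constant-region stub from the 3' end:
#' 21 bases for IgG2, 24 for IgG3.
#'
#' @param seq Merged nucleotide string.
#' @param isotype `"IgG2"` or `"IgG3"`.
#' @return Trimmed string, or `NA_character_` when the read is not
#'   longer than the trim length (discarded).
#' @export
trim_constant_region <- function(seq, isotype) {
  n <- constant_trim_length(isotype)
  len <- nchar(seq)
  ifelse(len > n, substr(seq, 1L, len - n), NA_character_)
}

#' Constant-region trim length per isotype
#' @param isotype `"IgG2"` or `"IgG3"`.
#' @return 21 for IgG2, 24 for IgG3.
#' @export
constant_trim_length <- function(isotype) {
  unname(c(IgG2 = 21L, IgG3 = 24L)[match.arg(isotype, c("IgG2", "IgG3"))])
}

#' VHH validity filter
#'
#' A merged unique sequence is retained when it has no ambiguous base,
#' its length is a multiple of three, and its frame-1 translation is
#' free of stop codons (i.e. it can encode a VHH peptide).
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return Logical vector.
#' @export
is_valid_vhh <- function(seqs) {
  vapply(seqs, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(FALSE)
    if (grepl("[^ACGT]", s)) return(FALSE)
    if (nchar(s) %% 3L != 0L) return(FALSE)
    !has_stop_codon(s)
  }, logical(1), USE.NAMES = FALSE)
}

#' Tabulate merged reads into a sequence-frequency table
#'
#' @param seqs Character vector of retained merged reads from one
#'   (week, isotype) sample.
#' @return A data.frame with columns `sequence` and `frequency`, sorted
#'   by descending frequency (ties: lexicographic sequence order).
#' @export
tabulate_reads <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(0), frequency = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab),
                    frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Process one paired-FASTQ sample into a sequence-frequency table
#'
#' Runs quality trimming, overlap merging, constant-region trimming and
#' the VHH validity filter, then tabulates unique sequences. The QC
#' report partitions the input pairs exactly:
#' `reads_in = merged_kept + merge_failed + trim_discarded +
#' validity_failed + quality_discarded`.
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files
#'   (optionally gzipped).
#' @param isotype `"IgG2"` or `"IgG3"`.
#' @param limit Quality-trim error-probability threshold.
#' @param mismatch_cost,gap_cost,min_score Overlap merge parameters.
#' @return A list with `table` (sequence-frequency data.frame) and `qc`
#'   (named integer vector of attrition counts).
#' @export
merge_sample <- function(r1, r2, isotype, limit = 0.01,
                         mismatch_cost = 2L, gap_cost = 3L,
                         min_score = 8L) {
  fq1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                      with.qualities = TRUE)
  fq2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                      with.qualities = TRUE)
  if (length(fq1) != length(fq2)) stop("mate files differ in read count")
  q1 <- as(Biostrings::PhredQuality(S4Vectors::mcols(fq1)$qualities),
           "IntegerList")
  q2 <- as(Biostrings::PhredQuality(S4Vectors::mcols(fq2)$qualities),
           "IntegerList")
  s1 <- as.character(fq1)
  s2 <- as.character(fq2)
  n <- length(s1)
  counts <- c(reads_in = n, quality_discarded = 0L, merge_failed = 0L,
              trim_discarded = 0L, validity_failed = 0L, merged_kept = 0L)
  kept <- character(0)
  for (i in seq_len(n)) {
    tf <- trim_quality(s1[i], q1[[i]], limit)
    tr <- trim_quality(s2[i], q2[[i]], limit)
    if (tf$discarded || tr$discarded) {
      counts["quality_discarded"] <- counts["quality_discarded"] + 1L
      next
    }
    m <- merge_read_pair(tf$seq, tr$seq, tf$qual, tr$qual,
                         mismatch_cost, gap_cost, min_score)
    if (is.null(m)) {
      counts["merge_failed"] <- counts["merge_failed"] + 1L
      next
    }
    t3 <- trim_constant_region(m, isotype)
    if (is.na(t3)) {
      counts["trim_discarded"] <- counts["trim_discarded"] + 1L
      next
    }
    if (!is_valid_vhh(t3)) {
      counts["validity_failed"] <- counts["validity_failed"] + 1L
      next
    }
    counts["merged_kept"] <- counts["merged_kept"] + 1L
    kept <- c(kept, t3)
  }
  list(table = tabulate_reads(kept), qc = counts)
}

#' Read a sequence-frequency TSV
#' @param path TSV with columns `sequence` and `frequency`.
#' @return data.frame with those columns.
#' @export
read_seqfreq <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "frequency") %in% names(df)))
  df$frequency <- as.integer(df$frequency)
  df[, c("sequence", "frequency")]
}

#' Write a sequence-frequency TSV
#' @param table data.frame with `sequence`, `frequency`.
#' @param path Output path.
#' @export
write_seqfreq <- function(table, path) {
  write.table(table[, c("sequence", "frequency")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run manifest
#'
#' JSON array of sample entries; each entry has `week`, `isotype`, and
#' one of (`r1` + `r2`), `fasta`, or `tsv`.
#'
#' @param path Manifest JSON path.
#' @return data.frame of samples.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  if (length(m) == 0L) {
    return(data.frame(week = integer(0), isotype = character(0)))
  }
  stopifnot(all(c("week", "isotype") %in% names(m)))
  if (anyDuplicated(m[, c("week", "isotype")]))
    stop("manifest has duplicate (week, isotype) entries")
  m$week <- as.integer(m$week)
  m
}
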