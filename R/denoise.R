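# Iterative frequency-driven error cleanup. The most frequent sequence
# ("reference sequence", RS) absorbs rarer same-length sequences within
# a frequency-dependent Hamming radius, unless their frequency ratio to
# the RS marks them as independent true variants (or derivatives of
# one). Repeats until the top frequency is 1.

#' Error-number threshold n for a reference sequence
#'
#' The Hamming radius within which rarer sequences are considered
#' candidate sequencing-error derivatives of the RS. Wider for more
#' abundant references, which seed more error copies: n = 3 for RS
#' frequency 2-400, 4 for 401-1000, 5 above 1000.
#'
#' @param rs_frequency RS read count (must be >= 2; iteration stops at 1).
#' @return Integer 3, 4 or 5.
#' @export
error_number_threshold <- function(rs_frequency) {
  if (any(rs_frequency < 2)) stop("RS frequency must be >= 2")
  ifelse(rs_frequency <= 400, 3L, ifelse(rs_frequency <= 1000, 4L, 5L))
}

#' Independence threshold r per number of base changes
#'
#' The maximum frequency ratio (member / RS) still compatible with the
#' member being a sequencing-error derivative. A sequence above the
#' threshold is an independent true variant: r = 8%, 3%, 1%, 0.2% for
#' 1, 2, 3 and >= 4 base changes.
#'
#' @param num_changes Number of base changes (>= 1).
#' @return Numeric ratio.
#' @export
independence_threshold <- function(num_changes) {
  if (any(num_changes < 1)) stop("num_changes must be >= 1")
  r <- c(0.08, 0.03, 0.01)
  ifelse(num_changes >= 4, 0.002, r[pmin(num_changes, 3)])
}

#' Build the dataset for integration around a reference sequence
#'
#' Extracts every sequence of the table equal in length to `rs` and
#' within Hamming distance `n` (the RS itself included at distance 0),
#' recording each member's substitution pattern relative to the RS.
#'
#' @param table Sequence-frequency data.frame.
#' @param rs Reference sequence (the current most frequent).
#' @param n Hamming radius; default derived from the RS frequency.
#' @return data.frame with `sequence`, `frequency`, `dist` and a list
#'   column `pattern` of "pos:base" substitution codes.
#' @export
build_integration_set <- function(table, rs, n = NULL) {
  i_rs <- match(rs, table$sequence)
  if (is.na(i_rs)) stop("rs not present in table")
  if (is.null(n)) n <- error_number_threshold(table$frequency[i_rs])
  d <- .hamming_to_ref(rs, table$sequence)
  keep <- which(!is.na(d) & d <= n)
  ds <- data.frame(sequence = table$sequence[keep],
                   frequency = table$frequency[keep],
                   dist = d[keep], stringsAsFactors = FALSE)
  ds$pattern <- lapply(ds$sequence, function(s) diff_pattern(rs, s))
  ds[order(ds$dist, ds$sequence), , drop = FALSE]
}

#' Remove independent sequences and their derivatives from a dataset
#'
#' A member whose frequency ratio to the RS strictly exceeds the
#' independence threshold for its number of base changes is an
#' independent sequence; members whose substitution pattern contains an
#' independent member's pattern are its derivatives. Both are removed
#' from the integration set (they remain in the main table for later
#' iterations).
#'
#' @param ds Output of [build_integration_set()].
#' @param rs_frequency Raw frequency of the RS.
#' @param derivative_mode `"superset"` (default): a derivative's
#'   pattern is a superset of an independent's pattern; `"exact"`
#'   requires identical patterns.
#' @param min_independent_freq Minimum frequency for a member to be
#'   ruled independent (default 2: the independence thresholds are
#'   meant to recover *major* variants, and a single-copy sequence is
#'   indistinguishable from an error whatever its ratio; set to 1 for
#'   the literal ratio-only rule).
#' @return `ds` restricted to integrable members, with attribute
#'   `removed` holding the excluded rows and their roles.
#' @export
mark_independent_and_derivatives <- function(ds, rs_frequency,
                                             derivative_mode = c("superset",
                                                                 "exact"),
                                             min_independent_freq = 2L) {
  derivative_mode <- match.arg(derivative_mode)
  is_member <- ds$dist > 0L
  ratio <- ds$frequency / rs_frequency
  indep <- is_member & ds$frequency >= min_independent_freq &
    ratio > independence_threshold(pmax(ds$dist, 1L))
  deriv <- rep(FALSE, nrow(ds))
  if (any(indep)) {
    ipat <- ds$pattern[indep]
    for (i in which(is_member & !indep)) {
      p <- ds$pattern[[i]]
      hit <- vapply(ipat, function(q) {
        if (derivative_mode == "superset") all(q %in% p)
        else length(q) == length(p) && setequal(q, p)
      }, logical(1))
      deriv[i] <- any(hit)
    }
  }
  removed <- ds[indep | deriv, , drop = FALSE]
  removed$role <- ifelse(indep[indep | deriv], "independent", "derivative")
  out <- ds[!(indep | deriv), , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' One cleanup pass on a full sequence-frequency table
#'
#' Repeatedly takes the most frequent sequence as RS (ties broken by
#' lexicographically smallest sequence), builds its integration set,
#' prunes independents/derivatives, sums the remaining frequencies into
#' the RS, and deletes the integrated rows, until the top frequency is
#' 1. Total frequency is conserved exactly.
#'
#' @param table Sequence-frequency data.frame.
#' @param derivative_mode See [mark_independent_and_derivatives()].
#' @param min_independent_freq See
#'   [mark_independent_and_derivatives()].
#' @param report Keep a per-absorption log as attribute `absorptions`.
#' @return Cleaned sequence-frequency data.frame, sorted by descending
#'   frequency (ties lexicographic).
#' @export
cleanup_table <- function(table, derivative_mode = "superset",
                          min_independent_freq = 2L, report = FALSE) {
  seqs <- as.character(table$sequence)
  freq <- as.integer(table$frequency)
  lens <- nchar(seqs)
  out_seq <- character(0)
  out_freq <- integer(0)
  log <- if (report) list() else NULL
  while (length(freq) > 0L) {
    fmax <- max(freq)
    if (fmax < 2L) break
    cand <- which(freq == fmax)
    i_rs <- cand[order(seqs[cand])[1L]]
    rs <- seqs[i_rs]
    rs_freq <- freq[i_rs]
    n <- error_number_threshold(rs_freq)
    same_len <- which(lens == lens[i_rs])
    d <- .hamming_to_ref(rs, seqs[same_len])
    in_set <- same_len[d <= n]
    d_set <- d[d <= n]
    # independence / derivative pruning
    keep_mask <- rep(TRUE, length(in_set))
    member <- d_set > 0L
    ratio <- freq[in_set] / rs_freq
    indep <- member & freq[in_set] >= min_independent_freq &
      ratio > independence_threshold(pmax(d_set, 1L))
    if (any(indep)) {
      pats <- lapply(seqs[in_set], function(s) diff_pattern(rs, s))
      ipat <- pats[indep]
      deriv <- rep(FALSE, length(in_set))
      for (k in which(member & !indep)) {
        p <- pats[[k]]
        for (q in ipat) {
          ok <- if (derivative_mode == "superset") all(q %in% p)
                else length(q) == length(p) && setequal(q, p)
          if (ok) { deriv[k] <- TRUE; break }
        }
      }
      keep_mask <- !(indep | deriv)
    }
    integ <- in_set[keep_mask]
    out_seq <- c(out_seq, rs)
    out_freq <- c(out_freq, sum(freq[integ]))
    if (report) {
      absorbed <- setdiff(integ, i_rs)
      if (length(absorbed)) {
        log[[length(log) + 1L]] <- data.frame(
          parent = rs, child = seqs[absorbed],
          child_frequency = freq[absorbed],
          dist = .hamming_to_ref(rs, seqs[absorbed]),
          stringsAsFactors = FALSE)
      }
    }
    seqs <- seqs[-integ]
    freq <- freq[-integ]
    lens <- lens[-integ]
  }
  out <- data.frame(sequence = c(out_seq, seqs),
                    frequency = c(out_freq, freq),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  if (report) {
    attr(out, "absorptions") <-
      if (length(log)) do.call(rbind, log)
      else data.frame(parent = character(0), child = character(0),
                      child_frequency = integer(0), dist = integer(0))
  }
  out
}
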