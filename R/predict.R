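# Bit-score trajectory analysis and hit-cluster prediction. For every
# cluster, each member sequence contributes one point per isotype at
# its week of first appearance with its V-region bit score; the OLS
# line through these points summarizes the lineage: a negative slope
# means ongoing somatic mutation, a high intercept means the lineage
# started near germline. Together with weekly dominant-clone turnover
# these give the three hit criteria.

#' Per-cluster bit-score trajectory points
#'
#' One point per chronological-table row of the cluster (IgG2 and IgG3
#' observations of the same sequence are separate points). `first_week`
#' is the earliest week with nonzero frequency; `weekly_share` columns
#' give the row's share of that isotype-week's total reads.
#'
#' @param members Character vector of the cluster's member sequences.
#' @param ct Chronological data.frame.
#' @param germ Assignments from [assign_vj()].
#' @return data.frame: `sequence_id`, `sequence`, `isotype`,
#'   `first_week`, `v_bitscore`, plus `share_w<week>` columns.
#' @export
cluster_trajectory <- function(members, ct, germ) {
  weeks <- chrono_weeks(ct)
  rows <- which(ct$sequence %in% members)
  fm <- freq_matrix(ct)
  iso_tot <- rowsum(fm, ct$isotype)  # per-isotype weekly totals
  sub <- fm[rows, , drop = FALSE]
  first_week <- apply(sub > 0L, 1L, function(x) weeks[which(x)[1]])
  denom <- iso_tot[ct$isotype[rows], , drop = FALSE]
  share <- sub / ifelse(denom > 0L, denom, NA_real_)
  share[is.na(share)] <- 0
  colnames(share) <- paste0("share_w", weeks)
  bs <- germ$v_bitscore[match(ct$sequence[rows], germ$sequence)]
  out <- data.frame(sequence_id = ct$sequence_id[rows],
                    sequence = ct$sequence[rows],
                    isotype = ct$isotype[rows],
                    first_week = first_week,
                    v_bitscore = bs,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(share))
  attr(out, "weeks") <- weeks
  out
}

#' Fit the bit-score-vs-first-week line
#'
#' Unweighted ordinary least squares of V-region bit score on week of
#' first appearance, one observation per trajectory point. The
#' intercept is the fitted value at week 0 — how close the hypothetical
#' founding sequence is to germline. With `weighted = TRUE` points are
#' weighted by maximum weekly frequency (sensitivity mode).
#'
#' @param points Output of [cluster_trajectory()].
#' @param weighted Frequency-weighted fit (default `FALSE`).
#' @param ct Chronological table, required when `weighted = TRUE`.
#' @return List: `slope`, `intercept`, `defined` (FALSE when all
#'   points share one first week, leaving the slope undefined).
#' @export
fit_bitscore_line <- function(points, weighted = FALSE, ct = NULL) {
  x <- points$first_week
  y <- points$v_bitscore
  if (length(unique(x)) < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_, defined = FALSE))
  }
  w <- NULL
  if (weighted) {
    if (is.null(ct)) stop("weighted fit needs the chronological table")
    w <- ct$max_freq[match(points$sequence_id, ct$sequence_id)]
  }
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  cf <- coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]), defined = TRUE)
}

#' Weekly dominant-clone turnover of a cluster
#'
#' For each week in which the cluster is present, the dominant member
#' (largest IgG2+IgG3 summed frequency; ties to the lexicographically
#' smaller sequence) is identified together with its week of first
#' appearance. The turnover index is the Spearman rank correlation
#' between calendar week and the dominant's first week: positive when
#' newly appearing sequences keep taking over. The criterion passes
#' when the index is positive and at least `min_dominants` distinct
#' sequences dominate.
#'
#' @param members Member sequences.
#' @param ct Chronological data.frame.
#' @param min_weeks Minimum weeks of presence (default 3; fewer fails).
#' @param min_dominants Minimum distinct weekly dominants (default 3).
#' @return List: `index`, `pass`, `dominants` (data.frame week /
#'   sequence / first_week).
#' @export
turnover_index <- function(members, ct, min_weeks = 3L,
                           min_dominants = 3L) {
  weeks <- chrono_weeks(ct)
  rows <- ct$sequence %in% members
  fm <- freq_matrix(ct)[rows, , drop = FALSE]
  seqs <- ct$sequence[rows]
  # pool isotypes: summed frequency per unique member sequence
  pooled <- rowsum(fm, seqs)
  useq <- rownames(pooled)
  first_week <- apply(pooled > 0L, 1L, function(x) weeks[which(x)[1]])
  present <- which(colSums(pooled) > 0L)
  if (length(present) < min_weeks) {
    return(list(index = NA_real_, pass = FALSE,
                dominants = data.frame(week = integer(0),
                                       sequence = character(0),
                                       first_week = integer(0))))
  }
  dom <- vapply(present, function(j) {
    f <- pooled[, j]
    cand <- which(f == max(f))
    cand[order(useq[cand])[1L]]
  }, integer(1))
  df <- data.frame(week = weeks[present], sequence = useq[dom],
                   first_week = first_week[dom],
                   stringsAsFactors = FALSE)
  idx <- suppressWarnings(cor(df$week, df$first_week, method = "spearman"))
  n_dom <- length(unique(df$sequence))
  pass <- isTRUE(idx > 0) && n_dom >= min_dominants
  list(index = idx, pass = pass, dominants = df)
}

#' Percentage appearance of a cluster in one week
#'
#' Sum of the cluster's percentage occupancy within IgG2 and within
#' IgG3 for the week (so a cluster holding every read of both isotypes
#' scores 200). `mode = "pooled"` instead pools counts over both
#' isotypes (ceiling 100).
#'
#' @param members Member sequences.
#' @param ct Chronological data.frame.
#' @param week Week to evaluate.
#' @param mode `"sum"` (default) or `"pooled"`.
#' @return Percentage.
#' @export
percentage_appearance <- function(members, ct, week,
                                  mode = c("sum", "pooled")) {
  mode <- match.arg(mode)
  col <- paste0("freq_w", week)
  stopifnot(col %in% names(ct))
  rows <- ct$sequence %in% members
  if (mode == "pooled") {
    tot <- sum(ct[[col]])
    return(if (tot > 0) 100 * sum(ct[[col]][rows]) / tot else 0)
  }
  out <- 0
  for (iso in unique(ct$isotype)) {
    tot <- sum(ct[[col]][ct$isotype == iso])
    if (tot > 0) out <- out + 100 * sum(ct[[col]][rows & ct$isotype == iso]) / tot
  }
  out
}

#' Maximum percentage appearance over post-immunization weeks
#'
#' @param members Member sequences.
#' @param ct Chronological data.frame.
#' @param mode See [percentage_appearance()].
#' @param week0 Pre-immunization week excluded from the maximum.
#' @return Largest weekly percentage appearance.
#' @export
max_percentage_appearance <- function(members, ct, mode = "sum",
                                      week0 = 0L) {
  weeks <- setdiff(chrono_weeks(ct), week0)
  if (length(weeks) == 0L) return(0)
  max(vapply(weeks, function(w)
    percentage_appearance(members, ct, w, mode), numeric(1)))
}

#' Predict hit-clusters from bit-score trajectories
#'
#' A cluster is called a predicted hit when (1) the bit-score slope is
#' negative, (2) the intercept ("initial bit score") exceeds
#' `intercept_threshold` (default 380 bits), and (3) the weekly
#' dominant-clone turnover criterion passes. Clusters with undefined
#' slope fail criterion (1) by convention and are flagged.
#'
#' @param clusters Named list of member-sequence vectors (from
#'   [cluster_pipeline()]).
#' @param ct Chronological data.frame.
#' @param germ Assignments from [assign_vj()].
#' @param intercept_threshold Bits (default 380).
#' @param min_dominants,min_weeks Turnover parameters.
#' @param mode Percentage-appearance mode.
#' @return data.frame sorted by descending `max_pct_appearance`:
#'   `cluster_id`, `n_members`, `slope`, `intercept`, `slope_defined`,
#'   `turnover_idx`, `n_dominants`, `turnover_pass`,
#'   `max_pct_appearance`, `predicted_hit`.
#' @export
predict_hits <- function(clusters, ct, germ, intercept_threshold = 380,
                         min_dominants = 3L, min_weeks = 3L,
                         mode = "sum") {
  rows <- lapply(names(clusters), function(id) {
    members <- clusters[[id]]
    pts <- cluster_trajectory(members, ct, germ)
    fit <- fit_bitscore_line(pts)
    to <- turnover_index(members, ct, min_weeks, min_dominants)
    data.frame(cluster_id = id,
               n_members = length(members),
               slope = fit$slope,
               intercept = fit$intercept,
               slope_defined = fit$defined,
               turnover_idx = to$index,
               n_dominants = length(unique(to$dominants$sequence)),
               turnover_pass = to$pass,
               max_pct_appearance =
                 max_percentage_appearance(members, ct, mode),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cluster_id = character(0), n_members = integer(0),
                         slope = numeric(0), intercept = numeric(0),
                         slope_defined = logical(0),
                         turnover_idx = numeric(0),
                         n_dominants = integer(0),
                         turnover_pass = logical(0),
                         max_pct_appearance = numeric(0))
  out$predicted_hit <- out$slope_defined & !is.na(out$slope) &
    out$slope < 0 & out$intercept > intercept_threshold & out$turnover_pass
  out <- out[order(-out$max_pct_appearance, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
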