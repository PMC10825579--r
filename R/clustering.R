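# Clonal cluster isolation. Unique sequences surviving the noise
# filters are grouped by (length, V gene, J gene); within a group,
# sequences closer than a JC69 distance threshold are linked and the
# connected components with more than seven members become clusters.
# Clusters touching the pre-immunization sample are discarded.

#' U40 "loneliness" counts
#'
#' For each unique sequence, the number of other equal-length unique
#' sequences differing by fewer than 40 base pairs (the sequence itself
#' and identical duplicates are not counted). Low U40 marks lonely
#' sequences with no mutational neighborhood — likely artifacts.
#'
#' @param seqs Character vector of unique nucleotide sequences.
#' @param limit Difference bound (counts distances 1..limit-1),
#'   default 40.
#' @return Integer vector aligned with `seqs`.
#' @export
u40_counts <- function(seqs, limit = 40L) {
  .neighbor_counts_under(seqs, as.integer(limit))
}

#' Noise prefilter on the chronological table
#'
#' Drops rows with maximum frequency 1 (unless the nucleotide sequence
#' is in `protected`, e.g. clones identified empirically by phage
#' display), then drops rows whose U40 — computed on the full table's
#' unique sequences before any filtering — is below `min_u40`.
#'
#' @param ct Chronological data.frame.
#' @param protected Character vector of protected sequences.
#' @param min_u40 Minimum U40 (default 10; "U40 < 10 excluded").
#' @return Filtered chronological data.frame with a `u40` column.
#' @export
prefilter_chronology <- function(ct, protected = character(0),
                                 min_u40 = 10L) {
  weeks <- chrono_weeks(ct)
  useq <- unique(ct$sequence)
  u40 <- u40_counts(useq)
  ct$u40 <- u40[match(ct$sequence, useq)]
  keep <- ct$max_freq > 1L | ct$sequence %in% protected
  ct <- ct[keep, , drop = FALSE]
  ct <- ct[ct$u40 >= min_u40, , drop = FALSE]
  rownames(ct) <- NULL
  attr(ct, "weeks") <- weeks
  ct
}

#' Group sequences by (length, V gene, J gene)
#'
#' @param ct Filtered chronological data.frame.
#' @param germ Assignments from [assign_vj()] covering `ct`'s
#'   sequences; unassigned sequences are excluded.
#' @param min_group Minimum number of unique sequences per group
#'   (default 8; smaller groups are removed).
#' @return Named list of character vectors of unique sequences; names
#'   are `<length>-<V>-<J>` keys.
#' @export
group_sequences <- function(ct, germ, min_group = 8L) {
  idx <- match(ct$sequence, germ$sequence)
  if (anyNA(idx)) stop("germline assignments missing for some sequences")
  v <- germ$v_gene[idx]
  j <- germ$j_gene[idx]
  ok <- !germ$unassigned[idx]
  df <- unique(data.frame(sequence = ct$sequence[ok],
                          key = paste(nchar(ct$sequence[ok]), v[ok],
                                      j[ok], sep = "-"),
                          stringsAsFactors = FALSE))
  groups <- split(df$sequence, df$key)
  groups[vapply(groups, length, integer(1)) >= min_group]
}

#' Jukes-Cantor (JC69) distance between equal-length sequences
#'
#' `d = -(3/4) ln(1 - 4p/3)` with p the proportion of differing sites.
#' Saturated pairs (p >= 0.75) get `Inf`.
#'
#' @param a,b Equal-length nucleotide strings.
#' @return JC69 distance.
#' @export
jc69_distance <- function(a, b) {
  p <- hamming(a, b) / nchar(a)
  jc69_from_p(p)
}

#' JC69 distance from a difference proportion
#' @param p Proportion of differing sites.
#' @return JC69 distance (`Inf` at or beyond saturation).
#' @export
jc69_from_p <- function(p) {
  out <- rep(Inf, length(p))
  ok <- p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  if (!is.null(dim(p))) dim(out) <- dim(p)
  out
}

#' Pairwise JC69 distance matrix for one group
#' @param seqs Equal-length nucleotide strings.
#' @return Numeric matrix with `seqs` as dimnames.
#' @export
jc69_matrix <- function(seqs) {
  h <- .hamming_matrix(seqs)
  d <- jc69_from_p(h / nchar(seqs[1L]))
  dim(d) <- dim(h)
  dimnames(d) <- list(seqs, seqs)
  d
}

#' Isolate clusters within a group at a distance threshold
#'
#' Builds a graph on the group's sequences with an edge wherever the
#' JC69 distance is at or below `threshold` (distances surpassing the
#' threshold are disconnected) and returns the connected components
#' with more than `min_cluster - 1` members.
#'
#' @param seqs Equal-length unique sequences of one group.
#' @param threshold JC69 distance cutoff (default 0.04).
#' @param min_cluster Minimum component size kept (default 8, i.e.
#'   "more than seven sequences").
#' @return List of character vectors (sorted members), one per cluster.
#' @export
isolate_clusters <- function(seqs, threshold = 0.04, min_cluster = 8L) {
  if (length(seqs) == 0L) return(list())
  d <- jc69_matrix(seqs)
  adj <- d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_cluster)
  lapply(keep, function(k) sort(seqs[comp$membership == k]))
}

#' Discard clusters containing pre-immunization sequences
#'
#' @param clusters List of member-sequence vectors.
#' @param ct Chronological data.frame (provides week-0 frequencies).
#' @param week0 The pre-immunization week (default 0).
#' @return Clusters whose members all have zero week-0 frequency.
#' @export
discard_preimmune <- function(clusters, ct, week0 = 0L) {
  col <- paste0("freq_w", week0)
  if (!col %in% names(ct)) return(clusters)
  w0 <- tapply(ct[[col]], ct$sequence, sum)
  Filter(function(members) {
    pres <- w0[members]
    all(is.na(pres) | pres == 0L)
  }, clusters)
}

#' Weekly summed frequencies of a cluster
#'
#' Sums the IgG2 and IgG3 rows of all member sequences per week.
#'
#' @param members Character vector of member sequences.
#' @param ct Chronological data.frame.
#' @return Named integer vector, one entry per week.
#' @export
cluster_weekly_totals <- function(members, ct) {
  rows <- ct$sequence %in% members
  fm <- freq_matrix(ct)
  totals <- colSums(fm[rows, , drop = FALSE])
  setNames(as.integer(totals), chrono_weeks(ct))
}

#' Rank clusters and assign cluster IDs
#'
#' Clusters are ranked by descending maximum weekly summed frequency
#' (ties: earlier peak week, then lexicographically smallest member
#' sequence) and named `<prefix>-1`, `<prefix>-2`, ...
#'
#' @param clusters List of member-sequence vectors.
#' @param ct Chronological data.frame.
#' @param prefix Cluster ID prefix (default "C").
#' @return Named list of clusters in rank order.
#' @export
assign_cluster_ids <- function(clusters, ct, prefix = "C") {
  if (length(clusters) == 0L) return(setNames(list(), character(0)))
  totals <- lapply(clusters, cluster_weekly_totals, ct = ct)
  max_tot <- vapply(totals, max, integer(1))
  peak_week <- vapply(totals, function(x)
    as.integer(names(x)[which.max(x)]), integer(1))
  first_member <- vapply(clusters, function(m) m[1L], character(1))
  ord <- order(-max_tot, peak_week, first_member)
  out <- clusters[ord]
  names(out) <- paste0(prefix, "-", seq_along(out))
  out
}

#' Neighbor-joining tree of a cluster
#'
#' NJ on the members' JC69 distance matrix, returned as a newick
#' string with the given labels as tips. Fewer than three members
#' yields a star tree.
#'
#' @param seqs Member sequences (equal length).
#' @param labels Tip labels (default the sequences' IDs if named, else
#'   `seq1..seqN`).
#' @return Newick string.
#' @export
build_nj_tree <- function(seqs, labels = NULL) {
  n <- length(seqs)
  if (is.null(labels)) {
    labels <- if (!is.null(names(seqs))) names(seqs)
              else paste0("seq", seq_len(n))
  }
  if (n < 3L) {
    return(paste0("(", paste0(labels, ":0", collapse = ","), ");"))
  }
  d <- jc69_matrix(seqs)
  dimnames(d) <- list(labels, labels)
  tr <- ape::nj(stats::as.dist(d))
  ape::write.tree(tr)
}

#' Run the full cluster-isolation stage
#'
#' U40/noise prefilter, (length, V, J) grouping, per-group component
#' extraction at the JC69 threshold, pre-immunization discard, and
#' cluster ID assignment.
#'
#' @param ct Chronological data.frame.
#' @param germ Assignments from [assign_vj()].
#' @param protected Protected sequences (see
#'   [prefilter_chronology()]).
#' @param threshold JC69 cutoff (default 0.04).
#' @param min_u40,min_group,min_cluster Filter parameters (defaults
#'   10, 8, 8).
#' @param prefix Cluster ID prefix.
#' @param week0 Pre-immunization week (default 0); `NULL` disables the
#'   discard.
#' @return List: `clusters` (named list of member vectors),
#'   `filtered_ct` (prefiltered table), `groups`, and `attrition`
#'   (named counts of rows/sequences surviving each step).
#' @export
cluster_pipeline <- function(ct, germ, protected = character(0),
                             threshold = 0.04, min_u40 = 10L,
                             min_group = 8L, min_cluster = 8L,
                             prefix = "C", week0 = 0L) {
  fct <- prefilter_chronology(ct, protected, min_u40)
  groups <- group_sequences(fct, germ, min_group)
  clusters <- unlist(lapply(groups, isolate_clusters,
                            threshold = threshold,
                            min_cluster = min_cluster),
                     recursive = FALSE, use.names = FALSE)
  if (is.null(clusters)) clusters <- list()
  n_before <- length(clusters)
  if (!is.null(week0)) clusters <- discard_preimmune(clusters, ct, week0)
  clusters <- assign_cluster_ids(clusters, ct, prefix)
  list(clusters = clusters, filtered_ct = fct, groups = groups,
       attrition = c(rows_in = nrow(ct), rows_prefiltered = nrow(fct),
                     groups_kept = length(groups),
                     clusters_found = n_before,
                     clusters_preimmune_discarded =
                       n_before - length(clusters),
                     clusters_kept = length(clusters)))
}
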