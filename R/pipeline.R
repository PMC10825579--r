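# End-to-end orchestration: denoise -> chronology -> prefilter ->
# germline -> clusters -> predictions, in memory or from a manifest on
# disk. All stage outputs are plain TSV/JSON so any stage can be
# inspected or replaced.

#' Analyze per-sample tables through the whole pipeline
#'
#' @param tables Nested list `tables[[week]][[isotype]]` of
#'   sequence-frequency data.frames (as produced by
#'   [simulate_repertoire()] or loaded from a manifest).
#' @param v_db,j_db Named germline sequence vectors.
#' @param protected Protected clone sequences (see
#'   [prefilter_chronology()]).
#' @param scoring Alignment scoring, see [default_scoring()].
#' @param threshold JC69 cluster cutoff (default 0.04).
#' @param min_u40,min_group,min_cluster Filter parameters.
#' @param intercept_threshold Hit-call intercept threshold in bits.
#' @param prefix Cluster ID prefix.
#' @param denoise Run the error cleanup on each sample (default TRUE).
#' @param week0 Pre-immunization week (default 0).
#' @return List: `clean_tables`, `ct` (chronological table),
#'   `filtered_ct`, `germ`, `clusters`, `predictions`, `attrition`.
#' @export
analyze_tables <- function(tables, v_db, j_db,
                           protected = character(0),
                           scoring = default_scoring(),
                           threshold = 0.04, min_u40 = 10L,
                           min_group = 8L, min_cluster = 8L,
                           intercept_threshold = 380, prefix = "C",
                           denoise = TRUE, week0 = 0L) {
  clean <- lapply(tables, function(by_iso)
    lapply(by_iso, function(t) if (denoise) cleanup_table(t) else t))
  by_iso <- function(iso) {
    out <- lapply(clean, function(x) x[[iso]])
    out[!vapply(out, is.null, logical(1))]
  }
  ct <- build_chronology(by_iso("IgG2"), by_iso("IgG3"))
  fct <- prefilter_chronology(ct, protected, min_u40)
  germ <- assign_vj(unique(fct$sequence), v_db, j_db, scoring)
  groups <- group_sequences(fct, germ, min_group)
  clusters <- unlist(lapply(groups, isolate_clusters,
                            threshold = threshold,
                            min_cluster = min_cluster),
                     recursive = FALSE, use.names = FALSE)
  if (is.null(clusters)) clusters <- list()
  n_found <- length(clusters)
  if (!is.null(week0)) clusters <- discard_preimmune(clusters, ct, week0)
  clusters <- assign_cluster_ids(clusters, ct, prefix)
  predictions <- predict_hits(clusters, ct, germ,
                              intercept_threshold = intercept_threshold)
  list(clean_tables = clean, ct = ct, filtered_ct = fct, germ = germ,
       clusters = clusters, predictions = predictions,
       attrition = c(rows_chronology = nrow(ct),
                     rows_prefiltered = nrow(fct),
                     rows_dropped = nrow(ct) - nrow(fct),
                     groups_kept = length(groups),
                     clusters_found = n_found,
                     clusters_preimmune_discarded =
                       n_found - length(clusters),
                     clusters_kept = length(clusters)))
}

# Load one manifest entry into a sequence-frequency table.
.load_sample <- function(entry, base_dir, limit, mismatch_cost,
                         gap_cost, min_score) {
  pth <- function(f) if (file.exists(f)) f else file.path(base_dir, f)
  if (!is.null(entry$tsv) && !is.na(entry$tsv)) {
    read_seqfreq(pth(entry$tsv))
  } else if (!is.null(entry$fasta) && !is.na(entry$fasta)) {
    ss <- Biostrings::readDNAStringSet(pth(entry$fasta))
    seqs <- as.character(ss)
    tabulate_reads(seqs[is_valid_vhh(seqs)])
  } else if (!is.null(entry$r1) && !is.na(entry$r1)) {
    merge_sample(pth(entry$r1), pth(entry$r2), entry$isotype, limit,
                 mismatch_cost, gap_cost, min_score)$table
  } else {
    stop("manifest entry for week ", entry$week, "/", entry$isotype,
         " has none of tsv/fasta/r1")
  }
}

#' Run the pipeline from a manifest on disk
#'
#' @param manifest Path to the run-manifest JSON (entries with `week`,
#'   `isotype` and one of `tsv`, `fasta`, or `r1`+`r2`).
#' @param v_fasta,j_fasta Germline FASTA paths.
#' @param out_dir Output directory; stage TSVs and `summary.json` are
#'   written there.
#' @param protected_fasta Optional FASTA of protected clone sequences.
#' @param limit,mismatch_cost,gap_cost,min_score Read-merging
#'   parameters (used only for FASTQ inputs).
#' @param ... Further parameters passed to [analyze_tables()].
#' @return The [analyze_tables()] result, invisibly.
#' @export
run_pipeline <- function(manifest, v_fasta, j_fasta, out_dir,
                         protected_fasta = NULL, limit = 0.01,
                         mismatch_cost = 2L, gap_cost = 3L,
                         min_score = 8L, ...) {
  m <- read_manifest(manifest)
  if (nrow(m) == 0L) stop("no samples in manifest")
  base_dir <- dirname(manifest)
  v_db <- read_germline_fasta(v_fasta)
  j_db <- read_germline_fasta(j_fasta)
  protected <- if (!is.null(protected_fasta))
    unname(read_germline_fasta(protected_fasta)) else character(0)
  tables <- list()
  for (i in seq_len(nrow(m))) {
    e <- as.list(m[i, ])
    w <- as.character(e$week)
    if (is.null(tables[[w]])) tables[[w]] <- list()
    tables[[w]][[e$isotype]] <-
      .load_sample(e, base_dir, limit, mismatch_cost, gap_cost,
                   min_score)
  }
  tables <- tables[order(as.integer(names(tables)))]
  res <- analyze_tables(tables, v_db, j_db, protected = protected, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_chronology(res$ct, file.path(out_dir, "chronology.tsv"))
  write_assignments(res$germ, file.path(out_dir, "germline.tsv"))
  membership <- do.call(rbind, lapply(names(res$clusters), function(id)
    data.frame(cluster_id = id, sequence = res$clusters[[id]],
               stringsAsFactors = FALSE)))
  if (is.null(membership))
    membership <- data.frame(cluster_id = character(0),
                             sequence = character(0))
  write.table(membership, file.path(out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$predictions, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_samples = nrow(m),
    weeks = sort(unique(m$week)),
    attrition = as.list(res$attrition),
    n_predicted_hits = sum(res$predictions$predicted_hit),
    n_clusters = length(res$clusters))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
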