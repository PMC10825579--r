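# Synthetic immunization time courses with full ground truth.
#
# Three lineage kinds mirror the dynamics the pipeline is built to
# separate:
#   responding — first seen shortly after immunization, nearly germline
#     at the start, accumulating amino-acid mutations every week while
#     newly arising clones keep replacing the dominant one;
#   static — pre-matured (many mutations at the outset), a fixed clone
#     set with a stable dominant, first seen after immunization;
#   preimmune — like static but already present in the week-0 sample,
#     so the clustering stage must discard them.
# Per-copy sequencing errors are injected on top of the true clone
# counts, giving the denoiser a known parent/child bookkeeping.

# Fixed constant-region stubs appended 3' of simulated amplicons (what
# trim_constant_region removes): 21 nt for IgG2, 24 nt for IgG3.
CONSTANT_TAIL <- c(IgG2 = "GGTCAACCGGTTACCGTCTCG",
                   IgG3 = "GGTCAACCGGTTACCGTCTCGACT")

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the
#' package's validation: weeks 0-14, 10,000 reads per (week, isotype),
#' 15 responding / 15 static / 5 preimmune lineages, responding
#' mutation rates drawn uniformly from 0.5-2 amino-acid mutations per
#' week, 30 pre-maturation mutations for static/preimmune lineages,
#' weekly dominant-clone replacement probability 0.6, and a 0.1%
#' per-base per-copy sequencing error rate.
#'
#' @param seed Integer seed (applied by [simulate_study()]).
#' @param weeks Integer sampling weeks, first must be 0.
#' @param n_v_genes,n_j_genes Germline database sizes.
#' @param n_responding,n_static,n_preimmune Lineage counts.
#' @param mutation_rate Amino-acid mutations/week for responding
#'   lineages; a length-2 vector is a per-lineage uniform range.
#' @param pre_maturation Amino-acid mutations applied to static and
#'   preimmune founders.
#' @param turnover_prob Weekly probability that a newly arisen clone
#'   replaces the dominant.
#' @param depth Reads per (week, isotype) sample.
#' @param seq_error_rate Per-base substitution probability per read
#'   copy (at most 3 substitutions per copy).
#' @param n_satellites Satellite clones per static/preimmune lineage.
#' @return Config list.
#' @export
sim_config <- function(seed = 1L, weeks = 0:14, n_v_genes = 5L,
                       n_j_genes = 3L, n_responding = 15L,
                       n_static = 15L, n_preimmune = 5L,
                       mutation_rate = c(0.5, 2), pre_maturation = 30L,
                       turnover_prob = 0.6, depth = 10000L,
                       seq_error_rate = 0.001, n_satellites = 11L) {
  stopifnot(weeks[1L] == 0L, !is.unsorted(weeks, strictly = TRUE),
            seq_error_rate >= 0, seq_error_rate <= 1,
            turnover_prob >= 0, turnover_prob <= 1)
  as.list(environment())
}

#' Simulate a germline V/J database
#'
#' Random stop-free V genes (~300 nt) pairwise more than 60
#' substitutions apart, and short J genes (~48 nt).
#'
#' @param config Config from [sim_config()] (uses `n_v_genes`,
#'   `n_j_genes`).
#' @return List with named character vectors `v` and `j`.
#' @export
simulate_germline_db <- function(config = sim_config()) {
  gen_set <- function(n, n_codons, min_dist) {
    out <- character(0)
    while (length(out) < n) {
      cand <- random_coding_sequence(n_codons)
      d <- if (length(out)) .hamming_to_ref(cand, out) else integer(0)
      if (!length(d) || min(d) > min_dist) out <- c(out, cand)
    }
    out
  }
  v <- gen_set(config$n_v_genes, 100L, 60L)
  j <- gen_set(config$n_j_genes, 16L, 10L)
  list(v = setNames(v, paste0("IGHV", seq_along(v))),
       j = setNames(j, paste0("IGHJ", seq_along(j))))
}

# One lineage's blueprint: founder sequence, clone roster with birth
# weeks, and per-week clone weights.
.simulate_lineage <- function(id, label, config, db) {
  weeks <- config$weeks
  nw <- length(weeks)
  v_id <- sample(names(db$v), 1L)
  j_id <- sample(names(db$j), 1L)
  junction <- random_coding_sequence(sample(5:15, 1L))  # 15-45 nt
  v_len <- nchar(db$v[[v_id]])
  rate <- if (length(config$mutation_rate) == 2L)
    runif(1L, config$mutation_rate[1L], config$mutation_rate[2L])
  else config$mutation_rate
  both <- runif(1L) < 0.5
  isotypes <- if (both) c("IgG2", "IgG3")
              else sample(c("IgG2", "IgG3"), 1L)
  lineage_weight <- exp(rnorm(1L, 0, 0.5))
  mk <- function(v_part) paste0(v_part, junction, db$j[[j_id]])

  if (label == "responding") {
    start_t <- sample(2:4, 1L)
    founder_v <- mutate_codons(db$v[[v_id]], sample(0:2, 1L))
    chain_v <- founder_v
    clones <- data.frame(sequence = mk(founder_v), born = start_t,
                         kind = "chain", stringsAsFactors = FALSE)
    dom <- 1L
    weight <- matrix(0, nrow = 0, ncol = nw)
    rows <- list()
    for (t in start_t:nw) {
      if (t > start_t) {
        k <- rpois(1L, rate)
        if (k > 0L) {
          chain_v <- mutate_codons(chain_v, k, region_len = v_len)
          clones <- rbind(clones, data.frame(sequence = mk(chain_v),
                                             born = t, kind = "chain",
                                             stringsAsFactors = FALSE))
          if (runif(1L) < config$turnover_prob) dom <- nrow(clones)
        }
        # minor sibling of the current dominant keeps the local
        # mutational neighborhood populated
        if (rate > 0) {
          sib_v <- mutate_codons(substr(clones$sequence[dom], 1L, v_len),
                                 1L)
          sib <- paste0(sib_v, substr(clones$sequence[dom], v_len + 1L,
                                      nchar(clones$sequence[dom])))
          clones <- rbind(clones, data.frame(sequence = sib, born = t,
                                             kind = "minor",
                                             stringsAsFactors = FALSE))
        }
      }
      active <- which((clones$kind == "chain" & clones$born >= t - 3L) |
                      (clones$kind == "minor" & clones$born >= t - 1L))
      active <- union(dom, active)
      w <- rep(0.4 / max(1L, length(active) - 1L), nrow(clones))
      w[setdiff(seq_len(nrow(clones)), active)] <- 0
      w[dom] <- 0.6
      rows[[t]] <- w
    }
  } else {
    start_t <- if (label == "preimmune") 1L else sample(2:3, 1L)
    founder_v <- mutate_codons(db$v[[v_id]], config$pre_maturation,
                               region_len = v_len)
    founder <- mk(founder_v)
    # satellites sit >= 4 nt from the founder: genuine minor variants
    # that the denoiser's independence rule must never absorb
    sats <- vapply(seq_len(config$n_satellites), function(s) {
      repeat {
        sv <- mutate_codons(founder_v, sample(2:3, 1L),
                            region_len = v_len)
        if (.hamming_to_ref(sv, founder_v)[1L] >= 4L) break
      }
      paste0(sv, substr(founder, v_len + 1L, nchar(founder)))
    }, character(1))
    clones <- data.frame(sequence = c(founder, sats),
                         born = c(start_t,
                                  start_t + (seq_along(sats) - 1L) %% 3L),
                         kind = c("chain", rep("minor", length(sats))),
                         stringsAsFactors = FALSE)
    clones$born <- pmin(clones$born, nw)
    rows <- list()
    for (t in start_t:nw) {
      active <- which(clones$born <= t)
      w <- rep(0, nrow(clones))
      others <- setdiff(active, 1L)
      if (length(others)) w[others] <- 0.4 / length(others)
      w[1L] <- 0.6
      rows[[t]] <- w
    }
  }
  # weight matrix: clones x weeks
  wm <- matrix(0, nrow = nrow(clones), ncol = nw)
  for (t in start_t:nw) wm[seq_along(rows[[t]]), t] <- rows[[t]]
  list(lineage_id = id, label = label, v_gene = v_id, j_gene = j_id,
       isotypes = isotypes, start_week = weeks[start_t],
       mutation_rate = if (label == "responding") rate else 0,
       lineage_weight = lineage_weight, clones = clones, weights = wm,
       founder = clones$sequence[1L])
}

#' Inject per-copy sequencing errors into a sequence-frequency table
#'
#' Each read copy independently receives substitutions at
#' `rate` per base (at most `max_errors` per copy); the perturbed
#' copies are re-tabulated. Total frequency is conserved.
#'
#' @param table data.frame with `sequence`, `frequency`.
#' @param rate Per-base substitution probability.
#' @param max_errors Cap on substitutions per copy (default 3).
#' @return Perturbed sequence-frequency data.frame.
#' @export
inject_errors <- function(table, rate, max_errors = 3L) {
  if (rate <= 0 || nrow(table) == 0L) return(table)
  seq_out <- character(0)
  freq_out <- integer(0)
  for (i in seq_len(nrow(table))) {
    parent <- table$sequence[i]
    cnt <- table$frequency[i]
    L <- nchar(parent)
    k <- pmin(rbinom(cnt, L, rate), max_errors)
    n_err <- sum(k > 0L)
    if (n_err == 0L) {
      seq_out <- c(seq_out, parent)
      freq_out <- c(freq_out, cnt)
      next
    }
    kk <- k[k > 0L]
    # positions: per-copy distinct; copies with one error (the vast
    # majority) are drawn in one vectorized call
    pos <- integer(sum(kk))
    off <- 0L
    ord <- order(kk)
    kk <- kk[ord]
    n1 <- sum(kk == 1L)
    if (n1 > 0L) {
      pos[seq_len(n1)] <- sample.int(L, n1, replace = TRUE)
      off <- n1
    }
    for (m in kk[kk > 1L]) {
      pos[off + seq_len(m)] <- sample.int(L, m)
      off <- off + m
    }
    chars <- strsplit(parent, "")[[1]]
    orig <- match(chars[pos], DNA_BASES)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    base <- DNA_BASES[(orig - 1L + shift) %% 4L + 1L]
    mutated <- .apply_substitutions(parent, kk, pos, base)
    tab <- base::table(mutated)
    seq_out <- c(seq_out, parent, names(tab))
    freq_out <- c(freq_out, cnt - n_err, as.integer(tab))
  }
  agg <- rowsum(freq_out, seq_out)
  out <- data.frame(sequence = rownames(agg),
                    frequency = as.integer(agg[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[out$frequency > 0L, , drop = FALSE]
  out <- out[order(-out$frequency, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a multi-week two-isotype repertoire
#'
#' @param config Config from [sim_config()].
#' @param db Germline database from [simulate_germline_db()].
#' @return List: `tables` (per week, per isotype sequence-frequency
#'   data.frames, after sequencing errors), `true_tables` (the same
#'   before errors), `truth` (lineage blueprint table and clone ->
#'   lineage map).
#' @export
simulate_repertoire <- function(config = sim_config(),
                                db = simulate_germline_db(config)) {
  labels <- c(rep("responding", config$n_responding),
              rep("static", config$n_static),
              rep("preimmune", config$n_preimmune))
  lineages <- lapply(seq_along(labels), function(i)
    .simulate_lineage(sprintf("lin%02d", i), labels[i], config, db))
  weeks <- config$weeks
  nw <- length(weeks)
  tables <- true_tables <- setNames(
    lapply(weeks, function(w) list()), as.character(weeks))
  for (t in seq_len(nw)) {
    for (iso in c("IgG2", "IgG3")) {
      segs <- lapply(lineages, function(ln) {
        if (!(iso %in% ln$isotypes)) return(NULL)
        w <- ln$weights[, t]
        if (sum(w) == 0) return(NULL)
        data.frame(sequence = ln$clones$sequence,
                   weight = w * ln$lineage_weight,
                   stringsAsFactors = FALSE)
      })
      segs <- do.call(rbind, segs)
      if (is.null(segs) || sum(segs$weight) == 0) {
        empty <- data.frame(sequence = character(0),
                            frequency = integer(0),
                            stringsAsFactors = FALSE)
        true_tables[[t]][[iso]] <- empty
        tables[[t]][[iso]] <- empty
        next
      }
      segs <- segs[segs$weight > 0, , drop = FALSE]
      cnt <- as.integer(rmultinom(1L, config$depth, segs$weight))
      agg <- rowsum(cnt, segs$sequence)
      tt <- data.frame(sequence = rownames(agg),
                       frequency = as.integer(agg[, 1L]),
                       stringsAsFactors = FALSE)
      tt <- tt[tt$frequency > 0L, , drop = FALSE]
      tt <- tt[order(-tt$frequency, tt$sequence), , drop = FALSE]
      rownames(tt) <- NULL
      true_tables[[t]][[iso]] <- tt
      tables[[t]][[iso]] <- inject_errors(tt, config$seq_error_rate)
    }
  }
  lineage_df <- do.call(rbind, lapply(lineages, function(ln)
    data.frame(lineage_id = ln$lineage_id, label = ln$label,
               v_gene = ln$v_gene, j_gene = ln$j_gene,
               isotypes = paste(ln$isotypes, collapse = ","),
               start_week = ln$start_week,
               mutation_rate = ln$mutation_rate,
               length = nchar(ln$founder),
               founder = ln$founder, stringsAsFactors = FALSE)))
  clone_map <- unlist(lapply(lineages, function(ln)
    setNames(rep(ln$lineage_id, nrow(ln$clones)), ln$clones$sequence)))
  # a sequence arising twice keeps its first lineage
  clone_map <- clone_map[!duplicated(names(clone_map))]
  list(tables = tables, true_tables = true_tables,
       truth = list(lineages = lineage_df, clone_map = clone_map))
}

#' Simulate a complete seeded study
#'
#' Seeds the RNG, draws the germline database and the repertoire.
#'
#' @param config Config from [sim_config()].
#' @return List: `config`, `db`, plus everything from
#'   [simulate_repertoire()].
#' @export
simulate_study <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  db <- simulate_germline_db(config)
  rep <- simulate_repertoire(config, db)
  c(list(config = config, db = db), rep)
}

#' Write simulation fixtures to disk
#'
#' Emits the germline FASTA files, one sequence-frequency TSV per
#' (week, isotype) sample, a manifest JSON, and the ground-truth
#' lineage table.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_fixtures <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste0(">", names(sim$db$v), "\n", sim$db$v),
             file.path(dir, "IGHV.fasta"))
  writeLines(paste0(">", names(sim$db$j), "\n", sim$db$j),
             file.path(dir, "IGHJ.fasta"))
  manifest <- list()
  for (w in names(sim$tables)) {
    for (iso in names(sim$tables[[w]])) {
      f <- sprintf("sample_w%s_%s.tsv", w, iso)
      write_seqfreq(sim$tables[[w]][[iso]], file.path(dir, f))
      manifest[[length(manifest) + 1L]] <-
        list(week = as.integer(w), isotype = iso, tsv = f)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  write.table(sim$truth$lineages, file.path(dir, "truth_lineages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write paired FASTQ mates for one simulated sample
#'
#' Turns a sequence-frequency table back into overlapping read pairs:
#' the template is the sequence plus its isotype's constant-region
#' stub; the forward mate is the template's first `read_len` bases and
#' the reverse mate the reverse complement of its last `read_len`
#' bases, all at uniform Phred `qual`.
#'
#' @param table Sequence-frequency data.frame.
#' @param isotype `"IgG2"` or `"IgG3"`.
#' @param r1,r2 Output FASTQ paths.
#' @param read_len Mate length (default 250).
#' @param qual Uniform Phred score (default 30).
#' @return Invisibly, the number of pairs written.
#' @export
write_fastq_pairs <- function(table, isotype, r1, r2, read_len = 250L,
                              qual = 30L) {
  tail <- CONSTANT_TAIL[[match.arg(isotype, c("IgG2", "IgG3"))]]
  seqs <- rep(table$sequence, table$frequency)
  qchar <- rawToChar(as.raw(qual + 33L))
  con1 <- file(r1, "w"); con2 <- file(r2, "w")
  on.exit({ close(con1); close(con2) })
  for (i in seq_along(seqs)) {
    tpl <- paste0(seqs[i], tail)
    L <- nchar(tpl)
    if (L < read_len) stop("template shorter than read length")
    fwd <- substr(tpl, 1L, read_len)
    rev <- revcomp(substr(tpl, L - read_len + 1L, L))
    q <- strrep(qchar, read_len)
    writeLines(c(paste0("@read", i), fwd, "+", q), con1)
    writeLines(c(paste0("@read", i), rev, "+", q), con2)
  }
  invisible(length(seqs))
}

#' Score pipeline predictions against simulation ground truth
#'
#' Maps each emitted cluster to the lineage contributing most of its
#' members, checks that no preimmune lineage survives, and computes
#' responding-vs-static balanced accuracy of the hit calls (a
#' responding lineage with no surviving cluster counts as a missed
#' hit).
#'
#' @param predictions Output of [predict_hits()].
#' @param clusters Named list of member-sequence vectors.
#' @param truth `truth` element of [simulate_study()] output.
#' @return List: `cluster_labels`, `n_preimmune_clusters`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
score_simulation <- function(predictions, clusters, truth) {
  lin_label <- setNames(truth$lineages$label, truth$lineages$lineage_id)
  cl_lineage <- vapply(clusters, function(members) {
    lin <- truth$clone_map[members]
    lin <- lin[!is.na(lin)]
    if (!length(lin)) return(NA_character_)
    names(sort(table(lin), decreasing = TRUE))[1L]
  }, character(1))
  cl_label <- setNames(unname(lin_label[cl_lineage]), names(clusters))
  hit <- setNames(predictions$predicted_hit, predictions$cluster_id)
  hit <- hit[names(clusters)]
  # lineage-level calls: a lineage is "called hit" if any of its
  # clusters is a predicted hit; responding lineages without clusters
  # are missed hits
  resp <- truth$lineages$lineage_id[truth$lineages$label == "responding"]
  stat <- truth$lineages$lineage_id[truth$lineages$label == "static"]
  called_hit <- vapply(c(resp, stat), function(l)
    any(hit[!is.na(cl_lineage) & cl_lineage == l]), logical(1))
  tp <- sum(called_hit[resp])
  fn <- length(resp) - tp
  fp <- sum(called_hit[stat])
  tn <- length(stat) - fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(cluster_labels = cl_label,
       n_preimmune_clusters =
         sum(cl_label == "preimmune", na.rm = TRUE),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)))
}
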