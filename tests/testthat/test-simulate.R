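test_that("simulated germline genes are distant, stop-free, and reproducible", {
  set.seed(1)
  db <- simulate_germline_db(sim_config(n_v_genes = 5L, n_j_genes = 3L))
  expect_equal(length(db$v), 5L)
  expect_equal(length(db$j), 3L)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_gt(hamming(db$v[[i]], db$v[[j]]), 60L)
    }
  }
  expect_false(any(vapply(db$v, vhhtrack:::has_stop_codon, logical(1))))
  set.seed(1)
  db2 <- simulate_germline_db(sim_config(n_v_genes = 5L, n_j_genes = 3L))
  expect_identical(db, db2)
})

test_that("degenerate dynamics reduce each lineage to its founder", {
  sim <- simulate_study(sim_config(seed = 4, weeks = 0:5,
                                   n_responding = 3L, n_static = 0L,
                                   n_preimmune = 0L, depth = 500L,
                                   mutation_rate = c(0, 0),
                                   turnover_prob = 0, seq_error_rate = 0))
  founders <- sim$truth$lineages$founder
  for (w in names(sim$tables)) {
    for (iso in names(sim$tables[[w]])) {
      expect_true(all(sim$tables[[w]][[iso]]$sequence %in% founders))
    }
  }
})

test_that("error-free tables pass through the denoiser unchanged", {
  sim <- simulate_study(sim_config(seed = 5, weeks = 0:6,
                                   n_responding = 3L, n_static = 2L,
                                   n_preimmune = 1L, depth = 1500L,
                                   seq_error_rate = 0))
  t <- sim$tables[["4"]][["IgG2"]]
  out <- cleanup_table(t)
  expect_equal(out[order(out$sequence), ],
               t[order(t$sequence), ], ignore_attr = TRUE)
})

test_that("error injection conserves reads and stays within 3 substitutions", {
  set.seed(6)
  tab <- data.frame(sequence = replicate(4, random_seq(90)),
                    frequency = c(2000L, 500L, 50L, 3L))
  out <- inject_errors(tab, rate = 0.01)
  expect_equal(sum(out$frequency), sum(tab$frequency))
  d <- vapply(out$sequence, function(s)
    min(vapply(tab$sequence, function(p) hamming_oracle(p, s),
               numeric(1))), numeric(1))
  expect_true(all(d <= 3))
})

test_that("responding lineages drift away from germline over the weeks", {
  sim <- simulate_study(sim_config(seed = 7, weeks = 0:10,
                                   n_responding = 3L, n_static = 0L,
                                   n_preimmune = 0L, depth = 2000L,
                                   mutation_rate = c(1.5, 2),
                                   seq_error_rate = 0))
  # bit score of the dominant clone early vs late
  for (lin in sim$truth$lineages$lineage_id) {
    cl <- names(sim$truth$clone_map)[sim$truth$clone_map == lin]
    v_id <- sim$truth$lineages$v_gene[sim$truth$lineages$lineage_id == lin]
    g <- sim$db$v[[v_id]]
    sc <- default_scoring()
    bits <- vapply(cl, function(s)
      bit_score(local_align(s, g, sc), sc$lambda, sc$k), numeric(1))
    expect_lt(bits[length(bits)], bits[1L])
  }
})

test_that("preimmune lineages appear at week 0 and are discarded downstream", {
  sim <- small_sim(seed = 8)
  pre <- sim$truth$lineages$lineage_id[sim$truth$lineages$label ==
                                         "preimmune"]
  pre_seqs <- names(sim$truth$clone_map)[sim$truth$clone_map %in% pre]
  w0 <- unlist(lapply(sim$tables[["0"]], `[[`, "sequence"))
  expect_true(any(w0 %in% pre_seqs))
  res <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
  sc <- score_simulation(res$predictions, res$clusters, sim$truth)
  expect_equal(sc$n_preimmune_clusters, 0L)
})

test_that("a seeded study is fully reproducible", {
  s1 <- simulate_study(sim_config(seed = 9, weeks = 0:4, n_responding = 2L,
                                  n_static = 1L, n_preimmune = 1L,
                                  depth = 400L))
  s2 <- simulate_study(sim_config(seed = 9, weeks = 0:4, n_responding = 2L,
                                  n_static = 1L, n_preimmune = 1L,
                                  depth = 400L))
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
})

test_that("fixtures round-trip through the disk-based pipeline", {
  sim <- small_sim(seed = 10)
  d <- withr::local_tempdir()
  emit_fixtures(sim, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_true(file.exists(file.path(d, "IGHV.fasta")))
  out1 <- file.path(d, "out1"); out2 <- file.path(d, "out2")
  res <- run_pipeline(file.path(d, "manifest.json"),
                      file.path(d, "IGHV.fasta"),
                      file.path(d, "IGHJ.fasta"), out1)
  expect_true(file.exists(file.path(out1, "summary.json")))
  expect_true(file.exists(file.path(out1, "predictions.tsv")))
  in_mem <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
  expect_equal(res$predictions, in_mem$predictions)
  # re-running on the same inputs is byte-identical
  run_pipeline(file.path(d, "manifest.json"), file.path(d, "IGHV.fasta"),
               file.path(d, "IGHJ.fasta"), out2)
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  expect_identical(readLines(file.path(out1, "predictions.tsv")),
                   readLines(file.path(out2, "predictions.tsv")))
})

test_that("an empty manifest is rejected", {
  d <- withr::local_tempdir()
  writeLines("[]", file.path(d, "manifest.json"))
  expect_error(run_pipeline(file.path(d, "manifest.json"), "v.fa", "j.fa",
                            file.path(d, "out")),
               "no samples")
})
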