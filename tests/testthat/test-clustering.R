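mutants <- function(parent, n, d_range = 1:3) {
  vapply(seq_len(n), function(i) {
    s <- parent
    for (p in sample.int(nchar(parent), sample(d_range, 1))) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }, character(1))
}

test_that("U40 counts equal-length neighbors within 39 differences", {
  ref <- strrep("ACGT", 25)                       # 100 nt
  at_dist <- function(d) {
    s <- ref
    for (p in seq_len(d)) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  seqs <- c(ref, at_dist(1), at_dist(39), at_dist(40))
  expect_equal(u40_counts(seqs)[1], 2L)           # 40 is not "fewer than 40"
  expect_equal(u40_counts(ref), 0L)               # alone -> 0
})

test_that("U40 matches an all-pairs Hamming oracle", {
  set.seed(61)
  parents <- replicate(4, random_seq(60))
  seqs <- unique(c(parents, unlist(lapply(parents, mutants, n = 30,
                                          d_range = 1:25))))
  got <- u40_counts(seqs)
  want <- vapply(seq_along(seqs), function(i) {
    d <- vapply(seqs[-i], function(s) hamming_oracle(seqs[i], s),
                numeric(1))
    sum(d >= 1 & d < 40)
  }, numeric(1))
  expect_equal(got, as.integer(want))
})

test_that("prefilter drops singletons (except protected) then low-U40 rows", {
  set.seed(62)
  parent <- random_seq(102)
  fam <- unique(c(parent, mutants(parent, 14)))
  lonely <- random_seq(102)
  tabs <- list(`0` = data.frame(sequence = character(0),
                                frequency = integer(0)),
               `1` = data.frame(sequence = c(fam, lonely),
                                frequency = c(5L, rep(2L, length(fam) - 2L),
                                              1L, 8L)))
  ct <- build_chronology(tabs, list())
  # the family member with max_freq 1 is dropped unless protected
  dropped <- ct$sequence[ct$max_freq == 1L & ct$sequence != lonely]
  f1 <- prefilter_chronology(ct)
  expect_false(dropped %in% f1$sequence)
  expect_false(lonely %in% f1$sequence)           # U40 = 0 < 10
  f2 <- prefilter_chronology(ct, protected = dropped)
  expect_true(dropped %in% f2$sequence)
  expect_true(all(f1$u40 >= 10L))
})

test_that("the U40 filter boundary keeps 10 and drops 9 neighbors", {
  set.seed(68)
  p1 <- random_seq(120); p2 <- random_seq(120)
  fam11 <- unique(c(p1, mutants(p1, 30)))[1:11]   # each member: U40 = 10
  fam10 <- unique(c(p2, mutants(p2, 30)))[1:10]   # each member: U40 = 9
  tabs <- list(`1` = data.frame(sequence = c(fam11, fam10),
                                frequency = rep(2L, 21)))
  ct <- build_chronology(tabs, list())
  f <- prefilter_chronology(ct)
  expect_setequal(f$sequence, fam11)
})

test_that("grouping keys on (length, V, J) and enforces the 8-sequence floor", {
  set.seed(63)
  sim <- small_sim()
  res <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
  groups <- group_sequences(res$filtered_ct, res$germ, min_group = 8L)
  for (key in names(groups)) {
    expect_gte(length(groups[[key]]), 8L)
    parts <- strsplit(key, "-")[[1]]
    expect_true(all(nchar(groups[[key]]) == as.integer(parts[1])))
    vj <- res$germ[match(groups[[key]], res$germ$sequence), ]
    expect_true(all(vj$v_gene == parts[2]))
    expect_true(all(vj$j_gene == parts[3]))
  }
  # mixed lengths with same V/J split into separate groups
  keys <- do.call(rbind, strsplit(names(groups), "-"))
  expect_true(all(table(paste(keys[, 2], keys[, 3])) >= 1))
})

test_that("JC69 distance follows the closed form with threshold edge cases", {
  a300 <- strrep("A", 300)
  b300 <- paste0(strrep("C", 3), strrep("A", 297))
  expect_equal(jc69_distance(a300, b300), 0.010067, tolerance = 1e-4)
  expect_equal(jc69_distance(a300, b300),
               -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-12)
  # 333 nt: 13 diffs crosses 0.04, 12 does not
  expect_gt(jc69_from_p(13 / 333), 0.04)
  expect_lte(jc69_from_p(12 / 333), 0.04)
  expect_equal(jc69_distance(a300, a300), 0)
  expect_equal(jc69_from_p(0.8), Inf)
  # strictly increasing in Hamming distance, symmetric
  p <- (1:20) / 100
  expect_true(all(diff(jc69_from_p(p)) > 0))
  expect_equal(jc69_distance(a300, b300), jc69_distance(b300, a300))
})

test_that("JC69 agrees with ape::dist.dna", {
  set.seed(64)
  a <- random_seq(300)
  b <- a
  for (p in sample.int(300, 9)) {
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(b, p, p)), 1)
  }
  bin <- ape::as.DNAbin(lapply(list(a = a, b = b),
                               function(s) strsplit(tolower(s), "")[[1]]))
  expect_equal(jc69_distance(a, b),
               as.numeric(ape::dist.dna(bin, model = "JC69")),
               tolerance = 1e-10)
})

test_that("cluster isolation extracts connected components above size 7", {
  # chain: adjacent pairs linked, ends far apart -> one transitive cluster
  base <- strrep("ACGT", 50)                      # 200 nt, 0.04 -> 8 diffs
  chain <- base
  for (i in 1:7) {
    nxt <- chain[i]
    for (p in (1:6) + (i - 1) * 6) {
      substr(nxt, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(nxt, p, p))[1]
    }
    chain <- c(chain, nxt)
  }
  expect_equal(length(isolate_clusters(chain)), 1L)
  expect_setequal(isolate_clusters(chain)[[1]], chain)
  # seven members only -> nothing emitted
  expect_equal(length(isolate_clusters(chain[1:7])), 0L)
  # two well-separated cliques -> two clusters
  set.seed(65)
  c1 <- c(base, mutants(base, 9, 1:3))
  other <- random_seq(200)
  c2 <- c(other, mutants(other, 9, 1:3))
  cl <- isolate_clusters(unique(c(c1, c2)))
  expect_equal(length(cl), 2L)
})

test_that("components match a brute-force transitive closure oracle", {
  set.seed(66)
  for (rep in 1:5) {
    parents <- replicate(3, random_seq(75))       # 0.04*75 -> <= 3 diffs
    seqs <- unique(unlist(lapply(parents, function(p)
      c(p, mutants(p, 40, 1:5)))))
    d <- jc69_matrix(seqs)
    adj <- d <= 0.04; diag(adj) <- FALSE
    labels <- components_oracle(adj)
    want <- split(seqs, labels)
    want <- lapply(unname(want[lengths(want) >= 8]), sort)
    got <- isolate_clusters(seqs)
    expect_setequal(lapply(got, paste, collapse = "|"),
                    lapply(want, paste, collapse = "|"))
  }
})

test_that("clusters touching week 0 are discarded", {
  tabs0 <- list(`0` = data.frame(sequence = "AAA", frequency = 3L),
                `1` = data.frame(sequence = c("AAA", "CCC"),
                                 frequency = c(2L, 5L)))
  ct <- build_chronology(tabs0, list())
  keep <- discard_preimmune(list(c("AAA", "TTT"), "CCC"), ct)
  expect_equal(keep, list("CCC"))
})

test_that("cluster IDs rank by maximum weekly summed frequency", {
  tabs <- list(`1` = data.frame(sequence = c("AAA", "CCC", "GGG"),
                                frequency = c(900L, 30L, 10L)),
               `2` = data.frame(sequence = c("CCC", "GGG"),
                                frequency = c(500L, 20L)))
  ct <- build_chronology(tabs, list())
  named <- assign_cluster_ids(list(c("CCC"), c("AAA"), c("GGG")), ct,
                              prefix = "Ig")
  expect_equal(names(named), c("Ig-1", "Ig-2", "Ig-3"))
  expect_equal(named[["Ig-1"]], "AAA")   # peak 900
  expect_equal(named[["Ig-2"]], "CCC")   # peak 500
})

test_that("neighbor joining recovers an additive four-taxon tree", {
  # build four sequences with block substitutions approximating additive
  # distances, then check the NJ split
  base <- strrep("ACGT", 100)             # 400 nt
  flip_block <- function(s, from, n) {
    for (p in from:(from + n - 1)) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  A <- base
  B <- flip_block(base, 1, 4)
  C <- flip_block(flip_block(base, 101, 12), 201, 4)
  D <- flip_block(flip_block(base, 101, 12), 301, 6)
  nwk <- build_nj_tree(c(A, B, C, D), labels = c("A", "B", "C", "D"))
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  # (A,B) vs (C,D) is the unique internal split
  dm <- ape::cophenetic.phylo(tr)
  expect_lt(dm["A", "B"], dm["A", "C"])
  expect_lt(dm["C", "D"], dm["B", "C"])
  # star tree for fewer than three members
  expect_match(build_nj_tree(c(A, B), labels = c("x", "y")),
               "^\\(x:0,y:0\\);$")
})

test_that("an unprotected singleton never changes emitted clusters", {
  set.seed(67)
  sim <- small_sim()
  res <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
  tabs <- sim$tables
  wk <- names(tabs)[3]
  extra <- vhhtrack:::random_coding_sequence(
    nchar(tabs[[wk]][["IgG2"]]$sequence[1]) / 3)
  tabs[[wk]][["IgG2"]] <- rbind(tabs[[wk]][["IgG2"]],
                                data.frame(sequence = extra,
                                           frequency = 1L))
  res2 <- analyze_tables(tabs, sim$db$v, sim$db$j)
  expect_equal(res2$clusters, res$clusters)
})
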