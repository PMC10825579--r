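# Small hand-built chronological table used across these tests:
# two isotypes, weeks 0..3, one "cluster" of three sequences.
make_fixture <- function() {
  g2 <- list(`0` = data.frame(sequence = "GGGG", frequency = 50L),
             `1` = data.frame(sequence = c("AAAA", "GGGG"),
                              frequency = c(80L, 20L)),
             `2` = data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                              frequency = c(30L, 60L, 10L)),
             `3` = data.frame(sequence = c("CCCC", "TTTT", "GGGG"),
                              frequency = c(20L, 70L, 10L)))
  g3 <- list(`0` = data.frame(sequence = "GGGG", frequency = 40L),
             `1` = data.frame(sequence = c("AAAA", "GGGG"),
                              frequency = c(10L, 30L)),
             `2` = data.frame(sequence = "GGGG", frequency = 40L),
             `3` = data.frame(sequence = "GGGG", frequency = 40L))
  ct <- build_chronology(g2, g3)
  germ <- data.frame(sequence = c("AAAA", "CCCC", "TTTT", "GGGG"),
                     v_gene = "IGHV1", v_raw = c(700L, 650L, 600L, 500L),
                     v_bitscore = c(500, 450, 400, 300),
                     j_gene = "IGHJ1", j_bitscore = 60,
                     unassigned = FALSE, stringsAsFactors = FALSE)
  list(ct = ct, germ = germ, members = c("AAAA", "CCCC", "TTTT"))
}

test_that("trajectory points carry first week, bit score, and isotype duplicity", {
  fx <- make_fixture()
  pts <- cluster_trajectory(fx$members, fx$ct, fx$germ)
  expect_equal(pts$first_week[pts$sequence == "CCCC"], 2L)
  # AAAA seen in both isotypes -> two points
  expect_equal(sum(pts$sequence == "AAAA"), 2L)
  expect_setequal(pts$isotype[pts$sequence == "AAAA"], c("IgG2", "IgG3"))
  expect_equal(unique(pts$v_bitscore[pts$sequence == "AAAA"]), 500)
  # weekly shares over all sequences of an isotype-week sum to 1
  full <- cluster_trajectory(unique(fx$ct$sequence), fx$ct, fx$germ)
  g2 <- full$isotype == "IgG2"
  expect_equal(sum(full$share_w2[g2]), 1)
  expect_equal(sum(full$share_w1[!g2]), 1)
})

test_that("the bit-score line reproduces collinear points exactly", {
  pts <- data.frame(first_week = c(0, 5, 10),
                    v_bitscore = c(500, 450, 400))
  fit <- fit_bitscore_line(pts)
  expect_equal(fit$slope, -10)
  expect_equal(fit$intercept, 500)
  expect_true(fit$defined)
})

test_that("the bit-score line equals the normal-equation oracle", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- sample(0:14, n, replace = TRUE)
    if (length(unique(x)) < 2) next
    y <- 500 - 8 * x + rnorm(n, 0, 25)
    fit <- fit_bitscore_line(data.frame(first_week = x, v_bitscore = y))
    want <- ols_oracle(x, y)
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
  }
})

test_that("a single-week cluster leaves the slope undefined", {
  fit <- fit_bitscore_line(data.frame(first_week = c(3, 3, 3),
                                      v_bitscore = c(400, 410, 390)))
  expect_false(fit$defined)
  expect_true(is.na(fit$slope))
})

test_that("turnover passes for rolling dominants and fails for static ones", {
  fx <- make_fixture()
  to <- turnover_index(fx$members, fx$ct)
  # dominants: w1 AAAA (90), w2 CCCC (60), w3 TTTT (70) - perfect turnover
  expect_equal(to$dominants$sequence, c("AAAA", "CCCC", "TTTT"))
  expect_equal(to$index, 1)
  expect_true(to$pass)
  # single dominant every week -> fail
  to2 <- turnover_index("GGGG", fx$ct)
  expect_false(to2$pass)
  expect_equal(length(unique(to2$dominants$sequence)), 1L)
  # cluster present in fewer than 3 weeks -> fail
  to3 <- turnover_index("TTTT", fx$ct)
  expect_false(to3$pass)
})

test_that("percentage appearance sums per-isotype occupancies", {
  fx <- make_fixture()
  # week 2: cluster holds 90/100 of IgG2 and 0/40 of IgG3
  expect_equal(percentage_appearance(fx$members, fx$ct, 2), 90)
  # week 1: 80/100 IgG2 + 10/40 IgG3 = 105
  expect_equal(percentage_appearance(fx$members, fx$ct, 1), 80 + 25)
  # absent week
  expect_equal(percentage_appearance(fx$members, fx$ct, 0), 0)
  # a cluster holding everything reaches 200
  expect_equal(percentage_appearance(unique(fx$ct$sequence), fx$ct, 2), 200)
  # pooled mode is capped at 100
  expect_equal(percentage_appearance(unique(fx$ct$sequence), fx$ct, 2,
                                     mode = "pooled"), 100)
  expect_equal(max_percentage_appearance(fx$members, fx$ct), 105)
})

test_that("hit calls are the conjunction of slope, intercept, and turnover", {
  fx <- make_fixture()
  clusters <- list(`C-1` = fx$members, `C-2` = "GGGG")
  pred <- predict_hits(clusters, fx$ct, fx$germ, intercept_threshold = 380)
  p1 <- pred[pred$cluster_id == "C-1", ]
  expect_true(p1$slope < 0 && p1$intercept > 380 && p1$turnover_pass)
  expect_true(p1$predicted_hit)
  p2 <- pred[pred$cluster_id == "C-2", ]
  expect_false(p2$predicted_hit)
  # conjunction invariant holds row-wise
  expect_equal(pred$predicted_hit,
               pred$slope_defined & pred$slope < 0 &
                 pred$intercept > 380 & pred$turnover_pass)
  # a high threshold flips the call
  pred2 <- predict_hits(clusters, fx$ct, fx$germ, intercept_threshold = 600)
  expect_false(any(pred2$predicted_hit))
})

test_that("hit calls are invariant to uniform depth scaling", {
  set.seed(82)
  sim <- small_sim()
  res <- analyze_tables(sim$tables, sim$db$v, sim$db$j)
  ct2 <- res$ct
  wcols <- paste0("freq_w", chrono_weeks(res$ct))
  ct2[wcols] <- lapply(ct2[wcols], function(x) x * 3L)
  ct2$max_freq <- ct2$max_freq * 3L
  attr(ct2, "weeks") <- chrono_weeks(res$ct)
  p1 <- predict_hits(res$clusters, res$ct, res$germ)
  p2 <- predict_hits(res$clusters, ct2, res$germ)
  expect_equal(p1, p2)
})
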