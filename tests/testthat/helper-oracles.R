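# Independent oracles used across the suite. These deliberately use
# naive brute-force formulations, not the package's own code paths.

random_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
         collapse = "")
}

# Hamming distance, naive R formulation.
hamming_oracle <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Brute-force modified-Mott: best substring by total (limit - p_err).
mott_oracle <- function(qual, limit) {
  p <- 10^(-qual / 10)
  sc <- limit - p
  n <- length(sc)
  best <- list(sum = 0, start = 0L, end = -1L)
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- sum(sc[i:j])
      if (s > best$sum) best <- list(sum = s, start = i, end = j)
    }
  }
  best
}

# Enumerate all gapless overlap offsets of f vs revcomp(r); best score.
overlap_oracle <- function(f, rc, mismatch_cost) {
  fv <- strsplit(f, "")[[1]]
  rv <- strsplit(rc, "")[[1]]
  nf <- length(fv); nr <- length(rv)
  best <- -Inf
  for (s in seq(-(nr - 1L), nf - 1L)) {
    lo <- max(1L, s + 1L); hi <- min(nf, s + nr)
    if (hi < lo) next
    fi <- lo:hi; ri <- fi - s
    m <- sum(fv[fi] == rv[ri])
    sc <- m - mismatch_cost * (length(fi) - m)
    best <- max(best, sc)
  }
  best
}

# Naive O(n*m) Smith-Waterman with affine gaps (full 3-matrix DP).
sw_oracle <- function(q, s, match, mismatch, gap_open, gap_ext) {
  qn <- utf8ToInt(q); sn <- utf8ToInt(s)
  n <- length(qn); m <- length(sn)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_ext,
                             H[i + 1, j] - gap_open - gap_ext)
      F[i + 1, j + 1] <- max(F[i, j + 1] - gap_ext,
                             H[i, j + 1] - gap_open - gap_ext)
      d <- H[i, j] + if (qn[i] == sn[j]) match else mismatch
      h <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      best <- max(best, h)
    }
  }
  best
}

# Connected components by transitive closure of a boolean adjacency
# matrix (repeated squaring until fixpoint).
components_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical component label: smallest reachable index
  apply(reach, 1L, function(r) min(which(r)))
}

# Closed-form OLS via normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1L], slope = beta[2L])
}

# Random sequence-frequency table whose sequences form loose mutation
# families (so the denoiser has real work to do).
random_family_table <- function(n_families = 5, len = 60) {
  seqs <- character(0); freqs <- integer(0)
  for (f in seq_len(n_families)) {
    parent <- random_seq(len)
    seqs <- c(seqs, parent)
    freqs <- c(freqs, sample(50:500, 1))
    for (k in seq_len(sample(3:8, 1))) {
      child <- parent
      for (p in sample.int(len, sample(1:4, 1))) {
        substr(child, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(child, p, p)), 1)
      }
      seqs <- c(seqs, child)
      freqs <- c(freqs, sample(1:10, 1))
    }
  }
  keep <- !duplicated(seqs)
  data.frame(sequence = seqs[keep], frequency = freqs[keep],
             stringsAsFactors = FALSE)
}

# Small simulated study shared by several test files.
small_sim <- function(seed = 11L, ...) {
  simulate_study(sim_config(seed = seed, weeks = 0:8, n_responding = 4L,
                            n_static = 4L, n_preimmune = 2L,
                            depth = 2000L, ...))
}
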