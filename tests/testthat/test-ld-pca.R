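test_that("ld_r2 is the squared dosage correlation over complete cases", {
  set.seed(7)
  x <- sample(0:2, 1000, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  y <- x
  y[1] <- (x[1] + 1L) %% 3L  # one flipped genotype
  g <- make_geno(cbind(x, y))
  # brute-force correlation oracle written out from the formula
  r_num <- sum((x - mean(x)) * (y - mean(y)))
  r_den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld_r2(g, 1, 2), (r_num / r_den)^2, tolerance = 1e-12)
  expect_equal(ld_r2(g, "rs1", "rs1"), 1.0)
  expect_equal(ld_r2(g, 1, 2), ld_r2(g, 2, 1))
})

test_that("independent SNPs show near-zero LD and monomorphic SNPs NA", {
  set.seed(8)
  g <- make_geno(cbind(rbinom(5000, 2, 0.3), rbinom(5000, 2, 0.3),
                       rep(1L, 5000)))
  expect_lt(ld_r2(g, 1, 2), 0.01)
  expect_true(is.na(ld_r2(g, 1, 3)))
})

test_that("ld_prune keeps independent SNPs and collapses duplicate blocks", {
  set.seed(9)
  ind <- vapply(1:5, function(j) rbinom(400, 2L, 0.3), integer(400))
  g <- make_geno(ind)
  expect_identical(ld_prune(g, 0.25), g$snps$snp_id)

  dup <- make_geno(cbind(ind[, 1], ind[, 1], ind[, 1], ind[, 1]))
  expect_identical(ld_prune(dup, 0.25), "rs1")
})

test_that("ld_prune agrees with an all-pairs window oracle and satisfies
           its own invariant on LD-blocked fixtures", {
  set.seed(10)
  spec <- simulation_spec(n_cases = 50, n_controls = 950, n_snps = 40,
                          maf = runif(40, 0.1, 0.5), baseline_risk = 0.05,
                          seed = 10)
  g <- simulate_cohort(spec)$genotypes
  for (src in c(3L, 17L, 30L))
    g <- inject_ld_block(g, src, 3, 0.95, seed = src)
  # restore genomic position order so blocks sit inside windows
  o <- order(g$snps$pos)
  g <- geno_matrix(g$dosage[, o], g$snps[o, ], g$samples)

  cfg <- list(r2 = 0.25, window = 10, step = 3)
  kept <- ld_prune(g, cfg$r2, cfg$window, cfg$step)

  # oracle: literal sliding-window, all-pairs, drop-later greedy
  p <- nrow(g$snps)
  keep <- rep(TRUE, p)
  starts <- unique(c(seq(1, max(p - cfg$window + 1, 1), cfg$step),
                     max(p - cfg$window + 1, 1)))
  for (s in starts) {
    win <- s:min(s + cfg$window - 1, p)
    for (i in win) for (j in win[win > i]) {
      if (!keep[i] || !keep[j]) next
      r2 <- ld_r2(g, i, j)
      if (!is.na(r2) && r2 > cfg$r2) keep[j] <- FALSE
    }
  }
  expect_identical(kept, g$snps$snp_id[keep])

  # invariant: no retained within-window pair above the threshold
  kidx <- match(kept, g$snps$snp_id)
  for (s in starts) {
    win <- kidx[kidx >= s & kidx <= s + cfg$window - 1]
    if (length(win) < 2) next
    for (i in seq_along(win)[-1]) {
      r2 <- ld_r2(g, win[i - 1], win[i])
      expect_false(!is.na(r2) && r2 > cfg$r2)
    }
  }
})

test_that("PC1 separates two simulated subpopulations", {
  set.seed(12)
  n <- 1000; p <- 500
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(p, 0.1, 0.35)
  f2 <- f1 + 0.15
  d <- matrix(0L, n, p)
  d[pop == 0, ] <- vapply(f1, function(q) rbinom(n / 2, 2L, q),
                          integer(n / 2))
  d[pop == 1, ] <- vapply(f2, function(q) rbinom(n / 2, 2L, q),
                          integer(n / 2))
  g <- make_geno(d)
  pcs <- compute_pcs(g, k = 2)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  expect_equal(colMeans(pcs), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
})

test_that("PCs are orthogonal, variance-ordered and permutation-invariant
           up to the sign convention", {
  set.seed(13)
  d <- vapply(runif(60, 0.1, 0.5), function(q) rbinom(300, 2L, q),
              integer(300))
  d[sample(length(d), 200)] <- NA  # exercise mean imputation
  g <- make_geno(d)
  k <- 4
  pcs <- compute_pcs(g, k = k)
  gram <- crossprod(pcs)
  expect_true(all(abs(gram[upper.tri(gram)]) < 1e-8 * gram[1, 1]))
  expect_true(all(diff(diag(gram)) <= 1e-8))

  perm <- sample(ncol(d))
  gp <- geno_matrix(g$dosage[, perm], g$snps[perm, ], g$samples)
  pcs_p <- compute_pcs(gp, k = k)
  for (j in seq_len(k))
    expect_true(max(abs(pcs[, j] - pcs_p[, j])) < 1e-8 ||
                  max(abs(pcs[, j] + pcs_p[, j])) < 1e-8)
})

test_that("degenerate PCA inputs error", {
  g <- make_geno(matrix(1L, 5, 3))  # identical rows, zero variance
  expect_error(compute_pcs(g, k = 1))
  set.seed(14)
  g2 <- make_geno(vapply(1:3, function(j) rbinom(10, 2L, 0.4), integer(10)))
  expect_error(compute_pcs(g2, k = 9), "rank")
})
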