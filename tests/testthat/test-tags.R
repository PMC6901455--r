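scan_row <- function(snp_id, pos, ap_p) {
  data.frame(snp_id = snp_id, pos = pos, ap_p = ap_p, significant = TRUE,
             stringsAsFactors = FALSE)
}

test_that("a high-LD block collapses to a single tag led by the smallest
           AP p-value", {
  # six same-gene SNPs in near-perfect LD, mimicking an IL23R-style block
  set.seed(61)
  base <- rbinom(3000, 2L, 0.15)
  g <- make_geno(matrix(base, ncol = 1), ids = "snpA", pos = 10)
  g <- inject_ld_block(g, 1, 5, 0.95, seed = 611)
  p <- c(8.24e-4, 1.13e-3, 8.56e-4, 4.94e-4, 3.00e-4, 3.31e-4)
  res <- scan_row(g$snps$snp_id, g$snps$pos, p)
  tags <- priority_prune(res, g, r2_threshold = 0.80)
  expect_identical(nrow(tags), 1L)
  expect_identical(tags$tag_snp, g$snps$snp_id[which.min(p)])
  expect_identical(tags$n_tagged, 5L)
  expect_identical(tags$ap_p_tag, 3.00e-4)
})

test_that("independent SNPs each become their own tag and ties break by
           position", {
  set.seed(62)
  g <- make_geno(vapply(1:4, function(j) rbinom(2000, 2L, 0.3),
                        integer(2000)))
  res <- scan_row(g$snps$snp_id, g$snps$pos, c(0.01, 0.002, 0.03, 0.004))
  tags <- priority_prune(res, g, 0.8)
  expect_identical(sort(tags$tag_snp), sort(res$snp_id))
  expect_true(all(tags$n_tagged == 0))

  dup <- make_geno(cbind(g$dosage[, 1], g$dosage[, 1]),
                   ids = c("late", "early"), pos = c(500, 100))
  res2 <- scan_row(c("late", "early"), c(500, 100), c(0.01, 0.01))
  tags2 <- priority_prune(res2, dup, 0.8)
  expect_identical(tags2$tag_snp, "early")
  expect_identical(tags2$tagged, "late")
})

test_that("priority pruning matches an independent oracle on random sets
           and keeps its invariants", {
  set.seed(63)
  for (rep in 1:6) {
    m <- sample(4:8, 1)
    base <- vapply(seq_len(m), function(j) rbinom(1500, 2L, 0.3),
                   integer(1500))
    # correlate a random subset pairwise by copying with noise
    for (j in seq_len(m)[-1]) if (runif(1) < 0.5) {
      src <- sample(j - 1, 1)
      keep <- rbinom(1500, 1, 0.95) == 1
      base[keep, j] <- base[keep, src]
    }
    g <- make_geno(base)
    pv <- signif(runif(m, 1e-5, 0.04), 3)
    res <- scan_row(g$snps$snp_id, g$snps$pos, pv)
    tags <- priority_prune(res, g, 0.8)

    r2mat <- outer(seq_len(m), seq_len(m),
                   Vectorize(function(a, b) ld_r2(g, a, b)))
    oracle <- priority_prune_oracle(g$snps$snp_id, pv, g$snps$pos,
                                    r2mat, 0.8)
    expect_identical(tags$tag_snp, vapply(oracle, `[[`, "", "tag"))
    expect_identical(lapply(strsplit(tags$tagged, ","),
                            function(x) x[nzchar(x)]),
                     unname(lapply(oracle, `[[`, "tagged")))

    # invariants: partition, tag p minimal within its block, tags untagged
    all_ids <- c(tags$tag_snp,
                 unlist(strsplit(tags$tagged[nzchar(tags$tagged)], ",")))
    expect_identical(sort(all_ids), sort(res$snp_id))
    for (i in seq_len(nrow(tags))) {
      members <- strsplit(tags$tagged[i], ",")[[1]]
      members <- members[nzchar(members)]
      if (length(members))
        expect_true(all(pv[match(members, g$snps$snp_id)] >=
                          tags$ap_p_tag[i]))
    }
    if (nrow(tags) > 1)
      for (i in seq_len(nrow(tags) - 1))
        for (j in (i + 1):nrow(tags)) {
          r2 <- ld_r2(g, tags$tag_snp[i], tags$tag_snp[j])
          expect_false(!is.na(r2) && r2 > 0.8)
        }
  }
})

test_that("locus labels restrict tagging and missing genotypes error", {
  set.seed(64)
  base <- rbinom(2000, 2L, 0.3)
  g <- make_geno(cbind(base, base), ids = c("a", "b"))
  res <- scan_row(c("a", "b"), c(100, 200), c(0.001, 0.002))
  loc <- c(a = "GENE1", b = "GENE2")
  tags <- priority_prune(res, g, 0.8, locus = loc)
  expect_identical(nrow(tags), 2L)  # perfect LD but different loci

  expect_error(priority_prune(scan_row("zz", 1, 0.01), g), "missing")
})
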