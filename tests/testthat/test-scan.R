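test_that("dominant coding collapses dosage to carrier status", {
  expect_identical(code_dominant(c(0L, 1L, 2L, NA)), c(0L, 1L, 1L, NA))
  expect_identical(code_dominant(rep(1L, 4)), rep(1L, 4))
  # recoding the coded allele turns a hom-carrier into a non-carrier
  expect_identical(code_dominant(2L - 2L), 0L)
  expect_error(code_dominant(c(0L, 3L)), "dosages")
})

test_that("compute_ap reproduces published worked examples and the
           additive null", {
  # printed ORs are themselves rounded to 2 d.p., so the recomputed AP can
  # move by up to one unit in the last printed digit
  ap <- compute_ap(table2_rows$or11, table2_rows$or01, table2_rows$or10)
  expect_true(all(abs(ap - table2_rows$ap_printed) <= 0.01 + 1e-12))
  expect_equal(round(compute_ap(2.06, 1.03, 1.00), 2), 0.50)
  expect_equal(compute_ap(1.5 + 2.0 - 1, 1.5, 2.0), 0)
  expect_equal(compute_ap(2.92, 1.18, 1.09), compute_ap(2.92, 1.09, 1.18))
  expect_error(compute_ap(-1, 1, 1), "or11")
})

test_that("crude combination fits equal closed-form 2x4 table ORs and the
           glm reference", {
  counts <- rbind(control = c(400, 250, 220, 130),
                  case = c(60, 55, 45, 80))
  ind <- expand_2x4(counts)
  fit <- fit_combination_model(ind$groups, ind$outcome)
  expect_true(fit$converged)
  expect_equal(unname(exp(fit$coef[c("g01", "g10", "g11")])),
               unname(crude_group_ors(counts)), tolerance = 1e-8)
  expect_identical(unname(fit$n_by_group), unname(as.integer(colSums(counts))))

  # formula-interface glm as an independent route to the same estimates
  ref <- glm(ind$outcome ~ ind$groups, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(vcov(ref)), tolerance = 1e-6)
})

test_that("null cohorts give coefficients near zero and empty cells are
           flagged, not fatal", {
  set.seed(31)
  spec <- simulation_spec(n_cases = 1000, n_controls = 3000, n_snps = 1,
                          maf = 0.3, or01 = 1, baseline_risk = 0.1,
                          sex_or = 1, age_or = 1, seed = 31)
  sim <- simulate_cohort(spec)
  grp <- combination_groups(code_dominant(sim$genotypes$dosage[, 1]),
                            sim$cohort$smoking_ever)
  y <- as.integer(sim$cohort$status == "LS")
  fit <- fit_combination_model(grp, y)
  se <- sqrt(diag(fit$vcov)[c("g01", "g10", "g11")])
  expect_true(all(abs(fit$coef[c("g01", "g10", "g11")]) < 3 * se))

  # zero carriers -> empty g10/g11 cells
  grp0 <- combination_groups(rep(0L, 400), rep(0:1, 200))
  fit0 <- fit_combination_model(grp0, rep(0:1, each = 200))
  expect_false(fit0$converged)
  expect_match(fit0$reason, "sparse")
})

test_that("delta-method AP inference matches its closed-form pieces", {
  b <- c(g01 = 0, g10 = 0, g11 = 0)
  V <- diag(1e-6, 3); dimnames(V) <- list(names(b), names(b))
  inf <- ap_inference(b, V)
  expect_equal(inf$ap, 0)
  expect_gt(inf$p, 0.99)

  # an AP of 0.56 with delta SE 0.17 must give the CI (0.22, 0.90) shape
  b <- c(g01 = log(1.18), g10 = log(1.09), g11 = log(2.92))
  V2 <- diag(c(0.1, 0.02, 0.075))
  dimnames(V2) <- list(names(b), names(b))
  inf <- ap_inference(b, V2)
  grad <- c(-exp(b[1] - b[3]), -exp(b[2] - b[3]), 1 - inf$ap)
  se_hand <- sqrt(drop(t(grad) %*% V2 %*% grad))
  expect_equal(inf$se, se_hand, tolerance = 1e-12)
  expect_equal(inf$ci, inf$ap + c(-1.96, 1.96) * se_hand, tolerance = 1e-12)
  # the printed-style interval: AP 0.56 with delta SE 0.17 -> (0.22, 0.90)
  expect_true(all(abs(0.56 + c(-1.96, 1.96) * 0.17 - c(0.22, 0.90)) < 0.01))

  V3 <- matrix(0, 3, 3, dimnames = list(names(b), names(b)))
  expect_false(ap_inference(b, V3)$ok)
})

test_that("bh_fdr matches hand-computable cases and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("run_scan output is internally consistent and deterministic", {
  spec <- simulation_spec(n_cases = 400, n_controls = 1200, n_snps = 30,
                          causal = 1:2, or01 = 1.2, or10 = 1.2,
                          ap_true = 0.6, baseline_risk = 0.08, seed = 41)
  sim <- simulate_cohort(spec)
  res <- run_scan(sim$genotypes, sim$cohort, "LS")
  res2 <- run_scan(sim$genotypes, sim$cohort, "LS")
  expect_identical(res, res2)

  conv <- res[res$converged, ]
  expect_gt(nrow(conv), 0)
  # Table-2-style internal consistency: ap recomputes from its own ORs
  expect_equal(conv$ap, compute_ap(conv$or11, conv$or01, conv$or10),
               tolerance = 1e-10)
  expect_true(all(conv$ap <= 1))
  expect_true(all(conv$or01 > 0 & conv$or10 > 0 & conv$or11 > 0))
  expect_equal(conv$fdr, bh_fdr(conv$ap_p), tolerance = 1e-12)
  expect_identical(attr(res, "fdr_family_size"), nrow(conv))
  expect_identical(unname(res$significant),
                   unname(res$converged & !is.na(res$ap) & res$ap > 0 &
                            res$ap_p < 0.05 & res$fdr < 0.05))
  # complete partition: group counts add to the analyzed sample count
  expect_true(all(rowSums(conv[, c("n00", "n01", "n10", "n11")]) ==
                    nrow(sim$cohort)))
})

test_that("degenerate scan designs are rejected with clear errors", {
  spec <- simulation_spec(n_cases = 50, n_controls = 150, n_snps = 3,
                          baseline_risk = 0.1, seed = 43)
  sim <- simulate_cohort(spec)
  expect_error(run_scan(sim$genotypes, sim$cohort, "non-LS"), "absent")

  co <- sim$cohort
  co$smoking_ever <- 1L  # constant exposure empties g00/g10
  expect_error(run_scan(sim$genotypes, co, "LS"), "no SNP")

  co2 <- sim$cohort[sample(nrow(sim$cohort)), ]
  expect_error(run_scan(sim$genotypes, co2, "LS"), "align")
})
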