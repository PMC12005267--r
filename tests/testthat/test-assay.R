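test_that("frequency and viability formulas are plain ratios with guards", {
  expect_equal(mutation_frequency(20, 2e7), 1e-6)
  expect_equal(mutation_frequency(0, 1e7), 0)
  expect_equal(mutation_frequency(75, 3e7), 2.5e-6)
  expect_error(mutation_frequency(5, 0), "viable_per_ml")
  expect_error(mutation_frequency(-1, 1e7), "canr_per_ml")

  expect_equal(viability_percent(5e6, 1e7), 50)
  expect_equal(viability_percent(1e7, 1e7), 100)
  expect_equal(viability_percent(3e6, 1e7), 30)
  expect_error(viability_percent(1e6, 0), "untreated_viable")
})

test_that("arm comparison reports median fold and a Mann-Whitney p", {
  res <- compare_arms(c(1, 2, 3) * 1e-7, c(2, 4, 6) * 1e-7)
  expect_equal(res$fold, 2.0)
  # complete separation at 3 vs 3: exact two-sided p = 2/20
  sep <- compare_arms(c(1, 2, 3), c(10, 20, 30))
  expect_equal(sep$p, 0.1)
  expect_equal(sep$p, brute_mw_two_sided(c(10, 20, 30), c(1, 2, 3)))

  same <- suppressWarnings(compare_arms(c(5, 6), c(5, 6)))
  expect_equal(same$fold, 1)
  expect_equal(same$p, 1)

  expect_error(compare_arms(numeric(), 1:3), "non-empty")
  expect_warning(compare_arms(c(1, 2), c(3, 4, 5)), "fewer than 3")
})

test_that("exact Mann-Whitney p equals rank-assignment enumeration", {
  set.seed(7)
  for (i in 1:30) {
    nx <- sample(3:6, 1)
    ny <- sample(3:6, 1)
    x <- round(rlnorm(nx), 6)
    y <- round(rlnorm(ny) * runif(1, 0.5, 3), 6)
    if (anyDuplicated(c(x, y))) next
    got <- suppressWarnings(compare_arms(x, y))$p
    expect_equal(got, brute_mw_two_sided(y, x), tolerance = 1e-12)
  }
})

test_that("arm exchange inverts the fold and preserves the p-value", {
  set.seed(17)
  u <- rlnorm(10, log(1e-7), 0.5)
  t <- rlnorm(10, log(2.5e-7), 0.5)
  a <- compare_arms(u, t)
  b <- compare_arms(t, u)
  expect_equal(a$fold, 1 / b$fold)
  expect_equal(a$p, b$p)
  # scale invariance: common rescaling changes neither fold nor p
  s <- compare_arms(u * 3.7e4, t * 3.7e4)
  expect_equal(s$fold, a$fold)
  expect_equal(s$p, a$p)
})

test_that("BH correction matches the literal step-up definition", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_error(bh_correct(c(0.5, 0)), "0, 1")
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")

  set.seed(23)
  p <- runif(50)
  q <- bh_correct(p)
  expect_equal(q, brute_bh(p))
  expect_true(all(q >= p))
  # monotone in sorted p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("genotype-level frequency analysis folds and adjusts across the call", {
  assay <- rbind(
    data.frame(genotype = "WT", treatment = rep(c("untreated", "treated"), each = 3),
               canr_per_ml = c(10, 11, 12, 10, 12, 14), viable_per_ml = 1e7),
    data.frame(genotype = "rad1", treatment = rep(c("untreated", "treated"), each = 3),
               canr_per_ml = c(10, 11, 12, 30, 33, 36), viable_per_ml = 1e7)
  )
  res <- suppressWarnings(frequency_analysis(assay))
  expect_equal(res$fold[res$genotype == "rad1"], 3.0)
  expect_equal(res$median_untreated[res$genotype == "rad1"], 1.1e-6)
  expect_equal(res$q, brute_bh(res$p))
})

test_that("viability analysis supports both comparison baselines", {
  assay <- rbind(
    data.frame(genotype = "WT", treatment = rep(c("untreated", "treated"), each = 4),
               canr_per_ml = 1,
               viable_per_ml = c(1e7, 1.1e7, 0.9e7, 1e7,
                                 0.99e7, 1.02e7, 0.97e7, 1.01e7)),
    data.frame(genotype = "rad1", treatment = rep(c("untreated", "treated"), each = 4),
               canr_per_ml = 1,
               viable_per_ml = c(1e7, 1.05e7, 0.95e7, 1e7,
                                 4.4e6, 4.5e6, 4.3e6, 4.6e6))
  )
  vs_wt <- viability_analysis(assay, compare = "wildtype", wildtype = "WT")
  expect_true(is.na(vs_wt$p[vs_wt$genotype == "WT"]))
  expect_equal(vs_wt$median_viability[vs_wt$genotype == "rad1"], 44.5)
  expect_lt(vs_wt$p[vs_wt$genotype == "rad1"], 0.05)

  vs_un <- viability_analysis(assay, compare = "untreated")
  expect_false(anyNA(vs_un$p))
  expect_lt(vs_un$p[vs_un$genotype == "rad1"], 0.05)
  expect_error(viability_analysis(assay, wildtype = "nope"), "not present")
})

test_that("delta-delta-Ct folds are 2^-ddCt with condition-matched baselines", {
  ct <- data.frame(
    sample = c("WT", "tetPOL2", "tetPOL3", "WT", "tetPOL2"),
    condition = c("plain", "plain", "plain", "dox", "dox"),
    target_ct = c(20, 20, 23, 20, 24),
    reference_ct = c(18, 18, 19, 18, 18)
  )
  res <- ddct_fold(ct, wildtype = "WT")
  get <- function(s, cond) res$fold[res$sample == s & res$condition == cond]
  expect_equal(get("WT", "plain"), 1)        # ddCt 0
  expect_equal(get("tetPOL2", "plain"), 1)   # ddCt 0
  expect_equal(get("tetPOL3", "plain"), 0.25)  # ddCt +2
  expect_equal(get("tetPOL2", "dox"), 0.0625)  # ddCt +4
  # ddCt -2 -> fold 4
  ct2 <- data.frame(sample = c("WT", "up"), condition = "plain",
                    target_ct = c(22, 20), reference_ct = c(18, 18))
  expect_equal(ddct_fold(ct2)$fold[2], 4)
  # ddCt +1 -> fold 0.5
  ct3 <- data.frame(sample = c("WT", "down"), condition = "plain",
                    target_ct = c(20, 21), reference_ct = c(18, 18))
  expect_equal(ddct_fold(ct3)$fold[2], 0.5)

  unpaired <- data.frame(sample = "tetPOL2", condition = "dox",
                         target_ct = 20, reference_ct = 18)
  expect_error(ddct_fold(unpaired), "no matched wild-type")
})
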