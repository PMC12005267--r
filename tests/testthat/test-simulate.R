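test_that("simulated genomes are reproducible with the requested composition", {
  g1 <- gen_genome(1, 10000, 0.38, seed = 7)
  g2 <- gen_genome(1, 10000, 0.38, seed = 7)
  expect_identical(unclass(g1), unclass(g2))
  expect_false(identical(unclass(gen_genome(1, 10000, 0.38, seed = 8)),
                         unclass(g1)))

  g <- gen_genome(2, 500, 0.5, seed = 1)
  expect_equal(unname(contig_lengths(g)), c(500L, 500L))

  big <- gen_genome(1, 1e5, 0.38, seed = 3)
  chars <- strsplit(unclass(big)[[1]], "")[[1]]
  gc <- mean(chars %in% c("C", "G"))
  expect_gte(gc, 0.36)
  expect_lte(gc, 0.40)

  expect_error(gen_genome(1, 50), "length_per_contig")
  expect_error(gen_genome(1, 1000, 0), "gc_fraction")
  expect_error(gen_genome(0, 1000), "n_contigs")
})

test_that("spiked cohorts respect their ground-truth contract", {
  g <- gen_genome(1, 20000, seed = 5)
  idx <- context_index(g)
  mu <- spike_mutations(g, n_samples = 3, n_mutations = 100, frac_c_to_a = 0.6,
                        target_enrichment = 2, seed = 6, index = idx)
  # determinism
  mu2 <- spike_mutations(g, n_samples = 3, n_mutations = 100, frac_c_to_a = 0.6,
                         target_enrichment = 2, seed = 6, index = idx)
  expect_equal(mu, mu2)
  # per-sample position disjointness and genome-matching refs
  for (s in unique(mu$sample)) {
    sub <- mu[mu$sample == s, ]
    expect_equal(nrow(sub), 100L)
    expect_false(anyDuplicated(paste(sub$contig, sub$pos)) > 0)
  }
  expect_silent(validate_mutations(mu, g))
  expect_true(all(mu$vaf == 1))
  # truth labels agree with the classifier
  cls <- classify_sbs(g, mu)
  expect_false(any(cls$skipped))
  expect_equal(cls$klass, mu$truth_klass)
  sig_ctx <- substr(cls$context, 1, 1) == "g" & cls$klass == "C>A"
  expect_equal(sig_ctx, mu$truth_signature)

  # target 0: the signature class is completely absent
  mu0 <- spike_mutations(g, n_mutations = 200, target_enrichment = 0,
                         seed = 9, index = idx)
  cls0 <- classify_sbs(g, mu0)
  expect_equal(sum(substr(cls0$context, 1, 1) == "g"), 0L)

  # infeasible requests fail loudly
  tiny <- gen_genome(1, 120, seed = 10)
  expect_error(spike_mutations(tiny, n_mutations = 5000, seed = 1),
               "more mutations requested")
})

test_that("contamination returns exact fate labels that curation reproduces", {
  g <- gen_genome(1, 30000, seed = 15)
  idx <- context_index(g)
  mu <- spike_mutations(g, n_samples = 4, n_mutations = 60, seed = 16,
                        index = idx)
  ct <- contaminate(mu, g, n_preexisting = 5, n_shared_pairs = 4,
                    frac_low_vaf = 0.1, seed = 17)
  res <- curate(ct$mutations, ct$baseline)
  expect_equal(unlist(res$report), unlist(ct$report))
  # the kept set is exactly the records labeled kept
  truth_kept <- ct$mutations[ct$mutations$truth == "kept", ]
  expect_setequal(paste(res$mutations$sample, res$mutations$contig,
                        res$mutations$pos, res$mutations$alt),
                  paste(truth_kept$sample, truth_kept$contig, truth_kept$pos,
                        truth_kept$alt))
  # baseline injections are removed from every carrier
  expect_equal(ct$report$n_preexisting_baseline, 5L)
  # 4 injected pairs contribute 8 shared records; accidental cross-sample
  # duplicates in the base cohort may add more
  expect_gte(ct$report$n_shared, 8L)

  # zero contamination on a collision-free cohort: curation is the identity
  disjoint <- rbind(mk_muts("S1", "c1", seq(10L, 100L, 10L), "C", "A"),
                    mk_muts("S2", "c1", seq(15L, 105L, 10L), "C", "A"))
  gd <- as_genome(c(c1 = paste(rep("C", 200), collapse = "")))
  clean <- contaminate(disjoint, gd, seed = 18)
  expect_true(all(clean$mutations$truth == "kept"))
  res2 <- curate(clean$mutations, clean$baseline)
  expect_equal(res2$report$n_kept, nrow(disjoint))
  # and on the spiked cohort, curation always reproduces the truth labels
  res3 <- curate(contaminate(mu, g, seed = 19)$mutations,
                 contaminate(mu, g, seed = 19)$baseline)
  expect_equal(res3$report$n_kept, sum(contaminate(mu, g, seed = 19)$mutations$truth == "kept"))
})

test_that("low-VAF contamination hits the requested fraction of records", {
  g <- gen_genome(1, 60000, seed = 25)
  mu <- spike_mutations(g, n_samples = 2, n_mutations = 500, seed = 26)
  ct <- contaminate(mu, g, frac_low_vaf = 0.1, seed = 27)
  n_low <- sum(ct$mutations$truth == "low_vaf")
  # binomial(1000, 0.1) within 3 sigma
  expect_gt(n_low, 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(n_low, 100 + 3 * sqrt(1000 * 0.1 * 0.9))
  expect_true(all(ct$mutations$vaf[ct$mutations$truth == "low_vaf"] < 0.9))
})

test_that("simulated assays encode the configured fold and viability drop", {
  a <- simulate_assay(seed = 3)
  expect_identical(a, simulate_assay(seed = 3))
  expect_equal(nrow(a), 24L)
  expect_setequal(unique(a$treatment), c("untreated", "treated"))
  expect_true(all(a$viable_per_ml > 0))
  expect_true(all(a$canr_per_ml >= 0))

  # with noise off, the encoded fold is recovered exactly up to Poisson noise
  quiet <- simulate_assay(n_per_arm = 200, lognormal_sigma = 0,
                          viable_sigma = 0, base_frequency = 1e-5,
                          true_fold = 2.5, seed = 4)
  res <- frequency_analysis(quiet)
  expect_equal(res$fold, 2.5, tolerance = 0.1)
  expect_error(simulate_assay(viability_drop = 1.2), "viability_drop")
  expect_error(simulate_assay(n_per_arm = 0), "n_per_arm")
})
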