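test_that("substitutions collapse to pyrimidine classes with correct contexts", {
  g <- as_genome(c(c1 = "TAGCATG"))
  # G>T at pos 3 has plus context aGc; collapsed: C>A in gCt
  r1 <- classify_sbs(g, mk_muts("S1", "c1", 3L, "G", "T"))
  expect_identical(r1$klass, "C>A")
  expect_identical(r1$context, "gCt")
  expect_false(r1$skipped)
  # C>A at pos 4 (context gCa) stays as is
  r2 <- classify_sbs(g, mk_muts("S1", "c1", 4L, "C", "A"))
  expect_identical(r2$klass, "C>A")
  expect_identical(r2$context, "gCa")
  # T>C with context aTg
  g2 <- as_genome(c(c1 = "CATGC"))
  r3 <- classify_sbs(g2, mk_muts("S1", "c1", 3L, "T", "C"))
  expect_identical(r3$klass, "T>C")
  expect_identical(r3$context, "aTg")
})

test_that("unclassifiable records are flagged and mismatches are errors", {
  g <- as_genome(c(c1 = "ACNTA"))
  edge <- classify_sbs(g, mk_muts("S1", "c1", 1L, "A", "T"))
  expect_true(edge$skipped)
  near_n <- classify_sbs(g, mk_muts("S1", "c1", 2L, "C", "A"))
  expect_true(near_n$skipped)
  expect_error(classify_sbs(g, mk_muts("S1", "c1", 2L, "G", "A")),
               "reference mismatch")
  expect_error(classify_sbs(g, mk_muts("S1", "c1", 9L, "A", "T")),
               "off contig")
})

test_that("spectra collapse strands and report cohort means", {
  g <- as_genome(c(c1 = "TAGCATGCAT"))
  # C>A at pos 4 and G>T at pos 3 are both C>A after collapse
  m <- rbind(mk_muts("S1", "c1", 4L, "C", "A"), mk_muts("S1", "c1", 3L, "G", "T"))
  sp <- mutation_spectrum(g, m)
  expect_equal(sp$classes["C>A", "S1"], 2L)
  expect_equal(sum(sp$classes), 2L)
  expect_equal(sum(sp$contexts), 2L)

  two <- rbind(mk_muts("S1", "c1", c(4L, 8L), "C", "A"),
               mk_muts("S1", "c1", 3L, "G", "T"),
               mk_muts("S2", "c1", 4L, "C", "A"))
  sp2 <- mutation_spectrum(g, two)
  expect_equal(unname(sp2$cohort_mean["C>A"]), 2.0)
})

test_that("spectrum class totals match a brute-force recount on random cohorts", {
  g <- gen_genome(2, 5000, 0.45, seed = 8)
  idx <- context_index(g)
  mu <- spike_mutations(g, n_samples = 2, n_mutations = 250, frac_c_to_a = 0.3,
                        seed = 9, index = idx)
  sp <- mutation_spectrum(g, mu)
  for (s in colnames(sp$classes)) {
    ref <- brute_spectrum_classes(g, mu[mu$sample == s, ])
    expect_equal(sp$classes[, s], ref$counts, ignore_attr = TRUE)
    expect_equal(unname(sp$skipped[s]), ref$skipped)
    # conservation: classified + skipped = input
    expect_equal(sum(sp$classes[, s]) + sp$skipped[s],
                 sum(mu$sample == s), ignore_attr = TRUE)
    # class totals equal context totals
    expect_equal(sum(sp$contexts[, s]), sum(sp$classes[, s]))
  }
})

test_that("window counts follow the documented conventions on tiny contigs", {
  # all A/T window
  g <- as_genome(c(c1 = "ATATATAT"))
  wc <- window_counts(g, "c1", 4L)
  expect_equal(wc$n_cyt, 0)
  expect_equal(wc$n_gcn, 0)
  # 'GCA': plus C at 2 is gCn (5' G); minus C at 1 (plus G) has 5' g via the
  # plus C at 2; both cytosines are motif cytosines
  wc2 <- window_counts(as_genome(c(c1 = "GCA")), "c1", 2L)
  expect_equal(wc2$n_cyt, 2)
  expect_equal(wc2$n_gcn, 2)
  expect_error(window_counts(g, "c1", 99L), "off contig")
  expect_error(window_counts(g, "nope", 1L), "unknown contig")
})

test_that("window counts equal the literal two-strand oracle on random draws", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(30:200, 1)
    gc <- runif(1, 0.2, 0.7)
    g <- gen_genome(1, max(n, 100), gc, seed = i)
    pos <- sample.int(contig_lengths(g)[[1]], 1)
    w <- sample(c(3L, 10L, 20L), 1)
    got <- window_counts(g, "contig_1", pos, window = w)
    want <- brute_window_counts(g, "contig_1", pos, window = w)
    expect_equal(got$n_cyt, unname(want["n_cyt"]))
    expect_equal(got$n_gcn, unname(want["n_gcn"]))
    # invariants: motif count within target count, bounded by window size
    expect_lte(got$n_gcn, got$n_cyt)
    expect_lte(got$n_cyt, 2 * w + 2)
  }
})

test_that("window counts never decrease when the window grows", {
  g <- gen_genome(1, 2000, seed = 55)
  pos <- c(1L, 2L, 500L, 1999L, 2000L)
  prev <- window_counts(g, "contig_1", pos, window = 0L)
  for (w in c(1L, 5L, 20L, 100L)) {
    cur <- window_counts(g, "contig_1", pos, window = w)
    expect_true(all(cur$n_cyt >= prev$n_cyt))
    expect_true(all(cur$n_gcn >= prev$n_gcn))
    prev <- cur
  }
})

test_that("spectra and window counts are invariant under strand flip", {
  g <- gen_genome(1, 3000, seed = 12)
  idx <- context_index(g)
  mu <- spike_mutations(g, n_mutations = 120, frac_c_to_a = 0.5, seed = 13,
                        index = idx)
  n <- contig_lengths(g)[[1]]
  flipped <- as_genome(c(contig_1 = paste(
    rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
      strsplit(unclass(g)[[1]], "")[[1]]])), collapse = "")))
  mu_f <- mu
  mu_f$pos <- n - mu$pos + 1L
  mu_f$ref <- unname(c(A = "T", C = "G", G = "C", T = "A")[mu$ref])
  mu_f$alt <- unname(c(A = "T", C = "G", G = "C", T = "A")[mu$alt])

  sp <- mutation_spectrum(g, mu)
  sp_f <- mutation_spectrum(flipped, mu_f)
  expect_equal(sp$classes, sp_f$classes)
  expect_equal(sp$contexts, sp_f$contexts)

  wc <- window_counts(g, "contig_1", mu$pos)
  wc_f <- window_counts(flipped, "contig_1", mu_f$pos)
  expect_equal(wc, wc_f)
})

test_that("generic central-pyrimidine motifs are supported", {
  # tCw: APOBEC-style context; check against a direct scan
  g <- as_genome(c(c1 = "ATCAGTCTA"))
  idx <- context_index(g, motif = "tCw")
  # plus strand: C at 3 (t_C_a: match), C at 7 (t_C_t: match)
  # minus strand: G at 5 -> minus C, flanks minus 5'=comp(plus 6)=A: no match
  expect_equal(sum(idx$contigs$c1$sig_ind), 2)
  expect_error(trimspect:::parse_motif("xCn"), "IUPAC")
  expect_error(trimspect:::parse_motif("gAn"), "pyrimidine")
  expect_error(trimspect:::parse_motif("gC"), "3-character")
})
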