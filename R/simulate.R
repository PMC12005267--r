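# synthetic-data generators: signature-spiked mutation cohorts, contaminated
# variant tables, and colony-count plating assays, all with ground truth

#' Spike synthetic mutation cohorts with a trinucleotide signature
#'
#' Places single-nucleotide substitutions on a genome with a controllable
#' excess of target-class changes (default C>A) in the motif context (default
#' `gCn`). `target_enrichment` is expressed on the scale of the windowed
#' enrichment statistic itself: the generator computes, for every candidate
#' cytosine (both strands), the motif and target-base content of its
#' +/-`window` bp background, and solves for the motif-placement probability
#' whose expected [enrichment()] equals the target. `target_enrichment = 1`
#' is the null, `0` places no motif-context mutations at all.
#'
#' Non-target-class mutations are placed uniformly on appropriate bases
#' according to `background_classes`. All records carry `vaf = 1`; positions
#' are disjoint within a sample; contig-edge positions (which cannot be
#' classified) are never used.
#'
#' @param genome a genome object with at least one motif and one non-motif
#'   candidate base.
#' @param n_samples number of isolates to simulate.
#' @param n_mutations substitutions per isolate.
#' @param frac_c_to_a fraction of each isolate's mutations that are
#'   target-class (C>A) changes.
#' @param target_enrichment desired windowed signature enrichment (>= 0).
#' @param background_classes named weights over the five non-target pyrimidine
#'   classes.
#' @param seed integer seed; fixed seed reproduces the cohort exactly.
#' @param placement `"calibrated"` (default) draws motif-context sites with
#'   the probability solved from `target_enrichment`; `"uniform"` ignores
#'   `target_enrichment` and places target-class mutations uniformly over all
#'   candidate bases in proportion to their abundance (the classical null of
#'   an unbiased mutagen).
#' @param window,motif,alt,index as in [build_table()].
#' @return a mutation table with truth columns `truth_klass` (the pyrimidine
#'   class each record was spiked as) and `truth_signature` (whether a
#'   target-class record was placed on a motif-context base). The realized
#'   motif-placement probability is attached as attribute `"placement_p"`.
#' @examples
#' g <- gen_genome(1, 5000, seed = 1)
#' mu <- spike_mutations(g, n_mutations = 100, target_enrichment = 2, seed = 2)
#' table(mu$truth_klass)
#' @export
spike_mutations <- function(genome, n_samples = 1L, n_mutations = 500L,
                            frac_c_to_a = 1, target_enrichment = 1,
                            background_classes = NULL, seed = 1L,
                            placement = c("calibrated", "uniform"),
                            window = 20L, motif = "gCn", alt = "A",
                            index = NULL) {
  placement <- match.arg(placement)
  genome <- as_genome(genome)
  if (!(frac_c_to_a >= 0 && frac_c_to_a <= 1)) {
    stop_("frac_c_to_a must lie in [0, 1]")
  }
  if (target_enrichment < 0) stop_("target_enrichment must be >= 0")
  if (is.null(index)) index <- context_index(genome, motif)
  mt <- index$motif
  alt <- toupper(alt)

  pool <- .candidate_pool(genome, index)
  if (!any(pool$sig) || all(pool$sig)) {
    stop_("genome must contain both motif and non-motif candidate bases")
  }
  p_motif <- if (placement == "uniform") mean(pool$sig) else {
    .calibrate_placement(index, pool, target_enrichment, window)
  }

  other_classes <- setdiff(SBS_CLASSES, paste0(mt$center, ">", alt))
  if (is.null(background_classes)) {
    background_classes <- stats::setNames(rep(1, 5L), other_classes)
  }
  if (!all(names(background_classes) %in% other_classes)) {
    stop_("background_classes names must be among: ",
          paste(other_classes, collapse = ", "))
  }
  w_bg <- stats::setNames(rep(0, 5L), other_classes)
  w_bg[names(background_classes)] <- background_classes

  # pools of plus-strand positions by (collapsed) center base, edges excluded
  pyr_pool <- list(C = pool, T = .base_pool(genome, "T"))
  n_target <- round(n_mutations * frac_c_to_a)
  n_bg <- n_mutations - n_target

  with_seed(seed, {
    recs <- lapply(seq_len(n_samples), function(si) {
      .spike_one(genome, paste0("S", si), pyr_pool, mt, alt, n_target, n_bg,
                 p_motif, w_bg)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "placement_p") <- p_motif
    attr(out, "target_enrichment") <- target_enrichment
    out
  })
}

# candidates the classifier can use: interior positions with an N-free
# trinucleotide; `key` identifies the site for within-sample disjointness
.candidate_pool <- function(genome, index) {
  do.call(rbind, lapply(names(index$contigs), function(cn) {
    ci <- index$contigs[[cn]]
    idx <- which(ci$all_ind)
    idx <- idx[idx > 1L & idx < ci$n]
    ok <- ci$chars[idx - 1L] != "N" & ci$chars[idx] != "N" &
      ci$chars[idx + 1L] != "N"
    idx <- idx[ok]
    data.frame(contig = rep(cn, length(idx)), pos = idx,
               sig = ci$sig_ind[idx], base = ci$chars[idx],
               key = paste(cn, idx), stringsAsFactors = FALSE)
  }))
}

.base_pool <- function(genome, center) {
  comp <- comp_base(center)
  len <- contig_lengths(genome)
  do.call(rbind, lapply(names(len), function(cn) {
    chars <- strsplit(unclass(genome)[[cn]], "", fixed = TRUE)[[1L]]
    idx <- which(chars == center | chars == comp)
    idx <- idx[idx > 1L & idx < length(chars)]
    ok <- chars[idx - 1L] != "N" & chars[idx + 1L] != "N"
    idx <- idx[ok]
    data.frame(contig = rep(cn, length(idx)), pos = idx,
               sig = FALSE, base = chars[idx], key = paste(cn, idx),
               stringsAsFactors = FALSE)
  }))
}

# solve for the motif-placement probability whose expected windowed
# enrichment equals the target; quadratic in p from
#   p * (p*CM + (1-p)*CN) = E * (p*GM + (1-p)*GN)
.calibrate_placement <- function(index, pool, E, window) {
  if (E == 0) return(0)
  ws <- do.call(rbind, lapply(unique(pool$contig), function(cn) {
    ci <- index$contigs[[cn]]
    rows <- pool$contig == cn
    data.frame(sig = pool$sig[rows],
               g = .wsum(ci$cum_sig, pool$pos[rows], as.integer(window)),
               c = .wsum(ci$cum_all, pool$pos[rows], as.integer(window)))
  }))
  GM <- mean(ws$g[ws$sig]); GN <- mean(ws$g[!ws$sig])
  CM <- mean(ws$c[ws$sig]); CN <- mean(ws$c[!ws$sig])
  a <- CM - CN
  b <- CN - E * (GM - GN)
  cc <- -E * GN
  p <- if (abs(a) < 1e-12) -cc / b else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) NA_real_ else {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      roots <- roots[roots >= 0 & roots <= 1]
      if (length(roots)) roots[1L] else NA_real_
    }
  }
  if (!is.finite(p) || p < 0 || p > 1) {
    stop_("target_enrichment ", E,
          " is not attainable on this genome (required motif-placement ",
          "probability outside [0, 1])")
  }
  p
}

.spike_one <- function(genome, sample_id, pyr_pool, mt, alt, n_target, n_bg,
                       p_motif, w_bg) {
  used <- character()
  draw <- function(cand, n) {
    if (n == 0L) return(cand[0L, , drop = FALSE])
    avail <- cand[!(cand$key %in% used), , drop = FALSE]
    if (nrow(avail) < n) {
      stop_("more mutations requested than available positions (need ", n,
            ", have ", nrow(avail), ")")
    }
    sel <- avail[sample.int(nrow(avail), n), , drop = FALSE]
    used <<- c(used, sel$key)
    sel
  }
  rec_from <- function(sel, klass, signature) {
    if (nrow(sel) == 0L) return(NULL)
    center <- substr(klass, 1, 1)
    to <- substr(klass, 3, 3)
    plus <- sel$base == center
    ref <- ifelse(plus, center, comp_base(center))
    alt_b <- ifelse(plus, to, comp_base(to))
    cbind(.new_mutation_table(sample_id, sel$contig, sel$pos, ref, alt_b, 1),
          truth_klass = klass, truth_signature = signature)
  }
  target_klass <- paste0(mt$center, ">", alt)
  k_motif <- stats::rbinom(1L, n_target, p_motif)
  cpool <- pyr_pool[[mt$center]]
  out <- list(
    rec_from(draw(cpool[cpool$sig, , drop = FALSE], k_motif),
             target_klass, TRUE),
    rec_from(draw(cpool[!cpool$sig, , drop = FALSE], n_target - k_motif),
             target_klass, FALSE)
  )
  if (n_bg > 0L) {
    counts <- as.integer(stats::rmultinom(1L, n_bg, w_bg))
    names(counts) <- names(w_bg)
    for (kl in names(counts)) {
      if (counts[[kl]] == 0L) next
      center <- substr(kl, 1, 1)
      pl <- pyr_pool[[center]]
      out <- c(out, list(rec_from(draw(pl, counts[[kl]]), kl, FALSE)))
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Contaminate a mutation cohort with preexisting and sub-threshold variants
#'
#' Exercises the curation rules with known ground truth: injects novel keys
#' that are present in the baseline culture (one random carrier sample each),
#' duplicates novel keys across random sample pairs, and assigns a
#' sub-threshold VAF (uniform on 0.3-0.89) to a random fraction of the
#' original records. Every returned record carries a `truth` label giving the
#' fate [curate()] should assign it, including records of the input cohort
#' that happen to share a key across samples by construction.
#'
#' @param mutations a clean mutation table (e.g. from [spike_mutations()]).
#' @param genome the genome the records live on (injected records take their
#'   reference base from it).
#' @param n_preexisting number of baseline-resident keys to inject.
#' @param n_shared_pairs number of novel keys to duplicate across a random
#'   pair of samples.
#' @param frac_low_vaf fraction of original records given a VAF below 0.9.
#' @param seed integer seed.
#' @return a list with `mutations` (contaminated table with column `truth`
#'   in `kept`/`low_vaf`/`baseline`/`shared`), `baseline` (the baseline
#'   culture's table) and `report` (the `filter_report` that a correct
#'   curation must produce).
#' @export
contaminate <- function(mutations, genome, n_preexisting = 0L,
                        n_shared_pairs = 0L, frac_low_vaf = 0, seed = 1L) {
  genome <- as_genome(genome)
  samples <- unique(mutations$sample)
  if (n_shared_pairs > 0L && length(samples) < 2L) {
    stop_("shared-pair injection needs at least 2 samples")
  }
  if (!(frac_low_vaf >= 0 && frac_low_vaf <= 1)) {
    stop_("frac_low_vaf must lie in [0, 1]")
  }
  with_seed(seed, {
    out <- mutations
    out$truth <- "kept"
    n <- nrow(out)
    low <- stats::runif(n) < frac_low_vaf
    out$vaf[low] <- stats::runif(sum(low), 0.3, 0.89)
    out$truth[low] <- "low_vaf"

    # accidental sharing inside the input cohort (precedence: VAF first)
    key <- .mut_key(out)
    ok <- out$truth == "kept"
    carriers <- tapply(out$sample[ok], key[ok], function(s) length(unique(s)))
    acc <- names(carriers)[carriers >= 2L]
    out$truth[ok & key %in% acc] <- "shared"

    novel <- .novel_keys(genome, out, n_preexisting + n_shared_pairs)
    base_keys <- utils::head(novel, n_preexisting)
    share_keys <- utils::tail(novel, n_shared_pairs)

    baseline <- if (n_preexisting > 0L) {
      cbind(.new_mutation_table("baseline", base_keys$contig, base_keys$pos,
                                base_keys$ref, base_keys$alt, 1))
    } else {
      .new_mutation_table(character(), character(), integer(), character(),
                          character(), numeric())
    }
    inject <- list()
    if (n_preexisting > 0L) {
      carrier <- sample(samples, n_preexisting, replace = TRUE)
      inj <- .new_mutation_table(carrier, base_keys$contig, base_keys$pos,
                                 base_keys$ref, base_keys$alt, 1)
      inj$truth <- "baseline"
      inject <- c(inject, list(inj))
    }
    if (n_shared_pairs > 0L) {
      for (i in seq_len(n_shared_pairs)) {
        pair <- sample(samples, 2L)
        inj <- .new_mutation_table(pair, share_keys$contig[i],
                                   share_keys$pos[i], share_keys$ref[i],
                                   share_keys$alt[i], 1)
        inj$truth <- "shared"
        inject <- c(inject, list(inj))
      }
    }
    extra_cols <- setdiff(names(out), c(MUTATION_COLS, "truth"))
    inject <- lapply(inject, function(d) {
      for (col in extra_cols) d[[col]] <- NA
      d[, names(out)]
    })
    res <- do.call(rbind, c(list(out), inject))
    rownames(res) <- NULL
    report <- new_filter_report(nrow(res), sum(res$truth == "low_vaf"),
                                sum(res$truth == "baseline"),
                                sum(res$truth == "shared"),
                                sum(res$truth == "kept"))
    list(mutations = res, baseline = baseline, report = report)
  })
}

.novel_keys <- function(genome, mutations, n) {
  if (n == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  len <- contig_lengths(genome)
  taken <- paste(mutations$contig, mutations$pos)
  picked <- NULL
  tries <- 0L
  while ((is.null(picked) || nrow(picked) < n) && tries < 50L) {
    tries <- tries + 1L
    cn <- sample(names(len), n, replace = TRUE, prob = len / sum(len))
    pos <- vapply(len[cn], function(L) sample.int(L - 2L, 1L) + 1L, integer(1))
    ref <- substring(unclass(genome)[cn], pos, pos)
    cand <- data.frame(contig = cn, pos = pos, ref = ref,
                       stringsAsFactors = FALSE)
    cand <- cand[ref != "N" & !(paste(cn, pos) %in% taken), , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$contig, cand$pos)), , drop = FALSE]
    picked <- rbind(picked, cand)
    picked <- picked[!duplicated(paste(picked$contig, picked$pos)), ,
                     drop = FALSE]
    taken <- c(taken, paste(picked$contig, picked$pos))
  }
  if (nrow(picked) < n) stop_("could not find ", n, " novel positions")
  picked <- picked[seq_len(n), , drop = FALSE]
  picked$alt <- vapply(picked$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1), USE.NAMES = FALSE)
  picked
}

#' Simulate a plating assay
#'
#' Colony-count data for one genotype with a known treated/untreated fold
#' difference. Culture-to-culture variability is lognormal on both the
#' per-culture mutation frequency and the viable count; resistant-colony
#' counts are Poisson draws on top (plating is a count process), so the data
#' show the overdispersion of real fluctuation-style assays. Treated cultures
#' have their frequency multiplied by `true_fold` and their viable count
#' reduced by `viability_drop`.
#'
#' Defaults emulate an NER-deficient strain under acute acetaldehyde
#' exposure: a 2.5-fold frequency increase, 44% surviving cells, cultures at
#' ~2e7 viable cells/mL and untreated frequencies around 5e-7.
#'
#' @param genotype genotype label.
#' @param n_per_arm cultures per arm.
#' @param base_frequency median untreated mutation frequency.
#' @param true_fold treated/untreated frequency ratio.
#' @param lognormal_sigma log-scale SD of the per-culture frequency.
#' @param viability_drop fraction of viable cells lost in the treated arm.
#' @param base_viable median viable colonies per mL.
#' @param viable_sigma log-scale SD of the viable count.
#' @param seed integer seed.
#' @return a plating-assay `data.frame` (genotype, treatment, canr_per_ml,
#'   viable_per_ml).
#' @examples
#' a <- simulate_assay(seed = 1)
#' frequency_analysis(a)$fold
#' @export
simulate_assay <- function(genotype = "rad1", n_per_arm = 12L,
                           base_frequency = 5e-7, true_fold = 2.5,
                           lognormal_sigma = 0.5, viability_drop = 0.56,
                           base_viable = 2e7, viable_sigma = 0.2, seed = 1L) {
  if (n_per_arm < 1L) stop_("n_per_arm must be >= 1")
  if (lognormal_sigma < 0 || viable_sigma < 0) stop_("sigmas must be >= 0")
  if (!(viability_drop >= 0 && viability_drop < 1)) {
    stop_("viability_drop must lie in [0, 1)")
  }
  with_seed(seed, {
    arm <- function(treatment, fold, keep) {
      viable <- base_viable * keep * stats::rlnorm(n_per_arm, 0, viable_sigma)
      freq <- base_frequency * fold * stats::rlnorm(n_per_arm, 0,
                                                    lognormal_sigma)
      canr <- stats::rpois(n_per_arm, freq * viable)
      data.frame(genotype = genotype, treatment = treatment,
                 canr_per_ml = canr, viable_per_ml = viable,
                 stringsAsFactors = FALSE)
    }
    rbind(arm("untreated", 1, 1), arm("treated", true_fold, 1 - viability_drop))
  })
}
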