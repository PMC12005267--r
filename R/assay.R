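# plating-assay statistics: mutation frequency, viability, Mann-Whitney
# comparisons with BH correction, and delta-delta-Ct qPCR fold changes

#' Per-culture mutation frequency
#'
#' Mutation frequency of one culture: canavanine-resistant colonies per mL
#' divided by viable colonies per mL.
#'
#' @param canr_per_ml resistant colonies per mL (non-negative).
#' @param viable_per_ml viable colonies per mL (strictly positive).
#' @return the frequency (vectorized).
#' @examples
#' mutation_frequency(20, 2e7)
#' @export
mutation_frequency <- function(canr_per_ml, viable_per_ml) {
  if (any(!is.finite(viable_per_ml) | viable_per_ml <= 0)) {
    stop_("viable_per_ml must be > 0")
  }
  if (any(!is.finite(canr_per_ml) | canr_per_ml < 0)) {
    stop_("canr_per_ml must be >= 0")
  }
  canr_per_ml / viable_per_ml
}

#' Percent viability after treatment
#'
#' `100 * treated_viable / untreated_viable`; water-treated cultures define
#' the 100% baseline.
#'
#' @param treated_viable viable colonies per mL after treatment.
#' @param untreated_viable viable colonies per mL of the matched untreated
#'   culture(s) (strictly positive).
#' @return percent viability (vectorized).
#' @export
viability_percent <- function(treated_viable, untreated_viable) {
  if (any(!is.finite(untreated_viable) | untreated_viable <= 0)) {
    stop_("untreated_viable must be > 0")
  }
  100 * treated_viable / untreated_viable
}

#' Compare treated and untreated frequency arms
#'
#' Fold change (ratio of medians, treated over untreated) and a two-sided
#' Mann-Whitney U p-value. For arms of at most 8 values without ties the
#' exact null enumeration is used; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param untreated,treated numeric vectors of per-culture frequencies (at
#'   least one value each; fewer than 3 per arm triggers a warning since the
#'   test is then uninformative).
#' @return a list with `fold` (`NA` when the untreated median is 0),
#'   `median_untreated`, `median_treated`, `p`, `n_untreated`, `n_treated`.
#' @examples
#' compare_arms(c(1, 2, 3) * 1e-7, c(2, 4, 6) * 1e-7)
#' @export
compare_arms <- function(untreated, treated) {
  if (length(untreated) == 0L || length(treated) == 0L) {
    stop_("both arms must be non-empty")
  }
  if (min(length(untreated), length(treated)) < 3L) {
    warning("fewer than 3 cultures in an arm; the rank test has little power")
  }
  mu <- stats::median(untreated)
  mt <- stats::median(treated)
  fold <- if (mu > 0) mt / mu else NA_real_
  ties <- anyDuplicated(c(untreated, treated)) > 0L
  exact <- !ties && length(untreated) <= 8L && length(treated) <= 8L
  p <- suppressWarnings(
    stats::wilcox.test(treated, untreated, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  list(fold = fold, median_untreated = mu, median_treated = mt, p = p,
       n_untreated = length(untreated), n_treated = length(treated))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved. The family is whatever set of p-values is passed
#' in one call (one analysis run).
#'
#' @param pvals p-values in (0, 1].
#' @return q-values in input order, each at least its raw p.
#' @export
bh_correct <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop_("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

.check_assay <- function(assay) {
  need <- c("genotype", "treatment", "canr_per_ml", "viable_per_ml")
  miss <- setdiff(need, names(assay))
  if (length(miss)) {
    stop_("assay table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(assay$treatment %in% c("untreated", "treated"))) {
    stop_("treatment must be 'untreated' or 'treated'")
  }
  assay
}

#' Mutation-frequency analysis per genotype
#'
#' For every genotype, computes per-culture mutation frequencies, compares
#' the treated and untreated arms ([compare_arms()]), and adjusts the
#' p-values of all genotypes in the call with [bh_correct()].
#'
#' @param assay a plating-assay table (see [read_assay_table()]).
#' @return a `data.frame` of class `"assay_tests"` with one row per genotype:
#'   `n_untreated`, `n_treated`, `median_untreated`, `median_treated`,
#'   `fold`, `p`, `q`.
#' @examples
#' a <- simulate_assay(seed = 1)
#' frequency_analysis(a)
#' @export
frequency_analysis <- function(assay) {
  assay <- .check_assay(assay)
  assay$freq <- mutation_frequency(assay$canr_per_ml, assay$viable_per_ml)
  gts <- unique(assay$genotype)
  rows <- lapply(gts, function(g) {
    u <- assay$freq[assay$genotype == g & assay$treatment == "untreated"]
    t <- assay$freq[assay$genotype == g & assay$treatment == "treated"]
    cm <- compare_arms(u, t)
    data.frame(genotype = g, n_untreated = cm$n_untreated,
               n_treated = cm$n_treated,
               median_untreated = cm$median_untreated,
               median_treated = cm$median_treated, fold = cm$fold, p = cm$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_correct(res$p)
  class(res) <- c("assay_tests", "data.frame")
  attr(res, "kind") <- "frequency"
  res
}

#' Viability analysis per genotype
#'
#' Per-culture percent viability is each treated culture's viable count over
#' the median untreated viable count of the same genotype (untreated cultures
#' define 100%). Two comparison modes are available: `"wildtype"` tests each
#' genotype's viability percentages against the wild-type strain's
#' (the mode used for survival assays in mutagen screens), `"untreated"`
#' tests treated against untreated viable counts within the genotype.
#'
#' @param assay a plating-assay table.
#' @param compare comparison mode, `"wildtype"` (default) or `"untreated"`.
#' @param wildtype genotype label of the wild-type strain (default `"WT"`).
#' @return a `data.frame` of class `"assay_tests"` with one row per genotype:
#'   `n_treated`, `median_viability`, `p`, `q` (the wild-type row has `NA`
#'   p/q in `"wildtype"` mode).
#' @export
viability_analysis <- function(assay, compare = c("wildtype", "untreated"),
                               wildtype = "WT") {
  compare <- match.arg(compare)
  assay <- .check_assay(assay)
  gts <- unique(assay$genotype)
  if (compare == "wildtype" && !(wildtype %in% gts)) {
    stop_("wild-type genotype '", wildtype, "' not present in assay table")
  }
  viab_of <- function(g) {
    u <- assay$viable_per_ml[assay$genotype == g & assay$treatment == "untreated"]
    t <- assay$viable_per_ml[assay$genotype == g & assay$treatment == "treated"]
    if (length(u) == 0L) stop_("no untreated cultures for genotype ", g)
    viability_percent(t, stats::median(u))
  }
  viabs <- lapply(stats::setNames(gts, gts), viab_of)
  rows <- lapply(gts, function(g) {
    v <- viabs[[g]]
    p <- if (compare == "wildtype") {
      if (g == wildtype) NA_real_ else {
        ties <- anyDuplicated(c(v, viabs[[wildtype]])) > 0L
        exact <- !ties && length(v) <= 8L && length(viabs[[wildtype]]) <= 8L
        suppressWarnings(stats::wilcox.test(v, viabs[[wildtype]],
                                            exact = exact)$p.value)
      }
    } else {
      u <- assay$viable_per_ml[assay$genotype == g &
                                 assay$treatment == "untreated"]
      t <- assay$viable_per_ml[assay$genotype == g &
                                 assay$treatment == "treated"]
      ties <- anyDuplicated(c(u, t)) > 0L
      exact <- !ties && length(u) <= 8L && length(t) <= 8L
      suppressWarnings(stats::wilcox.test(t, u, exact = exact)$p.value)
    }
    data.frame(genotype = g, n_treated = length(v),
               median_viability = stats::median(v), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  if (any(ok)) res$q[ok] <- bh_correct(res$p[ok])
  class(res) <- c("assay_tests", "data.frame")
  attr(res, "kind") <- paste0("viability_vs_", compare)
  res
}

#' @export
print.assay_tests <- function(x, ...) {
  cat("plating-assay tests (", attr(x, "kind"), "), BH family = ",
      nrow(x), " genotype(s)\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' qPCR fold change by the delta-delta-Ct method
#'
#' Per strain and condition: `dCt = target_ct - reference_ct` (first
#' normalization to the reference gene, ACT1 in the assays this models),
#' `ddCt = dCt(strain) - dCt(wild-type, same condition)` (second
#' normalization, pairing each condition with the wild-type grown under the
#' same condition), and fold change `2^-ddCt`. The wild type has fold 1 by
#' construction. Replicate rows for a sample/condition are averaged on the
#' dCt scale before the second normalization.
#'
#' @param ct a Ct table (see [read_ct_table()]).
#' @param wildtype sample label of the wild-type strain (default `"WT"`).
#' @return a `data.frame` with columns `sample`, `condition`, `delta_ct`,
#'   `ddct`, `fold`.
#' @examples
#' ct <- data.frame(sample = c("WT", "tetPOL2"), condition = "plain",
#'                  target_ct = c(20, 22), reference_ct = c(18, 18))
#' ddct_fold(ct)
#' @export
ddct_fold <- function(ct, wildtype = "WT") {
  need <- c("sample", "condition", "target_ct", "reference_ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    stop_("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct))) {
    stop_("Ct values must be finite")
  }
  ct$dct <- ct$target_ct - ct$reference_ct
  agg <- stats::aggregate(dct ~ sample + condition, data = ct, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$condition), function(d) {
    wt <- d$dct[d$sample == wildtype]
    if (length(wt) != 1L) {
      stop_("condition '", d$condition[1L], "' has no matched wild-type ('",
            wildtype, "') measurement; conditions must be paired")
    }
    d$ddct <- d$dct - wt
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  names(out)[names(out) == "dct"] <- "delta_ct"
  out[, c("sample", "condition", "delta_ct", "ddct", "fold")]
}
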