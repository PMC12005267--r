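# trinucleotide mutation-signature (TriMS) enrichment: contingency tables,
# the enrichment ratio, one-sided Fisher testing, and the cohort-level fit

#' Signature contingency tables
#'
#' The 2x2 table underlying the enrichment statistic: signature mutations
#' among all target-class mutations, and summed motif counts among summed
#' target-base counts over the +/-`window` bp backgrounds of those same
#' mutations.
#'
#' @param mut_sig number of signature (motif-context) mutations.
#' @param mut_all number of target-class mutations (includes `mut_sig`).
#' @param ctx_sig summed motif matches over the mutations' windows.
#' @param ctx_all summed target bases over the same windows.
#' @param n_skipped number of records excluded because they could not be
#'   classified (contig edge or `N` context).
#' @return an object of class `"trims_table"`.
#' @export
trims_table <- function(mut_sig, mut_all, ctx_sig, ctx_all, n_skipped = 0L) {
  vals <- c(mut_sig, mut_all, ctx_sig, ctx_all)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_("contingency counts must be finite and non-negative")
  }
  if (mut_sig > mut_all) stop_("mut_sig cannot exceed mut_all")
  if (ctx_sig > ctx_all) stop_("ctx_sig cannot exceed ctx_all")
  structure(list(mut_sig = as.numeric(mut_sig), mut_all = as.numeric(mut_all),
                 ctx_sig = as.numeric(ctx_sig), ctx_all = as.numeric(ctx_all),
                 n_skipped = as.integer(n_skipped)),
            class = "trims_table")
}

#' @export
print.trims_table <- function(x, ...) {
  cat("signature contingency table\n")
  cat(sprintf("  mutations: %g signature / %g target-class\n",
              x$mut_sig, x$mut_all))
  cat(sprintf("  background: %g motif / %g target bases in windows\n",
              x$ctx_sig, x$ctx_all))
  if (x$mut_all == 0) cat("  (empty: no target-class mutations)\n")
  invisible(x)
}

#' Build the signature contingency table for one cohort
#'
#' Classifies the cohort's mutations (pooled across isolates), keeps exactly
#' the strand-collapsed target-class changes (default C>A, so plus-strand G>T
#' records are counted via their reverse complement), and tallies: the number
#' whose pyrimidine context matches the motif (`mut_sig`), the total count
#' (`mut_all`), and the window sums of motif matches and target bases around
#' every counted mutation (`ctx_sig`, `ctx_all`). Records skipped by
#' [classify_sbs()] are excluded from both mutations and background.
#'
#' @param genome a genome object.
#' @param mutations curated mutation table for one cohort.
#' @param window background half-width in bp (default 20).
#' @param motif central-pyrimidine motif (default `"gCn"`).
#' @param alt the substituted base defining the target class (default `"A"`,
#'   i.e. C>A for a C-centered motif).
#' @param index optional precomputed [context_index()].
#' @return a `"trims_table"`; `mut_all = 0` marks an empty cohort, for which
#'   enrichment and the test are undefined downstream.
#' @export
build_table <- function(genome, mutations, window = 20L, motif = "gCn",
                        alt = "A", index = NULL) {
  if (is.null(index)) index <- context_index(genome, motif)
  mt <- index$motif
  if (!identical(mt$motif, motif)) {
    stop_("index was built for motif '", mt$motif, "', not '", motif, "'")
  }
  alt <- toupper(alt)
  if (!(alt %in% c("A", "C", "G", "T")) || alt == mt$center) {
    stop_("alt must be a base different from the motif center")
  }
  cls <- classify_sbs(genome, mutations)
  target <- !cls$skipped & cls$klass == paste0(mt$center, ">", alt)
  n_skip <- sum(cls$skipped)
  if (!any(target)) {
    return(trims_table(0, 0, 0, 0, n_skip))
  }
  hit <- cls[target, , drop = FALSE]
  f5 <- toupper(substr(hit$context, 1, 1))
  f3 <- toupper(substr(hit$context, 3, 3))
  is_sig <- f5 %in% mt$f5 & f3 %in% mt$f3
  ctx_sig <- 0
  ctx_all <- 0
  for (cn in unique(hit$contig)) {
    rows <- hit$contig == cn
    wc <- window_counts(genome, cn, hit$pos[rows], window = window,
                        motif = motif, index = index)
    ctx_all <- ctx_all + sum(wc$n_cyt)
    ctx_sig <- ctx_sig + sum(wc$n_gcn)
  }
  trims_table(sum(is_sig), sum(target), ctx_sig, ctx_all, n_skip)
}

#' Signature enrichment ratio
#'
#' The ratio of proportions `(mut_sig / mut_all) / (ctx_sig / ctx_all)`:
#' the motif fraction among target-class mutations over the motif fraction
#' among target bases in their backgrounds. Values above 1 indicate positive
#' enrichment of the signature.
#'
#' @param table a `"trims_table"`.
#' @return the enrichment; `0` when `mut_sig = 0`, `Inf` when `ctx_sig = 0`
#'   with `mut_sig > 0`, and `NA` for an empty table (`mut_all = 0`).
#' @examples
#' enrichment(trims_table(10, 10, 50, 100))
#' @export
enrichment <- function(table) {
  stopifnot(inherits(table, "trims_table"))
  if (table$mut_all == 0) return(NA_real_)
  if (table$mut_sig == 0) return(0)
  if (table$ctx_sig == 0) return(Inf)
  (table$mut_sig / table$mut_all) / (table$ctx_sig / table$ctx_all)
}

#' One-sided Fisher's exact test for signature enrichment
#'
#' Tests, in the 2x2 table
#' `[[mut_sig, mut_all - mut_sig], [ctx_sig, ctx_all - ctx_sig]]`, the
#' hypothesis that signature mutations are over-represented among
#' target-class mutations relative to motif representation among background
#' bases (alternative "greater").
#'
#' @param table a `"trims_table"`.
#' @return the one-sided p-value, or `NA` for an empty table.
#' @export
fisher_one_sided <- function(table) {
  stopifnot(inherits(table, "trims_table"))
  if (table$mut_all == 0) return(NA_real_)
  m <- matrix(c(table$mut_sig, table$mut_all - table$mut_sig,
                table$ctx_sig, table$ctx_all - table$ctx_sig),
              nrow = 2L, byrow = TRUE)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Fit signature enrichment across cohorts
#'
#' The main entry point for signature analysis. For each cohort (typically
#' genotype x treatment, pooled across isolates because per-isolate mutation
#' counts are too low for individual signature calls) it builds the
#' contingency table, computes the enrichment ratio and the one-sided Fisher
#' p-value, then adjusts the p-values of all defined cohorts in the call with
#' the Benjamini-Hochberg method. Cohorts with no target-class mutations are
#' reported with `NA` markers and excluded from the adjustment.
#'
#' @param genome a genome object.
#' @param mutations a curated mutation table.
#' @param cohort how to group records into cohorts: the name of a column of
#'   `mutations` (default `"cohort"` when present), or a named character
#'   vector mapping sample to cohort. With neither, all records form one
#'   cohort.
#' @param window,motif,alt,index as in [build_table()].
#' @return an object of class `"trims"`: a list with `results` (a
#'   `data.frame` with one row per cohort: counts, `enrichment`, `p`, `q`),
#'   `tables` (the per-cohort `"trims_table"`s), and the call parameters.
#'   Methods: `print`, `summary`, `coef` (named enrichment vector),
#'   `as.data.frame`, `plot`.
#' @examples
#' g <- gen_genome(1, 20000, seed = 1)
#' mu <- rbind(
#'   cbind(spike_mutations(g, n_mutations = 150, target_enrichment = 3,
#'                         seed = 2), cohort = "treated"),
#'   cbind(spike_mutations(g, n_mutations = 150, target_enrichment = 1,
#'                         seed = 3), cohort = "untreated"))
#' fit <- trims(g, mu)
#' fit
#' @export
trims <- function(genome, mutations, cohort = NULL, window = 20L,
                  motif = "gCn", alt = "A", index = NULL) {
  genome <- as_genome(genome)
  if (is.null(index)) index <- context_index(genome, motif)
  grp <- .cohort_of(mutations, cohort)
  cohorts <- unique(grp)
  tables <- lapply(stats::setNames(cohorts, cohorts), function(co) {
    build_table(genome, mutations[grp == co, , drop = FALSE], window = window,
                motif = motif, alt = alt, index = index)
  })
  res <- data.frame(
    cohort = cohorts,
    n_mut = vapply(tables, function(t) t$mut_all, numeric(1)),
    n_sig = vapply(tables, function(t) t$mut_sig, numeric(1)),
    ctx_sig = vapply(tables, function(t) t$ctx_sig, numeric(1)),
    ctx_all = vapply(tables, function(t) t$ctx_all, numeric(1)),
    enrichment = vapply(tables, enrichment, numeric(1)),
    p = vapply(tables, fisher_one_sided, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$q <- NA_real_
  defined <- !is.na(res$p)
  if (any(defined)) res$q[defined] <- bh_correct(res$p[defined])
  structure(list(results = res, tables = tables, window = window,
                 motif = motif, alt = alt, call = match.call()),
            class = "trims")
}

.cohort_of <- function(mutations, cohort) {
  if (is.null(cohort)) {
    if ("cohort" %in% names(mutations)) return(as.character(mutations$cohort))
    return(rep("all", nrow(mutations)))
  }
  if (is.character(cohort) && length(cohort) == 1L &&
      cohort %in% names(mutations)) {
    return(as.character(mutations[[cohort]]))
  }
  if (!is.null(names(cohort))) {
    miss <- setdiff(unique(mutations$sample), names(cohort))
    if (length(miss)) {
      stop_("no cohort assignment for sample(s): ", paste(miss, collapse = ", "))
    }
    return(unname(cohort[mutations$sample]))
  }
  stop_("'cohort' must be a column name or a named sample-to-cohort map")
}

#' @export
print.trims <- function(x, ...) {
  cat("TriMS signature enrichment (motif ", x$motif, ">", x$alt,
      ", window +/-", x$window, " bp)\n\n", sep = "")
  res <- x$results
  res$enrichment <- signif(res$enrichment, 4)
  res$p <- signif(res$p, 3)
  res$q <- signif(res$q, 3)
  print(res[, c("cohort", "n_mut", "n_sig", "enrichment", "p", "q")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.trims <- function(object, alpha = 0.05, ...) {
  res <- object$results
  pos <- !is.na(res$q) & res$enrichment > 1 & res$q < alpha
  structure(list(fit = object, alpha = alpha, positive = res$cohort[pos]),
            class = "summary.trims")
}

#' @export
print.summary.trims <- function(x, ...) {
  print(x$fit)
  cat("\npositively enriched (enrichment > 1, q < ", x$alpha, "): ",
      if (length(x$positive)) paste(x$positive, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.trims <- function(object, ...) {
  stats::setNames(object$results$enrichment, object$results$cohort)
}

#' @export
as.data.frame.trims <- function(x, ...) x$results

#' @export
plot.trims <- function(x, alpha = 0.05, ...) {
  res <- x$results
  e <- res$enrichment
  e[!is.finite(e)] <- NA
  bp <- graphics::barplot(e, names.arg = res$cohort, ylab = "enrichment",
                          ylim = c(0, max(1.2, e * 1.2, na.rm = TRUE)), ...)
  graphics::abline(h = 1, lty = 2)
  sig <- !is.na(res$q) & res$q < alpha & !is.na(e)
  if (any(sig)) {
    graphics::text(bp[sig], e[sig], labels = "*", pos = 3, cex = 1.4)
  }
  invisible(x)
}
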