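# mutation curation: VAF filtering and removal of preexisting/shared variants

.mut_key <- function(m) paste(m$contig, m$pos, m$ref, m$alt, sep = ":")

new_filter_report <- function(n_input, n_below_vaf, n_preexisting_baseline,
                              n_shared, n_kept) {
  rep <- list(n_input = as.integer(n_input),
              n_below_vaf = as.integer(n_below_vaf),
              n_preexisting_baseline = as.integer(n_preexisting_baseline),
              n_shared = as.integer(n_shared),
              n_kept = as.integer(n_kept))
  stopifnot(rep$n_input ==
              rep$n_below_vaf + rep$n_preexisting_baseline + rep$n_shared +
              rep$n_kept)
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("mutation curation report\n")
  cat(sprintf("  input records:        %d\n", x$n_input))
  cat(sprintf("  below VAF threshold:  %d\n", x$n_below_vaf))
  cat(sprintf("  preexisting/baseline: %d\n", x$n_preexisting_baseline))
  cat(sprintf("  shared across samples:%d\n", x$n_shared))
  cat(sprintf("  kept:                 %d\n", x$n_kept))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(n_input = x$n_input, n_below_vaf = x$n_below_vaf,
             n_preexisting_baseline = x$n_preexisting_baseline,
             n_shared = x$n_shared, n_kept = x$n_kept)
}

#' Variant-allele-frequency filter
#'
#' Keeps records whose VAF is at least `threshold` (inclusive, so calls at
#' exactly the threshold survive). Record order is preserved. A record without
#' a VAF is a hard error.
#'
#' @param mutations a mutation table with a `vaf` column of fractions.
#' @param threshold minimum VAF to keep, in (0, 1]; default 0.90, the
#'   near-homozygous cutoff used for haploid isolate sequencing.
#' @return the filtered mutation table.
#' @export
vaf_filter <- function(mutations, threshold = 0.9) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop_("threshold must be in (0, 1]")
  }
  if (nrow(mutations) == 0L) return(mutations)
  if (!("vaf" %in% names(mutations)) || anyNA(mutations$vaf)) {
    i <- if ("vaf" %in% names(mutations)) which(is.na(mutations$vaf))[1L] else 1L
    stop_("record without VAF cannot be VAF-filtered (sample ",
          mutations$sample[i], ", ", mutations$contig[i], ":",
          mutations$pos[i], ")")
  }
  mutations[mutations$vaf >= threshold, , drop = FALSE]
}

#' Remove preexisting and shared mutations
#'
#' Implements the curation rule for mutagen-exposure cohorts: a mutation is
#' treated as preexisting (not induced by the treatment) when its identity
#' `(contig, pos, ref, alt)` is present in the baseline (the sequenced
#' original, pre-treatment culture), or when it occurs in `share_min` or more
#' distinct samples. Removal of a shared key applies to every carrier sample.
#' Each record receives exactly one fate, with precedence baseline before
#' shared.
#'
#' @param mutations mutation table for all samples of one analysis batch.
#' @param baseline mutation table of the pre-treatment culture(s), or `NULL`.
#' @param share_min minimum number of distinct samples that makes a shared key
#'   preexisting (default 2).
#' @return a list with elements `mutations` (the retained records) and
#'   `report` (a `filter_report`).
#' @export
remove_preexisting <- function(mutations, baseline = NULL, share_min = 2L) {
  if (share_min < 2L) stop_("share_min must be >= 2")
  n_in <- nrow(mutations)
  if (n_in == 0L) {
    return(list(mutations = mutations,
                report = new_filter_report(0L, 0L, 0L, 0L, 0L)))
  }
  key <- .mut_key(mutations)
  base_keys <- if (is.null(baseline) || nrow(baseline) == 0L) character() else {
    unique(.mut_key(baseline))
  }
  in_base <- key %in% base_keys
  # sharing is counted over distinct samples among records not already removed
  # as baseline hits; duplicates within one sample do not trigger it
  rest <- !in_base
  carriers <- tapply(mutations$sample[rest], key[rest],
                     function(s) length(unique(s)))
  shared_keys <- names(carriers)[carriers >= share_min]
  shared <- rest & key %in% shared_keys
  keep <- rest & !shared
  list(mutations = mutations[keep, , drop = FALSE],
       report = new_filter_report(n_in, 0L, sum(in_base), sum(shared),
                                  sum(keep)))
}

#' Curate a mutation cohort
#'
#' Full curation: the VAF filter first, then baseline subtraction and removal
#' of keys shared across samples. Each input record is assigned exactly one
#' fate in the precedence order low-VAF, baseline, shared, kept, and the
#' report's counts always sum to the input size. Curation is idempotent:
#' re-curating its own output (with the same baseline) changes nothing.
#'
#' @inheritParams remove_preexisting
#' @param vaf_threshold VAF cutoff passed to [vaf_filter()]; use `NULL` to
#'   skip VAF filtering (e.g. for tables that no longer carry VAFs).
#' @return a list with `mutations` and `report` as in [remove_preexisting()].
#' @examples
#' g <- gen_genome(1, 1000, seed = 3)
#' spiked <- spike_mutations(g, n_samples = 3, n_mutations = 20, seed = 4)
#' cur <- curate(spiked)
#' cur$report
#' @export
curate <- function(mutations, baseline = NULL, vaf_threshold = 0.9,
                   share_min = 2L) {
  n_in <- nrow(mutations)
  if (is.null(vaf_threshold)) {
    passed <- mutations
    n_low <- 0L
  } else {
    passed <- vaf_filter(mutations, vaf_threshold)
    n_low <- n_in - nrow(passed)
  }
  res <- remove_preexisting(passed, baseline, share_min)
  list(mutations = res$mutations,
       report = new_filter_report(n_in, n_low,
                                  res$report$n_preexisting_baseline,
                                  res$report$n_shared, res$report$n_kept))
}
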