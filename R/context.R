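# strand-collapsed substitution classification, trinucleotide spectra, and
# windowed motif/background counting

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.context96 <- function() {
  fl <- c("a", "c", "g", "t")
  unlist(lapply(SBS_CLASSES, function(k) {
    as.vector(outer(fl, fl, function(f5, f3) paste0(f5, "[", k, "]", f3)))
  }))
}
CONTEXTS_96 <- .context96()

#' Parse a central-pyrimidine trinucleotide motif
#'
#' Motifs are written with lowercase IUPAC flanks and an uppercase pyrimidine
#' center, e.g. `"gCn"` (the acetaldehyde signature context) or `"tCw"` (the
#' APOBEC context).
#'
#' @param motif a 3-character motif string.
#' @return a list with `center` (`"C"` or `"T"`) and the flank base sets.
#' @keywords internal
parse_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) != 3L) {
    stop_("motif must be a single 3-character string such as 'gCn'")
  }
  center <- substr(motif, 2, 2)
  if (!(center %in% c("C", "T"))) {
    stop_("motif center must be an uppercase pyrimidine (C or T), got '",
          center, "'")
  }
  list(motif = motif, center = center,
       f5 = iupac_set(substr(motif, 1, 1)),
       f3 = iupac_set(substr(motif, 3, 3)))
}

# Per-contig indicator and prefix-sum machinery for O(1) window queries.
# "Both strands" counting: every plus-strand base equal to the motif center
# (e.g. C) or its complement (G, a minus-strand C) is a target base; a
# position is a motif match when the motif fits around it on either strand.
# Motif membership uses the genome's actual neighbors, so a match is detected
# even when the flanking base lies just outside a query window; a center at a
# contig end with a missing flank is never a match.

#' Precompute a genome context index
#'
#' Builds per-contig indicator vectors and prefix sums for the motif's center
#' base (both strands) and for motif matches, plus the genome-wide pool of
#' candidate positions. [window_counts()], [build_table()], [trims()] and
#' [spike_mutations()] accept a precomputed index to avoid rescanning the
#' genome in repeated calls.
#'
#' @param genome a genome object.
#' @param motif central-pyrimidine motif string (default `"gCn"`).
#' @return an object of class `"context_index"`.
#' @export
context_index <- function(genome, motif = "gCn") {
  genome <- as_genome(genome)
  mt <- parse_motif(motif)
  comp_center <- comp_base(mt$center)
  f5c <- comp_base(setdiff(mt$f5, "N"))
  f3c <- comp_base(setdiff(mt$f3, "N"))
  if ("N" %in% mt$f5) f5c <- c(f5c, "N")
  if ("N" %in% mt$f3) f3c <- c(f3c, "N")
  contigs <- lapply(stats::setNames(names(genome), names(genome)), function(cn) {
    chars <- strsplit(unclass(genome)[[cn]], "", fixed = TRUE)[[1L]]
    n <- length(chars)
    # a missing neighbor (contig end) behaves like the unknown base N: only
    # the unconstrained flank code 'n' matches it, so e.g. a C at the very
    # start of a contig is never a gCn cytosine, while one at the very end is
    prev <- c("N", chars[-n])
    nxt <- c(chars[-1L], "N")
    all_ind <- chars == mt$center | chars == comp_center
    sig_plus <- chars == mt$center & prev %in% mt$f5 & nxt %in% mt$f3
    # minus strand: plus base is the complement of the center; the motif's 5'
    # flank sits at pos+1 (complemented) and its 3' flank at pos-1
    sig_minus <- chars == comp_center & nxt %in% f5c & prev %in% f3c
    sig_ind <- sig_plus | sig_minus
    list(n = n, chars = chars, all_ind = all_ind, sig_ind = sig_ind,
         cum_all = cumsum(as.integer(all_ind)),
         cum_sig = cumsum(as.integer(sig_ind)))
  })
  pool <- do.call(rbind, lapply(names(contigs), function(cn) {
    ci <- contigs[[cn]]
    idx <- which(ci$all_ind)
    data.frame(contig = rep(cn, length(idx)), pos = idx,
               sig = ci$sig_ind[idx], stringsAsFactors = FALSE)
  }))
  structure(list(motif = mt, contigs = contigs, pool = pool),
            class = "context_index")
}

.wsum <- function(cum, pos, window) {
  n <- length(cum)
  lo <- pmax(1L, pos - window)
  hi <- pmin(n, pos + window)
  base <- numeric(length(pos))
  inner <- lo > 1L
  base[inner] <- cum[lo[inner] - 1L]
  cum[hi] - base
}

#' Windowed background counts around a position
#'
#' Counts, in the symmetric window `[pos - window, pos + window]` (truncated
#' at contig ends and including `pos` itself), the motif-center bases on both
#' strands (`n_cyt`: plus-strand C plus plus-strand G for a C-centered motif)
#' and the motif matches on both strands (`n_gcn` for the default `gCn`).
#' Motif membership of a base is decided from its true genomic neighbors, even
#' when a neighbor lies just outside the window.
#'
#' @param genome a genome object.
#' @param contig contig name.
#' @param pos 1-based position(s) on the contig.
#' @param window half-width in bp (default 20).
#' @param motif central-pyrimidine motif (default `"gCn"`).
#' @param index optional precomputed [context_index()].
#' @return a `data.frame` with one row per position and columns `n_cyt`,
#'   `n_gcn`.
#' @examples
#' window_counts(as_genome(c(c1 = "GCA")), "c1", 2)
#' @export
window_counts <- function(genome, contig, pos, window = 20L, motif = "gCn",
                          index = NULL) {
  if (is.null(index)) index <- context_index(genome, motif)
  ci <- index$contigs[[contig]]
  if (is.null(ci)) stop_("unknown contig: ", contig)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > ci$n)) {
    stop_("position off contig ", contig, " (length ", ci$n, ")")
  }
  data.frame(n_cyt = .wsum(ci$cum_all, pos, as.integer(window)),
             n_gcn = .wsum(ci$cum_sig, pos, as.integer(window)))
}

#' Classify substitutions as strand-collapsed pyrimidine changes
#'
#' Assigns each SNV to one of the 6 pyrimidine substitution classes
#' (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`) with its trinucleotide context.
#' When the reference base is a purine, the change and its context are
#' reverse-complemented so the mutated base is reported as a pyrimidine
#' (e.g. a G>T with plus-strand context `aGc` becomes `C>A` in `gCt`).
#' Contexts are written with lowercase flanks and an uppercase center.
#' Records at a contig edge or with an `N` in the trinucleotide cannot be
#' classified; they are flagged (`skipped = TRUE`), not dropped. A reference
#' base that does not match the genome is a hard error.
#'
#' @param genome a genome object.
#' @param mutations a mutation table.
#' @return the input table with added columns `klass`, `context`, `skipped`.
#' @export
classify_sbs <- function(genome, mutations) {
  genome <- as_genome(genome)
  validate_mutations(mutations)
  n <- nrow(mutations)
  out <- mutations
  out$klass <- rep(NA_character_, n)
  out$context <- rep(NA_character_, n)
  out$skipped <- rep(FALSE, n)
  if (n == 0L) return(out)
  len <- contig_lengths(genome)
  unknown <- !(mutations$contig %in% names(len))
  if (any(unknown)) {
    stop_("unknown contig '", mutations$contig[unknown][1L],
          "' in mutation table")
  }
  pos <- mutations$pos
  clen <- len[mutations$contig]
  if (any(pos < 1L | pos > clen)) {
    stop_("position off contig in mutation table (first bad row: ",
          which(pos < 1L | pos > clen)[1L], ")")
  }
  seqs <- unclass(genome)[mutations$contig]
  gbase <- substring(seqs, pos, pos)
  mm <- gbase != mutations$ref
  if (any(mm)) {
    i <- which(mm)[1L]
    stop_("reference mismatch at ", mutations$contig[i], ":", pos[i],
          " (genome ", gbase[i], ", record ", mutations$ref[i], ") and ",
          sum(mm) - 1L, " more")
  }
  edge <- pos == 1L | pos == clen
  left <- rep(NA_character_, n)
  right <- rep(NA_character_, n)
  left[!edge] <- substring(seqs[!edge], pos[!edge] - 1L, pos[!edge] - 1L)
  right[!edge] <- substring(seqs[!edge], pos[!edge] + 1L, pos[!edge] + 1L)
  hasN <- !edge & (gbase == "N" | left == "N" | right == "N")
  skip <- edge | hasN
  ok <- !skip
  pur <- ok & mutations$ref %in% c("A", "G")
  ref_p <- ifelse(pur, comp_base(mutations$ref), mutations$ref)
  alt_p <- ifelse(pur, comp_base(mutations$alt), mutations$alt)
  l_p <- ifelse(pur, comp_base(right), left)
  r_p <- ifelse(pur, comp_base(left), right)
  out$klass[ok] <- paste0(ref_p[ok], ">", alt_p[ok])
  out$context[ok] <- paste0(tolower(l_p[ok]), ref_p[ok], tolower(r_p[ok]))
  out$skipped <- skip
  out
}

#' Strand-collapsed mutation spectra
#'
#' Tabulates classified substitutions per isolate into the 6 pyrimidine
#' classes and the 96 trinucleotide contexts, and reports the cohort mean
#' (arithmetic mean of per-isolate class counts). Records that cannot be
#' classified (contig edge, `N` context) are counted as skipped per sample.
#'
#' @param genome a genome object.
#' @param mutations a curated mutation table with a `sample` column.
#' @return an object of class `"mutation_spectrum"` with components `classes`
#'   (6 x samples count matrix), `contexts` (96 x samples), `cohort_mean`
#'   (named numeric of per-class means) and `skipped` (named integer per
#'   sample).
#' @examples
#' g <- gen_genome(1, 2000, seed = 1)
#' mu <- spike_mutations(g, n_samples = 2, n_mutations = 40, seed = 2)
#' sp <- mutation_spectrum(g, mu)
#' sp$cohort_mean
#' @export
mutation_spectrum <- function(genome, mutations) {
  cls <- classify_sbs(genome, mutations)
  samples <- unique(cls$sample)
  classes <- matrix(0L, nrow = length(SBS_CLASSES), ncol = length(samples),
                    dimnames = list(SBS_CLASSES, samples))
  contexts <- matrix(0L, nrow = 96L, ncol = length(samples),
                     dimnames = list(CONTEXTS_96, samples))
  skipped <- stats::setNames(integer(length(samples)), samples)
  keep <- !cls$skipped
  key96 <- paste0(substr(cls$context, 1, 1), "[", cls$klass, "]",
                  substr(cls$context, 3, 3))
  for (s in samples) {
    rows <- keep & cls$sample == s
    tb <- table(factor(cls$klass[rows], levels = SBS_CLASSES))
    classes[, s] <- as.integer(tb)
    tb96 <- table(factor(key96[rows], levels = CONTEXTS_96))
    contexts[, s] <- as.integer(tb96)
    skipped[s] <- sum(cls$skipped & cls$sample == s)
  }
  structure(list(classes = classes, contexts = contexts,
                 cohort_mean = rowMeans(classes), skipped = skipped),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation spectrum:", ncol(x$classes), "isolate(s),",
      sum(x$classes), "classified SNV(s),", sum(x$skipped), "skipped\n")
  cat("mean substitutions per isolate:\n")
  print(round(x$cohort_mean, 2))
  invisible(x)
}

#' @export
as.data.frame.mutation_spectrum <- function(x, ...) {
  df <- as.data.frame.table(x$classes, stringsAsFactors = FALSE)
  names(df) <- c("klass", "sample", "count")
  df[, c("sample", "klass", "count")]
}

#' @param x a `"mutation_spectrum"` object.
#' @param ... passed to [graphics::barplot()].
#' @rdname mutation_spectrum
#' @export
plot.mutation_spectrum <- function(x, ...) {
  cols <- c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63", "#EBC6C4")
  graphics::barplot(x$cohort_mean, col = cols, border = NA,
                    ylab = "mean substitutions per isolate",
                    xlab = "pyrimidine substitution class", ...)
  invisible(x)
}
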