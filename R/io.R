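# readers/writers for variant, assay, Ct and result tables

MUTATION_COLS <- c("sample", "contig", "pos", "ref", "alt", "vaf")

.parse_vaf <- function(x) {
  # VarScan emits percent strings ("92.3%"); plain fractions are accepted too
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  out[pct] <- out[pct] / 100
  # bare numbers > 1 are percents as well
  big <- !pct & !is.na(out) & out > 1
  out[big] <- out[big] / 100
  out
}

.new_mutation_table <- function(sample, contig, pos, ref, alt, vaf = NA_real_) {
  data.frame(sample = as.character(sample), contig = as.character(contig),
             pos = as.integer(pos), ref = toupper(as.character(ref)),
             alt = toupper(as.character(alt)), vaf = as.numeric(vaf),
             stringsAsFactors = FALSE)
}

#' Read single-nucleotide variant calls
#'
#' Loads SNVs from either a per-isolate VCF (v4.x) or a VarScan2-style
#' tab-separated table with header columns `chrom`, `pos`, `ref`, `alt`,
#' `vaf`, `sample`. Only single-base substitutions are kept: indel and
#' multi-base rows are skipped and their count reported via a message and the
#' `"n_skipped"` attribute. Multi-allelic VCF rows are expanded to one record
#' per alternate allele. Positions are 1-based in both dialects and kept as
#' such.
#'
#' @param path input file.
#' @param format `"vcf"` or `"varscan"`.
#' @param sample sample identifier; required for a VCF without a genotype
#'   column, otherwise taken from the VCF's single sample column (multi-sample
#'   VCFs are rejected) or the TSV's `sample` column.
#' @return a mutation table: a `data.frame` with columns `sample`, `contig`,
#'   `pos`, `ref`, `alt`, `vaf` (fraction in \[0, 1\], `NA` when the source has
#'   no allele-frequency field).
#' @export
read_mutations <- function(path, format = c("varscan", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("variant file not found: ", path)
  if (format == "vcf") .read_mutations_vcf(path, sample) else {
    .read_mutations_varscan(path)
  }
}

.read_mutations_varscan <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "vaf", "sample")
  names(raw) <- tolower(names(raw))
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_("variant table ", path, " lacks required column(s): ",
          paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("variant table has no data rows: ", path)
    out <- .new_mutation_table(character(), character(), integer(),
                               character(), character(), numeric())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop_("malformed position in ", path, " at line ", bad[1L] + 1L,
          ": '", raw$pos[bad[1L]], "'")
  }
  ref <- toupper(trimws(raw$ref))
  alt <- toupper(trimws(raw$alt))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  n_skipped <- sum(!snv)
  if (n_skipped > 0L) {
    message("read_mutations: skipped ", n_skipped, " non-SNV row(s) in ", path)
  }
  vaf <- .parse_vaf(raw$vaf)
  badv <- which(snv & (is.na(vaf) | vaf < 0 | vaf > 1))
  if (length(badv)) {
    stop_("malformed variant allele frequency in ", path, " at line ",
          badv[1L] + 1L, ": '", raw$vaf[badv[1L]], "'")
  }
  out <- .new_mutation_table(raw$sample[snv], raw$chrom[snv], pos[snv],
                             ref[snv], alt[snv], vaf[snv])
  attr(out, "n_skipped") <- n_skipped
  out
}

.read_mutations_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) > 2L) {
    stop_("multi-sample VCF not supported (", ncol(gt) - 1L,
          " sample columns in ", path, "); analyses are per-isolate")
  }
  if (is.null(sample)) {
    if (!is.null(gt) && ncol(gt) == 2L) {
      sample <- colnames(gt)[2L]
    } else {
      stop_("VCF ", path, " has no sample column; supply `sample`")
    }
  }
  if (nrow(fix) == 0L) {
    warning("VCF has no variant rows: ", path)
    out <- .new_mutation_table(character(), character(), integer(),
                               character(), character(), numeric())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  # per-record VAF: VarScan's FORMAT/FREQ when present, else INFO AF=, else NA
  vaf <- rep(NA_real_, nrow(fix))
  if (!is.null(gt) && ncol(gt) == 2L) {
    freq <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = "FREQ")),
                     error = function(e) NULL)
    if (!is.null(freq)) vaf <- .parse_vaf(freq[, 1L])
  }
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""
  hit <- regexpr("(^|;)AF=[^;]+", info)
  has_af <- hit > 0L
  if (any(has_af)) {
    info_af <- rep(NA_character_, length(info))
    info_af[has_af] <- sub("^;?AF=", "", regmatches(info, hit))
    fill <- is.na(vaf) & has_af
    vaf[fill] <- .parse_vaf(info_af[fill])
  }

  rows <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    keep <- nchar(alts) == 1L & alts %in% c("A", "C", "G", "T") &
      nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") & alts != ref
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) next
    rows[[i]] <- .new_mutation_table(sample, fix[i, "CHROM"],
                                     as.integer(fix[i, "POS"]), ref,
                                     alts[keep], vaf[i])
  }
  if (n_skipped > 0L) {
    message("read_mutations: skipped ", n_skipped,
            " non-SNV allele(s) in ", path)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    .new_mutation_table(character(), character(), integer(), character(),
                        character(), numeric())
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Validate a mutation table, optionally against a genome
#'
#' Checks the structural invariants of a mutation table (required columns,
#' single-base `ref`/`alt` with `ref != alt`) and, when a genome is supplied,
#' that every position lies on a known contig and that `ref` matches the
#' genome base there. Reference mismatches are counted and reported with a
#' warning rather than dropped; structural problems are hard errors.
#'
#' @param mutations a mutation table (see [read_mutations()]).
#' @param genome optional genome to check coordinates and reference bases
#'   against.
#' @return the validated table, invisibly, with attribute `"n_ref_mismatch"`.
#' @export
validate_mutations <- function(mutations, genome = NULL) {
  need <- setdiff(MUTATION_COLS, "vaf")
  miss <- setdiff(need, names(mutations))
  if (length(miss)) {
    stop_("mutation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(mutations)) {
    ok_base <- mutations$ref %in% c("A", "C", "G", "T") &
      mutations$alt %in% c("A", "C", "G", "T")
    if (any(!ok_base)) {
      stop_("non-ACGT ref/alt in mutation table (first bad row: ",
            which(!ok_base)[1L], ")")
    }
    if (any(mutations$ref == mutations$alt)) {
      stop_("ref equals alt in mutation table (first bad row: ",
            which(mutations$ref == mutations$alt)[1L], ")")
    }
  }
  n_mm <- 0L
  if (!is.null(genome) && nrow(mutations)) {
    genome <- as_genome(genome)
    len <- contig_lengths(genome)
    unknown <- !(mutations$contig %in% names(len))
    if (any(unknown)) {
      stop_("unknown contig '", mutations$contig[unknown][1L],
            "' in mutation table")
    }
    off <- mutations$pos < 1L | mutations$pos > len[mutations$contig]
    if (any(off)) {
      stop_("position off contig in mutation table (first bad row: ",
            which(off)[1L], ")")
    }
    gbase <- substring(unclass(genome)[mutations$contig], mutations$pos,
                       mutations$pos)
    n_mm <- sum(gbase != mutations$ref)
    if (n_mm > 0L) {
      warning(n_mm, " record(s) whose ref does not match the genome base")
    }
  }
  attr(mutations, "n_ref_mismatch") <- n_mm
  invisible(mutations)
}

#' Read a plating-assay table
#'
#' Expects a tab- or comma-separated file with header columns `genotype`,
#' `treatment` (`untreated`/`treated`), `canr_per_ml` (canavanine-resistant
#' colonies per mL, non-negative) and `viable_per_ml` (viable colonies per mL,
#' strictly positive).
#'
#' @param path input file.
#' @return a validated `data.frame` of assay measurements.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop_("assay table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("genotype", "treatment", "canr_per_ml", "viable_per_ml")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_("assay table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("assay table has no data rows: ", path)
    return(raw[, need])
  }
  raw$canr_per_ml <- as.numeric(raw$canr_per_ml)
  raw$viable_per_ml <- as.numeric(raw$viable_per_ml)
  bad_t <- !(raw$treatment %in% c("untreated", "treated"))
  if (any(bad_t)) {
    stop_("treatment must be 'untreated' or 'treated' (row ",
          which(bad_t)[1L], ")")
  }
  if (any(!is.finite(raw$viable_per_ml) | raw$viable_per_ml <= 0)) {
    stop_("viable_per_ml must be > 0 (row ",
          which(!is.finite(raw$viable_per_ml) | raw$viable_per_ml <= 0)[1L], ")")
  }
  if (any(!is.finite(raw$canr_per_ml) | raw$canr_per_ml < 0)) {
    stop_("canr_per_ml must be >= 0 (row ",
          which(!is.finite(raw$canr_per_ml) | raw$canr_per_ml < 0)[1L], ")")
  }
  raw[, need]
}

#' Read a qPCR Ct table
#'
#' Expects columns `sample`, `condition` (e.g. `plain` / `doxycycline`),
#' `target_ct` and `reference_ct` (the reference-gene channel, ACT1 in the
#' assays this models). All Ct values must be finite.
#'
#' @param path input file.
#' @return a validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_("Ct table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("sample", "condition", "target_ct", "reference_ct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  }
  raw$target_ct <- as.numeric(raw$target_ct)
  raw$reference_ct <- as.numeric(raw$reference_ct)
  if (any(!is.finite(raw$target_ct)) || any(!is.finite(raw$reference_ct))) {
    stop_("non-finite Ct value in ", path)
  }
  raw[, need]
}

#' Write a result table as TSV
#'
#' Serializes any result table (filtered mutations, spectra, enrichment
#' results, assay statistics, ...) as tab-separated UTF-8 with a header row.
#' Numeric columns are written with 6 significant digits, so a read-back
#' equals the written values to that precision. Objects with an
#' `as.data.frame` method (e.g. [trims()] fits) are converted first.
#'
#' @param x a data frame or coercible object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  out <- x
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], 6L)
    }
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wt", encoding = "UTF-8")),
                  error = function(e) stop_("cannot write to ", path, ": ",
                                            conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
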