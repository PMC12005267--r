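# in-code fixtures shared across test files

mk_muts <- function(sample, contig, pos, ref, alt, vaf = 1) {
  data.frame(sample = sample, contig = contig, pos = as.integer(pos),
             ref = ref, alt = alt, vaf = vaf, stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a minimal per-isolate VarScan-style table
varscan_lines <- function(rows) {
  c("chrom\tpos\tref\talt\tvaf\tsample", rows)
}

vcf_lines <- function(body, sample = "S1", format_col = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                  if (format_col) paste0("\tFORMAT\t", sample) else ""))
  c(hdr, body)
}
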