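# independent brute-force oracles; deliberately literal re-derivations that
# share no code with the package internals

.CMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# literal both-strand scan: build the reverse-complement strand, list its
# cytosines and gCn motifs, map minus coordinates back to plus, count inside
# the clipped window
brute_window_counts <- function(genome, contig, pos, window = 20) {
  seqc <- strsplit(unclass(as_genome(genome))[[contig]], "", fixed = TRUE)[[1]]
  n <- length(seqc)
  minus <- rev(unname(.CMP[seqc]))
  lo <- max(1, pos - window)
  hi <- min(n, pos + window)
  in_win <- function(p) p >= lo & p <= hi

  plus_c <- which(seqc == "C")
  pg <- plus_c[plus_c >= 2]
  plus_gcn <- pg[seqc[pg - 1] == "G"]

  minus_c <- which(minus == "C")
  mg <- minus_c[minus_c >= 2]
  minus_gcn <- mg[minus[mg - 1] == "G"]
  minus_c_plus <- n - minus_c + 1
  minus_gcn_plus <- n - minus_gcn + 1

  c(n_cyt = sum(in_win(plus_c)) + sum(in_win(minus_c_plus)),
    n_gcn = sum(in_win(plus_gcn)) + sum(in_win(minus_gcn_plus)))
}

# strand collapse of one record, or NA when unclassifiable
brute_collapse <- function(seqc, pos, ref, alt) {
  n <- length(seqc)
  if (pos == 1 || pos == n) return(NULL)
  tri <- seqc[(pos - 1):(pos + 1)]
  if (any(tri == "N")) return(NULL)
  if (ref %in% c("A", "G")) {
    list(klass = paste0(.CMP[[ref]], ">", .CMP[[alt]]),
         tri = rev(unname(.CMP[tri])))
  } else {
    list(klass = paste0(ref, ">", alt), tri = tri)
  }
}

brute_build_table <- function(genome, muts, window = 20) {
  seqs <- unclass(as_genome(genome))
  ms <- 0; ma <- 0; cs <- 0; ca <- 0
  for (i in seq_len(nrow(muts))) {
    seqc <- strsplit(seqs[[muts$contig[i]]], "", fixed = TRUE)[[1]]
    p <- muts$pos[i]
    cl <- brute_collapse(seqc, p, muts$ref[i], muts$alt[i])
    if (is.null(cl) || cl$klass != "C>A") next
    ma <- ma + 1
    sig <- (muts$ref[i] == "C" && seqc[p - 1] == "G") ||
      (muts$ref[i] == "G" && seqc[p + 1] == "C")
    ms <- ms + sig
    wc <- brute_window_counts(genome, muts$contig[i], p, window)
    cs <- cs + wc[["n_gcn"]]
    ca <- ca + wc[["n_cyt"]]
  }
  list(mut_sig = ms, mut_all = ma, ctx_sig = cs, ctx_all = ca)
}

brute_spectrum_classes <- function(genome, muts) {
  seqs <- unclass(as_genome(genome))
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  counts <- setNames(numeric(6), classes)
  skipped <- 0
  for (i in seq_len(nrow(muts))) {
    seqc <- strsplit(seqs[[muts$contig[i]]], "", fixed = TRUE)[[1]]
    cl <- brute_collapse(seqc, muts$pos[i], muts$ref[i], muts$alt[i])
    if (is.null(cl)) skipped <- skipped + 1 else {
      counts[cl$klass] <- counts[cl$klass] + 1
    }
  }
  list(counts = counts, skipped = skipped)
}

# hypergeometric tail enumeration for the one-sided (greater) Fisher test
brute_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  if (r1 == 0) return(1)
  support <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(N, k)
  sum(exp(logp[support >= a]))
}

# literal step-up Benjamini-Hochberg definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(sorted[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Mann-Whitney by enumerating all rank assignments (no ties)
brute_mw_two_sided <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  w_obs <- sum(rank(c(x, y))[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(N, nx)
  ws <- colSums(sets) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
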