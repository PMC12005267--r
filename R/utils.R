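# shared internal helpers: base complementation, IUPAC sets, seeded evaluation

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(.COMP[x])

revcomp <- function(s) {
  vapply(s, function(one) {
    paste(rev(unname(.COMP[strsplit(one, "", fixed = TRUE)[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# lowercase IUPAC codes accepted in motif flanks; 'n' also matches the unknown
# base N so that windowed background counting treats N-adjacent cytosines the
# same way genome-wide counting would
.IUPAC <- list(
  a = "A", c = "C", g = "G", t = "T",
  r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
  k = c("G", "T"), m = c("A", "C"),
  b = c("C", "G", "T"), d = c("A", "G", "T"), h = c("A", "C", "T"),
  v = c("A", "C", "G"),
  n = c("A", "C", "G", "T", "N")
)

iupac_set <- function(code) {
  set <- .IUPAC[[tolower(code)]]
  if (is.null(set)) {
    stop("unknown IUPAC code in motif: '", code, "'", call. = FALSE)
  }
  set
}

# evaluate `code` with the RNG seeded, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
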