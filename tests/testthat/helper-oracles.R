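# Independent brute-force oracles. These re-derive expected behaviour from
# first principles and deliberately share no code with the implementation.

# degenerate sets re-stated independently of the package internals
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_match <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  length(s) == length(p) &&
    all(mapply(function(b, c) b %in% ORACLE_SETS[[c]], s, p))
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# positionwise scanner: every offset, both strands, no shared code with
# scan_sites (regex-based)
oracle_scan <- function(seq, pattern = "TNNCAC", both = TRUE) {
  seq <- toupper(seq)
  L <- nchar(pattern)
  n <- nchar(seq)
  rows <- list()
  for (start0 in seq_len(max(0L, n - L + 1L)) - 1L) {
    win <- substring(seq, start0 + 1L, start0 + L)
    if (oracle_match(win, pattern))
      rows[[length(rows) + 1L]] <- data.frame(
        start = start0, end = start0 + L, strand = "+", core = win,
        stringsAsFactors = FALSE)
    if (both && oracle_match(oracle_revcomp(win), pattern))
      rows[[length(rows) + 1L]] <- data.frame(
        start = start0, end = start0 + L, strand = "-",
        core = oracle_revcomp(win), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(start = integer(0), end = integer(0),
                         strand = character(0), core = character(0))
  out[order(out$start, factor(out$strand, levels = c("+", "-"))), ,
      drop = FALSE]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force interval merging: cluster sorted starts/ends with gap <= window
oracle_clusters <- function(starts, ends, window) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  run <- cumsum(c(TRUE, starts[-1L] - ends[-length(ends)] > window))
  lapply(split(seq_along(starts), run),
         function(i) c(min(starts[i]), max(ends[i]), length(i)))
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}
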