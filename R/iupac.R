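## Degenerate nucleotide sets. Input base N is deliberately absent from every
## set so that masked sequence can never generate a hit (conservative policy).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Core and extended consensus patterns for Brachyury binding sites
#'
#' `core_pattern()` returns the 6-bp TNNCAC core recognised by Brachyury
#' (Ci-Bra) in notochord CRMs; `extended_consensus()` returns the 12-bp
#' degenerate frame RWWNTNRCACYT shared with Drosophila Brachyenteron and
#' vertebrate Brachyury sites, in which the core occupies alignment
#' positions 5-10 (4 bases of 5' flank, 2 bases of 3' flank).
#'
#' @return A single character string (a valid IUPAC pattern).
#' @export
core_pattern <- function() "TNNCAC"

#' @rdname core_pattern
#' @export
extended_consensus <- function() "RWWNTNRCACYT"

check_iupac_pattern <- function(pattern) {
  pattern <- toupper(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  syms <- strsplit(pattern, "")[[1]]
  bad <- setdiff(syms, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "))
  pattern
}

#' Test whether a DNA base belongs to the degenerate set of an IUPAC code
#'
#' Comparison is case-insensitive. An input base `N` (masked sequence) matches
#' no code, including `N` itself: a masked position can never support a site
#' call.
#'
#' @param base Single DNA letter, one of A, C, G, T, N.
#' @param code Single IUPAC nucleotide code.
#' @return `TRUE` iff `base` is in the degenerate set of `code`.
#' @examples
#' iupac_matches("G", "R")  # TRUE:  R = A or G
#' iupac_matches("C", "W")  # FALSE: W = A or T
#' @export
iupac_matches <- function(base, code) {
  base <- toupper(base); code <- toupper(code)
  if (!is.character(base) || length(base) != 1L || !base %in% c("A", "C", "G", "T", "N"))
    stop("invalid base: ", base)
  if (!is.character(code) || length(code) != 1L || !code %in% names(IUPAC_SETS))
    stop("invalid IUPAC code: ", code)
  base %in% IUPAC_SETS[[code]]
}

#' Match a DNA string against an IUPAC pattern of the same length
#'
#' @param seq DNA string over A, C, G, T, N (case-insensitive).
#' @param pattern IUPAC pattern string of the same length.
#' @return `TRUE` iff every position matches per [iupac_matches()].
#' @examples
#' pattern_match("TGGCAC", "TNNCAC")  # TRUE
#' pattern_match("TAACAT", "TNNCAC")  # FALSE
#' @export
pattern_match <- function(seq, pattern) {
  pattern <- check_iupac_pattern(pattern)
  seq <- toupper(seq)
  if (nchar(seq) != nchar(pattern))
    stop("sequence length (", nchar(seq), ") != pattern length (",
         nchar(pattern), ")")
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(s), function(i) {
    if (!s[i] %in% c("A", "C", "G", "T", "N"))
      stop("invalid base in sequence: ", s[i])
    s[i] %in% IUPAC_SETS[[p[i]]]
  }, logical(1)))
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A, C, G, T, N (case-insensitive; output is
#'   uppercase). The empty string maps to itself.
#' @return The reverse complement; `revcomp(revcomp(x)) == toupper(x)`.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("invalid letter in sequence")
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

## Compile an IUPAC pattern into a fixed-length regular expression over
## A/C/G/T. Degenerate codes expand to character classes that exclude N, so
## the conservative N policy is preserved.
iupac_regex <- function(pattern) {
  pattern <- check_iupac_pattern(pattern)
  syms <- strsplit(pattern, "")[[1]]
  paste(vapply(syms, function(s) {
    set <- IUPAC_SETS[[s]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Mismatches of a 12-bp site against the extended consensus
#'
#' Reports the 1-based alignment positions at which a 12-bp site fails the
#' extended consensus (default RWWNTNRCACYT). Comparison is case-insensitive;
#' the printed case of catalog sites is metadata only.
#'
#' @param site12 12-base DNA string.
#' @param consensus IUPAC pattern of length 12.
#' @return A list of class `mismatch_report` with elements `site12`,
#'   `positions` (integer vector, subset of 1..12) and `count`.
#' @examples
#' consensus_mismatches("GACATGGCACTT")$positions  # 3
#' @export
consensus_mismatches <- function(site12, consensus = extended_consensus()) {
  consensus <- check_iupac_pattern(consensus)
  site12 <- toupper(site12)
  if (nchar(site12) != nchar(consensus))
    stop("site length (", nchar(site12), ") != consensus length (",
         nchar(consensus), ")")
  s <- strsplit(site12, "")[[1]]
  p <- strsplit(consensus, "")[[1]]
  bad <- !s %in% c("A", "C", "G", "T", "N")
  if (any(bad)) stop("invalid base in site: ", paste(s[bad], collapse = ", "))
  miss <- which(!mapply(function(b, c) b %in% IUPAC_SETS[[c]], s, p))
  structure(list(site12 = site12, positions = as.integer(miss),
                 count = length(miss)),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(x$site12, ": ", x$count, " mismatch(es)",
      if (x$count) paste0(" at position(s) ", paste(x$positions, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Build a degenerate consensus from aligned sites
#'
#' Computes per-position base frequencies over a set of aligned equal-length
#' sites and emits, at each position, the minimal IUPAC code covering all
#' bases whose frequency reaches `threshold`.
#'
#' @param sites Character vector (>= 2) of equal-length DNA strings.
#' @param threshold Minimum per-position frequency for a base to enter the
#'   emitted code (default 0.05).
#' @return A list with `pattern` (IUPAC string) and `freq` (4 x L matrix of
#'   base frequencies; columns sum to 1).
#' @export
build_consensus <- function(sites, threshold = 0.05) {
  if (length(sites) < 2L) stop("need at least 2 sites")
  sites <- toupper(sites)
  L <- unique(nchar(sites))
  if (length(L) != 1L) stop("sites must all have the same length")
  mat <- do.call(rbind, strsplit(sites, ""))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "T")
  pattern <- vapply(seq_len(L), function(j) {
    bases <- rownames(freq)[freq[, j] >= threshold]
    minimal_code(bases)
  }, character(1))
  list(pattern = paste(pattern, collapse = ""), freq = freq)
}

## Smallest IUPAC code whose set equals the given base set.
minimal_code <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS))
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  stop("no IUPAC code for base set: ", paste(bases, collapse = ""))
}
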