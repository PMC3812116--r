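#' Scan a sequence for core-pattern matches on one or both strands
#'
#' Finds every offset at which the oriented subsequence matches the degenerate
#' core pattern. Coordinates are 0-based half-open on the forward strand;
#' `core` is reported in site orientation (i.e. reverse-complemented for
#' minus-strand hits). Overlapping and nested matches are all reported.
#'
#' @param seq DNA string (A/C/G/T/N; case-insensitive). N never matches.
#' @param seq_id Sequence identifier carried into the output.
#' @param pattern IUPAC pattern (default the TNNCAC core).
#' @param strands `"both"` or `"forward"`.
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `strand` (+/-), `core`, sorted by `start` then strand
#'   (+ before -).
#' @examples
#' scan_sites("GACATGGCACTT", "Ci-Noto9-site", strands = "forward")
#' @export
scan_sites <- function(seq, seq_id = "seq", pattern = core_pattern(),
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(pattern)
  rx <- paste0("(?=", iupac_regex(pattern), ")")

  hit_starts <- function(s) {
    if (nchar(s) < L) return(integer(0))
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }

  fwd <- hit_starts(seq)               # 1-based
  res <- data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    core = character(0), stringsAsFactors = FALSE)
  if (length(fwd))
    res <- data.frame(seq_id = seq_id, start = fwd - 1L, end = fwd - 1L + L,
                      strand = "+", core = substring(seq, fwd, fwd + L - 1L),
                      stringsAsFactors = FALSE)
  if (strands == "both") {
    rc <- revcomp(seq)
    rev_hits <- hit_starts(rc)         # 1-based on the reverse strand
    if (length(rev_hits)) {
      n <- nchar(seq)
      start0 <- n - (rev_hits - 1L) - L    # forward-coordinate 0-based start
      minus <- data.frame(seq_id = seq_id, start = start0, end = start0 + L,
                          strand = "-",
                          core = substring(rc, rev_hits, rev_hits + L - 1L),
                          stringsAsFactors = FALSE)
      res <- rbind(res, minus)
    }
  }
  res <- res[order(res$start, factor(res$strand, levels = c("+", "-"))), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate site matches with 12-bp context and consensus mismatches
#'
#' For each hit the extended 12-bp context (4 bases 5' of the core, core,
#' 2 bases 3'; all in site orientation) is extracted and compared to the
#' extended consensus. Hits whose context window overruns a sequence end keep
#' the core hit but carry no context or mismatch report; downstream
#' classification treats them as low-confidence. The catalog requirement
#' status of each (oriented) core is also filled in.
#'
#' @param sites Data frame from [scan_sites()] (single sequence).
#' @param seq The sequence the sites came from.
#' @param catalog A [site_catalog()].
#' @param consensus 12-bp IUPAC pattern (default RWWNTNRCACYT).
#' @return `sites` with added columns `context12`, `mm_count`,
#'   `mm_positions` (comma-separated, "" when zero, NA without context) and
#'   `core_status`.
#' @export
annotate_sites <- function(sites, seq, catalog = site_catalog(),
                           consensus = extended_consensus()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  up <- 4L; down <- 2L    # flank widths of the 12-bp alignment frame
  if (nrow(sites) && (min(sites$start) < 0L || max(sites$end) > n))
    stop("site coordinates outside the sequence")
  context <- character(nrow(sites))
  mm_count <- rep(NA_integer_, nrow(sites))
  mm_pos <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$start[i]; e0 <- sites$end[i]
    if (sites$strand[i] == "+") {
      lo <- s0 - up; hi <- e0 + down
    } else {
      lo <- s0 - down; hi <- e0 + up
    }
    if (lo < 0L || hi > n) { context[i] <- NA_character_; next }
    win <- substring(seq, lo + 1L, hi)
    if (sites$strand[i] == "-") win <- revcomp(win)
    context[i] <- win
    mm <- consensus_mismatches(win, consensus)
    mm_count[i] <- mm$count
    mm_pos[i] <- paste(mm$positions, collapse = ",")
  }
  sites$context12 <- context
  sites$mm_count <- mm_count
  sites$mm_positions <- mm_pos
  sites$core_status <- if (nrow(sites))
    vapply(sites$core, core_status, character(1), catalog = catalog)
  else character(0)
  rownames(sites) <- NULL
  sites
}

#' Spacing between consecutive site matches
#'
#' Gaps use the edge-to-edge convention: `gap = downstream$start -
#' upstream$end` for consecutive pairs on one sequence. The helical offset is
#' the gap modulo the B-DNA helical period (10.5 bp); gaps that differ by
#' ~10.5 bp keep the two sites on the same helical face.
#'
#' @param sites Data frame of matches on one `seq_id`, sorted by `start`.
#' @param helical_period Helical period in bp (default 10.5).
#' @return Data frame with one row per consecutive pair: `up_start`,
#'   `up_core`, `down_start`, `down_core`, `gap`, `helical_offset`.
#' @export
site_spacing <- function(sites, helical_period = 10.5) {
  if (length(unique(sites$seq_id)) > 1L)
    stop("spacing requires matches from a single sequence")
  if (is.unsorted(sites$start))
    stop("matches must be sorted by start")
  if (nrow(sites) < 2L)
    return(data.frame(up_start = integer(0), up_core = character(0),
                      down_start = integer(0), down_core = character(0),
                      gap = integer(0), helical_offset = numeric(0)))
  i <- seq_len(nrow(sites) - 1L)
  gap <- sites$start[i + 1L] - sites$end[i]
  data.frame(up_start = sites$start[i], up_core = sites$core[i],
             down_start = sites$start[i + 1L], down_core = sites$core[i + 1L],
             gap = gap, helical_offset = gap %% helical_period)
}

#' Write site matches as BED6
#'
#' Name is the core hexamer; score is `12 - mm_count` when the 12-bp context
#' is present, else 0 (low-confidence edge hits).
#'
#' @param sites Annotated site data frame (see [annotate_sites()]).
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_sites_bed <- function(sites, file) {
  score <- ifelse(is.na(sites$mm_count), 0L, 12L - sites$mm_count)
  bed <- data.frame(sites$seq_id, sites$start, sites$end, sites$core,
                    score, sites$strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(sites)
}
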