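ONSET_LABELS <- c(early = "110-cell--early gastrula",
                  middle = "late gastrula/neural plate",
                  late_or_indirect = "neurula; relay candidate")

ZERO_SITE_CAVEAT <- paste(
  "late_or_indirect is a conditional prediction: it is valid only if the",
  "sequence is independently known to be notochord-active, in which case the",
  "CRM is a candidate for indirect (relay) regulation by Brachyury.")

#' Flag confident Brachyury sites
#'
#' A site is confident when its oriented core hexamer belongs to the chosen
#' whitelist of catalog cores and its 12-bp context carries at most
#' `max_flank_mm` mismatches against the extended consensus. Sites lacking a
#' complete context window (sequence edges) never count.
#'
#' @param sites Annotated site data frame (see [annotate_sites()]).
#' @param catalog A [site_catalog()].
#' @param max_flank_mm Maximum flank mismatches (default 4, the maximum
#'   observed among the 24 catalogued functional sites).
#' @param whitelist `"required_only"` (default; the 9 required cores) or
#'   `"required_plus_represented"`.
#' @return Logical vector along the rows of `sites`.
#' @export
confident_sites <- function(sites, catalog = site_catalog(),
                            max_flank_mm = 4,
                            whitelist = c("required_only",
                                          "required_plus_represented")) {
  whitelist <- match.arg(whitelist)
  wl <- core_whitelist(whitelist, catalog)
  toupper(sites$core) %in% wl &
    !is.na(sites$mm_count) & sites$mm_count <= max_flank_mm
}

#' Construct a CRM candidate
#'
#' @param seq_id Sequence identifier.
#' @param start,end 0-based half-open interval.
#' @param sites Annotated site data frame (possibly empty) inside the
#'   interval.
#' @return Unclassified object of class `crm_candidate`.
#' @export
crm_candidate <- function(seq_id, start, end, sites) {
  if (nrow(sites) && (min(sites$start) < start || max(sites$end) > end))
    stop("sites outside the candidate interval")
  structure(list(seq_id = seq_id, start = start, end = end, sites = sites,
                 n_confident = NA_integer_, architecture = NA_character_,
                 spacing = NULL),
            class = "crm_candidate")
}

#' Cluster site matches into CRM candidates
#'
#' Confident sites (per [confident_sites()]) are clustered into maximal runs
#' in which consecutive sites lie at most `window` bp apart (edge-to-edge);
#' each run becomes one candidate spanning the first site start to the last
#' site end. Candidates are classified on the way out.
#'
#' @param sites Annotated site data frame for one or more sequences, sorted
#'   by `seq_id` and `start`.
#' @param window Clustering window in bp (> 0; default 300, the upper end of
#'   the minimal-CRM size range).
#' @param min_sites Minimum confident sites per emitted candidate (default 1).
#' @inheritParams confident_sites
#' @return List of classified `crm_candidate` objects.
#' @export
call_candidates <- function(sites, window = 300, min_sites = 1,
                            catalog = site_catalog(), max_flank_mm = 4,
                            whitelist = "required_only") {
  if (window <= 0) stop("window must be > 0")
  conf <- sites[confident_sites(sites, catalog, max_flank_mm, whitelist), ,
                drop = FALSE]
  out <- list()
  for (id in unique(conf$seq_id)) {
    s <- conf[conf$seq_id == id, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (!nrow(s)) next
    gap_before <- c(Inf, s$start[-1L] - s$end[-nrow(s)])
    run <- cumsum(gap_before > window)
    for (r in unique(run)) {
      block <- s[run == r, , drop = FALSE]
      if (nrow(block) < min_sites) next
      cand <- crm_candidate(id, min(block$start), max(block$end), block)
      out[[length(out) + 1L]] <- classify_candidate(cand, catalog,
                                                    max_flank_mm, whitelist)
    }
  }
  out
}

#' Classify the architecture of a CRM candidate
#'
#' Counts confident sites and assigns the architecture class: `multiple`
#' (>= 2 confident sites; cooperative control), `single` (exactly 1), or
#' `none` (no confident site; candidate for indirect/relay regulation).
#' Cooperativity itself is not inferable from sequence: "multiple" is defined
#' purely by the confident-site count.
#'
#' @param candidate A [crm_candidate()].
#' @inheritParams confident_sites
#' @return The candidate with `n_confident`, `architecture` and `spacing`
#'   filled in.
#' @export
classify_candidate <- function(candidate, catalog = site_catalog(),
                               max_flank_mm = 4,
                               whitelist = "required_only") {
  conf <- candidate$sites[confident_sites(candidate$sites, catalog,
                                          max_flank_mm, whitelist), ,
                          drop = FALSE]
  candidate$n_confident <- nrow(conf)
  candidate$architecture <- if (nrow(conf) >= 2L) "multiple"
                            else if (nrow(conf) == 1L) "single"
                            else "none"
  candidate$spacing <- if (nrow(conf) >= 2L)
    site_spacing(conf[order(conf$start), , drop = FALSE])
  else NULL
  candidate
}

#' Predict the developmental onset class of a classified candidate
#'
#' Deterministic mapping from architecture to temporal onset of notochord
#' activity: multiple sites -> early (110-cell to early gastrula), a single
#' site -> middle (late gastrula/neural plate), no site -> late/indirect
#' (neurula; relay candidate). The zero-site prediction is conditional (see
#' the `caveat` field).
#'
#' @param candidate A classified [crm_candidate()].
#' @return List of class `onset_prediction` with `onset_class`,
#'   `stage_label`, `basis` (the confident-site count) and, for zero-site
#'   candidates, `caveat`.
#' @export
predict_onset <- function(candidate) {
  if (is.na(candidate$architecture))
    stop("candidate must be classified before onset prediction")
  cls <- switch(candidate$architecture,
                multiple = "early", single = "middle",
                none = "late_or_indirect")
  res <- list(onset_class = cls, stage_label = unname(ONSET_LABELS[cls]),
              basis = candidate$n_confident)
  if (cls == "late_or_indirect") res$caveat <- ZERO_SITE_CAVEAT
  structure(res, class = "onset_prediction")
}

#' @export
print.crm_candidate <- function(x, ...) {
  cat(sprintf("CRM candidate %s:%d-%d  sites=%d confident=%s arch=%s\n",
              x$seq_id, x$start, x$end, nrow(x$sites),
              ifelse(is.na(x$n_confident), "?", x$n_confident),
              ifelse(is.na(x$architecture), "unclassified", x$architecture)))
  invisible(x)
}

#' @export
print.onset_prediction <- function(x, ...) {
  cat(sprintf("onset: %s (%s), based on %d confident site(s)\n",
              x$onset_class, x$stage_label, x$basis))
  invisible(x)
}
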