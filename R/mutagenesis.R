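#' Specify an in-silico site mutation
#'
#' The packaged `cac_to_tct` scheme reproduces the canonical core ablation:
#' the CAC at bases 4-6 of a TNNCAC core becomes TCT (e.g. TGGCAC ->
#' TGGTCT), destroying the core match while preserving length. CAC-targeting
#' mutations were the most effective ablation in vivo, hence the named
#' default; arbitrary same-length replacements are available for everything
#' else (e.g. homeodomain-site ablation AATTAA -> TTTTGC).
#'
#' @param start 0-based start of the target interval on the forward strand.
#' @param strand `"+"` or `"-"`: orientation in which the scheme is applied.
#' @param scheme `"cac_to_tct"` (target must be a 6-bp TNNCAC core) or
#'   `"custom"`.
#' @param replacement Replacement string in site orientation (`custom` only).
#' @param width Width of the target interval (default 6; `custom` must match
#'   `nchar(replacement)`).
#' @return List of class `mutation_spec`.
#' @export
mutation_spec <- function(start, strand = "+",
                          scheme = c("cac_to_tct", "custom"),
                          replacement = NULL, width = 6L) {
  scheme <- match.arg(scheme)
  stopifnot(strand %in% c("+", "-"), start >= 0)
  if (scheme == "custom") {
    if (is.null(replacement)) stop("custom scheme needs a replacement string")
    width <- nchar(replacement)
  } else if (width != 6L) {
    stop("cac_to_tct applies to a 6-bp core")
  }
  structure(list(start = as.integer(start), strand = strand, scheme = scheme,
                 replacement = replacement, width = as.integer(width)),
            class = "mutation_spec")
}

#' Apply a site ablation to a sequence
#'
#' Length-preserving, idempotent: re-applying the same `cac_to_tct` spec to
#' an already-ablated core is a no-op. A `cac_to_tct` target that matches
#' neither TNNCAC nor its ablated form TNNTCT is an error.
#'
#' @param seq DNA string.
#' @param spec A [mutation_spec()].
#' @return The mutated sequence (uppercase).
#' @examples
#' ablate("AATGGCACTT", mutation_spec(2))  # TGGCAC -> TGGTCT
#' @export
ablate <- function(seq, spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  seq <- toupper(seq)
  lo <- spec$start; hi <- spec$start + spec$width   # 0-based half-open
  if (lo < 0L || hi > nchar(seq))
    stop("mutation target outside the sequence")
  target <- substring(seq, lo + 1L, hi)
  oriented <- if (spec$strand == "-") revcomp(target) else target
  if (spec$scheme == "cac_to_tct") {
    if (pattern_match(oriented, "TNNTCT")) return(seq)  # already ablated
    if (!pattern_match(oriented, core_pattern()))
      stop("cac_to_tct target does not match the TNNCAC core: ", oriented)
    mutated <- paste0(substring(oriented, 1L, 3L), "TCT")
  } else {
    mutated <- toupper(spec$replacement)
  }
  if (spec$strand == "-") mutated <- revcomp(mutated)
  paste0(substring(seq, 1L, lo), mutated, substring(seq, hi + 1L))
}

#' Ablate sites and predict the architecture/onset shift
#'
#' Applies the given ablations to the candidate's sequence, re-scans and
#' re-classifies the candidate interval, and maps the resulting architecture
#' to a predicted activity: `multiple -> active_early`, `single ->
#' active_middle`, and all confident sites ablated on a direct-target
#' candidate -> `inactive`. Confident sites of a multiple-site candidate are
#' treated as jointly necessary only when fully ablated; graded residual
#' activity after partial ablation of >2-site CRMs is flagged as a caveat,
#' not modelled.
#'
#' @param candidate A classified [crm_candidate()].
#' @param seq The sequence the candidate was called on.
#' @param ablations List of [mutation_spec()] (possibly empty), each
#'   targeting a site inside the candidate interval.
#' @inheritParams confident_sites
#' @param pattern Core pattern used for re-scanning.
#' @return List of class `mutation_effect`: `seq_mutated`, `before`/`after`
#'   (classified candidates), `predicted_architecture`,
#'   `predicted_activity` (`active_early`, `active_middle`, `inactive`, or
#'   `conditional_late` for candidates that had no site to begin with), and
#'   optionally `caveat`.
#' @export
predict_effect <- function(candidate, seq, ablations = list(),
                           catalog = site_catalog(), max_flank_mm = 4,
                           whitelist = "required_only",
                           pattern = core_pattern()) {
  if (is.na(candidate$architecture))
    stop("candidate must be classified first")
  for (spec in ablations) {
    if (spec$start < candidate$start ||
        spec$start + spec$width > candidate$end)
      stop("ablation at ", spec$start, " targets outside the candidate ",
           candidate$start, "-", candidate$end)
  }
  mut <- seq
  for (spec in ablations) mut <- ablate(mut, spec)
  rescan <- annotate_sites(scan_sites(mut, seq_id = candidate$seq_id,
                                      pattern = pattern),
                           mut, catalog)
  inside <- rescan[rescan$start >= candidate$start &
                     rescan$end <= candidate$end, , drop = FALSE]
  after <- classify_candidate(
    crm_candidate(candidate$seq_id, candidate$start, candidate$end, inside),
    catalog, max_flank_mm, whitelist)
  activity <- switch(after$architecture,
                     multiple = "active_early",
                     single = "active_middle",
                     none = if (candidate$n_confident > 0L) "inactive"
                            else "conditional_late")
  res <- list(seq_mutated = mut, before = candidate, after = after,
              predicted_architecture = after$architecture,
              predicted_activity = activity)
  ablated_n <- candidate$n_confident - after$n_confident
  if (candidate$n_confident > 2L && ablated_n > 0L &&
      after$n_confident >= 1L)
    res$caveat <- paste("partial ablation of a >2-site CRM: residual graded",
                        "activity is possible and not modelled")
  structure(res, class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("architecture %s -> %s; predicted activity: %s\n",
              x$before$architecture, x$predicted_architecture,
              x$predicted_activity))
  if (!is.null(x$caveat)) cat("caveat:", x$caveat, "\n")
  invisible(x)
}

#' Tabulate mutations as a delimited log
#'
#' @param seq Original sequence.
#' @param ablations List of [mutation_spec()].
#' @return Data frame with `start`, `strand`, `scheme`, `before`, `after`.
#' @export
mutation_log <- function(seq, ablations) {
  seq <- toupper(seq)
  rows <- lapply(ablations, function(spec) {
    before <- substring(seq, spec$start + 1L, spec$start + spec$width)
    after <- substring(ablate(seq, spec), spec$start + 1L,
                       spec$start + spec$width)
    data.frame(start = spec$start, strand = spec$strand, scheme = spec$scheme,
               before = before, after = after, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
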