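NOTOCHORD_CATEGORIES <- c("notochord_only", "notochord_plus_other")

#' Per-group staining fractions
#'
#' Converts a long staining count table (one row per construct, stage and
#' tissue-pattern category) into category fractions of the per-group total,
#' mirroring the convention of reporting the percentage of embryos showing
#' staining in a tissue as a fraction of all scored embryos in the group.
#'
#' @param table Data frame with columns `construct`, `stage`, `category`,
#'   `count` (counts >= 0).
#' @return Data frame with added `total`, `fraction` and `undefined` columns;
#'   groups whose total is zero are flagged `undefined = TRUE` with `NA`
#'   fractions (no error is thrown).
#' @examples
#' tab <- data.frame(construct = "wt", stage = "tailbud",
#'                   category = c("notochord_only", "notochord_plus_other",
#'                                "other_only"),
#'                   count = c(50, 30, 20))
#' staining_fractions(tab)$fraction  # 0.5 0.3 0.2
#' @export
staining_fractions <- function(table) {
  stopifnot(all(c("construct", "stage", "category", "count") %in%
                  names(table)))
  if (any(table$count < 0)) stop("counts must be >= 0")
  key <- interaction(table$construct, table$stage, drop = TRUE)
  totals <- tapply(table$count, key, sum)
  table$total <- as.numeric(totals[as.character(key)])
  table$undefined <- table$total == 0
  table$fraction <- ifelse(table$undefined, NA_real_,
                           table$count / table$total)
  table
}

#' Earliest stage at which notochord staining crosses a threshold
#'
#' Stages are taken in the order given by `stages` (or the factor levels /
#' first appearance of `table$stage`). The notochord-stained fraction at each
#' stage is the summed count of `notochord_categories` divided by the stage
#' total. The default threshold 0.10 follows the ~10% first-detection
#' convention; with `threshold = 0` the first stage with any notochord-stained
#' embryo qualifies.
#'
#' @param table Staining table for a single construct (columns `stage`,
#'   `category`, `count`).
#' @param threshold Fraction in `[0, 1]` (default 0.10).
#' @param stages Optional character vector giving stage order.
#' @param notochord_categories Categories counted as notochord staining.
#' @return List with `stage` (the qualifying stage name or `"none"`) and the
#'   per-stage `fractions`.
#' @export
onset_from_timecourse <- function(table, threshold = 0.10, stages = NULL,
                                  notochord_categories = NOTOCHORD_CATEGORIES) {
  if (!nrow(table)) stop("empty staining table")
  if (is.null(stages))
    stages <- if (is.factor(table$stage)) levels(table$stage)
              else unique(as.character(table$stage))
  frac <- vapply(stages, function(st) {
    rows <- table[as.character(table$stage) == st, , drop = FALSE]
    tot <- sum(rows$count)
    if (tot == 0) return(NA_real_)
    sum(rows$count[rows$category %in% notochord_categories]) / tot
  }, numeric(1))
  qualifies <- if (threshold > 0) !is.na(frac) & frac >= threshold
               else !is.na(frac) & frac > 0
  hit <- which(qualifies)
  list(stage = if (length(hit)) stages[hit[1L]] else "none",
       fractions = stats::setNames(frac, stages))
}

#' Exact two-sided test for equality of two proportions
#'
#' Fisher's exact (conditional hypergeometric) test on the 2x2 table
#' `(k1, n1-k1; k2, n2-k2)`: the two-sided p-value sums the probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one. Used as a documented stand-in where the source analysis
#' reports unspecified significance stars on staining proportions.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return Two-sided p-value.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  for (v in c(k1, n1, k2, n2))
    if (v < 0 || v != round(v)) stop("counts must be non-negative integers")
  if (k1 > n1 || k2 > n2 || n1 == 0 || n2 == 0)
    stop("invalid counts: need 0 <= k <= n and n > 0")
  m <- k1 + k2
  x <- max(0L, m - n2):min(n1, m)          # support of the first cell
  probs <- stats::dhyper(x, n1, n2, m)
  p_obs <- stats::dhyper(k1, n1, n2, m)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10 input mass over a dilution series.
#' The amplification efficiency is `10^(-1/slope) - 1` (1.0 = perfect
#' doubling, i.e. a Ct step of 1/log10(2) ~ 3.32 cycles per 10-fold
#' dilution).
#'
#' @param standards Data frame with column `ct` and either `mass` (ng) or
#'   `dilution` (fold dilution of the starting mass).
#' @param start_mass Starting mass in ng for dilution-style input
#'   (default 20).
#' @return List of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared` and the underlying `fit`.
#' @export
standard_curve <- function(standards, start_mass = 20) {
  stopifnot("ct" %in% names(standards))
  mass <- if ("mass" %in% names(standards)) standards$mass
          else if ("dilution" %in% names(standards)) {
            if (any(standards$dilution <= 0)) stop("dilution factors must be > 0")
            start_mass / standards$dilution
          } else stop("standards need a 'mass' or 'dilution' column")
  if (length(unique(mass)) < 2L)
    stop("degenerate fit: need at least 2 distinct dilution levels")
  fit <- stats::lm(ct ~ log10(mass), data = data.frame(ct = standards$ct,
                                                       mass = mass))
  slope <- unname(stats::coef(fit)[2L])
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Ct = %.3f %+.3f * log10(mass);  efficiency = %.3f  (R^2 = %.4f)\n",
              x$intercept, x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Interpolate quantities from Ct values via a standard curve
#'
#' @param ct Numeric Ct values.
#' @param curve A [standard_curve()].
#' @return Quantities on the mass scale of the standards.
#' @export
quantity_from_ct <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' ChIP-qPCR percent input, fold change and significance
#'
#' Quantities are interpolated from the fitted standard curve (not delta-delta
#' Ct). Percent input of an immunoprecipitated sample is
#' `100 * quantity_IP / (quantity_input / input_fraction)`; the fold change is
#' the ratio of mean antibody to mean IgG quantities, and the p-value is a
#' two-tailed Student's t test across replicate percent-input values.
#'
#' @param run List with elements `standards` (see [standard_curve()]),
#'   `samples` (data frame with `role` in `"ip"` (specific antibody), `"igg"`
#'   (mock control) and `"input"`, plus `ct` and `replicate`) and
#'   `input_fraction` (fraction of chromatin used as input, e.g. 0.01).
#' @param start_mass Passed to [standard_curve()].
#' @return List of class `chip_result`: `curve`, `percent_input` (data frame
#'   per IP replicate), `fold_change`, `p_value`.
#' @export
chip_enrichment <- function(run, start_mass = 20) {
  stopifnot(all(c("standards", "samples", "input_fraction") %in% names(run)))
  samples <- run$samples
  if (!any(samples$role == "igg")) stop("IgG control samples are required")
  if (!any(samples$role == "ip")) stop("antibody (ip) samples are required")
  if (!any(samples$role == "input")) stop("input samples are required")
  curve <- standard_curve(run$standards, start_mass = start_mass)
  q <- quantity_from_ct(samples$ct, curve)
  q_input <- mean(q[samples$role == "input"])
  adj_input <- q_input / run$input_fraction
  pct <- 100 * q / adj_input
  ip <- samples$role == "ip"; igg <- samples$role == "igg"
  percent_input <- data.frame(role = samples$role[ip | igg],
                              replicate = samples$replicate[ip | igg],
                              percent_input = pct[ip | igg])
  fold <- mean(q[ip]) / mean(q[igg])
  p <- if (stats::sd(pct[ip]) < 1e-12 && stats::sd(pct[igg]) < 1e-12) {
    if (abs(mean(pct[ip]) - mean(pct[igg])) < 1e-12) 1 else 0
  } else {
    stats::t.test(pct[ip], pct[igg], var.equal = TRUE)$p.value
  }
  structure(list(curve = curve, percent_input = percent_input,
                 fold_change = fold, p_value = p,
                 input_fraction = run$input_fraction),
            class = "chip_result")
}

#' @export
print.chip_result <- function(x, ...) {
  cat(sprintf("fold change (antibody/IgG) = %.2f;  t-test p = %.3g\n",
              x$fold_change, x$p_value))
  invisible(x)
}

#' Read/write delimited staining tables and qPCR runs
#'
#' Plain TSV round-trip for the two assay-table formats: staining tables
#' (`construct`, `stage`, `category`, `count`) and qPCR runs written as two
#' files (`<stem>_standards.tsv`, `<stem>_samples.tsv`) plus the input
#' fraction recorded in a JSON sidecar (`<stem>_meta.json`).
#'
#' @param file,stem Paths.
#' @param table,run Objects to write.
#' @return The read object, or the input invisibly for writers.
#' @export
read_staining_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_staining_table
#' @export
write_staining_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' @rdname read_staining_table
#' @export
write_qpcr_run <- function(run, stem) {
  utils::write.table(run$standards, paste0(stem, "_standards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$samples, paste0(stem, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(input_fraction = run$input_fraction),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(run)
}

#' @rdname read_staining_table
#' @export
read_qpcr_run <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"))
  list(standards = utils::read.delim(paste0(stem, "_standards.tsv"),
                                     stringsAsFactors = FALSE),
       samples = utils::read.delim(paste0(stem, "_samples.tsv"),
                                   stringsAsFactors = FALSE),
       input_fraction = meta$input_fraction)
}
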