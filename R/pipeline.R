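#' Build and validate a pipeline run configuration
#'
#' A single validated configuration object drives every pipeline stage.
#' Defaults are the documented paper-mode values: TNNCAC core,
#' RWWNTNRCACYT extended consensus, required-cores-only whitelist, 300-bp
#' clustering window, at most 4 flank mismatches, both-strand scanning with
#' single-strand null expectation, Poisson tail.
#'
#' @param fasta Input FASTA path (required by the run stages).
#' @param out_dir Output directory (created if missing).
#' @param pattern,consensus IUPAC patterns.
#' @param whitelist `"required_only"` or `"required_plus_represented"`.
#' @param window Clustering window in bp.
#' @param max_flank_mm Maximum flank mismatches for a confident site.
#' @param strands Scan mode, `"both"` or `"forward"`.
#' @param null_strands 1 or 2: strand convention of the enrichment null.
#' @param null_method `"poisson"` or `"binomial"`.
#' @param onset_threshold Staining-fraction threshold for onset calls.
#' @param seed Optional integer seed.
#' @param targets Data frame of mutation targets (`seq_id`, `start`,
#'   `strand`, `scheme`) for [run_mutate()].
#' @param config_file Optional JSON file of settings; explicit arguments
#'   override file values, which override defaults.
#' @return List of class `notocrm_config`.
#' @export
notocrm_config <- function(fasta = NULL, out_dir = tempfile("notocrm_"),
                           pattern = core_pattern(),
                           consensus = extended_consensus(),
                           whitelist = "required_only", window = 300,
                           max_flank_mm = 4,
                           strands = "both", null_strands = 1,
                           null_method = "poisson", onset_threshold = 0.10,
                           seed = NULL, targets = NULL, config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    supplied <- names(as.list(match.call()))[-1L]
    for (k in setdiff(names(file_cfg), c(supplied, "config_file")))
      cfg[[k]] <- file_cfg[[k]]
  }
  check_iupac_pattern(cfg$pattern)
  check_iupac_pattern(cfg$consensus)
  stopifnot(cfg$whitelist %in% c("required_only",
                                 "required_plus_represented"),
            cfg$window > 0, cfg$max_flank_mm >= 0,
            cfg$strands %in% c("both", "forward"),
            cfg$null_strands %in% c(1, 2),
            cfg$null_method %in% c("poisson", "binomial"),
            cfg$onset_threshold >= 0, cfg$onset_threshold <= 1)
  structure(cfg, class = "notocrm_config")
}

run_log <- function(config, stage, catalog) {
  list(stage = stage,
       parameters = config[setdiff(names(unclass(config)),
                                   c("targets"))],
       catalog_checksum = catalog$checksum,
       package_version = as.character(utils::packageVersion("notocrm")))
}

scan_all <- function(config, catalog) {
  seqs <- read_fasta(config$fasta)
  rows <- lapply(names(seqs), function(id)
    annotate_sites(scan_sites(seqs[[id]], seq_id = id,
                              pattern = config$pattern,
                              strands = config$strands),
                   seqs[[id]], catalog, consensus = config$consensus))
  list(seqs = seqs, sites = do.call(rbind, rows))
}

#' Run the site-scanning stage
#'
#' Scans every FASTA record for core matches, annotates them, and writes a
#' sorted BED6 file, a delimited detail table and a JSON log recording all
#' parameters and the catalog checksum. Re-running with the same
#' configuration produces byte-identical outputs; an empty FASTA yields
#' empty outputs with a warning.
#'
#' @param config A [notocrm_config()] with `fasta` set.
#' @return Invisibly, a list with `sites` and the output `files`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "notocrm_config"))
  if (is.null(config$fasta)) stop("config$fasta is required")
  catalog <- site_catalog()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- scan_all(config, catalog)
  if (!length(sc$seqs)) warning("empty FASTA: writing empty outputs")
  sites <- sc$sites
  if (is.null(sites)) sites <- annotate_sites(
    scan_sites("ACGT")[0, ], "ACGT", catalog)
  files <- file.path(config$out_dir,
                     c(bed = "sites.bed", detail = "sites.tsv",
                       log = "scan_log.json"))
  names(files) <- c("bed", "detail", "log")
  write_sites_bed(sites, files[["bed"]])
  utils::write.table(sites, files[["detail"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(run_log(config, "scan", catalog), files[["log"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sites = sites, files = files))
}

#' Run the CRM-prediction workflow
#'
#' Per locus: scan and annotate sites, cluster confident sites into
#' candidates (a locus with no confident site becomes one zero-site
#' candidate spanning the whole record, carrying the conditional
#' late/indirect caveat), classify, predict onset, and compute the
#' random-occurrence enrichment statistic. Writes a JSON report, a delimited
#' summary and a BED of candidate intervals.
#'
#' @param config A [notocrm_config()] with `fasta` set.
#' @return Invisibly, a list with `report` (per-locus list), `candidates`
#'   and the output `files`.
#' @export
run_predict <- function(config) {
  stopifnot(inherits(config, "notocrm_config"))
  if (is.null(config$fasta)) stop("config$fasta is required")
  catalog <- site_catalog()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- scan_all(config, catalog)
  report <- list(); all_cands <- list(); summary_rows <- list()
  for (id in names(sc$seqs)) {
    seq <- sc$seqs[[id]]
    sites <- sc$sites[sc$sites$seq_id == id, , drop = FALSE]
    cands <- call_candidates(sites, window = config$window,
                             catalog = catalog,
                             max_flank_mm = config$max_flank_mm,
                             whitelist = config$whitelist)
    if (!length(cands))
      cands <- list(classify_candidate(
        crm_candidate(id, 0L, nchar(seq), sites), catalog,
        config$max_flank_mm, config$whitelist))
    enr <- site_enrichment(seq, pattern = config$pattern,
                           bg = uniform_background(),
                           strands = if (config$null_strands == 1) "forward"
                                     else "both",
                           method = config$null_method)
    loc_report <- lapply(cands, function(cand) {
      onset <- predict_onset(cand)
      out <- list(seq_id = cand$seq_id, start = cand$start, end = cand$end,
                  n_sites = nrow(cand$sites),
                  n_confident = cand$n_confident,
                  architecture = cand$architecture,
                  onset_class = onset$onset_class,
                  stage_label = onset$stage_label,
                  spacing = cand$spacing,
                  sites = cand$sites)
      if (!is.null(onset$caveat)) out$caveat <- onset$caveat
      out
    })
    report[[id]] <- list(locus = id, length = nchar(seq),
                         enrichment = list(observed = enr$observed,
                                           expected = enr$expected,
                                           p_tail = enr$p_tail,
                                           strands = enr$strands,
                                           method = enr$method),
                         candidates = loc_report)
    all_cands <- c(all_cands, cands)
    for (cand in loc_report)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        locus = id, start = cand$start, end = cand$end,
        architecture = cand$architecture, n_confident = cand$n_confident,
        onset_class = cand$onset_class, stage_label = cand$stage_label,
        stringsAsFactors = FALSE)
  }
  files <- file.path(config$out_dir,
                     c("predict_report.json", "predict_summary.tsv",
                       "candidates.bed"))
  names(files) <- c("report", "summary", "bed")
  jsonlite::write_json(list(log = run_log(config, "predict", catalog),
                            loci = unname(report)),
                       files[["report"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.table(do.call(rbind, summary_rows), files[["summary"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates_bed(all_cands, files[["bed"]])
  invisible(list(report = report, candidates = all_cands, files = files))
}

#' Run the in-silico mutagenesis stage
#'
#' Applies the configured ablation targets, writes the mutated FASTA and a
#' before/after classification diff per locus.
#'
#' @param config A [notocrm_config()] with `fasta` and `targets` set;
#'   `targets` is a data frame with columns `seq_id`, `start`, `strand`
#'   (optional, default "+") and `scheme` (optional, default
#'   `"cac_to_tct"`).
#' @return Invisibly, a list with `effects` per locus and output `files`.
#' @export
run_mutate <- function(config) {
  stopifnot(inherits(config, "notocrm_config"))
  if (is.null(config$fasta)) stop("config$fasta is required")
  catalog <- site_catalog()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- config$targets
  if (is.null(targets) || !nrow(targets)) {
    warning("no mutation targets given: no-op")
    return(invisible(list(effects = list(), files = character(0))))
  }
  if (!all(targets$seq_id %in% names(read_fasta(config$fasta))))
    stop("mutation target names a sequence absent from the FASTA")
  sc <- scan_all(config, catalog)
  effects <- list(); mutated <- sc$seqs; diff_rows <- list()
  for (id in unique(targets$seq_id)) {
    seq <- sc$seqs[[id]]
    sites <- sc$sites[sc$sites$seq_id == id, , drop = FALSE]
    cands <- call_candidates(sites, window = config$window,
                             catalog = catalog,
                             max_flank_mm = config$max_flank_mm,
                             whitelist = config$whitelist)
    if (!length(cands))
      cands <- list(classify_candidate(
        crm_candidate(id, 0L, nchar(seq), sites), catalog,
        config$max_flank_mm, config$whitelist))
    tr <- targets[targets$seq_id == id, , drop = FALSE]
    specs <- lapply(seq_len(nrow(tr)), function(j)
      mutation_spec(tr$start[j],
                    strand = if ("strand" %in% names(tr)) tr$strand[j]
                             else "+",
                    scheme = if ("scheme" %in% names(tr)) tr$scheme[j]
                             else "cac_to_tct",
                    replacement = if ("replacement" %in% names(tr))
                      tr$replacement[j] else NULL))
    cand <- cands[[which.max(vapply(cands, function(x) x$n_confident,
                                    integer(1)))]]
    eff <- predict_effect(cand, seq, specs, catalog,
                          config$max_flank_mm, config$whitelist,
                          pattern = config$pattern)
    effects[[id]] <- eff
    mutated[[id]] <- eff$seq_mutated
    diff_rows[[id]] <- data.frame(
      locus = id, before = eff$before$architecture,
      after = eff$predicted_architecture,
      predicted_activity = eff$predicted_activity,
      stringsAsFactors = FALSE)
  }
  files <- file.path(config$out_dir,
                     c("mutated.fasta", "mutation_diff.tsv",
                       "mutate_log.json"))
  names(files) <- c("fasta", "diff", "log")
  write_fasta(mutated, files[["fasta"]])
  utils::write.table(do.call(rbind, c(diff_rows,
                                      list(make.row.names = FALSE))),
                     files[["diff"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(run_log(config, "mutate", catalog), files[["log"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(effects = effects, files = files))
}

#' Generate and persist a synthetic genome
#'
#' Wraps [gen_genome()] and writes the FASTA, the BED truth intervals and a
#' JSON manifest of all parameters for provenance.
#'
#' @param config A [notocrm_config()]; the seed is taken from it.
#' @param n_loci,class_mix,locus_length,gc,scrub Passed to [gen_genome()].
#' @return Invisibly, the `synthetic_genome` plus output `files`.
#' @export
run_simulate <- function(config, n_loci = 30,
                         class_mix = c(early = 1/3, middle = 1/3,
                                       late_or_indirect = 1/3),
                         locus_length = 600, gc = 0.5, scrub = TRUE) {
  stopifnot(inherits(config, "notocrm_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- gen_genome(n_loci = n_loci, class_mix = class_mix,
                       locus_length = locus_length, gc = gc,
                       seed = config$seed, scrub = scrub,
                       whitelist = config$whitelist,
                       max_flank_mm = config$max_flank_mm)
  files <- file.path(config$out_dir,
                     c("synthetic.fasta", "truth.tsv", "truth_sites.bed",
                       "manifest.json"))
  names(files) <- c("fasta", "truth", "bed", "manifest")
  write_fasta(genome$sequences, files[["fasta"]])
  utils::write.table(genome$truth, files[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ts <- genome$truth_sites
  if (nrow(ts))
    utils::write.table(data.frame(ts$locus, ts$start, ts$end, ts$core, 0L,
                                  ts$strand),
                       files[["bed"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  else file.create(files[["bed"]])
  jsonlite::write_json(genome$manifest, files[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, files = files))
}
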