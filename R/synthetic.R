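NOTOCHORD_STAGES <- c("110-cell", "early gastrula", "mid gastrula",
                      "late gastrula", "neural plate", "neurula",
                      "initial tailbud", "early tailbud")

## Class-specific logistic activation midpoints on the stage index scale
## (18 C staging): multiple-site CRMs switch on around the 110-cell/early
## gastrula transition, single-site around late gastrula/neural plate,
## indirect targets around neurulation.
ACTIVATION_DEFAULTS <- list(
  midpoint = c(early = 1.5, middle = 4.5, late_or_indirect = 6.5),
  scale = 0.5, plateau = 0.8)

#' Generate an i.i.d. background sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`; the same seed reproduces the same sequence
#' byte for byte.
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed Optional integer seed.
#' @return DNA string.
#' @export
gen_background <- function(length, gc = 0.5, seed = NULL) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Describe a set of sites to plant in a locus
#'
#' @param cores Character vector of TNNCAC hexamers, in 5'->3' genomic order.
#' @param orientations `"+"`/`"-"` per core (recycled).
#' @param flank_fidelity Per core (recycled): `"exact_consensus"` (flanks
#'   chosen to satisfy every consensus position that the core allows),
#'   `"paper_site"` (a catalogued functional 12-mer with that core, falling
#'   back to `exact_consensus` when none exists) or `"random"`.
#' @param spacings Gaps in bp between consecutive cores (edge-to-edge;
#'   length = number of cores - 1).
#' @param intended_class `"early"`, `"middle"` or `"late_or_indirect"`;
#'   must be consistent with the core count (>= 2 / 1 / 0).
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(cores = character(0), orientations = "+",
                       flank_fidelity = "exact_consensus",
                       spacings = integer(0),
                       intended_class = NULL) {
  cores <- toupper(cores)
  for (h in cores)
    if (!pattern_match(h, core_pattern()))
      stop("core does not match TNNCAC: ", h)
  n <- length(cores)
  if (n >= 2L && length(spacings) != n - 1L)
    stop("need length(cores) - 1 spacings")
  if (is.null(intended_class))
    intended_class <- if (n >= 2L) "early" else if (n == 1L) "middle"
                      else "late_or_indirect"
  expected <- if (n >= 2L) "early" else if (n == 1L) "middle"
              else "late_or_indirect"
  if (intended_class != expected)
    stop("intended_class '", intended_class, "' inconsistent with ", n,
         " planted site(s)")
  structure(list(cores = cores,
                 orientations = rep(orientations, length.out = n),
                 flank_fidelity = rep(flank_fidelity, length.out = n),
                 spacings = as.integer(spacings),
                 intended_class = intended_class),
            class = "plant_spec")
}

## Build the 12-mer to embed for one core. exact_consensus places flanks
## AAAA...CT, which satisfy R/W/W/N and Y/T; the only possible residual
## mismatch is alignment position 7 (core base 3) when that base is a
## pyrimidine, which the consensus does not allow for any flank choice.
make_site12 <- function(core, fidelity, catalog) {
  switch(fidelity,
    exact_consensus = paste0("AAAA", core, "CT"),
    paper_site = {
      hits <- catalog$sites$site12[
        toupper(substr(catalog$sites$site12, 5, 10)) == core]
      if (length(hits)) toupper(hits[[1L]]) else paste0("AAAA", core, "CT")
    },
    random = paste0(paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                          collapse = ""),
                    core,
                    paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                          collapse = "")),
    stop("unknown flank fidelity: ", fidelity))
}

#' Plant a CRM of known architecture into a background sequence
#'
#' Each core is embedded inside its 12-bp alignment frame (4 bp 5' flank,
#' 2 bp 3' flank, in site orientation) at deterministic offsets such that
#' consecutive cores are separated edge-to-edge by the requested spacings.
#' Scanning the output finds every planted site.
#'
#' @param background DNA string.
#' @param spec A [plant_spec()].
#' @param offset 0-based start of the first core.
#' @param seed Optional seed (used by `"random"` flank fidelity).
#' @param catalog A [site_catalog()].
#' @return List with `seq` and `truth` (data frame: `start`, `end`,
#'   `strand`, `core`, `site12`) of class `synthetic_locus`, plus
#'   `intended_class`.
#' @export
plant_crm <- function(background, spec, offset = 100L, seed = NULL,
                      catalog = site_catalog()) {
  stopifnot(inherits(spec, "plant_spec"))
  if (!is.null(seed)) set.seed(seed)
  seq <- toupper(background)
  n <- nchar(seq)
  k <- length(spec$cores)
  starts <- integer(k)
  if (k) {
    starts[1L] <- as.integer(offset)
    if (k > 1L)
      for (i in 2:k) starts[i] <- starts[i - 1L] + 6L + spec$spacings[i - 1L]
  }
  truth <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), core = character(0),
                      site12 = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    site12 <- make_site12(spec$cores[i], spec$flank_fidelity[i], catalog)
    s0 <- starts[i]
    if (spec$orientations[i] == "+") {
      lo <- s0 - 4L; hi <- s0 + 8L
      block <- site12
    } else {
      lo <- s0 - 2L; hi <- s0 + 10L
      block <- revcomp(site12)
    }
    if (lo < 0L || hi > n)
      stop("planted span [", lo, ",", hi, ") overflows the ", n,
           "-bp background")
    seq <- paste0(substring(seq, 1L, lo), block, substring(seq, hi + 1L))
    truth <- rbind(truth,
                   data.frame(start = s0, end = s0 + 6L,
                              strand = spec$orientations[i],
                              core = spec$cores[i], site12 = site12,
                              stringsAsFactors = FALSE))
  }
  hits <- scan_sites(seq)
  for (i in seq_len(nrow(truth)))
    if (!any(hits$start == truth$start[i] & hits$strand == truth$strand[i]))
      stop("internal error: planted site not recovered by the scanner")
  structure(list(seq = seq, truth = truth,
                 intended_class = spec$intended_class),
            class = "synthetic_locus")
}

#' Generate a synthetic multi-locus genome with planted architectures
#'
#' Per locus, a background is drawn and a CRM of the assigned class is
#' planted: early loci get two cooperative required cores (the
#' TAACAC/TCACAC pair with a 35- or 45-bp gap, the two spacings observed for
#' this arrangement in vivo), middle loci one required core, late loci none.
#' With `scrub = TRUE` backgrounds are rejection-sampled until they contain
#' no whitelisted core on either strand, and the planted locus is verified to
#' classify to its intended class, so chance hits cannot contaminate the
#' truth labels; generation fails with diagnostics after `max_retries`
#' rejected draws for a locus.
#'
#' @param n_loci Number of loci.
#' @param class_mix Named fractions for `early`, `middle`,
#'   `late_or_indirect` (must sum to 1; converted to deterministic counts).
#' @param locus_length Length of each locus in bp (default 600).
#' @param gc Background GC fraction.
#' @param seed Integer seed (the whole genome is a pure function of it).
#' @param scrub Reject chance whitelisted cores (default TRUE).
#' @param max_retries Retry bound per locus (default 1000).
#' @param catalog,whitelist,max_flank_mm Classification parameters used for
#'   scrubbing/verification.
#' @return List of class `synthetic_genome`: `sequences` (named character),
#'   `truth` (data frame: `locus`, `intended_class`, `n_sites`, plus one row
#'   per planted site), `manifest` (all parameters + seed).
#' @export
gen_genome <- function(n_loci = 30,
                       class_mix = c(early = 1/3, middle = 1/3,
                                     late_or_indirect = 1/3),
                       locus_length = 600, gc = 0.5, seed = NULL,
                       scrub = TRUE, max_retries = 1000,
                       catalog = site_catalog(),
                       whitelist = "required_only", max_flank_mm = 4) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  classes <- rep(names(class_mix), round(class_mix * n_loci))
  if (length(classes) < n_loci)
    classes <- c(classes, rep(names(class_mix)[1L],
                              n_loci - length(classes)))
  classes <- classes[seq_len(n_loci)]
  wl <- core_whitelist(whitelist, catalog)
  rx <- paste0("(?=", iupac_regex(core_pattern()), ")")

  has_whitelisted <- function(s) {
    hits <- scan_sites(s)
    any(hits$core %in% wl)
  }

  sequences <- character(n_loci)
  names(sequences) <- sprintf("locus_%02d", seq_len(n_loci))
  site_rows <- list()
  for (i in seq_len(n_loci)) {
    cls <- classes[i]
    spec <- switch(cls,
      early = plant_spec(c("TAACAC", "TCACAC"),
                         spacings = sample(c(35L, 45L), 1L),
                         flank_fidelity = "paper_site"),
      middle = plant_spec(sample(c("TGGCAC", "TGACAC", "TAACAC"), 1L),
                          flank_fidelity = "paper_site"),
      late_or_indirect = plant_spec())
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      bg <- gen_background(locus_length, gc = gc)
      if (scrub && has_whitelisted(bg)) next
      locus <- plant_crm(bg, spec, offset = 100L, catalog = catalog)
      if (scrub) {
        # planting can create whitelisted cores at the block/background
        # junctions: require the whitelisted hit set to equal the planted set
        hits <- scan_sites(locus$seq)
        wl_hits <- hits[hits$core %in% wl, , drop = FALSE]
        if (!identical(sort(paste(wl_hits$start, wl_hits$strand)),
                       sort(paste(locus$truth$start, locus$truth$strand))))
          next
        sites <- annotate_sites(hits, locus$seq, catalog)
        cands <- call_candidates(sites, catalog = catalog,
                                 max_flank_mm = max_flank_mm,
                                 whitelist = whitelist)
        recovered <- if (length(cands) == 1L)
          predict_onset(cands[[1L]])$onset_class
        else if (length(cands) == 0L) "late_or_indirect"
        else "ambiguous"
        if (recovered != cls) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("scrub failed for locus ", i, " (class ", cls, ") after ",
           max_retries, " retries; lower gc or shorten the locus")
    sequences[i] <- locus$seq
    if (nrow(locus$truth))
      site_rows[[length(site_rows) + 1L]] <-
        cbind(locus = names(sequences)[i], locus$truth,
              stringsAsFactors = FALSE)
  }
  truth_sites <- if (length(site_rows)) do.call(rbind, site_rows)
                 else data.frame(locus = character(0))
  truth <- data.frame(locus = names(sequences), intended_class = classes,
                      n_sites = vapply(names(sequences), function(l)
                        sum(truth_sites$locus == l), integer(1)),
                      stringsAsFactors = FALSE)
  structure(list(sequences = sequences, truth = truth,
                 truth_sites = truth_sites,
                 manifest = list(n_loci = n_loci,
                                 class_mix = as.list(class_mix),
                                 locus_length = locus_length, gc = gc,
                                 seed = seed, scrub = scrub,
                                 whitelist = whitelist,
                                 max_flank_mm = max_flank_mm)),
            class = "synthetic_genome")
}

#' Logistic notochord-activation probability per stage
#'
#' @param stage_index Integer stage index (1 = 110-cell, see
#'   `NOTOCHORD_STAGES`).
#' @param intended_class Onset class.
#' @param activation List with `midpoint` (named per class), `scale`,
#'   `plateau`.
#' @return Probability of notochord staining at that stage.
#' @export
activation_curve <- function(stage_index, intended_class,
                             activation = ACTIVATION_DEFAULTS) {
  mid <- activation$midpoint[[intended_class]]
  activation$plateau / (1 + exp(-(stage_index - mid) / activation$scale))
}

#' Expected onset stage of a synthetic time-course
#'
#' The first stage at which the configured logistic activation reaches the
#' detection threshold; this is what [onset_from_timecourse()] should
#' recover from generated tables.
#'
#' @inheritParams activation_curve
#' @param stages Stage names in order.
#' @param threshold Detection threshold (default 0.10).
#' @return Stage name.
#' @export
expected_onset_stage <- function(intended_class, stages = NOTOCHORD_STAGES,
                                 activation = ACTIVATION_DEFAULTS,
                                 threshold = 0.10) {
  p <- activation_curve(seq_along(stages), intended_class, activation)
  stages[which(p >= threshold)[1L]]
}

#' Generate a staged embryo-staining count table
#'
#' Binomial draws around a class-specific logistic activation curve: at each
#' stage, `n_per_stage` scored embryos stain in the notochord with the
#' logistic probability; notochord-stained embryos split into
#' notochord-only/notochord-plus-other, the rest into other-only/no-staining.
#'
#' @param intended_class Onset class driving the activation midpoint.
#' @param stages Ordered stage names.
#' @param n_per_stage Scored embryos per stage (> 0).
#' @param activation See [activation_curve()].
#' @param p_other Probability that a non-notochord embryo stains elsewhere.
#' @param p_noto_plus Probability that a notochord-stained embryo also stains
#'   elsewhere.
#' @param seed Optional seed.
#' @param construct Construct label for the table.
#' @return Staining table data frame (`construct`, `stage` as ordered factor,
#'   `category`, `count`).
#' @export
gen_embryo_counts <- function(intended_class, stages = NOTOCHORD_STAGES,
                              n_per_stage = 300,
                              activation = ACTIVATION_DEFAULTS,
                              p_other = 0.15, p_noto_plus = 0.4,
                              seed = NULL, construct = "synthetic") {
  if (n_per_stage <= 0) stop("n_per_stage must be > 0")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(stages), function(i) {
    p <- activation_curve(i, intended_class, activation)
    k <- stats::rbinom(1L, n_per_stage, p)
    k_plus <- stats::rbinom(1L, k, p_noto_plus)
    other <- stats::rbinom(1L, n_per_stage - k, p_other)
    data.frame(construct = construct, stage = stages[i],
               category = c("notochord_only", "notochord_plus_other",
                            "other_only", "no_staining"),
               count = c(k - k_plus, k_plus, other,
                         n_per_stage - k - other),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stage <- factor(out$stage, levels = stages, ordered = TRUE)
  out
}

#' Generate a synthetic ChIP-qPCR run with known ground truth
#'
#' Standards follow `Ct = intercept + slope * log10(mass)` with
#' `slope = -1/log10(1 + efficiency)` over the 5-/50-/500-/5,000-fold
#' dilution design (duplicates, 20 ng starting mass), plus Gaussian Ct noise.
#' Samples encode a planted antibody/IgG quantity ratio.
#'
#' @param enrichment_fold Planted IP/IgG enrichment (> 0).
#' @param efficiency Amplification efficiency in (0, 1].
#' @param replicates Biological replicates per role.
#' @param sigma_ct Gaussian Ct noise SD in cycles (default 0.15).
#' @param input_fraction Fraction of chromatin used as input (default 0.01).
#' @param igg_quantity IgG-precipitated quantity in ng.
#' @param input_quantity Input-aliquot quantity in ng.
#' @param ct_at_1ng Curve intercept (Ct of 1 ng).
#' @param seed Optional seed.
#' @return A qPCR run (list with `standards`, `samples`, `input_fraction`)
#'   plus a `truth` element recording the planted parameters.
#' @export
gen_qpcr <- function(enrichment_fold = 8, efficiency = 1.0, replicates = 3,
                     sigma_ct = 0.15, input_fraction = 0.01,
                     igg_quantity = 0.004, input_quantity = 0.5,
                     ct_at_1ng = 25, seed = NULL) {
  if (enrichment_fold <= 0) stop("enrichment_fold must be > 0")
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  slope <- -1 / log10(1 + efficiency)
  ct_of <- function(mass) ct_at_1ng + slope * log10(mass)
  dil <- rep(c(5, 50, 500, 5000), each = 2L)
  standards <- data.frame(dilution = dil, mass = 20 / dil)
  standards$ct <- ct_of(standards$mass) +
    stats::rnorm(nrow(standards), 0, sigma_ct)
  roles <- rep(c("ip", "igg", "input"), each = replicates)
  qty <- rep(c(enrichment_fold * igg_quantity, igg_quantity,
               input_quantity), each = replicates)
  samples <- data.frame(role = roles,
                        replicate = rep(seq_len(replicates), 3L),
                        ct = ct_of(qty) +
                          stats::rnorm(length(qty), 0, sigma_ct),
                        stringsAsFactors = FALSE)
  list(standards = standards, samples = samples,
       input_fraction = input_fraction,
       truth = list(enrichment_fold = enrichment_fold,
                    efficiency = efficiency, sigma_ct = sigma_ct))
}
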