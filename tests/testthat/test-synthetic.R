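test_that("gen_background is reproducible with the stated composition", {
  expect_identical(gen_background(500, 0.4, seed = 1),
                   gen_background(500, 0.4, seed = 1))
  expect_false(identical(gen_background(500, 0.4, seed = 1),
                         gen_background(500, 0.4, seed = 2)))
  s <- gen_background(20000, gc = 0.6, seed = 3)
  gc_obs <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.6), 3 * sqrt(0.6 * 0.4 / 20000))
  expect_error(gen_background(100, gc = 1.2), "gc")
})

test_that("extreme GC starves the scanner of TNNCAC hits", {
  s <- gen_background(2000, gc = 0.999, seed = 4)
  expect_lte(nrow(scan_sites(s, strands = "forward")),
             ceiling(10 * expected_count(2000, bg = gc_background(0.999))))
})

test_that("Monte-Carlo scan counts match the analytic expectation", {
  set.seed(8)
  n_sim <- 300
  counts <- vapply(seq_len(n_sim), function(i)
    nrow(scan_sites(gen_background(1200), strands = "forward")),
    numeric(1))
  expected <- expected_count(1200)
  se <- sd(counts) / sqrt(n_sim)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("plant_crm writes recoverable sites with the requested geometry", {
  bg <- gen_background(600, seed = 10)
  spec <- plant_spec(c("TAACAC", "TCACAC"), spacings = 35,
                     flank_fidelity = "paper_site")
  loc <- plant_crm(bg, spec, offset = 120)
  expect_identical(nchar(loc$seq), 600L)
  hits <- scan_sites(loc$seq)
  for (i in seq_len(nrow(loc$truth)))
    expect_true(any(hits$start == loc$truth$start[i] &
                      hits$core == loc$truth$core[i]))
  expect_identical(loc$truth$start[2] - loc$truth$end[1], 35L)
  # empty spec leaves the background untouched
  empty <- plant_crm(bg, plant_spec())
  expect_identical(empty$seq, toupper(bg))
  expect_identical(nrow(empty$truth), 0L)
  expect_error(plant_crm(gen_background(30, seed = 1), spec, offset = 10),
               "overflow")
})

test_that("planted orientations and fidelities behave as declared", {
  bg <- strrep("G", 200)
  minus <- plant_crm(bg, plant_spec("TGGCAC", orientations = "-"),
                     offset = 50)
  hit <- scan_sites(minus$seq)
  expect_identical(hit$strand, "-")
  expect_identical(hit$core, "TGGCAC")
  exact <- plant_crm(bg, plant_spec("TAACAC",
                                    flank_fidelity = "exact_consensus",
                                    intended_class = "middle"),
                     offset = 50)
  ann <- annotate_sites(scan_sites(exact$seq), exact$seq)
  expect_identical(ann$mm_count[ann$start == 50], 0L)
  # paper_site embeds a catalogued 12-mer for cores that have one
  ps <- plant_crm(bg, plant_spec("TGGCAC", flank_fidelity = "paper_site"),
                  offset = 50)
  expect_true(toupper(ps$truth$site12) %in%
                toupper(site_catalog()$sites$site12))
  expect_error(plant_spec("TAACAC", intended_class = "early"),
               "inconsistent")
})

test_that("gen_genome is deterministic and honours the class mix", {
  g1 <- gen_genome(n_loci = 9, seed = 21, locus_length = 400)
  g2 <- gen_genome(n_loci = 9, seed = 21, locus_length = 400)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(as.integer(table(g1$truth$intended_class)[
    c("early", "middle", "late_or_indirect")]), rep(3L, 3))
  # all-late mix plants no sites anywhere
  late <- gen_genome(n_loci = 4, class_mix = c(early = 0, middle = 0,
                                               late_or_indirect = 1),
                     seed = 22, locus_length = 400)
  expect_identical(nrow(late$truth_sites), 0L)
  expect_error(gen_genome(class_mix = c(early = 0.5, middle = 0.2,
                                        late_or_indirect = 0.2)),
               "sum to 1")
})

test_that("scrubbed loci contain no chance whitelisted cores", {
  g <- gen_genome(n_loci = 6, seed = 23, locus_length = 400)
  wl <- core_whitelist("required_only")
  for (id in names(g$sequences)) {
    hits <- scan_sites(g$sequences[[id]])
    planted <- g$truth_sites[g$truth_sites$locus == id, , drop = FALSE]
    chance <- hits[hits$core %in% wl &
                     !(hits$start %in% planted$start), , drop = FALSE]
    expect_identical(nrow(chance), 0L)
  }
})

test_that("gen_embryo_counts encodes the class-staggered activation", {
  tab <- gen_embryo_counts("early", n_per_stage = 500, seed = 31)
  expect_true(all(tapply(tab$count, tab$stage, sum) == 500))
  ons <- onset_from_timecourse(tab)
  expect_identical(ons$stage, expected_onset_stage("early"))
  expect_error(gen_embryo_counts("early", n_per_stage = 0), "> 0")
  # class ordering: early onset precedes middle precedes late
  stages <- notocrm:::NOTOCHORD_STAGES
  idx <- vapply(c("early", "middle", "late_or_indirect"),
                function(cls) match(expected_onset_stage(cls), stages),
                numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("gen_qpcr standards follow the configured efficiency curve", {
  run <- gen_qpcr(efficiency = 0.9, sigma_ct = 0, seed = 41)
  curve <- standard_curve(run$standards)
  expect_equal(curve$efficiency, 0.9, tolerance = 1e-9)
  run2 <- gen_qpcr(seed = 42)
  expect_identical(run2$samples$ct, gen_qpcr(seed = 42)$samples$ct)
  expect_error(gen_qpcr(enrichment_fold = -1), "> 0")
  expect_error(gen_qpcr(efficiency = 1.5), "efficiency")
})
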