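make_table <- function(counts, construct = "wt", stage = "tailbud") {
  data.frame(construct = construct, stage = stage,
             category = names(counts), count = unname(counts),
             stringsAsFactors = FALSE)
}

test_that("staining_fractions normalises per group and flags zero totals", {
  tab <- make_table(c(notochord_only = 50, notochord_plus_other = 30,
                      other_only = 20))
  out <- staining_fractions(tab)
  expect_equal(out$fraction, c(0.5, 0.3, 0.2))
  expect_equal(sum(out$fraction), 1)
  single <- staining_fractions(make_table(c(notochord_only = 7)))
  expect_equal(single$fraction, 1)
  zero <- staining_fractions(make_table(c(notochord_only = 0)))
  expect_true(zero$undefined)
  expect_true(is.na(zero$fraction))
  expect_error(staining_fractions(make_table(c(notochord_only = -1))),
               ">= 0")
})

test_that("generated tables recover their category probabilities", {
  set.seed(99)
  tab <- gen_embryo_counts("early", n_per_stage = 2000, seed = 99)
  last <- tab[tab$stage == "early tailbud", ]
  noto <- sum(last$count[last$category %in%
                           c("notochord_only", "notochord_plus_other")])
  n <- sum(last$count)
  p <- activation_curve(8, "early")
  expect_lt(abs(noto / n - p), 2 * sqrt(p * (1 - p) / n) + 0.01)
})

test_that("onset_from_timecourse finds the first qualifying stage", {
  stages <- paste0("st", 1:5)
  tab <- do.call(rbind, lapply(1:5, function(i)
    data.frame(construct = "wt", stage = stages[i],
               category = c("notochord_only", "other_only"),
               count = c(c(0, 0, 30, 80, 90)[i],
                         100 - c(0, 0, 30, 80, 90)[i]))))
  expect_identical(onset_from_timecourse(tab, 0.10, stages)$stage, "st3")
  allzero <- tab; allzero$count[allzero$category == "notochord_only"] <- 0
  expect_identical(onset_from_timecourse(allzero, 0.10, stages)$stage, "none")
  # threshold 0: first stage with any notochord-stained embryo
  one <- tab; one$count[one$category == "notochord_only"] <- c(0, 1, 5, 5, 5)
  expect_identical(onset_from_timecourse(one, 0, stages)$stage, "st2")
  expect_error(onset_from_timecourse(tab[0, ]), "empty")
})

test_that("compare_proportions is an exact two-sided conditional test", {
  expect_equal(compare_proportions(10, 100, 10, 100), 1.0)
  expect_lt(compare_proportions(0, 50, 50, 50), 1e-20)
  # brute-force hypergeometric enumeration oracle on small tables
  set.seed(44)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    got <- compare_proportions(k1, n1, k2, n2)
    want <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(got, compare_proportions(k2, n2, k1, n1))   # symmetry
  }
  expect_error(compare_proportions(5, 3, 1, 10), "invalid")
})

test_that("standard_curve recovers slope, intercept and efficiency", {
  # perfect doubling: Ct drops by log2(10) ~ 3.3219 per 10-fold dilution
  mass <- 20 / c(5, 50, 500, 5000)
  ct <- 30 - log10(mass) / log10(2)
  curve <- standard_curve(data.frame(mass = mass, ct = ct))
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  # two-point curve against a hand computation
  two <- standard_curve(data.frame(mass = c(10, 1), ct = c(20, 23.5)))
  expect_equal(two$slope, (20 - 23.5) / (log10(10) - log10(1)))
  expect_equal(two$intercept, 23.5)
  expect_error(standard_curve(data.frame(mass = c(1, 1), ct = c(20, 21))),
               "degenerate")
  # dilution-style input reproduces mass-style input
  dil <- standard_curve(data.frame(dilution = c(5, 50, 500, 5000), ct = ct))
  expect_equal(dil$slope, curve$slope)
})

test_that("chip_enrichment computes percent input and fold change", {
  run <- gen_qpcr(enrichment_fold = 8, sigma_ct = 0, seed = 1)
  res <- chip_enrichment(run)
  expect_equal(res$fold_change, 8, tolerance = 1e-9)
  expect_equal(res$curve$efficiency, 1.0, tolerance = 1e-9)
  # percent input of the input sample itself is 100 * input_fraction
  q_in <- quantity_from_ct(run$samples$ct[run$samples$role == "input"][1],
                           res$curve)
  expect_equal(100 * q_in / (q_in / run$input_fraction),
               100 * run$input_fraction)
  expect_error(chip_enrichment(list(standards = run$standards,
                                    samples = run$samples[
                                      run$samples$role != "igg", ],
                                    input_fraction = 0.01)), "IgG")
})

test_that("identical IP and IgG gives fold 1 and p about 1", {
  run <- gen_qpcr(enrichment_fold = 1, sigma_ct = 0, seed = 2)
  res <- chip_enrichment(run)
  expect_equal(res$fold_change, 1, tolerance = 1e-9)
  expect_equal(res$p_value, 1)
})

test_that("fold change is invariant to a curve-consistent Ct shift", {
  run <- gen_qpcr(enrichment_fold = 8, sigma_ct = 0.1, seed = 3)
  base <- chip_enrichment(run)$fold_change
  shifted <- run
  shifted$standards$ct <- shifted$standards$ct + 2.5
  shifted$samples$ct <- shifted$samples$ct + 2.5
  expect_equal(chip_enrichment(shifted)$fold_change, base, tolerance = 1e-9)
})

test_that("assay tables round-trip through the delimited readers", {
  tab <- gen_embryo_counts("middle", seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_staining_table(tab, f)
  back <- read_staining_table(f)
  expect_equal(back$count, tab$count)
  expect_identical(as.character(back$stage), as.character(tab$stage))
  unlink(f)
  run <- gen_qpcr(seed = 6)
  stem <- tempfile()
  write_qpcr_run(run, stem)
  back_run <- read_qpcr_run(stem)
  expect_equal(back_run$standards$ct, run$standards$ct)
  expect_equal(back_run$input_fraction, run$input_fraction)
  file.remove(paste0(stem, c("_standards.tsv", "_samples.tsv",
                             "_meta.json")))
})
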