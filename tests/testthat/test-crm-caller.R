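# two confident required-core sites separated by a chosen gap, with clean
# consensus flanks, inside a site-free background
two_site_seq <- function(gap = 35, pad = 60) {
  left <- strrep("T", pad)
  paste0(left, "AAAA", "TAACAC", "CT", strrep("T", gap - 6),
         "AAAA", "TCACAC", "CT", strrep("T", pad))
}

annotated <- function(seq, id = "locus") {
  annotate_sites(scan_sites(seq, seq_id = id), seq)
}

test_that("two cooperative sites 35 bp apart form one early candidate", {
  sites <- annotated(two_site_seq(35))
  cands <- call_candidates(sites, window = 300)
  expect_length(cands, 1L)
  cand <- cands[[1]]
  expect_identical(cand$architecture, "multiple")
  expect_identical(cand$n_confident, 2L)
  expect_identical(cand$spacing$gap, 35L)
  onset <- predict_onset(cand)
  expect_identical(onset$onset_class, "early")
  expect_identical(onset$stage_label, "110-cell--early gastrula")
})

test_that("an isolated single site yields a middle-onset candidate", {
  seq <- paste0(strrep("T", 50), "ATTT", "TGACAC", "CC", strrep("T", 50))
  cands <- call_candidates(annotated(seq))
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$architecture, "single")
  expect_identical(predict_onset(cands[[1]])$onset_class, "middle")
  expect_identical(predict_onset(cands[[1]])$stage_label,
                   "late gastrula/neural plate")
})

test_that("a zero-site interval is a conditional late/relay candidate", {
  seq <- strrep("GT", 100)       # no TNNCAC anywhere
  sites <- annotated(seq)
  expect_identical(nrow(sites[confident_sites(sites), ]), 0L)
  cand <- classify_candidate(crm_candidate("locus", 0L, nchar(seq), sites))
  expect_identical(cand$architecture, "none")
  onset <- predict_onset(cand)
  expect_identical(onset$onset_class, "late_or_indirect")
  expect_match(onset$caveat, "conditional")
})

test_that("clustering matches a brute-force interval-merging oracle", {
  set.seed(31)
  for (i in 1:20) {
    n_sites <- sample(2:8, 1)
    window <- sample(c(50, 150, 300), 1)
    gaps <- sample(5:500, n_sites - 1, replace = TRUE)
    starts <- cumsum(c(60, gaps + 6L))
    seq_len_total <- max(starts) + 60
    seq <- strrep("T", seq_len_total)
    for (s0 in starts)
      seq <- paste0(substring(seq, 1, s0 - 4), "AAAA", "TAACAC", "CT",
                    substring(seq, s0 + 9))
    sites <- annotated(seq)
    conf <- sites[confident_sites(sites), , drop = FALSE]
    cands <- call_candidates(sites, window = window)
    want <- oracle_clusters(conf$start, conf$end, window)
    expect_length(cands, length(want))
    for (k in seq_along(want)) {
      expect_identical(cands[[k]]$start, want[[k]][1])
      expect_identical(cands[[k]]$end, want[[k]][2])
      expect_identical(cands[[k]]$n_confident, as.integer(want[[k]][3]))
    }
  }
})

test_that("classification is monotone in confident-site removal", {
  sites <- annotated(two_site_seq(35))
  conf_idx <- which(confident_sites(sites))
  full <- classify_candidate(crm_candidate("locus", 0L, 10000L, sites))
  rank <- c(none = 0, single = 1, multiple = 2)
  for (drop in conf_idx) {
    reduced <- classify_candidate(
      crm_candidate("locus", 0L, 10000L, sites[-drop, , drop = FALSE]))
    expect_lte(rank[[reduced$architecture]], rank[[full$architecture]])
  }
})

test_that("whitelist and mismatch thresholds gate confidence", {
  # TTTCAC is represented_only: invisible to the default whitelist
  seq <- paste0(strrep("T", 50), "AAAA", "TTTCAC", "CT", strrep("T", 50))
  sites <- annotated(seq)
  expect_identical(sum(confident_sites(sites)), 0L)
  expect_identical(sum(confident_sites(sites,
                                       whitelist = "required_plus_represented")),
                   1L)
  # a confident core stops counting when the mismatch budget shrinks
  noto9 <- paste0(strrep("T", 30), "GACATGGCACTT", strrep("T", 30))
  s9 <- annotated(noto9)
  expect_identical(sum(confident_sites(s9, max_flank_mm = 1)), 1L)
  expect_identical(sum(confident_sites(s9, max_flank_mm = 0)), 0L)
})

test_that("edge sites without context never count as confident", {
  seq <- paste0("TAACAC", strrep("G", 40))
  sites <- annotated(seq)
  expect_true(any(is.na(sites$mm_count)))
  expect_identical(sum(confident_sites(sites)), 0L)
})

test_that("predict_onset requires a classified candidate", {
  cand <- crm_candidate("x", 0L, 100L,
                        annotated(strrep("G", 100)))
  expect_error(predict_onset(cand), "classified")
  expect_error(call_candidates(annotated(strrep("G", 50)), window = 0),
               "window")
})
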