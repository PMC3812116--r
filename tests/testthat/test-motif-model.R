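test_that("iupac_matches encodes the degenerate sets and rejects bad input", {
  expect_true(iupac_matches("G", "R"))
  expect_true(iupac_matches("T", "W"))
  expect_false(iupac_matches("C", "W"))
  expect_true(iupac_matches("g", "r"))          # case-insensitive
  # conservative policy: masked input never matches, not even N
  for (code in c("A", "N", "R", "B")) expect_false(iupac_matches("N", code))
  expect_error(iupac_matches("G", "X"), "invalid IUPAC code")
  expect_error(iupac_matches("U", "N"), "invalid base")
})

test_that("pattern_match agrees with the site/pattern examples", {
  expect_true(pattern_match("TGGCAC", "TNNCAC"))
  expect_false(pattern_match("TAACAT", "TNNCAC"))   # core-destroying change
  expect_false(pattern_match("TCACGC", "TNNCAC"))
  expect_error(pattern_match("TGGCA", "TNNCAC"), "length")
})

test_that("revcomp is an involution and handles edge cases", {
  expect_identical(revcomp("TGGCAC"), "GTGCCA")
  expect_identical(revcomp(""), "")
  expect_error(revcomp("ACGU"), "invalid")
  set.seed(101)
  for (i in 1:50) {
    s <- random_dna(sample(1:60, 1))
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(revcomp(s), oracle_revcomp(s))
  }
})

test_that("pattern matching commutes with reverse complementation", {
  # matching s against p is equivalent to matching revcomp(s) against the
  # reverse pattern with complemented codes
  comp_code <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 W = "W", S = "S", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")
  rc_pattern <- function(p) paste(rev(comp_code[strsplit(p, "")[[1]]]),
                                  collapse = "")
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(6)
    expect_identical(pattern_match(s, "TNNCAC"),
                     pattern_match(revcomp(s), rc_pattern("TNNCAC")))
  }
})

test_that("consensus_mismatches reproduces printed divergence positions", {
  expect_identical(consensus_mismatches("GACATGGCACTT")$positions, 3L)
  expect_identical(consensus_mismatches("TGATTAACACCT")$positions, c(1L, 2L))
  expect_identical(consensus_mismatches("AATATAACACCT")$positions, integer(0))
  rep <- consensus_mismatches("GACATGGCACTT")
  expect_identical(rep$count, length(rep$positions))
  expect_error(consensus_mismatches("ACGT"), "length")
})

test_that("core_status returns catalog statuses with the expected tallies", {
  cat <- site_catalog()
  expect_identical(core_status("TAACAC", cat), "required")
  expect_identical(core_status("TTTCAC", cat), "represented_only")
  expect_identical(core_status("TTCCAC", cat), "unobserved")
  expect_error(core_status("AAACAC", cat), "TNNCAC")
  tab <- table(cat$cores$status)
  expect_identical(unname(tab[["required"]]), 9L)
  expect_identical(sum(cat$cores$status != "required"), 7L)
})

test_that("core_whitelist modes select the right hexamer sets", {
  cat <- site_catalog()
  expect_length(core_whitelist("required_only", cat), 9L)
  expect_length(core_whitelist("required_plus_represented", cat), 15L)
  expect_false("TTCCAC" %in% core_whitelist("required_plus_represented", cat))
})

test_that("build_consensus recovers fixed positions and normalises", {
  cat <- site_catalog()
  built <- build_consensus(toupper(cat$sites$site12), threshold = 0.05)
  pat <- strsplit(built$pattern, "")[[1]]
  expect_identical(pat[c(5, 8, 9, 10)], c("T", "C", "A", "C"))
  expect_true(all(abs(colSums(built$freq) - 1) < 1e-12))
  # two identical sites collapse to themselves with zero degeneracy
  same <- build_consensus(c("AATATAACACCT", "AATATAACACCT"))
  expect_identical(same$pattern, "AATATAACACCT")
  expect_error(build_consensus(character(0)), "at least 2")
})

test_that("catalog loading validates structure and round-trips", {
  cat <- site_catalog()
  expect_s3_class(cat, "site_catalog")
  expect_identical(nrow(cat$cores), 16L)
  expect_identical(nrow(cat$sites), 24L)
  expect_length(cat$checksum, 2L)
  # every functional site has a TNNCAC core at alignment positions 5-10
  cores <- toupper(substr(cat$sites$site12, 5, 10))
  expect_true(all(vapply(cores, pattern_match, logical(1),
                         pattern = "TNNCAC")))
  # and every such core is present in the core catalog
  expect_true(all(cores %in% cat$cores$hexamer))
})
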