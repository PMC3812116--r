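---
title: "Methods: Brachyury site architecture and the temporal read-out of notochord enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Brachyury site architecture and the temporal read-out of notochord enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notocrm)
```

## The model

In the ascidian notochord, the T-box transcription factor Brachyury (Ci-Bra)
is expressed continuously from early cleavage stages, yet its target genes
switch on in a staggered sequence. The regulatory logic behind this temporal
read-out is encoded in the *architecture* of each target's cis-regulatory
module (CRM): how many functional Brachyury binding sites it carries.

`notocrm` implements this model at the sequence level:

* A **binding site** is a 6-bp core matching the degenerate consensus
  `TNNCAC` (16 possible instantiations), embedded in a 12-bp alignment
  frame `RWWNTNRCACYT` shared with Drosophila Brachyenteron and vertebrate
  Brachyury sites (core at alignment positions 5--10; 4 bp of 5' flank,
  2 bp of 3' flank). The model is consensus/mismatch based throughout: no
  position weight matrix, no log-odds scores, no affinity prediction.
* A packaged **catalog** records, for each of the 16 cores, whether it has
  been experimentally *required* for notochord activity (9 cores), merely
  *represented* in a CRM (6), or never observed (1); and the 24 aligned
  functional 12-bp sites with their individual/cooperative mechanism labels.
* A site found by the scanner is **confident** when its oriented core is on
  the chosen whitelist (default: the 9 required cores) and its 12-bp context
  diverges from the extended consensus at no more than `max_flank_mm`
  positions (default 4, the maximum divergence observed among the 24
  catalogued functional sites). Hits too close to a sequence end to have a
  complete 12-bp context are retained but never count as confident.
* **Architecture and onset.** Confident sites within `window` bp of each
  other (default 300, the upper end of the observed minimal-CRM size range
  of 65--300 bp) form one CRM candidate. A candidate with two or more
  confident sites is classed `multiple` and predicted to activate *early*
  (110-cell--early gastrula); exactly one confident site gives `single` and
  *middle* onset (late gastrula/neural plate); none gives `none` and a
  conditional *late/indirect* prediction (neurula; relay candidate).
  Cooperativity cannot be inferred from sequence, so `multiple` is defined
  purely by count. The zero-site prediction is conditional on independent
  evidence that the sequence is notochord-active; every report carries that
  caveat.
* **Enrichment null.** Putative-site enrichment is judged against an i.i.d.
  background: the expected count is `(L - 5) * p * strands` with `p` the
  product of per-position degenerate-set probabilities, and the tail
  probability is Poisson (exact binomial retained as an oracle). For a
  1,200-bp sequence under a uniform background the single-strand
  expectation is 1195/256 ≈ 4.67 — below 5, which is the convention the
  package adopts as "paper mode" (the printed bound is only consistent with
  single-strand counting); reports always state the strand mode. The null
  ignores the non-independence of overlapping windows, as the back-of-
  envelope original does; this slightly misstates the variance but not the
  mean.
* **In-silico mutagenesis** reproduces the canonical core ablation: the CAC
  half of a TNNCAC core becomes TCT (`TGGCAC -> TGGTCT`), destroying the
  core while preserving length. CAC-targeting mutations were the most
  effective class of ablation in vivo, hence this is the packaged named
  scheme; arbitrary same-length replacements cover everything else (e.g. a
  homeodomain-site ablation `AATTAA -> TTTTGC`). Re-classification after
  ablation yields the predicted shift: removing one of two sites converts an
  early candidate to a middle one; removing all confident sites of a direct
  target predicts inactivity.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pattern` | `TNNCAC` | 6 bp | the Brachyury core consensus |
| `consensus` | `RWWNTNRCACYT` | 12 bp | conserved extended frame |
| `whitelist` | `required_only` | — | the 9 experimentally required cores |
| `max_flank_mm` | 4 | positions | max divergence among the 24 functional sites |
| `window` | 300 | bp | upper end of minimal-CRM sizes (65--300 bp) |
| `null_strands` | 1 | — | the only mode consistent with the printed "<5" bound |
| `onset_threshold` | 0.10 | fraction | the ~10% first-detection convention |
| helical period | 10.5 | bp | B-DNA turn; spacing reports give gap mod 10.5 |

The clustering window is a documented package choice, not a measured value:
no numeric window is stated anywhere in the source analysis. Spacing is
measured edge-to-edge (core end to next core start); the source does not
state its convention, and edge-to-edge makes the two observed two-site
geometries come out at exactly 35 and 45 bp.

## The synthetic world

The generators produce every input the pipeline consumes, with known truth:

* `gen_background(length, gc, seed)` — i.i.d. bases, `P(G)=P(C)=gc/2`.
* `plant_crm()` — writes 12-bp site blocks at deterministic offsets with
  chosen cores, orientations, flank fidelity (`exact_consensus`, a
  catalogued `paper_site`, or `random`) and edge-to-edge spacings. The
  default multi-site geometry is the TAACAC/TCACAC pair at 35 or 45 bp, the
  two spacings observed for this arrangement in vivo.
* `gen_genome()` — 30 loci of 600 bp by default (the scale of the 560-bp
  region from which the two-site prediction was validated). With
  `scrub = TRUE`, backgrounds are rejection-sampled until they carry no
  whitelisted core on either strand, and the planted locus is verified to
  contain whitelisted cores exactly at the planted positions and to
  classify to its intended class (planting can otherwise create junction
  cores). The retry bound is 1,000 per locus, after which generation fails
  with diagnostics rather than silently degrading the truth labels.
* `gen_embryo_counts()` — binomial staining counts around a logistic
  activation curve on the 8-stage index (110-cell ... early tailbud, 18°C
  staging). Midpoints 1.5 / 4.5 / 6.5 for early / middle / late, scale 0.5,
  plateau 0.8: these place first detection (fraction ≥ 0.10) at the
  110-cell, late-gastrula and neurula stages respectively, matching the
  observed staging of the three classes, and keep the expected fraction at
  the onset stage (≈0.22) comfortably clear of the threshold so recovery is
  limited by binomial noise only. The transcription-to-detection lag is
  ignored.
* `gen_qpcr()` — the 5-/50-/500-/5,000-fold dilution design in duplicate
  from 20 ng, `Ct = intercept - log10(mass)/log10(1+E)`, Gaussian Ct noise
  (σ = 0.15 cycles; the source specifies no noise model), and samples
  encoding a planted antibody/IgG ratio.

A green recovery test establishes that the *pipeline arithmetic* is
self-consistent on data drawn from its own assumptions. It does not
establish performance on real genomes: real backgrounds are not i.i.d.
(CpG structure, repeats, composition heterogeneity), real functional sites
are context-dependent (identical cores can be essential in one CRM and
dispensable in another, as the catalogued TGGCAC and TCGCAC cases show),
and chromatin state is not modelled at all.

## Numerical and design choices

* **Masked input.** An `N` in input sequence matches no IUPAC code,
  including `N` — masked regions can never generate hits.
* **Coordinates.** 0-based half-open internally and in BED output; 1-based
  only inside human-readable strings.
* **Minus-strand reporting.** Forward-coordinate start/end with
  orientation-local core and context strings.
* **Degenerate consensus emission.** `build_consensus()` emits the minimal
  IUPAC code covering all bases with per-position frequency ≥ 0.05; the
  threshold is configurable because no value is stated in the source.
* **Case-pattern regression.** Recomputing mismatches for the 24 catalogued
  sites reproduces the printed lowercase marking for 22; the two exceptions
  both print an uppercase T at alignment position 7 although T ∉ R, an
  internal inconsistency of the printed table (other rows lowercase exactly
  this situation). They are whitelisted by name in the regression test.
* **Proportion test.** The source marks significance on staining
  proportions without naming the test; `compare_proportions()` is a
  two-sided Fisher exact (own hypergeometric enumeration, with
  `stats::fisher.test` as the independent test oracle). The qPCR
  comparison uses the named two-tailed Student's t test on replicate
  percent-input values; when both groups are exactly constant and equal the
  p-value is defined as 1.
* **Ct interpolation** uses the fitted standard curve, not ΔΔCt, matching
  the described standard-curve protocol. Efficiency is `10^(-1/slope) - 1`.
* **Ablation idempotency.** `cac_to_tct` on an already-ablated `TNNTCT`
  hexamer is a no-op; on anything else that is not a TNNCAC core it is an
  error. This reconciles idempotent re-application with strict target
  validation.
* **Config files** are JSON (no YAML parser is available in the supported
  dependency set); precedence is CLI flag > file value > default.
* **Scaled simulations.** The Monte-Carlo check of the enrichment null runs
  300 simulated sequences in the unit-test suite and the full 2,000 in
  `scripts/acceptance.R`; both must agree with the analytic expectation
  within 3 standard errors.

## Known limitations

* Graded residual activity (e.g. a three-site CRM that keeps weak activity
  after a double mutation and dies only on the triple) is outside the
  discrete architecture model; `predict_effect()` flags partial ablation of
  >2-site candidates with a caveat instead of guessing.
* The identity of the relay intermediary for zero-site CRMs is unknown and
  not modelled; the late/indirect call is conditional by construction.
* No Markov background, no multiple-testing control across loci, no
  palindromic/dimer site model, no chromatin or conservation tracks.
* Distance to the transcription start site is accepted as annotation but
  never used as a filter: functional sites occur from a few hundred bp
  upstream to >9 kb into a gene body, with no evident positional constraint.
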