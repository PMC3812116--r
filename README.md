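# notocrm

Sequence-level analysis of Brachyury-driven notochord enhancers.

## The problem

In ascidian embryos the T-box transcription factor Brachyury (Ci-Bra) is the
master regulator of notochord formation. It is present in notochord nuclei
essentially continuously, yet its target genes activate in a staggered
temporal sequence. The resolution of this paradox is *cis*-regulatory: the
number of functional Brachyury binding sites in a target's minimal
cis-regulatory module (CRM) sets the developmental onset of its activity.
CRMs with **multiple** cooperative sites switch on *early* (110-cell to
early gastrula), CRMs with a **single** main site switch on in *mid*
development (late gastrula/neural plate), and CRMs with **no** Brachyury
site — indirect targets driven through a relay factor — switch on *late*
(neurula).

`notocrm` packages this model for regulatory genomicists: it scans DNA for
degenerate Brachyury sites, judges their enrichment against a random
background, clusters them into CRM candidates, classifies candidate
architecture, predicts temporal onset, ablates sites in silico to predict
onset shifts, and implements the quantification arithmetic for the two assay
types used to validate such predictions (reporter-staining time courses and
ChIP-qPCR).

## The model in brief

* **Core site:** the 6-bp degenerate consensus `TNNCAC` (16 instantiations;
  a packaged catalog records which 9 are experimentally *required*, which 6
  are merely *represented*, and the 1 never observed).
* **Extended frame:** `RWWNTNRCACYT` (12 bp; core at positions 5–10), the
  consensus conserved between Drosophila Brachyenteron and chordate
  Brachyury sites. A scanner hit is *confident* if its core is whitelisted
  and its 12-bp context has ≤ 4 mismatches to this frame.
* **Enrichment null:** under an i.i.d. background, the expected core count
  in `L` bp on one strand is `(L−5) · Πᵢ P(setᵢ)`; for 1,200 bp uniform
  this is `1195/256 ≈ 4.67` (< 5), with a Poisson upper tail for observed
  counts.
* **Architecture → onset:** ≥ 2 confident sites within 300 bp → `multiple`
  → early; 1 → `single` → middle; 0 → `none` → late/indirect (conditional).
* **Ablation:** `TNNCAC → TNNTCT` (CAC→TCT) destroys a core in place;
  re-classification predicts the onset delay (two sites → one: early →
  middle) or inactivation (all sites ablated).

## Worked example

Plant the two-site geometry observed in vivo (TAACAC + TCACAC, 35-bp gap)
into a clean random background, then analyse it:

```r
library(notocrm)

bg  <- gen_background(600, gc = 0.5, seed = 15)
crm <- plant_crm(bg, plant_spec(c("TAACAC", "TCACAC"), spacings = 35,
                                flank_fidelity = "paper_site"), offset = 150)

sites <- annotate_sites(scan_sites(crm$seq, seq_id = "locus1"), crm$seq)
subset(sites, core_status == "required")
#>   seq_id start end strand   core    context12 mm_count mm_positions core_status
#> 1 locus1   150 156      + TAACAC TGATTAACACCT        2          1,2    required
#> 3 locus1   191 197      + TCACAC AAACTCACACAG        2        11,12    required

cand <- call_candidates(sites)[[1]]
cand
#> CRM candidate locus1:150-197  sites=2 confident=2 arch=multiple
predict_onset(cand)
#> onset: early (110-cell--early gastrula), based on 2 confident site(s)
cand$spacing
#>   up_start up_core down_start down_core gap helical_offset
#> 1      150  TAACAC        191    TCACAC  35            3.5
```

Both planted sites are recovered with their catalogued 12-bp contexts (2
flank mismatches each, well under the 4 allowed), they cluster into one
candidate, and the two-site architecture predicts early onset. The 35-bp
edge-to-edge gap sits 3.5 bp off an exact helical repeat (10.5 bp per turn).

In-silico mutagenesis predicts the onset shift:

```r
predict_effect(cand, crm$seq, list(mutation_spec(150)))
#> architecture multiple -> single; predicted activity: active_middle
predict_effect(cand, crm$seq, list(mutation_spec(150), mutation_spec(191)))
#> architecture multiple -> none; predicted activity: inactive
```

Ablating one site demotes the CRM to single-site (middle onset); ablating
both predicts loss of notochord activity — the behaviour observed in vivo
for two-site CRMs.

Enrichment against the random-occurrence null:

```r
site_enrichment(crm$seq, bg = uniform_background())
#> observed 2 vs expected 2.324 (poisson): P(X >= obs) = 0.6747
expected_count(1200, strands = 1)
#> [1] 4.667969
```

Two cores in 600 bp is exactly what chance predicts (p = 0.67) — site
*clustering and quality*, not raw counts, carry the architectural signal. A
1.2-kb sequence is expected to contain ~4.67 chance cores on one strand, so
an observation of 15 in such a CRM is a strong enrichment.

## Pipeline and CLI

`run_scan()`, `run_predict()`, `run_mutate()` and `run_simulate()` drive the
FASTA → BED6/TSV/JSON workflow from a validated `notocrm_config()`. A
command-line front end with subcommands `scan`, `predict`, `mutate`,
`simulate` lives at `inst/cli/notocrm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","notocrm.R",package="notocrm"))')" \
    scan --fasta loci.fasta --out results/
```

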