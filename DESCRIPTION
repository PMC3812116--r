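Package: notocrm
Title: Brachyury Binding-Site Architecture and Temporal Classification of
    Notochord Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-level analysis of Brachyury (T-box) driven notochord
    cis-regulatory modules (CRMs). Implements degenerate IUPAC matching
    against the TNNCAC core and the extended 12-bp RWWNTNRCACYT consensus,
    packaged catalogs of core hexamers and functional binding sites, a
    both-strand site scanner with flank-mismatch annotation, an i.i.d.
    background null for site enrichment, CRM-candidate calling with
    architecture-based prediction of developmental onset (multiple-site
    early, single-site middle, zero-site late/relay), in-silico site
    ablation with predicted onset shifts, quantification arithmetic for
    reporter-staining tables and ChIP-qPCR standard curves, and synthetic
    generators for all inputs with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
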