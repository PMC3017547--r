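Package: methimprint
Title: Imprinted-Locus Methylation Analysis for Uniparental Embryonic Stem Cell Lines
Version: 0.1.0
Authors@R: person("methimprint", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Control-anchored normalization and imprinted-locus analysis of
    Infinium-style DNA methylation beta-values, built for comparing
    parthenote-derived (uniparental) and conventionally-derived (biparental)
    human embryonic stem cell lines. Provides beta-value computation from
    paired methylated/unmethylated signals, per-probe range-scaling against
    fully-methylated, fully-unmethylated and half-methylated control samples,
    three-state methylation calling, a tissue partial-methylation filter with
    a discordance parameter for identifying imprinted CpG sites,
    uniparental-origin consistency testing, differential methylation of
    imprinted genes, correlation-based sample clustering, delta-delta-Ct
    fold-regulation analysis for PCR arrays, and a seeded synthetic-data
    generator emulating the full study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
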