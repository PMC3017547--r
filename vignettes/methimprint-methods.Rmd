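---
title: "Methods: imprinted-locus methylation analysis for uniparental ES lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imprinted-locus methylation analysis for uniparental ES lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A methylation beadarray measures, per CpG probe and sample, a methylated
and an unmethylated fluorescence intensity. The methylation fraction is

$$\beta = \frac{M}{M + U} \in [0, 1].$$

At a genomic imprint, one parental allele is methylated and the other is
not, so any biparental sample — somatic tissue, primary cells,
conventionally derived ES cells — sits near $\beta = 0.5$ (*partial*
methylation). A parthenote-derived ES line carries two maternal genome
copies: a maternally methylated DMR should read $\beta \approx 1$, a
paternally methylated DMR $\beta \approx 0$. That asymmetry is the entire
signal this package extracts; everything else is normalization and
counting.

Because a probe's dynamic range drifts probe to probe, $\beta$ is
normalized per probe by **range scaling** against control samples: fully
methylated DNA (SssI methyltransferase treated), fully unmethylated DNA
(whole-genome amplified) and their 1:1 mixture, each assayed in
triplicate. With per-probe anchor means $\beta_{\mathrm{full}}$ and
$\beta_{\mathrm{zero}}$,

$$\beta' = \mathrm{clip}_{[0,1]}\!\left(\frac{\beta - \beta_{\mathrm{zero}}}
{\beta_{\mathrm{full}} - \beta_{\mathrm{zero}}}\right),$$

and the half-methylated control, which should land at 0.5 after scaling,
is kept as an internal QC check (`control_qc`).

After averaging technical replicates per line, each (probe, line) value is
called **unmethylated** ($\beta' \le t_{\mathrm{low}}$), **methylated**
($\beta' \ge t_{\mathrm{high}}$) or **partial**, with `failed` for missing
data. Imprinted CpG sites are then identified post hoc: among probes
annotated to imprinted genes, keep those called partial in at least
$N_{\mathrm{tissue}} - d$ tissue samples, where $d$ is the allowed
discordance ($d = 0$ demands 5/5 agreement in the reference design,
$d = 1$ allows 4/5). Gene counts are distinct gene symbols among retained
probes. Downstream statistics:

* **definitive fraction** over a site set and line group:
  $(\#\mathrm{unmeth} + \#\mathrm{meth}) / (\#\mathrm{unmeth} +
  \#\mathrm{meth} + \#\mathrm{partial})$, failed calls excluded entirely;
  reported after subtracting the tissue group's fraction as the
  unmethylated baseline;
* **uniparental consistency**: among retained sites whose parthenote-group
  call is definitive and whose imprint direction is annotated, the
  fraction where (maternally methylated ∧ methylated) or (paternally
  methylated ∧ unmethylated);
* **differential imprinted genes**: per gene, the group difference of mean
  normalized $\beta$ (or the largest single-probe difference), flagged at
  $|\Delta| \ge \delta$;
* **clustering**: average-linkage agglomeration under distance
  $1 - r$ (Pearson by default) between samples;
* **correlation vs discordance curves**: for each $k$, sites where at
  least $n - k$ of the $n$ reference-group lines agree on a state; each
  sample is correlated with the reference-group mean $\beta$ over those
  sites, for the all-probes and imprinted-probes universes.

The PCR-array layer is the standard ΔΔCt method:
$\Delta C_t = \overline{C_t}(\mathrm{gene}) -
\overline{C_t}(\mathrm{housekeeping})$ per group (means over replicate
plates, not-detected wells imputed to a ceiling), fold change
$2^{-\Delta\Delta C_t}$, and fold regulation equal to the fold change when
$\ge 1$ and its negative reciprocal otherwise (0.25 → −4).

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `alpha` | 0 | intensity | β denominator pseudocount; the plain ratio has none, 100 is the common stabilizer for real intensities |
| `eps_range` | 0.3 | β | minimum full−zero anchor separation for a probe to be normalizable; three anchors must be separable for a 3-state call to mean anything |
| `t_low`, `t_high` | 0.3, 0.7 | β | state thresholds; boundary values go to the definitive states (≤ / ≥) — an explicit, documented tie-break. Unpublished in the original analysis: recalibrate for real data |
| `d` | 0 | tissues | allowed tissue discordance in the imprint filter |
| `delta` | 0.2 | β | differential-methylation effect threshold; also unpublished, surfaced and recorded in every output |
| `tol` (QC) | 0.05 | β | allowed drift of the normalized half control from 0.5 |
| `nd_ceiling` | 35 | cycles | imputation for not-detected qPCR wells (array-vendor convention) |
| scatter `threshold` | 4 | fold | up/down classification cutoff |

## What the synthetic generator emulates — and what it does not

`simulate_dataset` plants the study's statistical structure, scaled down
to 5,000 probes by default: 47 imprinted genes × 4 probes each, of which
half (`dmr_fraction = 0.5`) are true DMRs — encoding the caveat that
assignment to an imprinted gene does not make a probe imprinted; 60% of
imprinted genes maternally methylated; 5 tissues, 4 primary lines, 2
conventional and 5 parthenote ES lines at 2 technical replicates, and all
three control classes in triplicate. True DMRs put every biparental class
at mean 0.5 and the parthenote class at 1 or 0 by direction. Non-DMR
probes draw one background mean from a 0.1/0.9 mixture (weight 0.7 low).
Observed values are Beta-distributed around the true mean with
concentration κ (default 50; κ = ∞ gives noise-free data; means at exactly
0 or 1 are jittered by machine ε so both Beta shape parameters stay
positive), and channel signals are the observed fraction times a
log-normal total intensity (meanlog 9, sdlog 0.4, arbitrary units).
Technical replicates share a line's true means and differ only in noise
draws. These defaults are the stated design; the noise defaults are
conventions, since the original study reports no array noise level.

One deliberate extension: both ES-cell classes are hypermethylated by 0.3
at 10% of the non-imprinted background probes (`esc_hyper_fraction`,
`esc_hyper_shift`). Without some ES-specific signal, conventional ES
samples are statistically identical to tissue and no clustering method
could place the ES lines on their own branch — yet that topology (ES lines
together, more methylated than somatic samples) is exactly what the
reference analysis observes and what the generator is asked to emulate.
The shift touches no imprinted-gene probe, so DMR recovery, consistency
and differential-imprinting behaviour are unchanged; setting
`esc_hyper_fraction = 0` restores a generator in which all non-DMR probes
share one mean across classes.

Features of real arrays the generator does **not** model: probe
cross-hybridization, SNP-affected probes, dye bias, chip/position batch
effects, copy-number artifacts, detection-p-value failures. A green test
on synthetic data therefore establishes that the *pipeline logic* is
correct under the stated noise model — not that the default thresholds
reproduce any particular real dataset.

## Numerical and design choices

* **Anchors are means** over control triplicates, not medians: the
  simplest unbiased choice with n = 3.
* **Out-of-range values clip** to [0, 1] after scaling; β is a fraction
  and the original method is silent on truncation vs pass-through.
  Clipping makes the noise-free controls exactly constant.
* **Replicate aggregation precedes calling** (call on the mean), rather
  than voting per-replicate calls: with two replicates a vote has no
  majority and boundary artifacts multiply.
* **Failed tissue calls count against retention** in the imprint filter —
  conservative site selection.
* **Tissue baseline** is read as subtraction (`group − tissue`); the
  phrase "normalized with tissue as baseline" is ambiguous (rescaling and
  per-probe re-anchoring are alternatives), so the simplest reading is
  implemented and surfaced as its own function rather than guessed further.
* **Group state for consistency testing** is the modal state over a
  group's non-failed line calls, ties resolved to partial (i.e.
  non-definitive): a tie is evidence the group is *not* cleanly
  definitive, so it is excluded rather than forced to a side.
* **Clustering determinism**: samples are sorted lexicographically before
  `hclust`, so equal-height merges resolve identically regardless of
  input order; Pearson is the default correlation with Spearman available
  by flag.
* **Correlation-curve reference group** is configurable (default the
  parthenote class). The original figure caption refers to 7 reference
  lines where only 5 parthenote lines were assayed; the mechanism is
  implemented and the group choice exposed instead of resolving that
  inconsistency.
* **Degenerate inputs**: β with zero total signal is missing, not 0;
  constant samples produce missing correlations (and clustering then
  refuses, rather than silently placing them); an all-partial site set
  has definitive fraction 0; an all-failed one is an error, not NaN.

## Known limitations

* Raw IDAT parsing is out of scope; input starts at tabular signal or β
  exports (including the series-matrix text dialect).
* No statistical significance machinery: the differential-imprinting call
  is an effect-size threshold, and fold regulation carries no p-values,
  mirroring the magnitude-only reference analysis.
* Reproducing the original headline counts (92 sites / 23 genes at d = 0,
  30 genes at d = 1, 45/92 definitive, 45/47 differential) on the real
  data requires the unpublished probe→imprinted-gene annotation and
  calibration of `t_low`, `t_high` and `delta`; the package reproduces the
  *mechanisms* and the worked arithmetic (45/92 = 48.9% ≈ 49%;
  $2^{-\log_2 26.42} \to$ fold regulation −26.42) exactly.
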