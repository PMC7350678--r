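---
title: "metaboplot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaboplot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboplot)
```

This vignette explains what `metaboplot` computes, the assumptions behind
each stage, the parameters that matter, and the choices made where the
problem left genuine design freedom.  It states no empirical result that
the test suite does not itself compute.

## The data model

Everything revolves around one long table: a record per
(compound, sample) with an intensity that is either a non-negative peak
area or *missing*.  Five common input layouts (vendor-style long lists and
wide matrices) are melted into this shape at import.  Two parsing rules
deserve attention:

* **Missing means missing.**  Empty cells and the tokens `NA`, `NaN`,
  `N/F`, `N/A` become `NA` and stay `NA` through every later stage.  No
  imputation, no zero filling: missingness in metabolomics is informative
  (absent compounds, sub-detection-limit concentrations, integration
  failures) and silently replacing it would manufacture false confidence.
  Two opt-in dialect-specific rules exist: zeros-as-missing for
  samples-in-rows matrices, and an intensity threshold for the wide
  matrix layouts, where a value passes when it *reaches* the threshold
  (`x >= t`); the boundary is kept because the threshold expresses "the
  smallest trustworthy signal", not "the largest untrustworthy one".
* **Duplicate names merge with retention time.**  Targeted libraries reuse
  names across chromatographic peaks.  A name occurring at more than one
  retention time becomes `"name@RT"` with the RT fixed to two decimals —
  enough to separate peaks that differ by the ~0.01 min resolution of the
  annotation, and stable under re-export.  A duplicated name *without* an
  RT is an unrecoverable ambiguity and errors immediately.

Delimiters are sniffed among comma/semicolon/tab; semicolon-separated
files additionally accept comma decimal marks (the common European export
combination).  Header matching is case- and whitespace-insensitive, since
vendor exports are not consistent about either.

## Normalisation

All three corrections divide each sample's intensities by a per-sample
factor \(c_s\):

* external: \(c_s\) is a user-supplied correction value (cell count,
  protein mass);
* internal standards: \(c_s = \sum_{m \in S} I(m, s)\) over the selected
  standard compounds — a *sum*, so abundant standards dominate by design;
* total peak sum: \(c_s = \sum_m I(m, s)\) over all non-missing rows.

"Absolute" mode reports \(I/c_s\) (units change, e.g. area per µg
protein); "relative" mode reports \(I/c_s \cdot \overline{c}\), with
\(\overline{c}\) the arithmetic mean of the factors over the *included*
samples, so intensities keep their scale and, on complete data, the grand
total is preserved exactly — a property the tests assert to 1e-9.  A
standard that is missing in one sample contributes zero to that sample's
sum (with a warning) rather than erroring: that is the only reading of
"summed over standards" consistent with the no-imputation policy.  The
internal step can run before the external one (standards spiked during
extraction) or after it (normalising to a detected metabolite); the
configured order is executed literally, because the two orders genuinely
differ whenever correction values differ between samples.

## Replicate quality control

For metabolite \(m\) and sample \(s\) in a condition with replicate set
\(R\), the fold change \(f(m,s) = I(m,s) / \operatorname{mean}_{r \in R}
I(m,r)\) is exactly centred at 1 per metabolite — the reason the
denominator is the arithmetic mean and not the median.  The per-sample
distribution of \(f\) over all metabolites shows replicate agreement at a
glance, robustly: a single outlying metabolite barely moves it, and
missing values simply contribute nothing.

Flagging uses a different denominator.  Because the self-inclusive mean
compresses a \(k\)-fold-off sample to \(kn/(n+1)\) (a doubled sample among
three replicates scores 1.5, never 2), an outlier could never reach a
2-fold threshold under the centred statistic.  Samples are therefore
flagged on the *leave-one-out* mean fold change — each intensity divided
by the mean of the other replicates, which recovers exactly \(k\) for a
uniformly \(k\)-fold-off sample — when it reaches the tolerance
(default 2) on the log2 scale.  Both statistics appear in the QC export.
Whether QC runs before or after internal normalisation is configurable;
the default (after external, before internal) is this package's choice,
not a claim about any other tool's behaviour.

## Isotope tracing and natural-abundance correction

Isotopologues arrive as name suffixes: `"Glucose +6"` is glucose with a
6 Da shift.  Only a *trailing* `" +n"` (space, plus, digits) is consumed,
so `"NAD+ +5"` keeps its internal plus; shifts beyond M+30 are rejected.
Grouping is a lossless partition: absent shifts are not zero-filled in
storage, only rendered as zero-height stack segments.

The correction model is the classical low-resolution one.  Each atom
contributes an independent mass-shift distribution, so a molecule's
pattern is the convolution of per-atom polynomials:

* a nominally labelled tracer atom is heavy with probability equal to the
  tracer purity, light otherwise;
* the remaining tracer-element atoms pick up heavy isotopes at natural
  abundance (binomial);
* unless `tracer_only = TRUE`, all other elements convolve in their
  natural isotopes, with +2 species (¹⁸O, ³⁴S) handled exactly by the
  polynomial convolution rather than a per-shift binomial approximation.

Defaults: ¹³C 1.1 %, ²H 0.0115 %, ¹⁵N 0.364 %, ¹⁷O 0.038 %, ¹⁸O 0.205 %,
³³S 0.75 %, ³⁴S 4.21 %; phosphorus is monoisotopic, and elements outside
C/H/N/O/P/S are rejected (no Si/Cl/Br, so chlorinated or silylated GC-MS
derivatives are out of scope).  The table is overridable per call.
`tracer_only = TRUE` is the default because high-resolution analysers
mass-resolve non-tracer isotopes away from the tracer series — the regime
in which the familiar anchors hold (C3 natural M+1 ≈ 3 %, C10 ≈ 10 %).
This is a deliberate simplification relative to resolution-dependent
correction models, which need the analyser's resolving power as input; the
package does not attempt those.

Column \(j\) of the correction matrix is the pattern of a molecule with
\(j\) labelled atoms, truncated to the observed shifts; the measured
vector is deconvolved by non-negative least squares (Lawson–Hanson
active set — implemented in the package because no NNLS solver is
available among the declared dependencies, and cross-checked in the tests
against an independent quadratic-programming solution).  NNLS rather than
matrix inversion because an inverse can and does produce negative
"intensities" on noisy data, which no honest mass-isotopomer distribution
contains.  Missing isotopologue entries enter the solver as zeros with a
warning, and the output marks those compounds.  An all-zero measurement
returns all zeros rather than erroring.

One printed-number subtlety: "M+1 at 10 % for a 10-carbon molecule" can be
read as the absolute M+1 fraction (\(\binom{10}{1} 0.011 \cdot 0.989^9
\approx 9.96\,\%\)) or as the ratio to M+0 (\(\approx 11.1\,\%\)).  The
package and its acceptance anchors use the absolute fraction, which rounds
to the quoted 10 %.

## Statistics

Two-sample comparisons only: the pooled-variance t test and the Wilcoxon
rank-sum test (the two-sample variant; conditions are independent groups),
pairwise or against a reference condition.  Groups need at least two
non-missing values; anything smaller renders as `n/a`.  Star thresholds
follow the conventional scheme (0.05/0.01/0.001/0.0001); numeric display
rounds to three significant figures with a `<0.001` floor.  **No
multiple-testing correction is applied** — with hundreds of metabolites,
users scanning for stars should expect ~5 % false positives under the
null and correct externally if needed.

## Plotting

Bars and scatterplots show mean ± standard deviation (the *sample* SD,
\(n-1\) denominator).  Boxes use the linear-interpolation quartile
convention with whiskers at the most extreme value within 1.5 IQR; violins
use Silverman's bandwidth and mark the median.  Violin and box plots
unlock at 5 and 10 replicate measurements per condition respectively —
density and quartile summaries below those counts are decoration, not
information.  The x axis is always discrete (conditions), never a numeric
scale, and condition names must be unique; grouped designs are out of
scope.  Condition colours come from the sample table (hex or R colour
names) or a fixed qualitative palette; isotopologue stacks use pinned
colour scales (8 colours to M+7, or a 16-colour stepped rainbow to M+15)
so tracing figures are comparable across experiments.  File names are the
sanitised compound names (`: ; < > / \ | ? * "` become `_`, collisions get
numeric suffixes); outputs bundle into a zip with sorted member order so
identical runs produce identical listings.

## The fixture generator

Synthetic data stand in for real exports everywhere in the tests.  The
generator emulates: log-normal compound abundances (median 1e6, 2-fold
spread), per-condition log-normal effects (sd 0.3), multiplicative
replicate noise (sd 0.1), missing values injected at a configurable rate
and concentrated 3:1 in the low-abundance tertile (mirroring how
sub-detection-limit compounds dominate real missingness), and — for
tracing — measured isotopologue vectors forward-simulated as
`correction_matrix %*% true_MID * abundance * noise`, so the correction
stage has exact ground truth.  What it does *not* emulate: retention-time
drift, correlated compound panels, heteroscedastic detector noise,
batch effects and real chromatographic artefacts.  A green test therefore
establishes the *computational contracts* (parsing fidelity, algebraic
identities, parameter recovery), not instrument-level robustness.

## Numerical choices and degenerate inputs

* Fold changes and MIDs are undefined on all-missing groups: dropped with
  warnings, never silently zeroed.
* NNLS tolerance scales with `crossprod(A, b)`; correction matrices are at
  most 31×31, far below any conditioning concern.
* A compound observed at a shift larger than its tracer-atom count is a
  hard error (the formula cannot explain the signal).
* Empty inputs parse to empty tables; an all-zero measured vector corrects
  to all zeros.
* Ties in the design's order column break by first appearance in the file.
* The 25 MB input cap mirrors a hosting constraint of interactive tools;
  it is enforced but configurable, since it is not a scientific limit.

## Known limitations

Single-tracer correction only (no simultaneous ¹³C+¹⁵N), no
resolution-dependent correction, no positional isotopomers or flux
estimation, no raw-file parsing or peak integration, no grouped/nested
condition axes, and raw p-values only.  The XLSX writer is deliberately
minimal (one sheet, inline strings) — sufficient for the structured-table
exports, not a general spreadsheet library.
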