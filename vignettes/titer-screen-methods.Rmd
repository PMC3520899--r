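---
title: "Methods: quantifying viral titer in arrayed lentiviral library screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying viral titer in arrayed lentiviral library screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titerscreen)
```

# The problem

Arrayed lentiviral overexpression libraries package one ORF-expressing
construct per well of a 96-well plate. Virus is produced by transfecting
each construct, together with packaging plasmids, into HEK293T cells; an
IRES-GFP cassette on the same transcript as the ORF makes the producing
cells fluorescent, so the total GFP fluorescence of a well after
supernatant harvest is an operational proxy for the viral titer achieved
by that clone. A screen of this kind needs four quantitative steps, each
of which this package implements and tests:

1. **Plate normalization.** Background fluorescence varies between plate
   batches. Each plate carries four mock wells (no expression plasmid);
   subtracting the mean mock fluorescence zeroes the plate so wells are
   comparable across the library.
2. **Titer classification.** Control-derived thresholds partition wells
   into categories: *detected* production above two pooled mock standard
   deviations; *sufficient* production above the minimum observed for the
   empty-vector positive control; *high* and *low* tails at fixed
   cutoffs; and exclusion of wells whose expression-plasmid DNA prep
   fell below the detectable range.
3. **Transduction-rate quantification.** For selected clones, target
   cells are infected and imaged in two channels; the fraction of
   GFP-positive nuclei measures the titer actually delivered. A
   three-channel variant (Hoechst/PI/GFP) counts live and dead cells.
4. **Group comparison.** Replicate wells are summarized per gene, and
   low- versus high-titer gene groups are compared with the Aspin-Welch
   unequal-variance test.

Because instrument data from such screens are proprietary and bulky, the
package ships seeded synthetic generators for plates and well images
with recorded ground truth; every downstream stage is validated against
that truth.

# Plate model and normalization

A simulated plate draws one batch background offset
$b \sim N(\mu_b, \sigma_b)$ (defaults 2000, 400 a.u.). Column 12 is the
control column: rows A–D hold empty-vector wells, rows E–H mock wells (a
fixed convention; the screen design only requires one freed column). Raw
fluorescence is background plus the well's true normalized value; mock
wells are background plus noise $N(0, \sigma_m)$.

Normalization subtracts the plate's 4-mock mean, so the normalized mock
wells average exactly zero on every plate. Mock SDs use the sample
divisor $n-1$ (only 4 mocks per plate; the unbiased variance is the
sensible small-sample choice). The detection threshold pools the
normalized mock values of **all** plates, rather than using per-plate
thresholds, because the screen operates with single library-wide
cutoffs; a `per_plate = TRUE` option exposes per-plate diagnostics.

One subtlety fixed the default $\sigma_m = 1422$: centring each plate on
its own 4-mock mean shrinks the pooled SD of the residuals by
$\sqrt{1 - 1/4}$, so a raw mock noise SD of $1232/\sqrt{3/4} = 1422$
puts the pooled two-SD detection threshold near 2464 a.u., the operating
point of the screen this generator emulates.

## The fluorescence mixture

Sample-well true fluorescence follows a four-component mixture of
(shifted) log-normals — *failed*, *low*, *typical*, *high* — because the
observed well distribution is strongly right-skewed with a spike near
zero and a long tail past 50,000 a.u. The distributional family is a
modelling decision of this package, not an inference from data: any
right-skewed family with these four regimes would serve, and the tests
only rely on the components' locations relative to the thresholds.

Default fractions 0.030/0.050/0.900/0.020 and component parameters were
derived once from the screen-level operating characteristics this
generator emulates — about 95% of wells above detection, about 90% above
the empty-vector floor, a small population above 50,000 a.u. — and are
not tuned thereafter. Likewise the empty-vector wells draw from
$N(12420, 2700)$ truncated at zero, placing the expected library minimum
(820 control wells) near 4,000 a.u.; insert sizes are log-normal
$(\mu_{\log} = 7.2, \sigma_{\log} = 0.55)$, clamped to 75–13,037 bp,
giving roughly 4% of inserts above the 3,500 bp QC limit; and DNA preps
fail (fall below 20 ng/µl) with probability 0.02.

## Classification conventions

Tie-breaks are stated once and tested at the boundaries: thresholds
phrased "above x" are inclusive ($\geq$) for detection and sufficiency,
strict ($>$) for the high tail; the low tail "below 3,000" is strict
($<$). DNA exclusion dominates every fluorescence category, but wells
with *missing* DNA measurements are never excluded — only measured
sub-threshold preps are. Classification is monotone in fluorescence for
fixed DNA, which the suite checks as a property.

# Image model and quantification

## The synthetic well image

Nuclei are rendered as flat-core discs of radius $r \sim U(4, 6)$ px
with a Gaussian edge falloff ($\sigma_e = 1$ px), placed by rejection
sampling with a minimum boundary gap (8 px) so that no two nuclei touch.
A flat core rather than a pure Gaussian radial profile keeps the
half-maximum radius at $r$, so the rasterized disc area $\approx \pi
r^2$ is an exact ground truth for the segmenter regardless of where a
global threshold lands; with a Gaussian profile the thresholded area
would depend sensitively on the threshold and no exact truth would
exist. The marker channel adds the same disc shapes with class-dependent
amplitude (8,000 a.u. for marker-positive nuclei, 300 for negative) over
a 150 a.u. background with $N(0, 80)$ pixel noise; channels quantize to
16-bit. The generator draws, in a documented order, radii, marker
classes, dead classes, positions, then pixel noise, all from a single
seeded stream — tests replay the stream to verify the truth tables.

What the generator deliberately does **not** emulate: touching or
overlapping nuclei, clumps, mitotic figures, illumination gradients,
vignetting, PSF blur, autofluorescence, or cell loss. Passing tests
therefore demonstrate that the measurement operators are correct on
resolvable objects, not that segmentation would survive confluent
cultures; on real clumpy images a watershed split (intentionally
omitted here) would be the first necessary extension.

## Segmentation and scoring

The pipeline is the simplest one consistent with per-nucleus
high-content readouts: Gaussian smooth ($\sigma = 2$ px), global Otsu
threshold, hole filling, connected components (8-connectivity by
default, 4 available), and an area filter of 30–5,000 px². Smoothing and
thresholding use EBImage; component labelling builds a pixel-adjacency
graph. Two guards protect against the classic Otsu failure mode on
object-free images, where a global threshold merely splits the noise
distribution: segmentation returns zero objects if the foreground would
cover more than half the frame, or if the foreground mean exceeds the
background mean by fewer than 4 background SDs. Pixel coordinates are
0-based (row, col); areas are in px²; intensities are arbitrary units,
assumed consistent within a run.

Per-nucleus marker scoring is the arithmetic mean of marker pixels under
the nuclear mask — nothing more; tests compare it against an explicit
pixel loop.

## Marker-positivity threshold

Mock (untransduced) wells define the null distribution of per-nucleus
marker means. Rather than a threshold "set visually", which is not
reproducible, the package uses the empirical 0.995 quantile of the mock
means; below 200 mock nuclei the extreme quantile is too unstable and
the threshold falls back to mean + 3 SD. Both `q` and the fallback
cutoff are exposed. Positivity is strict (`>`), so calibration nuclei
sitting exactly at the threshold stay negative. Note one consequence the
tests account for: by construction about $1 - q$ of true-negative
nuclei exceed a quantile threshold, so an estimator using it has
expectation $p + (1-q)(1-p)$ rather than exactly $p$; unbiasedness
checks therefore use a fixed separable threshold, while the calibrated
threshold is validated against closed-form normal quantiles and by the
affine-invariance property (rescaling well and calibration intensities
together leaves every rate unchanged). A well with zero nuclei reports
a *missing* rate, never 0.

## Live/dead counting

In the three-channel assay the Hoechst and PI channels are segmented
independently, each giving its own object count; GFP status is scored on
the Hoechst nuclei, yielding the proportion of GFP-positive cells in the
Hoechst-stained population. The GFP channel is also segmented for its
own object count.

# Replicate summaries and the Aspin-Welch test

Per-gene summaries average replicate wells (typically 4, from
independent single-colony isolates), recording exclusions with reasons;
a single surviving replicate reports a missing SD rather than 0. The
group comparison pools per-well values within each group and cell line —
matching how replicate titer assays are summarized — with a `by_gene`
option that aggregates to gene means first as a sensitivity check. No
multiple-testing correction is applied across cell lines; raw p-values
are reported.

The Aspin-Welch test is implemented from its formula (it is the
statistic under study, not a convenience call):

$$t = \frac{m_1 - m_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}, \qquad
\nu = \frac{(s_1^2/n_1 + s_2^2/n_2)^2}
       {\frac{(s_1^2/n_1)^2}{n_1-1} + \frac{(s_2^2/n_2)^2}{n_2-1}},$$

with a two-sided p-value from the $t_\nu$ distribution (sidedness is
conventional; the separations in this application make it immaterial).
Degenerate input with both variances zero and equal means is defined as
$t = 0$, $p = 1$; zero variances with unequal means is an error. The
suite checks the statistic against `stats::t.test(var.equal = FALSE)` as
an independent oracle, the algebraic reduction to Student's $t$ under
equal $n$ and variances, antisymmetry under group swap, the
Welch-Satterthwaite df bounds $[\min(n_1,n_2)-1,\; n_1+n_2-2]$, and the
empirical type-I error rate under the null.

# Numerical and design choices, collected

- Well labels are zero-padded ("A01"–"H12") so lexicographic order is
  reading order; all CSVs use comma separators, "." decimals, and no
  thousands separators.
- Sample SD (divisor $n-1$) everywhere a spread is reported.
- Histograms use half-open bins $[lo, hi)$ with the last bin closed, so
  counts always conserve $n$.
- Every generator requires an explicit seed, and all randomness in a
  call derives from it; identical configuration and seed reproduce
  byte-identical outputs, which the suite asserts on written files.
- Image stacks are multi-page 16-bit TIFFs with a sidecar CSV recording
  channel order; round trips are bit-exact, including the 0 and 65,535
  extremes.
- Pipeline runs write their resolved configuration (package version,
  seed, thresholds) next to their outputs.

# Problem sizes used by the test suite

The suite validates normalization on 50 simulated plates; exact
classification against ground truth on 10 well-separated plates plus
boundary cases; segmentation on 100 images of 512×512 px with 20–200
nuclei each, requiring the exact true count in at least 99% of images;
rate recovery on 200 wells of 100 nuclei at true fractions 0.05–0.95;
Welch behaviour on 1,000 null simulations; and end-to-end determinism of
the demo pipeline (6 plates, 12 genes × 4 wells, 192 px images). These
sizes were chosen so the full suite exercises every claim in a few
minutes on a single core while keeping the binomial/standard-error
bounds meaningful.

# Known limitations

- No watershed or other splitting of touching nuclei; real confluent
  images are out of scope.
- No illumination or spatial plate-effect correction (no B-score/loess);
  the normalization model is mock-mean zeroing only, as in the screen
  design it follows.
- The fluorescence mixture family and the image noise model are
  synthetic stand-ins; absolute agreement with any instrument's units is
  limited to order of magnitude.
- The empty-vector floor is a sample minimum and therefore a
  high-variance statistic; across seeds it moves by hundreds of a.u.,
  which is faithful to how such a threshold behaves in practice.
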