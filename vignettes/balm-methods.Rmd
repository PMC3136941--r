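---
title: "Modelling MBD-seq tag distributions with bi-asymmetric-Laplace mixtures"
author: "balm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MBD-seq tag distributions with bi-asymmetric-Laplace mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balm)
```

## The problem

MBD-seq enriches methylated DNA fragments with a methyl-CpG binding domain
protein and sequences one end of each fragment.  A mapped read ("tag")
therefore marks one boundary of a fragment whose interior contains the
methylated CpG.  Around a single methylated site the 5' ends of
forward-strand tags pile up upstream and reverse-strand tags downstream,
producing the familiar bimodal strand-split profile of all single-end
enrichment assays.  Unlike transcription-factor binding sites, methylated
CpGs are dense — often tens of bases apart — so the analytical question is
not just "where are the enriched regions" but "how much methylation signal
does each individual CpG carry".  This package answers that with a
parametric mixture model; its scope is the modelling machinery plus a
synthetic-data generator that lets every stage be exercised and validated
without any external dataset.

## The tag model

The 5'-end offset of a tag relative to its source site is modelled per
strand with an asymmetric Laplace distribution (ALD),

$$f(x;\theta,\kappa,\sigma) \;=\;
  \frac{\sqrt2}{\sigma}\,\frac{\kappa}{1+\kappa^2}\,
  \exp\!\Bigl(-\frac{\sqrt2}{\sigma}\,\kappa^{s(x)}\,|x-\theta|\Bigr),
  \qquad s(x)=\begin{cases}+1 & x\ge\theta\\ -1 & x<\theta,\end{cases}$$

with location $\theta$ (the mode, in bp), scale $\sigma$ (bp) and
asymmetry $\kappa>0$ ($\kappa=1$ is the symmetric Laplace).  A
*bi*-asymmetric-Laplace model (BALM) is a strand pair of ALDs together
with strand weights: the forward mode sits near $-\ell/2$ and the reverse
mode near $+\ell/2$, where $\ell$ is the mean fragment length.  The
sharp-peaked, heavy-tailed Laplace shape fits empirical offset histograms
better than a Gaussian of matched moments, which the test suite
demonstrates on skewed synthetic offsets (the ALD's binned
sum-of-squared-error "goodness of fit" beats the Gaussian's in ≥95% of
seeds).

### Closed-form maximum likelihood

The ALD admits a two-step closed-form MLE.  With
$\alpha(\theta)$ and $\beta(\theta)$ the mean positive and negative
deviations about a candidate location, the profile likelihood depends on
$\theta$ only through $H(\theta)=\sqrt{\alpha}+\sqrt{\beta}$; the estimate
is the sample point minimizing $H$, after which
$\hat\kappa=(\beta/\alpha)^{1/4}$ and
$\hat\sigma=\sqrt2\,(\alpha\beta)^{1/4}(\sqrt\alpha+\sqrt\beta)$.
Three numerical details matter:

* **Boundary exclusion.** At the sample extremes one of $\alpha,\beta$
  vanishes and the profile likelihood degenerates to a one-sided
  exponential with $\kappa\to0$, outside the parameter space; such
  candidates are excluded.  This also makes tiny symmetric samples (e.g.
  $\{-a,0,a\}$) resolve to the intuitive $\hat\theta=0$, $\hat\kappa=1$.
* **Determinism.** The candidate search runs over sorted unique sample
  points with prefix sums ($O(n\log n)$); ties in $H$ break toward the
  smallest candidate, so fits are reproducible to the bit.
* **Oracle equivalence.** The closed form is verified in the test suite
  against direct numerical maximization of the log-likelihood
  (multi-start L-BFGS-B); agreement is required within $10^{-3}$ log-units
  over 100 random parameter draws, and parameters are recovered within 5%
  at $n=10^4$.

### Fitting the BALM from data

`fit_balm()` pools signed offsets of tags around a site list (window
±1000 bp) and fits one ALD per strand.  Two robustness measures are
needed on realistic data:

* **Strand-aware assignment.** A tag is attributed to the site nearest its
  *shifted* 5' position (forward $+\ell/2$, reverse $-\ell/2$), i.e. its
  maximum-likelihood source site.  Nearest-raw-position assignment breaks
  down as soon as sites sit closer than the fragment length — a forward
  tag lying 75 bp upstream of its true site is nearer to the site's
  upstream neighbour — and drives the fitted modes toward zero.
* **Trimmed refit.** Offsets pooled over a wide window are an ALD plus a
  sliver of uniform background whose large deviations inflate
  $\hat\sigma$ by tens of percent.  After a first fit, each strand is
  refitted on offsets within 5 fitted scales of the fitted mode (two
  rounds).  The ALD tail beyond $5\sigma$ holds under $10^{-3}$ of its
  mass, so the trim discards essentially no signal.

The mean fragment length itself is estimated from bimodal pileup regions
as the distance between forward and reverse strand-mean 5' positions,
summarized across regions by a tag-count-weighted **median**: the
occasional pileup that is not a genuine single peak (a sparse background
window, or an amplified background stretch whose strand-mean distance is
arbitrary) would otherwise drag a plain mean far from the truth.

## Region discovery

1. **Initial scan.** All tags are shifted toward the fragment midpoint by
   $\ell/2$ and a 50 bp window sliding in 25 bp steps flags windows whose
   shifted-tag count exceeds a threshold; overlapping windows merge into
   regions and the mean shifted position is a provisional site.  The
   default threshold is the smallest integer $T$ with
   $P(X \ge T) < 10^{-5}$ for $X\sim\text{Poisson}(N\,w/L_g)$ — the
   expected window count under a uniform background.
2. **Weighted enrichment.** With a fitted BALM, every genomic position
   receives the sum over nearby tags of the mode-normalized strand
   density $\mathrm{ALD}_s(p - pos)/\mathrm{ALD}_s(\theta_s)$ — a
   perfectly placed tag contributes exactly 1, so thresholds read as
   effective tag counts.  The score is linear in the tags, and the
   scanning implementation is required (in tests) to match brute-force
   per-position summation to $10^{-9}$.  Runs above the local threshold,
   padded by $\ell/2$ and merged, are the candidate regions.
3. **Fisher filtering.** With input data, each region's treatment/control
   counts are tested one-sided against the library totals
   (hypergeometric tail, identical to `fisher.test(alternative =
   "greater")`); regions with $p \ge \alpha$ (default 0.05) are dropped.
   No multiple-testing correction is applied here — false discovery is
   measured separately by Monte-Carlo simulation.

### Copy-number correction (GRAI)

Cancer genomes carry amplified segments where input and signal pile up
alike.  The genome region amplification index of bin $i$ is
$\mathrm{GRAI}_i = (n_i/L_i)\,/\,(N/L_g)$ — local over global input-tag
density (default 10 kb bins).  The bin-length-weighted genome mean of the
track is exactly 1 by construction.  Detection thresholds are multiplied
by $\max(\mathrm{GRAI}, 1)$ and per-CpG tag masses divided by it: an
amplified region must clear a proportionally higher bar and its apparent
signal is deflated, while apparently *depleted* regions are never given a
lower bar (the floor at 1 is a deliberate asymmetry; only amplification
is corrected, because a below-baseline index more often reflects input
sampling noise than a real deletion).

## Within-region mixtures, EM and BIC

Within a region the tag likelihood is a $K$-component mixture
$\sum_j \pi_j\,w_s\,\mathrm{ALD}_s(x_i - c_j)$ whose centers $c_j$ are
candidate target sites.  The global shape ($\kappa,\sigma$, strand
weights) stays frozen — the shape is a property of the library, not of a
region, and freezing it prevents component collapse on sparse regions —
so the free parameters are $K$ centers and $K-1$ weights
($k_{\text{free}} = 2K-1$).

* **E-step / M-step.** Responsibilities are standard; weights update by
  mean responsibility; each center updates by the *exact* weighted ALD
  location MLE with fixed shape.  That objective is piecewise linear in
  the center with breakpoints at the tag-implied sites
  ($x_i - \theta_{s_i}$), so the update evaluates all breakpoints within
  ±200 bp of the current center via prefix sums and picks the maximizer.
  Both steps are exact, so the log-likelihood is provably nondecreasing;
  the tests assert this on every seeded run.
* **Component floor.** A component whose weight falls below
  `min_tags_per_component / n` (default 10 tags' worth) is dropped: BIC
  alone will happily pay for a "component" consisting of one stray
  background tag, and a site supported by fewer tags than the minimum is
  not reportable.
* **Model selection.** $K = 1..K_{\max}$ are fitted (5 seedings each: one
  deterministic quantile spread plus k-means++-style restarts on the
  implied site positions) and the fit minimizing
  $\mathrm{BIC} = k\log n - 2\log L$ wins; the sweep stops after the BIC
  has worsened twice.  $K_{\max}$ defaults to region length / 50 bp
  (capped at 20), matching the model's ~50 bp resolution scale.
* **Seeding.** Every stochastic step derives its seed from the master
  seed plus the region index, so a rerun with the same configuration is
  byte-identical.

The outer loop alternates model fitting and mixture fitting: pass 1 fits
the BALM on the coarse initial-scan sites, passes 2..t refit it on the
EM-refined component centers.  On isolated peaks one refinement pass
suffices; on CpG-dense regions (sites at ~60 bp spacing) the fitted scale
converges geometrically (roughly 70 → 60 → 40 → 22 bp per pass in the
packaged end-to-end test), so dense data benefit from t = 4-5.  The
package default is t = 2.

## Per-CpG methylation scores

Each component is assigned to the nearest CpG within 25 bp (a component
with no CpG in range is still reported as a non-CpG site — spike-in and
transcription-factor use).  The effective mass of a CpG is
$\sum \pi_j n / \mathrm{GRAI}$ over its components, and the score is
$\min(1, \text{mass}/\text{calibration})$.  The calibration — the mass
that saturates the score — defaults to the 95th percentile of
per-component effective masses in the run.  This rank-based choice makes
scores comparable across sequencing depths but is a declared convention,
not an estimate of absolute methylation: scores from different runs are
comparable only through their own calibrations, and a run consisting
mostly of weak sites will stretch its scale accordingly.  Scores above
0.8 are read as hypermethylated and below 0.2 as hypomethylated.  CpGs
inside an enriched region with no assigned component score 0; CpGs
outside any region are unobserved and are exported as 0 in the
genome-wide file.

## False discovery rate

FDR is estimated by Monte-Carlo simulation matched to the observed data:
uniform background tags over the non-excluded genome (scaled per-bin by
the GRAI when input is available) plus peaks planted at random positions
with depths resampled from the observed region tag counts and offsets
drawn from the fitted BALM.  A detection within 100 bp of a planted site
counts as true; FDR = false / total detections, tabulated over a grid of
enrichment thresholds (the track is computed once and re-thresholded).

## What the synthetic data do and do not emulate

The generators produce: toy genomes with CG-suppressed background and
CpG-regular islands in fully / partially / unmethylated states (6:3:2,
echoing a validation design of 6 fully, 3 partially and 2 unmethylated
regions); MBD-seq-like tags (per-site Poisson counts proportional to the
methylation state, strand drawn from the model weights, offsets from the
strand ALDs, uniform background, copy-number-scaled counts inside
amplified intervals); input libraries reflecting copy number only;
two-site spike-ins at separations 100/50/25 bp with depth presets
low/medium/high = 50/200/500 tags per site; and nested-subsample
coverage-saturation curves.  The generating BALM defaults to fragment
length 150 bp, $\sigma$ = 30 bp and $\kappa$ = 1.3 (mirrored on the
reverse strand), consistent with sonication to 50-350 bp followed by
~100-200 bp size selection.

Deliberately not emulated: read sequences and base qualities, mapping
error and mappability structure, fragment-length dependence on CpG
density, chromatin accessibility bias, and partial methylation as cell
mixture at single-molecule level (a partially methylated site simply
yields proportionally fewer tags).  Passing tests therefore demonstrate
the estimators' correctness under the stated generative model, not
robustness to every artefact of real libraries.

Island CpG spacing defaults to 60 bp — an order of magnitude above
background density yet at the mixture's resolution scale, so each
methylated CpG can carry its own component and per-CpG truth recovery is
a meaningful test.  Real CpG islands are denser (~10 bp); there,
individual CpGs inside one island are not separately resolvable by any
~50 bp-resolution method, and this package, like the approach it
implements, reports the resolvable mixture structure.

## Problem sizes used in the packaged analyses

The test-suite and the reproduction script run at desk scale, chosen so
each stage still has the statistical headroom its claims need: the
reference model is trained on 30 simulated peaks of 500 tags plus 2000
background tags on a 1 Mb chromosome; resolution benchmarks use 20
seeded replicates per separation; the end-to-end truth-recovery study
uses a 100 kb genome, 11 islands, 400 tags per fully methylated site, a
20-fold amplified 4 kb segment, and 5 outer passes.

## Known limitations

* The methylation score's calibration is rank-based (see above); absolute
  cross-run comparisons need a shared calibration.
* Shape parameters are global; libraries with locus-dependent fragment
  size distributions violate this.
* The M-step restricts center candidates to ±200 bp of the current
  center; a component initialized grossly far from any tag mass moves in
  200 bp increments and relies on the multi-start seeding to recover.
* Single-end data only; no BAM/CRAM input (text SAM is supported).
* The EM resolution floor is ~50 bp at low depth; below it the BIC
  correctly prefers one merged component, which is a feature of honest
  model selection, not a bug.
* The goodness-of-fit value is computed against the offset histogram of
  the *current* site list, so it is comparable between models evaluated
  on the same site list but not across outer passes that change the
  list's density; refinement across passes shows up in the fitted scale
  approaching the library's true scale, not necessarily in a monotone
  gof sequence.
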