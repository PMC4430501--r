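---
title: "Methods: occupancy deconvolution and interaction calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy deconvolution and interaction calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind petdecon, the
meaning and defaults of its tuning parameters, the numerical choices
made in the implementation, and its intended problem sizes and limits.

## 1. Generative model

A ChIA-PET experiment crosslinks a protein to chromatin, fragments the
chromatin by sonication, ligates fragment ends, and sequences the two
ends of each ligation product. Every read pair is reduced to its two 5′
alignment coordinates and strands, ordered so that mate 1 is the
lower-coordinate end. Two ligation classes generate the pairs:

* **Self-ligation**: both ends come from one protein-bound fragment.
  If the protein sits at location $u$ and the sonicated fragment has
  length $L$ with an internal break fraction $\beta$, the pair is
  approximately $\langle u-\beta L,\ u+(1-\beta)L\rangle$ with
  orientation −+ and a span on the order of $L$. Self-ligation pairs
  therefore sample the **marginal occupancy** $p(u)$ convolved with a
  2D **read spread function** (RSF) $r(\delta_1,\delta_2)$, the joint
  distribution of the two end offsets induced by fragmentation.
* **Inter-ligation**: the ends come from two different bound fragments,
  so the pair samples the **joint occupancy**
  $p(u,v)$ of two locations, each end independently smeared by the
  corresponding 1D marginal of the RSF, with orientation uninformative.

Only −+ intra-chromosomal pairs can be self-ligation; the other three
orientation classes (++, +−, −−) arise from inter-ligation only, and by
strand symmetry inter-ligation populates all four classes equally.

### Assumptions

* The RSF is shared genome-wide (sonication is sequence-independent at
  the resolution of interest), unimodal, and supported within a few
  fragment lengths of the bound location.
* Occupancy is concentrated: most mass sits in peaks much narrower than
  the fragment length, which is what makes the deconvolution
  well-posed in practice.
* Inter-ligation end pairs are conditionally independent given the two
  occupied locations.
* Sequencing depth undersamples the space of interacting location
  pairs, so observed per-anchor totals underestimate full-sampling
  totals — this is what the missing-mass correction of §5 addresses.

## 2. Self/inter classification (`classify_self_ligation`)

The inter fraction among −+ pairs is estimated by symmetry:
$\hat\pi = \tfrac{1}{3}(N_{++}+N_{+-}+N_{--})\,/\,N_{-+}$, clipped to
$[0,1]$. Span densities for the self and inter components are estimated
by weighted 1D kernel density estimates of the −+ span distribution and
of the pooled other-orientation span distribution, and each −+ pair
$i$ with span $d_i$ receives the posterior self weight
$w_i = \max\!\big(0,\ 1-\hat\pi\, f_{\text{other}}(d_i)/f_{-+}(d_i)\big)$,
additionally forced to 0 beyond a hard distance cap.

Parameters and defaults:

* `max_self_distance = 5e4` bp — spans beyond 50 kb are never
  self-ligation at realistic fragment sizes; the cap stops the tail of
  the self KDE from leaking weight onto obvious loops.
* `h_mp`, `h_other` — bandwidths for the two span densities, selected
  by least-squares cross-validation (LSCV) over a log-spaced grid of 20
  candidates between 10 bp and 10 kb; LSCV is evaluated on a subsample
  of at most 5,000 points for cost. The grid brackets everything from
  sharp fragment-length modes to the very diffuse inter-span
  distribution.

## 3. Blind deconvolution (`blind_deconvolve`)

Within a training window (the `window_size` stretch holding the most
self-ligation weight; default 5 Mb), the weighted 2D KDE of −+ end
pairs $(x_i, y_i)$ with bandwidth `h_self` is evaluated on a band: bins
$i$ along the genome by `bin_size` (default 10 bp) and span offsets
$a = 0,\dots,2W/\text{bin}$ up to the RSF half-width `rsf_half_width`
($W$, default 500 bp). The model for the band is

$$ M(i,a) \;=\; \sum_{d} \; p(i-d)\; r(d,\ d+a), $$

a 1D occupancy vector $p$ convolved with a 2D RSF $r$ supported on
$[-W,W]^2$. Both are recovered by alternating multiplicative
Richardson–Lucy updates, each of which preserves total mass and
nonnegativity:

* occupancy update: $p(j) \leftarrow p(j)\sum_{i,a} r(i-j,\ i-j+a)\,
  \frac{D(i,a)}{M(i,a)}$ (normalized);
* RSF update: $r(d,e) \leftarrow r(d,e)\sum_{i} p(i-d)\,
  \frac{D(i,\ e-d)}{M(i,\ e-d)}$ (normalized).

The RSF update is the *correlation* (adjoint) form of the forward
model: the forward map is linear in $r$ with kernel $p(i-d)$, so the
multiplicative update back-projects the data/model ratio through that
same kernel. Using the adjoint rather than a convolution keeps the
pair $(p, r)$ a fixed point exactly when the model matches the data.

The schedule (`occ_updates = 10`, `rsf_updates = 10`, `rounds = 5`)
alternates blocks of occupancy and RSF updates; a warning reports the
last L1 change if the tolerance is not reached, since with a sharply
peaked occupancy the RSF ridge keeps reshaping slowly long after the
occupancy estimate has stabilized. The RSF is initialized uniform on
the band; a flat RSF peak is an error because λ would be undefined.

**λ and the genome-wide track.** The recovered RSF peaks at some
$\langle -\lambda, \lambda\rangle$; $\lambda$ estimates half the modal
sonication fragment length. Extending RL deconvolution genome-wide
would be needlessly costly, so the final occupancy track uses a
diagonal-slice shortcut: the 2D self-pair KDE evaluated along the
anti-diagonal $(u-\lambda,\ u+\lambda)$ is exactly a 1D KDE of pair
midpoints with bandwidth $h/\sqrt2$, times a factor
$\exp(-(\lambda-s_i)^2/h^2)$ per pair with half-span $s_i$. This keeps
the genome-wide pass linear in the number of pairs.

## 4. Conditional joint occupancy (`conditional_field`)

For anchors $v_1,\dots,v_k$ (e.g. transcription start sites), each
inter-ligation pair whose end $y$ has nonzero spread at an anchor
contributes to that anchor's profile through its other end $x$:

$$ \hat p(u \mid v_i) \;\propto\; \sum_{\text{pairs}}
   g(y \mid v_i)\, m_{v_i}\; g(x \mid u)\, m_u, $$

where $g(\cdot\mid\cdot)$ is the strand-appropriate 1D RSF marginal and
$m_u$ the marginal occupancy of bin $u$. The global normalizer
factorizes per pair into the product of its two end sums, so anchor
masses $t_i$ and the non-anchor remainder share one scale. Each scan
over bins extends one bin beyond the $\pm W$ support because the
offset-to-grid rounding can land the outermost bin center back inside
the RSF support; the likelihood itself is exactly zero beyond support,
so the widened scans make the sums exact rather than approximate.
Anchors with read support but zero marginal occupancy are flagged
rather than scored.

## 5. Significance (`call_interactions`)

Candidate regions are maximal runs of profile bins with mass above a
floor `f` (default `1e-15`, i.e. "numerically nonzero"). For a region
with conditional mass $q$ and marginal occupancy mass $q'$, with $n$
effective inter-ligation pairs, the test asks whether joint draws
exceed marginal draws: $Y\sim\mathrm{Bin}(n, q)$,
$Z\sim\mathrm{Bin}(n, q')$ independent, and the p-value is
$1-\Pr(Y>Z)$, computed exactly by
$\sum_z \binom{n}{z}{q'}^z(1-q')^{n-z}\,\Pr(Y>z)$ for $n \le 10^4$ and
by a normal approximation with continuity correction above that.

**Missing-mass correction.** Undersampling makes the observed anchor
totals $t_i$ underestimate their full-sampling values, inflating $q$
relative to $q'$. Given a scale $c \ge 1$ such that the full-sampling
total is $c\,t_{\max}$ at the best-covered anchor, unobserved mass
$\tau_i$ is distributed so that corrected totals are proportional to
the anchors' marginal occupancies $m_i$:
$(t_i+\tau_i)\big/\sum_j (t_j+\tau_j) = m_i\big/\sum_j m_j$. Solving
the constraint for $\tau_i$ gives the cyclic update

$$ \tau_i \;=\; \frac{m_i \sum_{j\ne i}(t_j+\tau_j)}{\sum_{j\ne i} m_j}
   \;-\; t_i, \qquad \text{floored at } 0, $$

with the best-covered anchor pinned at $\tau_{\max}=(c-1)t_{\max}$.
The $-t_i$ term is required for the stated constraint to hold at the
fixed point: without it the update converges to totals proportional to
$m_i$ *plus* the observed $t_i$, which breaks the proportionality
identity the correction is defined by. The implementation iterates the
update to a $10^{-10}$ fixed point and the test suite verifies the
constraint to $10^{-8}$ on all unfloored coordinates. Region p-values
then use $q = \text{mass}\,t_i/(t_i+\tau_i)$ — equivalently, the
region's share of the corrected total.

**Calibrating $c$.** $c$ is not identifiable from the data alone, so it
is set operationally: spurious contacts are overwhelmingly supported by
a single read pair, so $c$ is chosen (by bisection on $\log c$, range
$[1.01, 10^4]$) to make single-pair regions at most a `target`
fraction (default 0.1, with a 0.05 band below) of the significant set.
This premise needs sparsity — at genome scale the space of location
pairs is so large that two independent spurious ligations of the same
pair are rare. On deliberately tiny simulated genomes a site-colliding
noise model can violate it (see §6). If single-pair calls are already
below target at $c = 1.01$, no deflation is applied. Within each
anchor, the most likely jointly occupied location `eloc` is the
argmax-mass bin of the region (ties to the left), and p-values are
optionally Benjamini–Hochberg adjusted across regions.

## 6. Simulator (`simulate_chia_pet`)

The simulator generates data *from the generative model of §1*, which
is exactly what makes it a fair test of the estimator and also bounds
what it can establish:

* self pairs: site $u$ drawn by weight, $L\sim N(300, 30)$ floored at
  50 bp, $\beta\sim U(0.3, 0.7)$, pair
  $\langle u-\beta L,\ u+(1-\beta)L\rangle$ with −+ strands; pairs
  falling off the chromosome are resampled so emitted counts match the
  configuration exactly;
* loop pairs: a planted loop is drawn by intensity, each end
  independently fragmented as above with a uniformly random strand;
* noise pairs: both endpoints uniform over the genome, strands uniform.
  An optional `noise_site_fraction` places that fraction of noise ends
  at random occupied sites instead; it is off by default and exists to
  stress the calibration of §5 with proximity-ligation-like noise. On
  the bundled 40-site toy genome it produces repeated ligations of the
  same site pair far more often than a genome-scale experiment would,
  which violates the single-pair sparsity premise — a fixture-scale
  artifact worth knowing about when designing null studies.

`default_scenario()` plants 20 anchor–distal loops spanning 5–500 kb
on two 2 Mb chromosomes with 30,000/3,000/3,000 self/loop/noise pairs,
and is used for the end-to-end tests: λ recovery within one grid step,
≥ 90% loop recall with `eloc` within ±50 bp of the planted distal
sites, and ≤ 7% nominally significant candidate regions on the
loop-free variant.

## 7. Numerical choices and problem sizes

* All kernels are Gaussian with hard truncation: 1D KDE at $8h$, 2D at
  squared distance $128 h^2$, band evaluation at $6h$ — relative
  truncation error below $e^{-32}$, so results match direct summation
  to the $10^{-12}$ tolerances used in the tests.
* Grid offsets are rounded half-to-even (R's `round`), which is why
  support scans carry the one-bin margin of §4.
* LSCV double sums are $O(n^2)$ and therefore subsampled (5,000 points
  in 1D, 2,000 in 2D) before scanning the bandwidth grid.
* The RL band has (window / bin) × (2W / bin + 1) cells; the default
  5 Mb window with 10 bp bins and $W = 500$ is ~5×10⁷ cells per update
  and dominates `estimate_occupancy` runtime. Reduce `window_size` for
  interactive work, as in the README example.
* The conditional field costs one end-sum per read-pair end plus one
  spread per (anchor-hitting end × support bins); genome size enters
  only through the dense occupancy track (8 bytes per 10 bp bin).

Intended scale: bacterial-to-small-mammalian simulated genomes and
library sizes up to a few hundred thousand pairs run in minutes on one
core. The package is a method study, not a production aligner-to-loops
workflow: it starts from coordinate-level read pairs (BEDPE), not BAM.

## 8. Limitations

* One shared RSF genome-wide; no local fragmentation biases.
* The occupancy track is piecewise-constant at `bin_size`; features
  narrower than a bin are not representable.
* Inter-chromosomal pairs contribute to classification and to the
  conditional field, but the windowed 2D joint density view is
  intra-window only.
* The undersampling scale $c$ is calibrated, not estimated; its
  single-pair premise fails when the space of spurious contacts is
  small (tiny genomes, very deep libraries).
* P-values are conditional on the estimated occupancy and RSF;
  uncertainty in those upstream estimates is not propagated.
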