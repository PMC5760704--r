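---
title: "Methods: clonal deconvolution and the neutral-evolution test in umclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal deconvolution and the neutral-evolution test in umclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umclone)
```

`umclone` reconstructs the life history of a uveal melanoma from one bulk
sample: which aberrations were present in the most recent common ancestor
(MRCA) of all tumor cells, which arose in later subclones, and whether the
mutations accumulated after the MRCA are compatible with selection-free
(neutral) growth. This vignette is the package's account of the models
behind each stage, the defaults and why they hold, and the numerical and
design choices a maintainer would want stated.

## From read counts to cancer cell fractions

The observable at a somatic variant is the variant allele frequency,
`alt / (alt + ref)`. Two nuisance processes separate it from the quantity of
biological interest, the cancer cell fraction (CCF): contamination by normal
cells (purity $\rho$) and local copy number. With tumor total copy number
$n_t$, germline copy number $n_n$ (2 on autosomes; 1 on male X/Y) and $m$
mutant copies per tumor cell,

$$\mathrm{E[VAF]} = \frac{m\,\rho\,\mathrm{CCF}}{\rho\,n_t + (1-\rho)\,n_n}.$$

`ccf_from_vaf()` is the exact algebraic inverse and is deliberately not
clipped: CCF estimates above 1 usually flag an inconsistency (wrong
multiplicity, wrong segment, super-clonal artifact) and hiding them would
hide the problem.

Choices here that the data do not pin down:

* **Multiplicity** is estimated per mutation as
  $m = \mathrm{clamp}(\mathrm{round}(\mathrm{VAF} \cdot (\rho n_t + (1-\rho)n_n)/\rho),\, 1,\, \mathrm{major\ CN})$.
  Phasing $m$ to parental alleles is out of scope; on 8q-amplified regions
  this can under-call $m = 2$ states for borderline VAFs, which would
  inflate the CCF of those mutations by up to 2x; the clamp to the major
  copy number bounds the damage.
* **Subclonal segments** (clonal fraction $c < 1$) use the
  fraction-weighted effective total copy number
  $n_t^{\mathrm{eff}} = c\,n_t + (1-c)\,n_n$ in the denominator — one
  consistent adjustment rather than per-case branching.
* **Confidence intervals** on the CCF are Wilson 95% score intervals on the
  VAF pushed through the (monotone) inverse. The Wilson interval behaves
  well at the low read counts where clonality calls are hardest.

## Dirichlet-process clustering

Mutations are clustered on the CCF scale with a truncated stick-breaking
Dirichlet-process mixture. The emission is binomial on the alt count with
success probability given by the forward model above evaluated at the
cluster's CCF, so depth and copy number weight each mutation's evidence
correctly; no Gaussian approximation on VAF is made.

* **Truncation K = 10.** UM carries few clusters (typically 1–4); ten
  components leave generous room while keeping sweeps cheap.
* **Base measure Uniform(0, 1.25).** Allowing locations above 1 stops the
  clonal cluster from being squeezed below 1 by sampling noise; 1.25 bounds
  the super-clonal range actually seen with noisy purity estimates.
* **Concentration $\alpha \sim$ Gamma(1, 1)**, resampled every sweep from
  its stick-breaking full conditional.
* **Grid locations.** Cluster CCFs live on a 0.005-step grid over
  (0, 1.25]. The binomial log-likelihood of every mutation at every grid
  point is precomputed once, making both the location full conditional
  (sampled exactly, no Metropolis tuning) and the assignment step table
  lookups. The grid resolution is an order of magnitude below every
  decision threshold in the pipeline (0.05 tolerance, 0.10 filter).
* **Defaults n_iter = 1500, burn_in = 500.** On the package's test problems
  (up to ~600 mutations) the sampler reaches its stationary behavior well
  inside the burn-in; both are exposed.

**Summarisation.** Raw component labels switch and transient single-member
components appear; neither is meaningful. Clusters are therefore identified
from the posterior pairwise co-assignment matrix (average linkage, cut at
probability 0.5). Each cluster is anchored per retained sweep at the
component holding the plurality of its members; parts whose anchors coincide
in most sweeps are merged (they are one cluster seen twice), and a part
consisting of a single mutation is folded into the cluster it co-assigns
with most — a lone mutation flickering between modes is an uncertain
assignment, not a clone. Every mutation is then assigned to its
maximum-posterior-probability cluster, ties resolved toward the higher-CCF
cluster. Cluster CCFs are posterior means of the anchored location with
2.5/97.5 percentile intervals; mutation counts carry the interval of the
anchored per-sweep occupancy counts.

**Filtering and counting.** Clusters located below CCF 0.10 are dissolved —
their mutations are plausibly spread across several clones rather than
forming one — and their members move to the smallest surviving cluster; the
top cluster is never dissolved. The threshold is applied on the adjusted
(CCF) scale, the scale on which the motivating concern lives. A discrete
cluster is one with at least two members; a cluster whose posterior
occupancy is borderline (40–60% of sweeps) is counted regardless, the
deterministic analogue of two human reviewers resolving a disagreement by
taking the higher count.

## Pigeonhole clone trees

The highest-CCF cluster becomes the MRCA, child of the normal-cell root,
with CCF fixed at 1 by construction. Remaining clusters attach, in
descending CCF order, wherever the pigeonhole constraint holds: at every
node, children's CCFs may sum to at most the node's CCF plus a tolerance
(default 0.05, the CI-level slack the data imply; configurable).

Because a cluster may fit under several parents, `build_clone_tree()`
enumerates *all* valid topologies (feasible since clusters are few;
$(K-1)!$ candidate parent vectors, enumerated up to K = 9, greedy beyond)
and records the union of valid parents per cluster as `ambiguous_parents` —
rare unplaceable aberrations are mapped to all possible nodes rather than
silently to one. An incremental-greedy alternative was rejected after it
provably under-reports valid parents: a sibling's placement can block a slot
that a different, equally valid topology frees. For the single tree that is
drawn, each cluster takes the highest-CCF (shallowest) valid parent — the
convention matching the default architecture of subclones hanging off the
MRCA; which single tree the data cannot distinguish is exactly what the
ambiguity record preserves.

Copy-number aberrations attach to the node whose cluster CCF interval
contains their clonal fraction (nearest mean as fallback); driver labels
follow their mutation's cluster. An aberration on the MRCA node is called
`MRCA` only if the underlying cluster is compatible with clonality — its
95% CCF interval contains 1.0 and its mean is at least 0.9 — which
operationalises "present in 100% of tumor cells" under sampling noise.

The life-history SVG encodes, exactly: node disc area proportional to clone
cell fraction, branch Euclidean length proportional to branch mutation
count, branch width proportional to cell fraction. Branches carry
`data-node` / `data-count` attributes so the geometry is machine-checkable;
ambiguous placements are additionally drawn dashed under each alternative
parent.

## The neutral-evolution test

Under neutral growth after the MRCA, the cumulative number of subclonal
mutations at frequency $\ge f$ follows

$$M(f) = \frac{\mu}{\beta}\left(\frac{1}{f} - \frac{1}{f_{max}}\right),$$

with $\mu/\beta$ the mutation rate per effective cell division.
`test_neutrality()` fits $M(f)$ against $1/f - 1/f_{max}$ by least squares
*through the origin* — $M(f_{max}) = 0$ is part of the model, so estimating
an intercept would fit noise — and reports
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of $M$
(the conventional form; a zero-intercept $SS_{tot}$ about zero would
flatter the fit). Defaults, all exposed:

| parameter | default | rationale |
|---|---|---|
| window | 0.12–0.24 VAF | reliably called subclonal mutations at typical purity |
| clonal cutoff | 0.25 VAF | diploid heterozygous clonal peak boundary (public vs private) |
| min. mutations | 12 | below this the fit is not meaningful; sample not evaluable |
| $R^2$ threshold | 0.98, strict | the neutrality decision boundary |

$M(f)$ is evaluated at observed VAFs (on dense data a fixed grid gives the
same verdict), with the model's anchor point $(f_{max}, 0)$ appended when no
observed VAF sits exactly at $f_{max}$; the anchor lies on every
zero-intercept line, so it never changes a perfect fit. The stored $R^2$ is
floored at 0: the raw statistic can be negative for a fit worse than the
mean, and any such fit is non-neutral either way (the raw value is kept in
`r_squared_raw`). A degenerate series in which all evaluation points
coincide raises an error rather than returning a fabricated fit. The fit is
performed on raw VAFs, not CCFs, matching how the window thresholds are
defined.

## What the synthetic generator does and does not emulate

`simulate_tumor()` emulates: one clonal cluster (CCF = 1) carrying the
configured Gq/BSE drivers at their canonical loci; up to a few subclones at
fixed CCFs validated against the pigeonhole constraint (default topology:
all children of the MRCA); canonical CNAs (LOH3, 6p+, 8q+) emitted as
segments whose clonal fraction equals their clone's CCF, with the mutation
VAFs on those segments computed through the same forward model the
estimator inverts (a clonal *BAP1* on LOH3 attains the elevated hemizygous
VAF); a neutral tail drawn by exact inverse-CDF sampling from the $1/f^2$
density on $[f_{min}, f_{max}]$, with Poisson-distributed mutation numbers
of mean $(\mu/\beta)(1/f_{min} - 1/f_{max})$; and reads as
depth $\sim$ Poisson(mean) conditioned on $\ge 1$ (zero-depth sites are
unobservable) with binomial alt counts. The tail is sampled in VAF space
with $f_{max}$ defaulting to 0.5, the diploid heterozygous ceiling, because
the neutrality test also operates in VAF space; tail VAFs are attenuated by
purity and tail mutations are placed on CNA-free chromosomes, where that
VAF-space definition is exact.

It does **not** emulate sequencing error, mapping artifacts, germline SNPs,
subclone birth-time dynamics (CCFs are specified, not grown), multi-region
sampling, or sex-chromosome dosage (drivers are placed assuming a diploid X).
Passing tests therefore demonstrate correctness of the estimators under the
generative model they assume — purity, copy number and binomial noise — not
robustness to caller artifacts or segmentation error in real data.

A note on one interaction worth knowing: a WGS-density neutral tail is a
*continuum* of CCFs, which a mixture model necessarily chops into several
multi-mutation clusters. A tumor simulated with both a single clone and a
dense tail will thus report one cluster at CCF 1 plus tail clusters below
it — that is the honest output of a discrete-cluster model applied to
non-discrete data, and it is why the package's integration tests assert the
cluster count on tail-free tumors and the neutrality verdict on tailed
ones.

## Problem sizes and reproducibility

The shipped tests run tumors of 60–540 mutations at depth 100x, Gibbs
chains of 600–1500 sweeps, 20-seed replicate sweeps for the recovery and
single-clone properties, 50-seed sweeps for the neutrality Monte-Carlo
checks, and 200 random instances for the tree-enumeration equivalence
property — sizes chosen to exercise every code path at the study's stated
conditions while keeping a full run around a minute. Every stochastic
function takes an explicit seed; rerunning any stage with the same inputs
and seed is byte-identical, and every written table records its seed in a
header comment.

## Known limitations

* Single-sample analysis only; no multi-region or longitudinal joint trees.
* Multiplicity states above 1 are estimated, not phased; amplified regions
  carry the corresponding CCF uncertainty.
* The clustering assumes discrete clones; a neutral continuum fragments
  (see above), so cluster counts on WGS-scale data should be read together
  with the neutrality verdict.
* Isodisomy-3 timing requires allele-specific phasing output that is out of
  scope here.
* The tree search is exhaustive only to 9 clusters; beyond that a greedy
  attachment is used and flagged as unenumerated.
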