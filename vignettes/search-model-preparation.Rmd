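---
title: "Preparing predicted models for molecular replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing predicted models for molecular replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mrprep turns deep-learning predicted protein models into molecular
replacement (MR) search models. This vignette explains the models and
procedures behind each stage, the parameters that matter, the design
decisions that were genuinely open, and what the synthetic fixtures do and
do not establish about real data.

## Confidence metrics and their detection

Prediction programs overload the PDB B-factor column with a per-residue
confidence value: AlphaFold2 and ESMFold write pLDDT (0–100, occasionally
rescaled to 0–1), RoseTTAFold writes an estimated r.m.s.d. from the true
structure in Å, and a deposited experimental structure carries genuine B
factors. `detect_confidence_kind()` classifies a value vector by its
distribution:

* all values in [0, 1] → fractional pLDDT;
* all values in [0, 100] with at least 5% above 20 → pLDDT on the 0–100
  scale;
* all values within [0, 20] → per-residue r.m.s.d. in Å;
* anything else → already a B factor.

The 5% guard exists because an accurate r.m.s.d. profile lives almost
entirely below 20 Å, while any credible pLDDT profile has a substantial
fraction of residues above 20. The heuristic can be wrong on pathological
inputs (for example a uniformly terrible prediction with every pLDDT below
20), which is why every entry point accepts a declared kind that overrides
detection. Negative values are rejected outright.

The representative value of a residue is taken from its C^α atom, falling
back to the residue's first atom; prediction programs write one value per
residue, so per-atom variation is not modelled.

## Converting confidence to B factors

MR programs weight atoms by their B factors, so the confidence value must
become a plausible displacement parameter. mrprep uses a two-step closed
form. A fractional pLDDT *p* maps to an error estimate

$$\mathrm{rmsd}(p) = \min\!\big(\mathrm{rmsd\_cap},\;
  s \cdot e^{\,k (m - p)}\big)$$

with midpoint $m = 0.7$, scale $s = 1.5$ Å and slope $k = 4$: a residue at
the conventional confidence boundary pLDDT 70 maps to exactly 1.5 Å, and
the curve decays exponentially with increasing confidence (pLDDT 100 gives
$1.5\,e^{-1.2} \approx 0.45$ Å). The error then becomes an isotropic B
factor through the standard relation

$$B = \frac{8\pi^2}{3}\,\mathrm{rmsd}^2,$$

so pLDDT 70 corresponds to $B \approx 59.22$ Å². All four constants are
exposed in `conversion_params()`. The cap (default 20 Å) bounds the B
factor for residues with pLDDT near zero, where the uncapped exponential
(about 24.7 Å at $p = 0$) would give B values in the thousands; 20 Å is
already far beyond any useful atomic weight, so the exact cap value has no
practical effect on MR and simply keeps outputs representable. RoseTTAFold
r.m.s.d. values skip the first step (capped at `rmsd_cap`), and
`bfactor_already` profiles pass through unchanged. The inverse
`bfactor_to_rmsd()` recovers the r.m.s.d. to 1e-9 relative error, which the
tests verify on a dense grid.

## Pruning and segment clean-up

`prune_low_confidence()` keeps exactly the residues with pLDDT at or above
the threshold, default 70 — the conventional boundary below which predicted
conformations stop being trustworthy for MR. The comparison is inclusive
("70 or better" keeps a residue at exactly 70). For r.m.s.d. profiles no
universal cutoff convention exists, so an explicit Å ceiling is required
rather than silently reusing a pLDDT number. The operation is idempotent
and order-preserving.

Pruning leaves behind scraps: short runs of confident residues between
removed regions. `remove_short_segments()` groups residues into contiguous
segments — same chain, consecutive author numbering, successive
C^α–C^α distance at most 4.5 Å — and drops segments shorter than 3
residues. The 4.5 Å ceiling exceeds the 3.8 Å virtual bond with margin but
breaks at genuine chain gaps; both parameters are exposed. A two- or
three-residue island contributes almost nothing to the MR likelihood and
mostly adds noise, hence the default of 3.

The pipeline (`run_prepare()`) converts first and prunes second, using the
pre-conversion profile for the cutoff; the library functions leave the
order to the caller, since both orders are defensible and the profile
argument makes either explicit.

`trim_to_target()` cuts a model to residue ranges, and
`align_to_target()` produces those ranges by global pairwise alignment
(BLOSUM62, affine gaps, defaults 10/0.5) of the model sequence against a
target FASTA — the standard way to restrict a database hit to the region it
shares with the target. The scoring scheme is configuration, not contract:
any sensible global alignment gives the same ranges on near-identical
sequences, which is the regime that matters here.

## Splitting into rigid units

Domain movements between prediction and crystal are the main reason a
high-accuracy prediction still fails MR, so the model is dissected into
units that can be placed independently.

**Coordinate route.** `split_by_coordinates()` clusters C^α positions in
space. The default is agglomerative Ward clustering (`hclust`,
`ward.D2`), chosen over alternatives because it is fully deterministic,
favours compact clusters of comparable spread — exactly the "rigid unit"
intuition — and needs no tuning beyond the cluster count. Seeded k-means is
available as an alternative; with a fixed seed it is reproducible
bit-for-bit. The cluster count is user-controlled; mrprep deliberately does
not auto-select it, and `default_split_sweep()` instead exposes the
standard practice of trying one, two and three clusters and letting the MR
step adjudicate. Residues lacking a C^α (unusual, but legal input) join the
cluster of the nearest preceding C^α-bearing residue so the partition stays
exhaustive.

**PAE route.** The predicted aligned error matrix encodes the expected
positional error of residue *i* when the structure is aligned on residue
*j*; rigid units appear as low-error blocks. `split_by_pae()` symmetrizes
the matrix as $s_{ij} = (p_{ij} + p_{ji})/2$ (producers disagree on whether
the matrix is symmetric, and no direction is privileged for rigidity), then
builds a weighted graph: an edge joins residues with $s_{ij} \le 10$ Å and
carries weight $(1/\max(s_{ij}, 0.25))^{1}$. The 10 Å cutoff severs pairs
whose relative placement is essentially unknown; the 0.25 Å floor bounds
the weight where PAE values saturate near zero; the exponent sharpens or
softens the contrast. Each connected component is partitioned by greedy
modularity maximization — communities agglomerated pairwise in residue
order, always taking the merge with the largest modularity gain, ties to
the lowest indices, stopping when no merge improves modularity at the given
resolution. The implementation is in-package because the available graph
libraries offer either a deterministic greedy method without a resolution
parameter or resolution-aware methods that are randomized; determinism and
a tunable resolution were both required. At resolution 1 it agrees with the
standard deterministic greedy implementation in igraph, which the tests
check on planted block graphs.

Every partition ends with `enforce_min_domain()`: domains smaller than 20
residues merge into the domain with the nearest C^α centroid (ties to the
lower id), smallest first, until stable. A 10-residue fragment is not a
viable search model — its scattering contribution is too small to produce a
believable rotation/translation signal — so undersized clusters are folded
back rather than emitted.

Domains may be discontiguous in sequence: two sequence-distant regions that
pack together form one rigid body and are deliberately kept in one domain.

## Scoring

`score_model()` reports the mean pLDDT with the conventional bands
(below 50 very low, 50–70 low, 70–90 confident, 90 and above very high; a
mean of 70 or more marks a high-confidence prediction) and a
coverage-weighted score
$\sum_i \mathrm{pLDDT}_i / L_\mathrm{target}$ — mean pLDDT times coverage —
which ranks a full-length model of moderate confidence above a confident
fragment, the behaviour wanted when choosing among database hits. This
score follows the idea behind MrParse's H-score (coverage-weighted
confidence) but is defined by the formula above and makes no claim of
numerical equality with that published score, whose exact form is not
reproduced here.

## Synthetic fixtures and what they establish

`generate_model()` builds a single-chain C^α-only trace with planted
architecture: each domain is a self-avoiding fixed-step random walk
(step 3.8 Å, non-adjacent contact floor 3.5 Å) confined to a sphere of
radius $3 \cdot \mathrm{size}^{1/3}$ Å — roughly the packing density of a
globular domain — translated so its realized centroid sits exactly on the
planted centroid line (default 50 Å spacing). Linkers are equilateral
circular-arc bridges, so every virtual bond in the chain has exactly the
step length; a linker that cannot span the gap at that step length is
rejected as infeasible rather than stretched. Per-residue pLDDT is drawn at
90 ± 3 in domains and 45 ± 5 in linkers (clamped to [0, 100]): confident
domains, disordered linker, which is the regime the preparation pipeline is
built for. `generate_pae()` draws intra-domain entries at 2 ± 0.5 Å and
everything else at 25 ± 3 Å, independently for (i, j) and (j, i) so that
downstream symmetrization is actually exercised, with a zero diagonal. All
draws come from one stream seeded by the spec (coordinates, then pLDDT,
then PAE), so fixtures are pure functions of their spec.

The recovery tests use centroid separations of five times the domain radius
(60 Å for 60-residue domains, with 15-residue linkers so the bridge is
geometrically feasible) and establish that well-separated planted domains
are recovered essentially always (adjusted Rand index ≥ 0.95 in at least
98% of 100 seeded runs; observed rate 1.0), and that noise-free PAE blocks
whose inter-block error exceeds the edge cutoff are recovered exactly.

What the fixtures do **not** emulate: secondary structure, side chains,
realistic compactness or contact order, smooth spatially-correlated PAE
noise, or multi-chain interleaving. Two consequences matter. First, passing
the planted-truth tests shows correctness of the clustering machinery, not
performance on borderline real architectures — domains in contact, hinge
motions, or PAE matrices with correlated off-block noise can and do split
differently from any reference implementation. Second, greedy modularity on
a *dense block with i.i.d. noisy weights* can over-partition the block into
a few communities (a known property of modularity maximization under noise)
— real PAE matrices are much smoother than the i.i.d. fixture noise, and
the min-domain merge absorbs small fragments, but users slicing very noisy
matrices should expect to lower the resolution or raise `min_domain`.

## Numerical and degenerate-input choices

* Tie-breaks everywhere are by lower residue index / lower domain id, and
  domain ids are renumbered by ascending first residue index, so all
  deterministic routes are bit-reproducible.
* An empty model is a valid result of pruning (and pruning an empty model
  is the identity), but writing an empty model is an error.
* PDB fixed columns bound coordinates to (−1000, 10000) and B below 1000;
  values outside are an error that points to mmCIF output.
* PAE matrices must be square and non-negative; the legacy flat JSON
  dialect must cover all L² index pairs; a PAE whose size differs from the
  model's residue count is an error, never a silent truncation (a mismatch
  means mixed inputs).
* Multi-model files contribute their first model; HETATM records, waters
  and non-blank/'A' altlocs are dropped — search models are polymer-only.
* Problem sizes in the test and acceptance runs (fixtures of 60-residue
  domains, 100 recovery seeds, 1000-permutation ARI null) were chosen as
  the smallest sizes at which the statistical properties under test are
  stable.

## Known limitations

* The PAE community parameters (cutoff 10 Å, floor 0.25 Å, power 1,
  resolution 1) are sensible defaults, not fitted values; borderline
  architectures are sensitive to them.
* Cluster-count selection is out of scope by design; the k = 1–3 sweep plus
  user control covers current practice.
* Multimer PAE layouts are not handled specially: the matrix is assumed to
  index residues in model file order across chains.
* The coverage-weighted score is mrprep's own named score; compare it only
  with itself.
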