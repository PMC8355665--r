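---
title: "Collagen (I) alpha-chain phyloproteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen (I) alpha-chain phyloproteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colchain)
```

## The problem

Type I collagen is the dominant structural protein of bone and the
biomolecule most likely to survive in ancient skeletal material.  In
most vertebrates it is a trimer of alpha1 and alpha2 chains; many
teleost fishes additionally express an alpha3 chain, the product of a
duplication of the alpha1 gene (COL1A1a/COL1A1b).  Because the protein
is sequenced routinely by mass spectrometry of archaeological bone,
collagen offers a route to placing extinct fishes on phylogenies when
DNA is gone.  `colchain` packages the full desk-scale workflow for this
kind of analysis: assembling chain sequences into a fixed-width
partitioned alignment, telling alpha1 from alpha3, quantifying how
trees inferred from different chains disagree, and converting
partitioned clock output into per-chain substitution rates — together
with a synthetic-data generator that makes every stage testable against
known ground truth.

## Chain identity: the T32/33 and position-1264 rules

The alpha1 and alpha3 helical domains are similar enough that public
databases frequently mislabel alpha3 as "alpha1".  Two diagnostics
separate them:

* **T32/33 window.** At helical positions 334–350 (tryptic peptides 32
  and 33 of alpha1), alpha1 chains carry lysine (K) at the ninth window
  position, so trypsin — which cleaves C-terminal to K or R, but not
  before proline — splits the window into two peptides.  In alpha3 the
  K is replaced by glutamine (Q) and the window survives digestion as a
  single peptide.  In zebrafish the two windows read
  `GGPGVVGPKGATGEPGR` (alpha1) and `GANGPMGAQGASGESGR` (alpha3).
* **Position 1264.** In full procollagen coordinates, residue 1264 is
  cysteine in alpha1 and serine in alpha3.

`classify_chain()` applies the window rule always and the 1264 rule
when it receives a full procollagen, and reports `alpha1`, `alpha3`,
`conflict` (the rules disagree) or `indeterminate` (neither rule
fires).  We deliberately do not force a call on non-K/Q or non-C/S
residues: the rules are empirical regularities over a finite species
set, and unseen taxa may violate them.

Window localization is by pairwise global-in-query alignment (BLOSUM62,
affine gap open 10, extension 0.5) against bundled reference chains.
The references are *synthetic* collagen-like sequences built
deterministically in code — no third-party accession is redistributed —
but they carry the diagnostic features at their canonical coordinates:
glycine at (almost) every third helical position, conserved K/R tryptic
boundaries, the published zebrafish T32/33 peptides at 334–350 and
Cys/Ser at procollagen position 1264.  Queries are aligned against both
the alpha1-like and alpha3-like references and the better-scoring
alignment anchors the coordinates; the two references share their
coordinate system, so the choice affects robustness, not numbering.
Position 1264 is defined in the reference procollagen's own 1-based
coordinates and transferred to queries through the alignment; an
alignment score below a configurable floor (default 0) raises a
"no homology" error rather than producing a garbage window.

The proline-suppression rule in `tryptic_digest()` is on by default
(standard trypsin specificity); the published worked examples are
insensitive to it.

## The partitioned alignment

`concatenate_chains()` builds the taxa × 3161 matrix in fixed column
order alpha1 (1–1058), alpha2 (1059–2099), alpha3 (2100–3161).  Input
chains must already be aligned to these canonical widths — the package
performs no multiple-sequence alignment, and a relaxed-length mode
exists only for classifier inputs such as single peptides.  A taxon
enters the alignment only if it contributes both alpha1 and alpha2; a
missing alpha3 is filled with dashes, treating absence as biological
(several lineages genuinely lack the chain) rather than as missing
observation.  For tetraploid taxa carrying A/B isoform pairs, one copy
enters the alignment under an explicit isoform policy (default A,
overridable); the choice is recorded in the run manifest rather than
hidden.  All partition coordinates are 1-based closed intervals in
every output format (NEXUS charsets, TSV sidecars).

## Tree space

Congruence between two topologies is counted on non-trivial leaf
bipartitions (unrooted; a rooted clade mode is available).  Because
"shared node positions" is directional when resolutions differ, both
denominators are reported (A-in-B and B-in-A).

Distances between trees use the quartet metric: the number of 4-leaf
subsets whose induced subtrees differ.  The implementation derives each
quartet's state from the four-point condition on unit-branch-length
path distances; the test suite checks it exhaustively against a
brute-force oracle that extracts every induced subtree.  Unresolved
quartets (polytomies) count as different from resolved ones by default
(`unresolved_policy = "differ"`); on fully resolved samples the policy
is inert, and the raw differing-quartet count is exposed rather than
any similarity-rescaled variant.

Quartet-distance matrices are generally non-Euclidean, so before
classical multidimensional scaling we apply the Cailliez correction:
the smallest constant `c` added to every off-diagonal dissimilarity
that makes the matrix Euclidean-embeddable, computed as the largest
eigenvalue of the standard 2n × 2n companion matrix of the
Gower-centered first and second powers.  Classical MDS then reports
per-axis variance fractions from the positive spectrum; NMDS (via
`vegan`'s stress engine, best of 20 seeded restarts plus a
metric-scaling start, max 500 iterations, stress tolerance 1e-6)
reports a single 0–1 stress instead, since rank-based embeddings have
no per-axis variance decomposition.  Duplicate topologies in a sample
are detected via identical quartet-state vectors and drive the density
shading of the tree-space plot.

## Substitution rates

Two routes produce per-chain rates:

1. **Clock-summary arithmetic** (`per_chain_rate()`): given a mean
   clock rate *m* (substitutions/site/Ma) and relative partition rates
   *r\_p* from a partitioned relaxed-clock analysis, the per-site rate
   is *m·r\_p* and the whole-chain rate is *R\_p = m·r\_p·L\_p* for
   chain length *L\_p*.  Values are exact products; rounding is purely
   presentational (half-up, one decimal for *R\_p*).  The mean row is
   the arithmetic mean of the three chains — with a pooled
   interpretation also computable from the table, since the two
   readings of a "mean" row differ.
2. **Fixed-chronogram maximum likelihood** (`fit_chain_rates()`): with
   the time-tree fixed, per-partition rates are independent, so the
   joint optimum decomposes into three bounded one-dimensional
   optimizations of the Felsenstein pruning likelihood on the log-rate
   scale (default search interval 1e-6 to 0.05 subs/site/Ma, optimizer
   tolerance 1e-7), with profile-likelihood intervals.  This estimator
   is the package's desk-scale counterpart of a Bayesian partitioned
   relaxed-clock run: it targets the same quantity (per-partition site
   rates per Ma) without re-implementing MCMC, tree dating or fossil
   calibration, which are out of scope.

The substitution model is Dayhoff's empirical amino-acid model, the
standard choice for collagen; its published exchangeabilities and
stationary frequencies are bundled as constants, the rate matrix is
scaled to one expected substitution per site per unit branch length,
and transition probabilities come from the exact spectral matrix
exponential.  Gaps and `X` are treated as missing data, so dash-filled
(absent) alpha3 chains contribute nothing to that partition's
likelihood.  No within-partition rate heterogeneity is modelled: the
model-selection result behind the Dayhoff choice reported no gamma
component, and the flag is reserved but off.

Degenerate inputs are handled explicitly: a zero-duration tree still
has an exact likelihood (the sum of log stationary frequencies when
sequences agree), but rate *estimation* on a zero-duration chronogram
is refused, as is an all-gap partition.  Doubling all branch durations
halves the estimated rates — rate and time are confounded on a fixed
topology, which is why the chronogram's time scale must come from
elsewhere.

## The synthetic-data generator

`make_dataset()` emulates the statistical structure of a compiled fish
collagen database; its defaults are the study conditions, not tuning
knobs:

* chain lengths 1058/1041/1062; per-site rates 0.00067/0.00088/0.00094
  subs/site/Ma (alpha1/alpha2/alpha3);
* a shared ultrametric chronogram with 430-Ma crown age (the calibrated
  bony-fish time scale), sampled by a birth–death process conditioned
  jointly on the taxon count and the crown age via the closed-form
  conditioned speciation-age distribution;
* invariant masks: the glycine frame, conserved K/R tryptic boundaries,
  and the chain-diagnostic T32/33 signatures, frozen during simulation
  so classification has exact ground truth;
* alpha3 missing in 15% of taxa (the observed minority), sampled
  independently per taxon — real alpha3 loss clusters taxonomically
  (cyprinids, herring), which is deliberately not modelled;
* 10% tetraploid taxa with A/B isoform pairs diverged by a target drawn
  uniformly from 3–10%, produced by post-hoc substitutions at the tips
  rather than explicit gene-tree duplication: the observable is the
  divergence band, not the duplication process;
* an alpha1-vs-alpha3 paralog separation applied at the root and
  calibrated through the substitution model so the *expected* tip-level
  divergence approaches a 27% target (the empirically observed band is
  25–29%).

Sequences evolve by exact event-by-event simulation of the
continuous-time Markov chain, and every substitution is logged; tests
replay the log from the root and require byte-identical tips.  Chains
are rooted at the bundled collagen-like references (mimicking real
collagen conservation); the lower-level `simulate_chain()` defaults to
stationary random roots.

Two caveats the generator makes explicit rather than hiding.  First,
with the default rates on a 430-Ma tree, independent evolution alone
already produces about 33% expected alpha1–alpha3 divergence under
homogeneous per-chain rates, slightly above the empirical 25–29% band;
the calibration therefore clamps at zero extra separation, and the
dataset records its calibrated expectation (`alpha13_calibration`) so
tests can check realized against expected.  Real chains saturate lower
because sites vary in constraint — exactly the within-chain rate
heterogeneity the uniform-rate model omits.  Second, for parameter-
recovery studies the masks should be off (`use_masks = FALSE`): the
estimator assumes every site in a partition evolves at the partition
rate, and a third of structurally frozen sites would depress estimates
by roughly that fraction.  That mismatch is a statement about models,
not a defect of either component, and the recovery tests are run under
the estimator's own model.  Passing tests on this generator therefore
demonstrate internal correctness of the pipeline, not that real
collagen obeys uniform rates, site independence, or indel-free
evolution (no indels are simulated; the analysis consumes fixed-width
alignments).

## Problem sizes and numerical choices in the test suite

The suite exercises: quartet distances against the brute-force oracle
on 6–9-leaf trees (50 seeded pairs); Cailliez constants against a
bisection scan on 4–6-point matrices and against base R's additive
constant; pruning likelihoods against explicit internal-state
enumeration on 3–4-leaf trees with 20 sites; rate recovery on 20-taxon,
430-Ma, full-length datasets over five seeds (requiring the alpha3 >
alpha2 > alpha1 ordering and 15% relative accuracy); classifier
accuracy on a 100-taxon simulated database; and lineage-through-time
curves of the tree sampler against the closed-form conditioned
birth–death expectation over 400 replicates.  These sizes were chosen
as the smallest at which each property is sharply testable.  Ties in
the four-point condition are read as unresolved quartets; eigenvalues
are declared positive above a 1e-12 relative threshold in MDS; and all
randomness everywhere flows from explicit integer seeds, with derived
streams for independent stages.

## Limitations

Bayesian tree search, relaxed-clock dating, fossil calibration and
model selection are intentionally absent; the package consumes their
outputs (tree samples, chronograms, parameter summaries) rather than
producing them.  No alpha2-vs-alpha1 discriminator exists — alpha2
identity is taken from annotation, as no diagnostic analogous to T32/33
is described.  Indel handling is limited to pass-through of pre-aligned
input.  The classifiers anchor coordinates to synthetic references;
with real data, substituting curated reference accessions for the
bundled stand-ins is recommended and supported via the `reference`
arguments.
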