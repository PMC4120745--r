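---
title: "Methods: ORF1 architecture classification and reticulate-evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ORF1 architecture classification and reticulate-evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orf1evo)
```

## The problem

Jockey-superfamily LINEs (lineages CR1, L2 and Jockey) pair a conserved,
tree-like ORF2 (apurinic endonuclease, APE, plus reverse transcriptase, RT)
with a structurally volatile ORF1. ORF1s are assembled from a small set of
modules — RNA-recognition motifs (RRM), gag-like CCHC zinc knuckles, plant
homeodomains (PHD), the composite Tnp22 unit (coiled-coil + RRM + C-terminal
domain, deposited as a single database entry), esterases, and zinc-finger /
leucine-zipper elements — and the same module set recurs in different orders
and copy numbers across subgroups. This package operationalizes the analysis
of that contrast: annotate the modules, classify the architectures, build
the ORF2 phylogeny, and ask where ORF1 history disagrees with ORF2 history.

## Domain annotation

### Profile scanning

Annotation uses ungapped position-specific score tables (one per domain
family) rather than a profile-profile search against external databases.
Each packaged profile derives from a fixed consensus string: the consensus
residue carries probability 0.6 per position, the remainder is uniform over
the other 19 residues, and weights are log-odds against a uniform 1/20
background (overridable). Every window of profile length is scored; greedy
non-overlapping maxima above a raw-score floor of 0 are reported. Random
windows score around $-0.7L$ for a profile of length $L$, so the floor
suppresses noise without touching genuine matches, which score near
$+2.5 L$ at low divergence.

This is a deliberate simplification with one property that matters here:
the downstream *decision rule* — take the top hit per region, accept at
probability > 85% — is preserved exactly, and the bundled simulator seeds
its domains from the same consensus strings, so annotation is exact on
synthetic data at low-to-moderate divergence. What is lost relative to a
real HMM–HMM search is remote-homology sensitivity; the package makes no
claim of detecting domains a profile database would find in real, deeply
diverged sequences.

### Probability calibration

A hit's probability is the empirical percentile of its raw score among the
maximum window scores of `n_null` random background sequences of the same
length as the scanned ORF1 (default `n_null = 1000`; below 100 the
calibration is refused as unstable). The statistic is monotone in the raw
score and deterministic given the seed. Two consequences are worth knowing:

- a true consensus-derived hit scores far above every null maximum and
  calibrates at 100;
- on a *random* sequence, each profile's best hit is itself a draw from the
  null-maximum distribution, so its percentile is roughly uniform — about a
  15% chance per profile of crossing 85. In realistic inputs these spurious
  calls are mostly eliminated by overlap resolution against genuine
  full-probability hits, and architectures built from them leave the type
  assignment unchanged in the configurations the simulator produces; but a
  fully random "ORF1" should not be expected to come back empty.

### Coiled coils

Coiled-coil segments are called from heptad periodicity: over a sliding
window (default 21 residues, three heptads; any multiple of 7 of at least
14 is allowed) the score is the mean Kyte–Doolittle hydropathy at the
`a`/`d` register positions minus the mean elsewhere, maximized over the
seven registers. An ideal amphipathic heptad (hydrophobic `a`/`d`, charged
elsewhere) scores about 7.5; shuffles of the *same* residue composition
stay below 6.5 in roughly 99% of trials, which fixes the default threshold
at 6.5. The choice trades sensitivity for specificity deliberately: called
segments are treated as inert context (`CC`) by the classifier, so false
negatives are harmless while false positives would pollute signatures.

## Architecture classification

The ordered accepted domains, plus the fraction of the ORF1 they cover,
map to a type and subtype by a fixed precedence:

1. coverage < 0.10 → **V** (unclassified; too little of the ORF identified);
2. esterase → **IV** (B with upstream zf/lz, else A);
3. Tnp22 → **II** (C with PHD upstream, B with PHD downstream, A alone);
4. RRM immediately upstream of a CCHC → **I** (C with any PHD, B with ≥ 2
   RRMs and ≥ 3 CCHCs, else A);
5. PHD → **III** (B with a downstream RRM, else A);
6. otherwise **V**.

The precedence V → IV → II → I → III is what makes the grammar total and
single-valued: PHD-bearing type I and II architectures (IC, IIB, IIC) must
not be captured by the PHD rule, and the esterase and Tnp22 composites must
win over their own sub-modules. The packaged 20-subgroup fixture exercises
every branch, and the classifier reproduces its type column exactly.

Two judgment calls are encoded explicitly rather than silently:

- **Subtype IB vs IC without a PHD.** One L2 subgroup (L2_8) has the same
  two-RRM/three-CCHC architecture as the Jockey-lineage IB subgroup yet was
  assigned IC in the source study on phylogenetic grounds. The classifier
  stays a pure function of architecture (it returns IB); the published
  assignment is reproduced through an auditable per-subgroup *context
  override*, flagged in the output (`context_override`). Only major type I
  accepts an override.
- **Novel architectures.** Any architecture whose signature is not among
  those attested in the fixture is still classified (the grammar is total)
  but flagged `novel`, so downstream users can distinguish interpolation
  from attested ground.

- **CCHC multiplicity.** Subtype A vs B within type I is decided by RRM
  count (≥ 2) plus CCHC count (≥ 3); a single-RRM ORF1 stays A regardless
  of how many knuckles follow, matching the fixture's IA rows with three
  CCHCs.

## Phylogenetics

Distances come from pairwise-deletion p-distances on the APE+RT
concatenation, corrected by default with the Kimura amino-acid formula
$d = -\ln(1 - p - 0.2 p^2)$ (options: Poisson, raw p). This closed form is
a surrogate for matrix-based ML distances: monotone in $p$, adequate for
topology at the divergences involved, and dependency-free. Pairs beyond the
correction's domain ($p \gtrsim 0.854$) are set to a configurable ceiling
(default 5) and flagged rather than silently truncated.

Neighbor joining is the standard Saitou–Nei agglomeration with two fixed
conventions for reproducibility: ties in the Q criterion break toward the
smallest lexicographic pair of node ids (a node is named by the smallest
leaf in its subtree), and negative estimated branch lengths clamp to 0.
The implementation is exact on additive matrices (verified against path
lengths and against an independent NJ implementation in the test suite).
Bootstrap supports resample alignment columns with replacement and report,
per internal bipartition of the full-data tree, the percentage of replicate
trees containing it — stored as integer percents on internal nodes, the
convention the newick reader/writer round-trips.

Fitch small parsimony roots the unrooted tree arbitrarily on a leaf edge
and runs the standard two-pass count (rooting-independent; verified against
exhaustive minimization on small trees). Subgroups are delineated as
maximal clades with bootstrap support at or above a floor whose leaves
share one (type, subtype) label; leaves in no qualifying clade become
singletons, and an optional merge step fuses same-type non-sister groups,
mirroring how published subgroups are sometimes non-monophyletic but share
an ORF1 structure.

## RRM clustering

Only the region between the RNP2 and RNP1 consensus boxes is shared by all
RRMs, so exactly that region — projected onto hit coordinates — is excised
for clustering; elements with two RRMs contribute upstream (`U`) and
downstream (`D`) units. Pairs are scored by Smith–Waterman local alignment
(BLOSUM62, gap open 10 / extend 4); the attraction is the z-score of the
observed score against `n_shuffle = 200` shuffles of one member, floored at
0. Shuffling always the lexicographically smaller id makes the weight
symmetric and input-order-free by construction. Clusters are connected
components above an attraction floor (default z ≥ 3 — our choice; the
visual clustering this replaces has no published cutoff), which makes
cluster extraction monotone: raising the floor can only split, never merge.
The 2-D force layout (attraction ∝ weight, uniform repulsion, damped
steps, seeded start) is for visualization only and carries no inferential
weight.

## Transfer detection

The ORF2 tree defines lineages; the ORF1 tree, built from the extracted
RRM+CCHC block (or full ORF1) of the elements that possess it, is where
intrusions show. For each lineage $L$ monophyletic in the ORF2 tree
(restricted to the shared leaf set), the midpoint-rooted ORF1 tree is
searched for the smallest clade containing all $L$ leaves *and at least as
many foreign leaves as $L$ leaves*. A candidate requires (i) more than 50%
of those foreign leaves to carry one single other label $H$, and (ii) the
span of $H$'s own leaves in the ORF1 tree to contain $L$ leaves — i.e. the
host lineage is broken by the intrusion. Condition (ii) is what separates a
genuine embedding from ordinary sister-lineage geometry, where the clade
above $L$ is pure $H$ but $H$ itself is intact; without it, every clean
lineage pair would be a false candidate. The walk-up rule (grow until
foreign leaves reach parity) handles the common case where the transferred
set is itself monophyletic in the ORF1 tree, so the literal "smallest clade
containing $L$" would contain no foreign leaves at all. Both thresholds are
exposed as parameters; the defaults reproduce the published two-position
embedding pattern on constructed trees and recover simulated transfers.

`n_embedding_positions` counts maximal $L$-only clades inside the host
span (the published case has two); `delta_fitch` reports the lineage-label
Fitch difference between the trees (zero when the transferred clade is
intact in both, so it is reported, not gated on). The permutation test —
Fitch score of the focal-vs-rest labeling against uniformly shuffled labels,
$p = (1 + \#\{stat_{perm} \le stat_{obs}\}) / (n_{perm} + 1)$ — has no
counterpart in the source analysis, which read the pattern off the tree; it
is labeled an auxiliary statistic in all reports. Because the statistic is
a small integer, the p-values are conservative (discrete), not exactly
uniform under the null.

## The simulator

`generate_dataset()` emulates the data-generating process the analysis
assumes, with ground truth for every stage:

- **Trees.** Each lineage is a Yule tree (`yule_rate = 1`) scaled to a
  common height of 0.3 time units, joined by backbone stems of 0.3; with
  `subst_rate = 0.5` this puts within-lineage p-distances around 0.1–0.25
  and between-lineage distances around 0.4–0.55 — diverged enough to
  separate lineages cleanly, inside the Kimura correction's domain. Default
  size is 20 taxa in 3 lineages, the scale at which the whole pipeline runs
  in seconds.
- **Sequences.** APE (100 aa) and RT (150 aa) evolve by per-branch Poisson
  substitution (uniform replacement over the other 19 residues), matching
  the 20-state Jukes–Cantor-type closed form the tests check. There is no
  indel process: columns are positionally homologous by construction, which
  removes any dependence on an external aligner. This is the simulator's
  biggest idealization — real ORF1 alignments need gapped alignment and
  their blocks differ in length.
- **ORF1.** Each lineage's ORF1 is a segment list (terminal linkers of 25
  aa, inter-domain linkers of 10 aa, domains seeded from the profile
  consensus strings; default roots: a type I RRM×2+CCHC×3 for Jockey, a
  Tnp22 for L2, a PHD for CR1). PHD gain (N-terminal or a downstream slot,
  equal odds), PHD loss and esterase gain are per-branch Poisson events
  (default rates 0); horizontal transfers replace a recipient clade's whole
  ORF1 with the donor lineage's state *at a random internal donor node*, so
  recipients nest inside — not sister to — the donor clade, which is the
  geometry the detector (and the published pattern) is about. Every event
  goes to a log keyed by the affected clade, and replaying the log against
  the tree must reproduce the leaf architectures exactly — the simulator's
  bookkeeping invariant, tested directly.

What passing on synthetic data does *not* show: robustness to alignment
error, to indels, to domain divergence beyond profile sensitivity, or to
the sampling heterogeneity of curated element databases. The simulator is a
correctness instrument for the pipeline's logic, not a realism claim.

## Numerical and reproducibility choices

- Coordinates are 0-based half-open internally; human-readable output is
  the only place 1-based rendering may appear.
- One gap dialect (`-`); `.` is rejected at parse time with the offending
  line named.
- Every stochastic step takes a seed; sub-streams derive from the master
  seed by a fixed affine map and all seeded evaluation restores the
  caller's RNG state. Reruns with identical inputs, config and seed are
  byte-identical, and every output file carries the package version and a
  config hash in its header.
- Missing values stay missing: an identity over fewer than two sequences,
  or a blank cell in the packaged table, is `NA`, never 0.

## Problem sizes

The test suite and the acceptance script run the pipeline at 10–20 taxa,
bootstrap sizes of 40–500, calibration nulls of 200–1000, 50 additive
matrices for the NJ oracle, 100 trees for the Fitch oracle, and 25–50
simulation replicates for transfer recovery — sizes chosen so the full
suite completes in a couple of minutes on one CPU while every decision rule
runs at its default settings.

## Known limitations

- The profile scan is ungapped and database-free; remote homologs and
  length-variant domains in real data will be missed.
- The Kimura amino-acid correction is a surrogate for model-based
  distances; at saturation it degrades to a flagged ceiling.
- The embedding rule quantifies what was originally a visual inference;
  its two thresholds (foreign-majority fraction, parity walk-up) are
  defensible but not unique operationalizations.
- The classifier covers architectures attested in the packaged table plus
  everything its grammar can express; genuinely new module combinations
  classify by precedence but are flagged `novel` rather than validated.
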