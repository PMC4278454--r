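---
title: "Models and methods behind ZWstrata"
author: "ZWstrata authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ZWstrata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZWstrata)
```

# The scientific problem

Birds are female-heterogametic: females carry a Z and a W chromosome,
males two Z copies. Once recombination between the proto-Z and proto-W
stops in a chromosomal region, the Z- and W-linked copies of each gene in
that region (a *gametolog* pair) begin to diverge independently. Regions
that stopped recombining at the same time form an *evolutionary stratum*:
a band of the Z chromosome whose gametologs share a similar synonymous
divergence (dS). ZWstrata reconstructs this history from coding sequence
alone: it identifies W-linked genes, pairs them with their Z partners,
estimates dS with uncertainty, dates recombination suppression with a
molecular clock, distinguishes suppression events shared across species
from lineage-specific ones using gene trees, detects ongoing genetic
exchange (gene conversion), and asks which selective regime W and Z
sequences evolve under.

All stages run on simulated data generated by the package itself, so
every claim the test suite makes is checked against a known truth.

# The simulator: study conditions as defaults

`simulationConfig()` encodes the four-taxon system the pipeline targets:
chicken (*Gallus gallus*, Gg), turkey (*Meleagris gallopavo*, Mg), duck
(*Anas platyrhynchos*, Ap) and zebra finch (*Taeniopygia guttata*, Tg) on
the topology (((Gg, Mg), Ap), Tg) with splits at 30, 90 and 130 My.
Defaults, chosen once:

* **Rates.** The combined Z+W synonymous rate is 3.8e-9 substitutions
  per site per year — the constant also used by the dating clock — split
  1:2.4 between W and Z for male-biased mutation. The split itself is a
  labelled assumption (only the sum is an established constant); both
  rates are configurable.
* **Substitution process.** An HKY nucleotide proposal process
  (kappa = 2) layered over codons. Nonsynonymous proposals are accepted
  with probability omega (rejection sampling); proposals creating stop
  codons are discarded, and the proposal intensity is inflated by the
  exact stop-hit fraction so the realised synonymous rate per site per
  year equals the configured rate — this keeps the clock identity
  `E[dS] = (muW + muZ) * T_supp` exact rather than approximate. Values
  of omega above 1 (used to simulate episodic positive selection) add a
  nonsynonymous-only event stream at the excess rate; omega may be a
  per-codon vector.
* **Selection.** omega = 0.2 on both chromosomes by default — ordinary
  purifying selection on coding genes.
* **Histories.** A locus evolves as a single proto-sequence until its
  recombination-suppression event, then duplicates into Z and W lineages
  (muZ and muZ-omegaZ before the event, since a recombining locus is
  effectively Z-like). Suppression on an ancestral branch (GgMg or
  GgMgAp) yields a *shared* history — the W copies of the descendant
  species form a clade — while suppression on a terminal branch yields
  an *independent* one. The default 30-locus layout mirrors the five
  suppression events of the study system (two Galloanserae-ancestral,
  two Galliform, one Anseriform-specific) with Z positions drawn from
  the corresponding intervals.
* **Ancillary channels.** Fixed Z-W differences are exported as
  female-limited SNPs (plus one segregating W variant when a young pair
  has no fixed difference); `simulateExpression()` emits a
  `SummarizedExperiment` in which W genes are female-limited up to a
  sub-threshold technical leakage, exercising the classifier's rounding
  rule.

What the simulator does **not** emulate: indels and alignment error
(sequences stay colinear), rate variation among sites and loci beyond
the omega structure, expression dosage effects, read-level artefacts,
and recombination hotspots. Passing tests therefore demonstrate
correctness of the inference machinery under the stated model, not
robustness to every artefact of real data.

# Divergence estimation

`mlPairwiseDivergence()` fits a Goldman-Yang codon model (61 sense
codons, transition/transversion ratio kappa, dN/dS ratio omega, F3x4
codon frequencies estimated from the pair) by maximising the pairwise
likelihood over (t, kappa, omega) on the log scale with a bounded
quasi-Newton optimiser; three fixed starting points are scored and the
best polished (the others serve as fallbacks), with a log-likelihood
tolerance of 1e-8. dS and dN are derived from the fitted substitution
flux — dS = t·rhoS / (3·rhoS1), where rhoS is the synonymous fraction of
flux at the MLE and rhoS1 the same fraction at omega = 1 — so
omega = dN/dS holds exactly. Standard errors come from the observed
information via the delta method, and the 95% interval is the estimate
±1.96 SE floored at zero. Gapped or masked codon columns are dropped
pairwise (complete-case); at least 50 ungapped codons are required by
default.

`ng86Divergence()` is the deliberately independent counting oracle:
fractional site counts per codon, pathway-averaged difference counts
(pathways through stop codons excluded), and a Jukes-Cantor correction.
Site counting follows the original convention in which nonsense
mutations are eliminated from the opportunity count, so each position
contributes one full site and S + N = 3L. With the PAML-style variant
(stop targets kept in a denominator of 3) the counting estimate runs a
few percent above the codon-model estimate by construction; under the
original convention the two agree within ~0.01 for dS ≤ 0.3 when the
data match the counting model (kappa = 1). That is also why the
oracle-agreement test simulates at kappa = 1, omega = 1: a counting
method with a Jukes-Cantor correction is only an oracle under its own
model, and validating the ML estimator against it elsewhere would test
the oracle's bias, not the estimator. Under the generator default
kappa = 2 the NG86 estimate is biased upward (about 15% at dS 0.34)
while the ML estimate stays on the clock line.

Estimates with dS > 1 fail `checkSaturation()` and are excluded from
dating and strata assignment; the boundary dS = 1 passes.

# Dating and strata

`clockDate()` is the linear clock T = dS / 3.8e-9 years, reported in
millions of years and rounded to the nearest My (matching the precision
of reported dates); confidence intervals map through the same formula.
The gate refuses saturated input rather than returning an unreliable
date.

`assignStrata()` compares each candidate locus against the *orthologous
reference gene* (not a pooled stratum interval — a pooled mode exists
behind `poolReference = TRUE`): overlapping 95% intervals place the
locus in the reference stratum; disjoint intervals with lower candidate
dS mark it lineage-specific. A gene-tree call of "independent" overrides
CI overlap (the conflict is flagged), because topology is the stronger
evidence when the two disagree. `summarizeStrata()` reports, per
stratum, the Z interval, dS range and clock-dated range, ordered along
the chromosome.

# Gene trees and the shared/independent call

`mlTree()` enumerates *every* unrooted topology over the 4-8 sequences
(3, 15, 105, ... trees), optimises branch lengths and kappa for each
under HKY85 with empirical base frequencies (a GTR extension was
considered and left out: at these divergences HKY captures the
transition bias that matters, and exhaustive enumeration must stay
cheap), and returns the global optimum rooted on the designated
outgroup (the finch Z ortholog). Identical sequences make every
topology equally likely; the result is then flagged star-like.

`bootstrapSupport()` resamples codon triplets (preserving the reading
frame; plain-column resampling is available) and scores each enumerated
topology on each replicate. The default engine is RELL: replicates
re-weight the per-site log-likelihoods of each topology at its
original-data MLE instead of re-optimising branch lengths. Because the
topology set is exhaustively enumerated, the winner per replicate is a
true maximum over topologies; only branch-length re-optimisation is
skipped. `method = "full"` re-runs the whole search per replicate and
agrees with RELL within a few points on test loci; RELL makes the
paper-scale 1000 replicates effectively free.

`classifyTopology()` encodes the biological dichotomy: *shared*
suppression means the W sequences of different species form a supported
clade (divergence predates speciation); *independent* means each
species' Z and W pair off. The default support threshold is 95%,
following the reported usage; anything unresolved stays unresolved.

# Gene-conversion detection

Conversion between gametologs copies a tract from one chromosome onto
the other, homogenising it. `silentPolymorphicSites()` restricts the
search to columns where every present codon encodes the same amino acid
but nucleotides differ — heterogeneous selection at replacement sites
would otherwise mimic conversion. `findFragments()` then looks for long
stretches where a Z-W pair is identical, bounded by disagreeing sites,
and scores each fragment by its *alignment span in bp* (monomorphic
columns between the bounding sites included, matching the track-length
semantics of conversion tables). Under gscale = 0 no internal mismatch
is allowed; under gscale = 2 each mismatch costs 2.5 mean inter-site
spacings of span, so two mismatches cancel roughly five matches' worth
of identity. A linear-time recurrence finds the fragments and is tested
against brute-force enumeration.

Significance comes from `permutationTest()`: the contents of the
polymorphic sites are permuted across their fixed positions (the
spec'd 10,000 permutations by default; the calibration test uses its
designated reduced 2,000), and
`sim_p = (1 + #{permutation max >= score}) / (nPerm + 1)`. Span scoring
matters here: scoring fragments by the *count* of agreeing sites makes
the null maximum coarsely discrete and the test conservative (type-I
error near 0.01-0.02 at alpha = 0.05), while the span statistic is
nearly continuous and calibrates correctly (measured 0.045 on 400 null
loci, with sim_p uniform by Kolmogorov-Smirnov). `corrected_p` applies
a Bonferroni factor over the tested Z-W pairs; a Karlin-Altschul-style
run-length tail bound (`ka_p`) is reported alongside as the
length-corrected analytical analogue. Only between-group (Z vs W) pairs
are scored, the pairwise analogue of a grouped conversion scan;
the outgroup is excluded from testing but still informs the profile.

Fragments are classed *inner* when no sequence outside the pair shares
the pair's states over the fragment (evidence for conversion between
the two aligned sequences' ancestors) and *outer* when some outside
sequence carries essentially the same run (ancestral identity, or an
event involving sequences outside the pair); ambiguous cases default to
outer. The share threshold is 90%.

Because fragments are bounded by variable sites, a tract can spuriously
bridge exons separated by dissimilar introns; `filterFragmentsByExon()`
drops exons where the within-exon span is under 50 bp (strictly less —
exactly 50 bp survives) and discards fragments left spanning nothing.

`inferDirection()` votes over the fragment's sites: the shared state is
compared with the consensus of each member's chromosome group among the
remaining sequences (the outgroup counting toward the Z side); a site
votes for the member whose group consensus it matches exclusively, and
the donor is called at ≥3 informative sites with ≥80% agreement. When
votes are insufficient, a maximum-likelihood tree of the
fragment-spanning exon columns is built and its topology class
(cluster-by-sex vs cluster-by-species) reported as an annotation — the
direction itself stays unknown, since inside the tract recipient and
donor are identical and tree shape alone cannot orient the transfer.
`recomputeDivergenceExcluding()` re-estimates dS without the converted
exons; removing a homogenised tract should raise the estimated
divergence time, and the before/after pair is reported.

# Selection tests

`buildBranchTree()` provides the two fixed gene-tree templates — shared
suppression, (Tg Z, (((Gg W, Mg W), Ap W), ((Gg Z, Mg Z), Ap Z))), and
independent suppression, (Tg Z, (((Gg W, Mg W), (Gg Z, Mg Z)),
(Ap Z, Ap W))) — pruned to the taxa present, with every branch whose
descendants are all W (or all Z) labelled foreground, including the
clade stem.

`branchModelLrt()` fits a two-ratio codon model (background and
foreground omega; branch lengths and kappa re-optimised under every
model, the standard behaviour) and compares the free model against
foreground omega fixed to 1 (neutrality) or 0 (strict purifying
selection), each on one degree of freedom against chi-squared. The
omega = 0 null fixes the foreground class only; a foreground
nonsynonymous difference then simply shifts onto background paths and
penalises the likelihood rather than erroring. If numerical
optimisation leaves the free model below a null, the free fit is
restarted from the null solution, so nesting holds by construction.

`branchSiteTest()` is model A: site classes 0 (0 < omega0 < 1
everywhere), 1 (neutral everywhere), and 2a/2b (foreground
omega2 >= 1 layered over classes 0 and 1, proportions split
accordingly). The alternative estimates omega2; the null fixes
omega2 = 1. The LRT is reported against chi-squared(1) — used for the
significance flags, the common conservative practice — and against the
50:50 mixture of a point mass at zero and chi-squared(1) alongside.

The tree likelihood engine is shared by all of these (Felsenstein
pruning, generic over 4 nucleotide or 61 codon states, with
transition matrices from the symmetric eigendecomposition of the
reversible generator) and is cross-checked against the pairwise
estimator: on a two-taxon tree the branch-model log-likelihood at the
pairwise MLE matches the pairwise log-likelihood to 1e-4.

# Homology and W-gene identification

The similarity scorer is Smith-Waterman local alignment (match +5,
mismatch -4, affine gaps) with a Karlin-Altschul e-value
E = K·m·n·exp(-lambda·S); lambda is solved exactly for the scoring
scheme, K is a documented calibration constant (0.1) — e-values here
implement a ranked cutoff (1e-10 by default), not exact tail
probabilities. A tabular hit reader accepts precomputed outfmt-6-like
tables in place of the internal aligner. `pairGametologs()` implements
the three-step rule (W query → reference W → reference Z → reciprocal
best hit in the species set, with a next-best fallback when
reciprocity fails); the reciprocal check runs against the combined W+Z
reference so that a young, slow-evolving species W gene — which can
out-score the true Z ortholog — fails reciprocity exactly as in the
motivating analysis, and the route taken is recorded per pair. The wet-lab
verification of Z linkage is replaced by a flag on any chosen Z gene that
is itself in the W candidate set. The coverage <25% AND aligned length
<150 bp exclusion is the literal conjunction (a disjunctive variant sits
behind a flag; single-metric failures are kept but flagged borderline).
Paralogs resolve to the minimal-dS pair with deterministic tie-breaks
(longest alignment, then id).

`classifyWCandidates()` uses explicit stand-in thresholds — the original
figure-based rule is not published as numbers — defaulting to:
female-limited when every male sample rounds to ≤0 at two decimals and
the female mean is ≥1; strongly-female-biased at a ≥10-fold
female/male ratio. Tightening the male threshold can only shrink the
candidate set (monotonicity is tested). `verifyDistinctGametologs()`
guards the very young pairs (dS < 0.02): a pair is accepted as genuinely
distinct only with a fixed Z-W difference or a female-limited W-specific
SNP.

# Alignment handling

`buildCodonAlignment()` aligns translated proteins (Needleman-Wunsch
with BLOSUM62 for pairs; centre-star progressive alignment for small
sets — adequate for closely related gametolog CDS, not a general MSA
engine; an external aligner is pluggable) and threads the codons back,
so gaps always occupy whole codons. Internal stop codons are an error
naming the codon; terminal stops are stripped. The manual
"remove poorly aligned regions" step is replaced by the deterministic
`maskPoorRegions()` rule: codon columns over 50% gapped, or 5-codon
windows under 40% mean pairwise identity, are masked (whole codons
only; idempotent; the thresholds are explicit stand-ins since no
published criteria exist). All API coordinates are 0-based half-open
alignment columns.

# Numerical choices and degenerate inputs

* Optimisers: L-BFGS-B on log (or logit) scales throughout, with
  likelihood caches keyed on (kappa, omega) so branch-length
  perturbations do not recompute eigendecompositions.
* Identical sequences: pairwise estimates return exact zeros with zero
  SE; tree search warns and flags star-likeness; the permutation test
  returns sim_p = 1 on a single polymorphic site.
* Ties: hit ranking breaks ties by target id; paralog resolution by
  aligned length then id; fragment ordering by score then position —
  all deterministic.
* Every stochastic routine takes an explicit integer seed and
  reproduces byte-for-byte.

# Problem sizes in the checks

The validation suite simulates at the study's stated scales — 900 bp
CDS, 30-50 loci for stratum and topology checks, 50 replicates per arm
of the selection calibration, 400 null loci for the conversion
calibration — with the reduced permutation (2,000) and full bootstrap
(1,000, cheap under RELL) replicate counts the corresponding checks
designate. The acceptance script re-runs the same computations at
moderately smaller replicate counts (printed in its output) chosen to
keep a complete run in minutes; sizes are stated next to each number it
writes.

# Known limitations

* F3x4 codon frequencies are a product approximation: when the true
  codon usage is not in the F3x4 family (the simulator's uniform sense
  usage is not), the fitted total divergence runs a few percent high,
  apportioned between dS and dN by the noise in omega. The effect is
  bounded (~5% on t at the divergences used here), shared with any
  codon-model software using the same frequency default, and absorbed
  by the stated tolerance bands; empirical-codon-frequency variants
  would remove it at the cost of 60 extra free parameters.
* The centre-star protein aligner degrades on deeply diverged or
  repeat-rich sets; plug in an external aligner for real data.
* The Karlin-Altschul K is a fixed constant, so absolute e-values are
  approximate (cutoff semantics are preserved).
* RELL bootstrap under-disperses supports slightly when branch lengths
  are far from their resampled optima; use `method = "full"` when exact
  re-optimised supports matter more than runtime.
* The branch-site test at these tree depths has limited power for weak
  episodic selection; the power checks use strong effects.
* Direction inference requires informative relatives; with only the
  pair and an outgroup it will usually return unknown.
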