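---
title: "Models and methods behind cypevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cypevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypevol)
```

`cypevol` analyses the birth-and-death evolution of the cytochrome P450
(CYP) gene superfamily: how often genes duplicate, die, and change under
selection, and how those dynamics differ between biosynthesis-type
(B-type) and detoxification-type (D-type) genes. This vignette explains
the models each stage assumes, the tunable parameters and their defaults,
what the simulators do and do not emulate, and the numerical choices made
where the design was genuinely open.

## Distances

**p-distance** is the proportion of differing nucleotide sites among the
comparable (both non-missing) positions of a pair. Gaps (`-`) and
ambiguity codes (`N` for nucleotides, `X` for proteins) are missing data
everywhere; alignment columns at which *strictly more than* 20% of
sequences show missing data are excluded up front (`filter_columns()`,
`max_gap_fraction = 0.20`). Under *pairwise* deletion each pair is
compared on its own comparable positions; under *complete* deletion every
column with any missing value is removed for all pairs. Pairwise-deletion
matrices can violate additivity or even the triangle inequality, so
`nj_build()` records a metricity diagnostic alongside the tree.

**JTT distance** is the one-parameter maximum-likelihood distance between
two protein sequences under the Jones–Taylor–Thornton replacement matrix
(the standard empirical matrix for globular proteins), computed by
`phangorn::dist.ml`. Distances at the saturation bound (10
substitutions/site) are clamped and flagged.

**NG86 dN/dS.** Synonymous (S) and nonsynonymous (N) *sites* per codon
are counted position by position as the fraction of single-nucleotide
changes that preserve the amino acid; changes creating stop codons are
excluded from both numerator and denominator, so each position
contributes exactly one site and S + N = 3 per sense codon. *Differences*
between codons separated by 2–3 changes are averaged with equal weight
over all minimal substitution pathways, preferring pathways that avoid
stop-codon intermediates (all pathways are used only when every one
passes through a stop). The proportions pS = Sd/S and pN = Nd/N are
corrected for multiple hits with the Jukes–Cantor formula
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$; the correction is isolated
behind a switch (`correction = "none" | "jukes_cantor"`) because the
analysis this package reimplements does not state which correction its
distance software applied, and JC is that era's default. Ratios with
pS ≥ 3/4 are flagged saturated.

## Trees and branch lengths

Neighbor-joining follows the Saitou–Nei agglomeration (via `ape::nj`);
for an additive matrix the realized path lengths reproduce the input
exactly, which the suite verifies on random 8-taxon trees. Bootstrap
support resamples alignment columns (codon columns for coding
alignments) with replacement, rebuilds the tree per replicate, and
reports the percentage of replicates containing each original
bipartition; replicates with undefined distances are dropped and the
denominator adjusted. Support values are kept at full precision
internally and rounded only for display.

OLS branch lengths solve the linear least-squares system in which each
pairwise distance is the sum of branch lengths on the connecting path.
Negative solutions are possible on noisy matrices; they are clamped to
zero with a warning followed by one refit pass of the remaining branches.
The clamped lengths are what downstream ratios (e.g. constraint `f`) use.
A rooted binary input is unrooted first because the two root branches are
only jointly identifiable.

## Classification

B/D type assignment formalises "significant clustering with known
references" as: the query takes the label of the *smallest* clade
containing it whose reference members are unanimous and whose defining
branch has bootstrap support of at least `min_support` (default 80, the
support level treated as reliable in this literature). Unsupported
internal branches are treated as unresolved and skipped, which makes the
assignment stable under adding arbitrary unsupported structure.
`unassigned` is an explicit outcome, never a guess.

Family and subfamily grouping uses single-linkage clustering of pairwise
protein identity at the nomenclature thresholds (family ≥ 0.40,
subfamily ≥ 0.55). Single linkage matches how the nomenclature behaves
in practice (chains of pairwise-similar genes share a family) and makes
subfamily clusters nest within family clusters by construction.

Conserved sites are columns whose modal residue frequency among
non-missing residues *strictly exceeds* the threshold (default 0.95);
group-diagnostic sites require within-group fixation of a residue absent
from every other group (a relaxable within-group threshold is exposed but
defaults to 1.0, matching the worked residues that motivated the rule).

## Gene content: Dollo reconstruction and rates

Genes arise once: each ortholog group is gained exactly once, at the MRCA
of the species possessing it, and can only be lost below that node
(Dollo parsimony — appropriate because independent re-invention of the
same gene is not a plausible event, unlike in Fitch parsimony). Within
the gained region, ancestral copy numbers are fitted by a small dynamic
program minimising the total number of unit events (one per copy-number
step per branch, plus the origin gains at the MRCA); ties resolve to the
smallest ancestral count, which places copy-number changes as late
(towards the tips) as parsimony allows. An exhaustive enumeration oracle
(`brute_force_min_events()`, ≤8 species) verifies minimality in the
suite. Pseudogenization is an annotation-driven event — a
functional-to-pseudogene status change — placed at the MRCA branch of the
species sharing the inactivating state, or the pendant branch for a
single species; it is not inferred from counts.

Event rates are `100 x count / window`, with the window in myr. The
packaged 15-species chronogram carries TimeTree-style node ages scaled by
a single factor so the total branch length equals 2,685 myr; individual
ages are therefore approximate and the calibration age used in dating is
always an explicit argument. The post-eutherian window for D-type rates
defaults to the printed 432 myr but is a user input, because which
branches make up that window is not fully specified in the source
analysis.

## Dating

**Duplications.** Under a molecular clock, the path length from a
duplication node to a calibration node (`b_pre`) and from the calibration
node to a tip (`b_post`, accumulated over `T_cal` myr) give
$\hat t = T_\mathrm{cal}\,(b_\mathrm{pre} + b_\mathrm{post})/b_\mathrm{post}$
per tip lineage. All lineage estimates and their range are reported; the
*minimum* is the headline (conservative) estimate. The estimator is
scale-invariant in the branch lengths. When starting from an alignment,
distances are JC-corrected, branch lengths fitted by OLS, and the
duplication node placed at the midpoint of the branch separating the two
duplicate clades — the clock assumption applied to that branch. The
uncertainty interval offered (`duplication_time_bootstrap()`) is a
nonparametric bootstrap over alignment columns; the source analysis
printed "±" values without stating an estimator, so this interval is the
package's own choice and is documented as such.

**Pseudogenizations.** For a pseudogene and a functional ortholog that
diverged $T$ mya, nonsynonymous changes accrue at $f\,r_S$ while the gene
was functional (duration $2T - t$ summed over both lineages) and at $r_S$
after inactivation (duration $t$), while synonymous changes accrue at
$r_S$ throughout. The observed ratio $R = d_N/d_S$ therefore mixes the
two regimes: $R = f + (1 - f)\,t/(2T)$, inverted as
$t = 2T\,(R - f)/(1 - f)$. The endpoints are exact: $t(R = f) = 0$ and
$t(R = 1) = 2T$ before clamping. Because $R$ is noisy at short $T$,
estimates outside $[0, T]$ are clamped and flagged rather than rejected.
The functional baseline $f$ is ideally estimated from functional ortholog
pairs of the same family over the same species pair; a user-supplied $f$
is accepted (and used in the recovery tests, where truth is known).

## Functional constraint

For each gene, NG86 dN and dS matrices over the four primates (human,
chimpanzee, rhesus macaque, marmoset) are fitted independently by OLS on
the fixed species topology — the gene tree is forced equal to the species
tree, so no topology estimation noise enters — and
$f = \sum b_N / \sum b_S$ over the five branches; the degree of
functional constraint is $1 - f$. Genes with $\sum b_S = 0$ are excluded
with a warning. The B-vs-D comparison reports means, SDs and medians per
type and a two-sided Mann–Whitney U test: exact (no ties, n ≤ 20) or a
normal approximation with tie-corrected variance and continuity
correction; the variant used is recorded in the output because the two
can differ in the third decimal at these sample sizes — the source
analysis itself reports two slightly different p-values for this
comparison in different places.

## The simulators: what they emulate, and what they do not

`simulate_gene_content()` draws gains, losses and pseudogenizations as
Poisson processes per gene lineage along chronogram branches. Gains add a
functional copy to the same ortholog group (so matrix entries can exceed
1); losses remove the copy and terminate its event stream;
pseudogenization relabels the copy, which then stays inert. Defaults are
the B-type study conditions: 0.7 / 0.6 / 0.19 events per 100 myr and 22
root lineages. One consequence of terminating events deserves note: the
*realized* number of loss events is below the naive Poisson expectation
λL/100, because lost lineages stop producing events. The suite therefore
checks the gain channel of the surviving root lineage (an exact Poisson
marking) against λL/100 and the loss channel against an analytic
survival recursion.

`simulate_codon_sequences()` evolves codons by candidate single-nucleotide
changes at rate $r_S/3$ per change slot (nine slots per codon), so the
synonymous substitution rate per synonymous site is exactly $r_S$.
Synonymous candidates are always accepted, nonsynonymous candidates with
probability $f$, and candidates creating stops are rejected in functional
regimes and accepted in pseudogene regimes. This acceptance-probability
process was chosen over a rate-matrix codon model because it *is* the
definition of $f$ that NG86 estimates, making recovery tests directly
interpretable. Root sequences are uniform over the 61 sense codons; the
transition/transversion ratio κ defaults to 1 (no bias) to keep NG86
unbiased, with κ > 1 available as a stress test. A regime switch on a
branch (offset from its rootward end) is inherited by all descendants.

What the simulators do **not** emulate: insertions/deletions and
alignment error, rate variation among sites and lineages, gene
conversion, codon-usage and GC bias, and selection regimes between
"functional with constant f" and "dead". Passing recovery tests
therefore show the estimators are correct *under the stated model*, not
that real CYP data meet that model.

Study-condition parameters not fixed by the reimplemented analysis were
chosen once: $r_S = 0.002$ substitutions per synonymous site per myr (a
typical vertebrate nuclear synonymous rate, giving mammal-scale
divergences on the fixture tree), and the per-scenario sequence lengths
and replicate counts used in the suite (2,000 codons / 100 replicates
for constraint recovery, 3,000 codons / 200 replicates for
pseudogenization-time recovery, 5,000 codons / 100 replicates for
duplication dating) — sizes at which the estimators' sampling error is
small relative to the tolerances being checked while the whole suite
stays desk-scale.

## Numerical choices and degenerate inputs

- Seeds: one master seed expands into per-stage streams through a
  counter scheme, so adding a stage does not shift other stages' draws;
  identical configurations give bit-identical outputs.
- Undefined quantities are explicit: zero comparable sites gives `NA`
  with a warning, dS = 0 makes dN/dS undefined, an all-absent ortholog
  group is skipped, an all-tied Mann–Whitney comparison returns p = 1
  with a degenerate flag.
- Strictness conventions: the gap rule is strictly greater than 20%; the
  conservation rule strictly greater than the threshold; family identity
  thresholds are ≥.
- NJ ties are resolved by `ape`'s deterministic agglomeration; trees are
  invariant to input label order up to that rule.
- All coordinates in site reports are 1-based original alignment
  positions, carried through filtering by the `column_map` attribute.

## Known limitations

- Dollo reconstruction cannot see events that cancel (a gain followed by
  loss of the same copy) or losses on branches that merely shift the
  apparent origin rootward; at low rates this affects a few percent of
  simulated histories, an identifiability limit of parsimony itself.
- The duplication-date headline uses the youngest lineage estimate, which
  is conservative and slightly downward-biased when all lineages are
  noisy.
- p-distances saturate on deep divergences; dating from alignments uses
  JC-corrected distances, but beyond ~0.75 differences per site no
  correction rescues the signal and distances are flagged instead.
- The packaged chronogram's individual node ages are approximate
  (rescaled to the stated total); analyses needing exact ages should
  supply their own dated tree.
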