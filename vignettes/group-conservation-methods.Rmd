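---
title: "Methods: group-specific conservation analysis of protein family alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-specific conservation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupcons)
```

## The problem

Protein families that share a fold often diverge in function: distinct
subfamilies (here, the motivating case is a family of structurally
homologous enzymes partitioned into four functional groups) keep different
residues at the positions that define their particular chemistry, while
only a handful of positions remain conserved across the whole family.
`groupcons` locates both kinds of site in a multiple sequence alignment:

* positions conserved family-wide (identity census and residue-class
  similarity census),
* positions conserved *within one group but not across the family*
  (the group-entropy scan, a suite of six column conservation estimators,
  and a simplified evolutionary trace),
* the phylogenetic scaffolding (bootstrap neighbor joining) used to define
  the groups in the first place.

All reports use 1-based alignment column indices, and `map_residue()`
translates an alignment index into the residue number of the ungapped
sequence, the notation in which sites are usually cited (e.g. "His25 at
alignment index 142").

## Conventions for counting residues

The alphabet is the 20 canonical amino acids. Input letters `B, Z, J, U,
O` are normalized to `X`, and `X` is treated as a gap throughout: every
statistic is defined over the canonical alphabet only. Gap characters
`.`, `~`, `-` are accepted on input and emitted as `-`.

Identity conservation of a column is the frequency of the modal residue
with *all* sequences in the denominator, gapped ones included. This is
the pinned convention for the census statistics; it makes heavily gapped
columns score low without a separate gap penalty. Ties between residues
break alphabetically, and rounding (nearest integer, ties away from
zero) is applied only at reporting — bins are computed on exact values.

The default similarity classes are aliphatic `{I, V, L, M}`, aromatic
`{F, W, Y}` and acid-amide `{D, N}`; they may overlap and are
user-configurable. Whether tyrosine belongs with the aromatics is a
judgment call in some families — the class list is an argument, not a
constant, precisely so users can test both conventions.

## The group-entropy scan

For group $g$ at column $j$, residue counts $n_{g,a}$ over the group's
non-gap members are smoothed with a background pseudocount of total mass
$\beta$ (default 1):

$$ f_{g,a} = \frac{n_{g,a} + \beta q_a}{N_g + \beta}. $$

**Group entropy** is the Kullback–Leibler divergence (base 2, bits) of
the group's distribution from the distribution $r$ of all sequences
*not* in the group, computed with the same smoothing:

$$ GE_g(j) = \sum_a f_{g,a} \log_2 \frac{f_{g,a}}{r_a} \ge 0, $$

zero exactly when the group looks like its complement. **Family
entropy** is the KL divergence of the family-wide distribution from the
background $q$ (default uniform): high FE means family-wide
conservation. A group-specific site is one with high GE and low FE.

Columns with gaps are not scored: if the gap fraction within the group
*or* within its complement exceeds `gap_max` (default 0.5; 0 gives the
strict any-gap-excludes rule), the column is marked `excluded` with `NA`
entropies — never a silent zero. Gaps never enter the frequency counts.

Selection offers two modes. `threshold` keeps columns with
`GE >= theta_g` (default 10 bits) and `FE <= theta_f` (default 3 bits).
Because the absolute scale of a smoothed KL divergence depends on group
sizes and $\beta$, the package also provides a `top_k` mode (top `k`
columns by GE among those with acceptable FE), which is the
recommendation when comparing groups of very different sizes: ranks are
far more stable than raw scores. For the same reason the package makes
no claim of reproducing any particular historical program's numeric
scale; the scan's accuracy is established by recovery of planted sites
in synthetic alignments (below).

With the default benchmark (four groups of 50, $\beta = 1$, uniform
$q$), a planted group-private residue at 95% within-group frequency
yields GE near 10 bits — the complement's smoothed frequency for that
residue is about $0.05/151$, so the dominant term alone contributes
$0.9 \log_2(0.9 \cdot 151 / 0.05) \approx 10$ — while background columns
stay below 1 bit. Family-conserved columns score FE ≈ 3.7 bits versus
under 1.6 for group-specific ones, which is what makes the
`theta_f = 3` ceiling effective.

## The estimator suite

Six per-column estimators are provided, all oriented so that *higher =
more conserved* and all in bits: Shannon entropy (score
$\log_2 20 - H$), relative entropy against a background, Jensen–Shannon
divergence against a background ($\lambda = 0.5$, bounded by 1 bit),
property entropy (Shannon entropy over a six-class disjoint
physicochemical partition, score $\log_2 6 - H$), von Neumann entropy
(score $\log_2 20 - S(\rho)$ for the density matrix
$\rho = DSD/\mathrm{tr}(DSD)$, $D = \mathrm{diag}(\sqrt{p})$), and mean
pairwise similarity (sum of pairs). Column frequencies receive a
pseudocount of $10^{-6}$ per residue (configurable) so logarithms stay
finite; with the identity similarity the von Neumann entropy reduces
exactly to the Shannon entropy, which the tests verify to $10^{-9}$.

Three backgrounds (BLOSUM62 marginals, Swiss-Prot composition, Pfam
composition) and seven BLOSUM matrices (35, 40, 45, 50, 62, 80, 100) are
bundled. Substitution scores are converted to a similarity for the von
Neumann and sum-of-pairs estimators by rescaling to $[0,1]$ and
normalizing to a unit diagonal ($S_{ab}/\sqrt{S_{aa}S_{bb}}$); this keeps
all six scores non-negative, so the gap adjustment — multiplying by the
column's non-gap fraction — is monotone: adding gaps can never raise an
adjusted score.

A column is "identified" by one run when it ranks in the top fraction
$\varphi$ (default 0.05) of adjusted scores; the cutoff count is
$\max(1, \lfloor \varphi n \rfloor)$ with ties broken by ascending
index. The *floor* matters: methods that ignore the background and
matrix produce identical rankings in all 21 sweeps, and a ceiling would
deterministically carry the same just-past-the-boundary column into
every run, polluting the consensus by construction. The consensus of a
method is the intersection of its identified sets over all 21
(background × matrix) combinations — methods insensitive to a parameter
still run per combination, so a column missed in even one run drops out.

## Evolutionary trace (simplified)

The trace cuts a UPGMA dendrogram of the sequences (average-linkage
clustering of the same JTT distances used for the NJ tree) at the
$P - 1$ greatest merge heights, giving $P$ subgroups; ties in the cut
are resolved deterministically by leaf-name order. A column is a trace
column when every subgroup is internally invariant; gaps break
invariance by default (an `ignore_gaps` mode drops them instead). A
trace column is group-specific when at least two subgroups disagree.
Family-invariant columns are trace columns at every $P$; finer
partitions can both add and remove trace columns, so no monotonicity in
$P$ is claimed.

The original trace formulation works on a similarity dendrogram from a
particular server whose partition numbering is not reconstructible;
this package's contract is the deterministic UPGMA-cut definition above.

## Phylogenetics

Columns with a gap fraction above `gap_fraction_max` (default 0.8) are
trimmed first; the trimmed-to-original index map is returned so sites
can be reported in original coordinates. Pairwise distances are
maximum-likelihood estimates under the JTT model (via `phangorn`'s ML
machinery, the same model as PHYLIP's `protdist` default), capped at
`d_max = 10` substitutions/site with a warning on saturated pairs; gaps
are treated as missing data. Trees come from Saitou–Nei neighbor
joining (`ape::nj`), which is exact on additive matrices — verified on
random trees to $10^{-9}$ in both topology and path length. Negative
branch lengths (possible only on non-additive input) are clamped to
zero; the clamp does not redistribute the deficit to the sister edge,
a deliberate simplification that leaves additive reconstructions
untouched.

The bootstrap resamples columns with replacement; replicate $i$ uses
seed `seed + i`, so any single replicate can be regenerated in
isolation. The consensus is *strict* majority rule: a bipartition is
retained iff it appears in more than 50% of replicates (a split in
exactly half is dropped), and each retained split is annotated with its
support as $100 \times$ frequency. Supports are counted by canonical
bipartition keys, so differently rooted representations of the same
unrooted tree count as the same split.

## Motif patterns

Patterns use the dialect of published motif tables: literal residues,
`[...]` alternation sets, and `x` for "any residue". Matching is exact,
reports every (possibly overlapping) occurrence against the *degapped*
sequence, and a wildcard never matches a gap. `motif_presence()` maps
the first match of each group back to alignment-index coordinates —
which is why a motif's alignment span can be much longer than its
pattern length when indels interrupt it — and flags motifs found in
exactly one group as group-exclusive. Probabilistic scoring (E-values,
mismatch tolerance) is out of scope; the patterns are deterministic.

## The synthetic benchmark

`generate_alignment()` builds alignments with known ground truth. Per
column: *family-conserved* — one residue at frequency $c$ in every
sequence; *group-specific* — residue $r_g$ at frequency $c$ within its
group, other groups drawing from a background with $r_g$ excluded
(a `soft_exclusion` leakage probability is available for harder
benchmarks); *class-conserved* — uniform draws within a residue class at
frequency $c$; *background* — i.i.d. from a column-specific
Dirichlet($\alpha = 0.5$) distribution. Gaps are i.i.d. per cell
(default 5%), with optional contiguous group-private indel blocks.

The default configuration — 4 groups × 50 sequences, 500 columns, 10
family-conserved columns, 10 group-specific columns per group, 5 columns
per similarity class, $c = 0.95$ — is the package's standard benchmark
and stays fixed across tests. Randomness derives from one master seed,
with per-column substreams (a fixed affine function of seed and column
index) so individual columns are reproducible in isolation.

What the generator does *not* emulate: phylogenetic correlation among
sequences (rows are exchangeable within a group), realistic indel
processes, or alignment error. Passing the recovery benchmarks therefore
demonstrates correctness of the statistics under clean group structure,
not robustness to tree-shaped confounding — on real families, closely
related sequences inflate within-group conservation estimates, and
users should weight or subsample dense clades. Distances for the
phylogeny tests are instead simulated directly from trees under the JTT
model, which covers the correlated case for that stage.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: the 200-sequence ×
500-column benchmark for the group-entropy scan; a 105-column alignment
(5 invariant columns, 100 background) for estimator-consensus purity;
200 random 5–8 leaf trees for NJ exactness; 250 bootstrap replicates of
a 12-taxon, 300-site JTT simulation for consensus supports; one
10,000-site pair at $t = 0.5$ for JTT distance recovery; and 1,000
random pattern/sequence cases against a brute-force regex oracle for
motif scanning. These sizes were chosen so each property is measured
with comfortable statistical margin while a full run stays in the tens
of seconds.

Tolerances: analytic identities are asserted at $10^{-9}$; the JTT
recovery at $\pm 0.05$ substitutions/site; the group-entropy benchmark
demands AUC ≥ 0.99 and full top-15 recovery. Degenerate inputs are
explicit errors (all-gap columns in the census report 0% with no modal
residue; sum-of-pairs with fewer than two residues is `NA`; a column
excluded by the gap rule is flagged, not zeroed).

## Known limitations

* The group-entropy scale depends on $\beta$, group sizes and the
  background; compare ranks, not raw bits, across datasets.
* The estimator consensus depends on the identification fraction
  $\varphi$; there is no universally correct cutoff, and the default
  0.05 should be read as "the top twentieth of columns", not a
  significance level.
* The trace and UPGMA stages assume the JTT distances are meaningful,
  which degrades for alignments with under ~50 comparable sites per
  pair.
* MSF checksums are parsed but not verified.
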