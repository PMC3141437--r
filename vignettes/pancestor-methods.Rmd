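---
title: "Models and conventions behind pancestor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind pancestor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancestor)
```

pancestor analyses a collection of sequenced genomes through a single
central object: an ortholog-group × genome matrix of gene copy counts with
functional and pseudogene copies kept apart. This vignette documents the
models, the conventions chosen where the methodology literature leaves
choices open, the synthetic-data generator and its defaults, and the known
limitations. Nothing here reports an empirical result that the test suite
or the acceptance script does not itself compute.

## The data model

An `OrthologSet` extends `SummarizedExperiment` with two integer assays,
`functional` and `pseudo`. A pseudogene is *presence without function*:
evidence that the lineage once carried the gene, but no working copy.
Because different questions need different notions of presence, every
presence-based operation takes a `presenceMode`:

* `any_copy` — a pseudogene still counts as presence. This is the default
  for core-set membership and ancestral presence reconstruction, where the
  question is whether the family ever resided in the genome. A core group
  that survives only as a pseudogene somewhere is *retained* but annotated
  as a functional loss, so erosion is visible without shrinking the core.
* `functional_only` — only working copies count. This is the right mode
  when asking what a genome can currently do (functional distributions,
  per-genome missing-gene reports).

Phenotype signatures use a hybrid convention: on the flag-positive side
presence is `any_copy` (a positive genome that has pseudogenized a
signature gene still carries the historical signal, and is reported in a
`pseudo_only` column), while flag-negative genomes must lack the group
entirely, functional or not. This is the only way a signature set can
simultaneously be exclusive to the phenotype and still exhibit
pseudogenized members in an eroding positive genome — the situation that
motivates reporting the two facts together.

Genome metadata carries a hard invariant: `coding_bp + noncoding_bp +
pseudogene_bp == genome_size_bp`, enforced at parse time and in the class
validity method. Clade labels are one of `clade1`, `clade2`, `outgroup`,
`unassigned`; outgroup genomes participate in cores (which span the whole
collection) but never in clade signatures or clade rate tests.

## Core sets and signatures

For a relaxed-core specification with threshold $k$, a group is a member
iff the number of *finished* genomes lacking it is $\le k$; draft genomes
are either wildcards (presence and absence both allowed) or required to
contain the group. Draft assemblies can miss genes for technical reasons,
which is why absence is only ever counted against finished genomes. All
operations are deterministic set algebra; the lattice
strict ⊆ RCF ⊆ RCF1 ⊆ RCF2 ⊆ RCF3 and the single-copy subset relation are
verified property-style on random matrices against exhaustive per-group
scans.

## Paralog profile and COG assignment

A group is *paralogous* in a genome when its copy count there is ≥ 2; the
generator produces only tip-specific (in-paralog) duplicates, matching
what OrthoMCL-style clustering labels as recent duplications. The
"proportion of groups with paralogs" uses, by default, the number of
groups with ≥ 1 copy in that genome as denominator (a per-genome quantity
that is comparable across genomes of very different sizes); a matrix-wide
denominator is available via `denominator = "matrix"`.

COG categories are assigned per group by plurality among member best hits
after discarding hits with e-value ≥ 0.01. Members without a passing hit
form a pseudo-category "none": if "none" wins the plurality the most
abundant real category is used instead, and ties among real categories
break lexicographically — an explicit, documented convention, since any
fixed tie-break is equally defensible and reproducibility matters more
than the choice. Functional distributions exclude pseudogene copies by
default and always carry an `unassigned` bin so rows sum to exactly 1.
Transposase-heavy families can be carved into a `t` subcolumn that remains
counted inside category L; the transposase group list is a configuration
input because COG identifiers, not category letters, define it.

## The composition test

The test asks whether non-coding nucleotides are spread evenly over
genomes. The statistic is Pearson's $X^2 = \sum (O-E)^2/E$ on a 2 × G
table (coding vs non-coding bp per genome, pseudogene bp merged into the
non-coding row by default — eroded regions no longer code). The null
distribution is sampled by drawing $B$ multinomial tables of the same
grand total with cell probabilities $E/n$, i.e. under independence of
nucleotide class and genome; the p-value uses the add-one convention
$p = (1 + \#\{X^2_b \ge X^2\})/(B+1)$, so the smallest attainable value at
$B = 2000$ is $1/2001 < 0.001$ and $p = 0$ is impossible. Multinomial
resampling (rather than conditioning on both margins) was chosen because
the genome "margin" is not an experimental constraint; the Monte-Carlo
p-value converges to the asymptotic $\chi^2$ tail, which the tests check
on a small table. Per-genome calls come from the non-coding Pearson
residual with a ±2 threshold (configurable).

One caveat is inherent to the data: with tables in raw base pairs the cell
counts are in the millions and the test has essentially unlimited power,
so *any* heterogeneity is significant. The statistic scales linearly with
the counts (documented and tested), and analyses that want an
effect-size-like reading can divide the table into kbp units first; the
default stays raw bp so that the qualitative conclusion does not depend on
a rescaling choice.

## Ancestral reconstruction

**Fitch parsimony** runs the classical bottom-up pass (intersection where
non-empty, else union, each union costing one change), generalised to
polytomies by iterated pairwise combination in child order. The reported
cost is this union count. Node state sets are then refined top-down to the
exact set of states attainable in at least one most-parsimonious
reconstruction, computed with a unit-cost dynamic program: on binary trees
this is exact and agrees with the Fitch count; on polytomies the iterated
pass can overcount changes relative to the true minimum, which is why the
package's reconstruction pipelines operate on binary trees. A branch is
flagged *equivocal* when either endpoint admits more than one optimal
state — the situation drawn as bi-coloured branches on trait maps.

The root gene-content interval counts, over all groups, those whose root
set is exactly {present} (the minimum) and adds those with root set
{absent, present} (the maximum). Ambiguous groups count toward the maximum
only: the minimum is the content defensible under *every* optimal
reconstruction, the maximum under *some* optimal reconstruction.

**Sankoff parsimony** uses cost $|i-j|$ between parent and child copy
numbers — one duplication or one loss per step. The state alphabet is
0..max(observed copies); under a linear cost no optimal reconstruction
can use a state outside the observed range (any assignment above the
maximum could be lowered to the maximum without increasing any edge cost,
and symmetrically below the minimum), so the truncation is lossless.
Summing per-group root minima and maxima gives the copy-number-based
content interval.

**Squared-change parsimony** minimises $\sum_e (x_{parent}-x_{child})^2 /
w_e$ with $w_e = 1$ (default) or the branch length. The objective is
strictly convex, so instead of iterating, the package solves the zero-
gradient linear system (the tree Laplacian restricted to internal nodes)
exactly; tests compare against a generic numerical optimizer and probe
local optimality with random perturbations. Unweighted is the default
because reconstructions in the comparative literature frequently ignore
branch lengths for this optimisation and the choice is not always
reported; both modes are exposed and the weighted root on a two-tip tree
equals the inverse-branch-length weighted mean (the Brownian/GLS root),
which is tested. Weighted mode refuses zero-length branches by name
rather than dividing by zero.

## Independent contrasts and rate tests

`picContrasts` implements the standard post-order recursion: contrast
$x_a - x_b$, standard deviation $\sqrt{v_a + v_b}$, weighted-average
working value, and branch-length correction $v_a v_b/(v_a+v_b)$. It
requires a binary rooted tree with strictly positive branch lengths and
tells the user to resolve polytomies rather than silently pruning.

Clade assignment of a contrast is strict: a contrast belongs to a clade
iff *every* descendant tip of its node carries that label; anything
spanning clades or touching outgroup/unassigned tips is `excluded`. This
generalises the usual practice of dropping the single basal between-clade
contrast to collections with outgroups.

The clade rate test is a two-tailed Wilcoxon rank-sum on the absolute
standardized contrasts: under Brownian motion, contrast magnitudes scale
with $\sigma$, so a location shift in magnitudes is a rate difference.
The exact distribution is enumerated when both groups have ≤ 12 contrasts
and no ties; otherwise the normal approximation with tie and continuity
corrections is used.

The through-origin regression first positivizes pairs (x < 0 flips both
signs, leaving the fitted line invariant), then uses slope
$\sum xy/\sum x^2$, $r = \sum xy/\sqrt{\sum x^2 \sum y^2}$ and
$t = r\sqrt{(n-1)/(1-r^2)}$ on $n-1$ degrees of freedom — $n-1$, not
$n-2$, because the no-intercept model estimates one parameter. Traits are
not log-transformed by default; pass transformed values if a
multiplicative scale is wanted.

## The synthetic-data generator

The generator emulates the structure of a ~58-genome collection with two
basal clades, one heavily pseudogenized tip, and phenotypes evolving on
the tree. Defaults (all per unit branch length where applicable):

| parameter | default | rationale |
|---|---|---|
| `n_tips` | 58 | the scale of a phylum-wide collection |
| `birth_rate` | 1 | Yule tree, expected depth ≈ ln n |
| `n_families` | 2000 | desk-scale stand-in for ~16k groups |
| `p0` | 0.3 | root carries a minority of extant families |
| `gain_rate`, `loss_rate` | 0.1, 0.15 | mild net loss; see below |
| `dup_rate` | 0.3 | terminal-branch copy birth, gives realistic in-paralog loads |
| `gene_length_bp` | 1000 | typical bacterial CDS |
| `noncoding_mean` | 0.15 | typical non-coding fraction |
| `pseudo_fraction` | 0.64 | the eroding-tip scenario |
| `draft_fraction` | 1/3 | roughly the finished/draft split of real collections |
| `cog_error` | 0.1 | enough corruption to exercise the majority rule |

Presence evolves by a two-state continuous-time chain with the closed-form
transition probabilities exposed as `gainLossTransition` (also the
analytic oracle in the tests). The gain/loss defaults were fixed by a
design consideration rather than biological calibration: parsimony-based
root reconstruction is only consistent when the process is not strongly
loss-biased — under heavy net loss, families surviving in few, clustered
tips are parsimony-reconstructed as root-absent and the interval
systematically undershoots. The defaults sit in the regime where the
method's assumptions hold, which is what makes ground-truth validation
meaningful; strongly loss-biased regimes remain available through the
configuration, with the caveat that the parsimony interval is then biased
downward. Genome erosion is instead exercised explicitly through the
pseudogenization target.

Duplications attach to terminal branches only, so every simulated paralog
is an in-paralog — matching what the clustering-based definition of
paralogy in the input data can actually see. Consequences: internal-node
truth for copy numbers is 0/1, and copy-number reconstruction on simulated
data is informative about presence, not about ancestral amplification.

What the generator does *not* emulate: horizontal transfer (gains are
i.i.d. per family), rate heterogeneity across families (optional gamma
multipliers were considered and left out of the defaults), correlated
gain/loss between families, genome rearrangement, and sequence-level
evolution. Passing tests therefore demonstrate algorithmic correctness
and calibration under the stated models, not robustness to these
real-data violations.

Determinism: every generator is a pure function of its inputs and seed;
emitted files re-parsed through the package reproduce the in-memory
objects exactly, and the pipeline report is byte-identical across runs
with the same inputs and seed.

## Validation problem sizes

The acceptance checks use: exhaustive-enumeration oracles on 200 random
instances (trees ≤ 7 tips for Fitch, ≤ 6 for Sankoff, 200-group matrices
for the set algebra); 50 random 8-tip trees against a numerical convex
optimizer (agreement to 1e-6); 2000 Brownian replicates on a fixed 16-tip
Yule tree for contrast calibration and 500 replicates on a 32-tip tree for
slope recovery; a balanced 128-tip tree for the rate test's size (1000
replicates) and power (200 replicates at a 4:1 variance ratio) — the
half-normal calculation $P(|X_1|>|X_2|) = (2/\pi)\arctan 2 \approx 0.70$
shows ~63 contrasts per clade are needed for power above 90%, which fixed
the tree size a priori; 100 gain/loss replicates of 500 families on
58-tip trees for interval coverage; and 1000 random matrices for the
core-set lattice. These sizes are the package's chosen trade-off between
statistical resolution and a test suite that runs in minutes.

## Known limitations

* Fitch on polytomies (iterated pairwise combination) approximates the
  minimum change count from above; use binary trees for reconstruction.
* The copy-number Sankoff interval inherits parsimony's insensitivity to
  branch lengths; it is a combinatorial, not probabilistic, statement.
* The composition test's power at bp resolution makes significance nearly
  automatic; interpret the residuals, not the p-value alone.
* Signature sets are presence/absence logic; they cannot see dosage,
  regulation, or convergent sequence-level changes.
* The clade rate test compares magnitudes of standardized contrasts and
  assumes the within-clade Brownian model is otherwise correct; branch
  length transformations (Grafen, Pagel's λ) are out of scope.
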