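---
title: "Codon-pairing phylogenomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-pairing phylogenomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonpair)
library(ape)
```

## The biological model

When two codons translated by the same tRNA sit close together on an mRNA,
the ribosome can reuse the tRNA before it diffuses away, which measurably
increases translational efficiency. "Close together" is modelled as a sliding
window of `w` codons, the ribosome footprint. Footprint estimates range from
about 5 to 15 codons, with 28 nucleotides (about nine codons) the commonly
accepted value, so `window = 9` is the default and 2–11 is the usual sweep.

Three flavours of pairing are detected per gene:

* **identical** — two occurrences of the same codon within the window; the
  codon is recorded;
* **co-tRNA** — two *non-identical* codons encoding the same amino acid
  within the window; the residue is recorded (two identical codons alone
  never qualify);
* **combined** — any two synonymous codons within the window; the residue is
  recorded. Combined pairing equals the union of co-tRNA residues with the
  image of the identical codons through the genetic code, and the package
  tests enforce that nesting as an invariant.

Encoding is deliberately binary: a symbol either pairs somewhere in the gene
or it does not, regardless of multiplicity. This makes the signal robust to
gene length, and the `length_correlations()` diagnostic quantifies exactly
that: the raw count of pairing *events* scales almost perfectly with gene
length while the number of distinct paired symbols does not track it the
same way.

"Within a window of `w` codons" is implemented as pairwise codon-position
distance `j - i <= w - 1`, which is provably equivalent to scanning every
contiguous `w`-codon window, runs in `O(n w)`, and handles genes shorter than
the window with no special casing. Codons containing ambiguity letters (N
etc.) can never pair but keep their position, so they do not shrink the
distance between flanking codons; stop codons are likewise inert. The test
suite checks the implementation against a literal window-scan oracle on a
thousand random genes.

## The alignment-free distance

Each gene's pairing set, alphabetized into a tuple, is a *motif*; the set of
distinct nonempty motifs over all genes of a species is its *profile*. For
profiles `a` and `b`,

```
Dist(A, B) = 1 - |a ∩ b| / min(|a|, |b|)
```

with one guard: when the smaller profile does not exceed 5% of the larger
(`min/max <= 0.05`, inclusive because the rule is phrased as "does not
exceed"), the pair is assigned the maximum distance 1.0. Without the guard a
two-gene genome sharing one motif with a 20 000-gene genome would score a
misleading distance of 0.5. Two empty profiles also take the guard path —
absence of any motif is no evidence of similarity. Note the quantity is
containment-normalized and is *not* a metric; no triangle inequality is
asserted anywhere. Distances of exactly 1.0 are saturated: the pair carries
no ranking information, which is what `saturation_profile()` quantifies
against a reference tree.

Trees are recovered from the matrix by standard Saitou–Nei neighbor joining
(via **ape**), with negative branch lengths clamped to zero. NJ is the
default and only distance method; the matrix is also exported in square
PHYLIP format for external tools.

## The parsimony character matrix

Each (ortholog, symbol) combination becomes a column scored `1` (pairs), `0`
(present but does not pair) or `?` (ortholog call unavailable). Filtering
follows a fixed linear order:

1. **informative columns** — ortholog called in at least 4 species, symbol
   paired in at least one species and unpaired in at least one;
2. **species coverage** — species with fewer than 5% non-`?` cells are
   dropped;
3. **group viability** — if fewer than 5% of the input species survive, the
   group is declared not analyzable (a dedicated condition class and CLI exit
   status 3, distinct from I/O failure).

Columns are *not* re-filtered after species removal — the flow is a single
pass; `--refilter` opts into one extra pass for users who want closure. The
stated informative rule admits autapomorphic columns (one taxon per state),
which are not strictly parsimony-informative in the classical sense;
`--strict-informative` (`strict = TRUE`) opts into the two-taxa-per-state
rule instead. The default follows the stated rule. The matrix is written as
a TNT `xread` block plus a key file (ordered `ortholog<TAB>symbol` list) and
an optional taxon-name map so sanitized names remain reversible; tree search
itself is TNT's job and out of scope here.

## Tree evaluation

* `edge_overlap()` prunes both trees to their shared leaves and counts shared
  non-trivial bipartitions, reporting both directional percentages and their
  mean. The mean is the headline number; a star tree has zero bipartitions
  and its directional percentage is an `NA` sentinel rather than a fake 0 or
  100. With several equally parsimonious source trees,
  `edge_overlap_avg()` averages the comparisons.
* `fitch_length()` / `retention_index()`: parsimony steps come from a Sankoff
  dynamic program with unit costs, which is exact on polytomies and treats
  `?` as `{0, 1}`. For a binary character, the maximum steps `g` use the
  closed form `min(#0, #1)` over scored taxa (the star-tree bound) and the
  minimum `m` is 1 when both states occur. `RI = (g - s)/(g - m)`; characters
  with `g <= m` have no defined RI and are skipped from the per-character
  mean. Whether "average RI" should be the per-character mean or the pooled
  ensemble value is ambiguous in the literature, so both are always reported;
  the per-character mean is the default headline.
* `ri_permutation_test()` shuffles leaf labels only (topology and branch
  lengths fixed), recomputes the mean RI each time, and reports
  `(1 + #{null >= observed}) / (1 + n_perm)`. The seed is mandatory and the
  run is bit-reproducible.

## The simulator

`simulation_config()` + `evolve_states()` evolve one binary state per
(ortholog, symbol) down a known tree: Bernoulli(`root_pairing_prob`) at the
root, then a symmetric two-state Markov chain in which a state flips across a
branch of length `l` with probability `(1 - exp(-2 r l)) / 2`. This is the
exact transition probability of the continuous-time symmetric chain, so
disagreement between distant species saturates at 1/2 rather than oscillating
— the property all downstream monotonicity checks rely on.

`realize_cds()` turns a target symbol set into an actual coding sequence by
construction: each target symbol becomes a block of two adjacent codons
(identical duplicates, or two distinct synonymous codons for co-tRNA),
blocks are separated by `window - 1` filler codons, and fillers rotate
through a pool that is disjoint from the target symbols (disjoint synonymous
families in residue modes) with rotation period at least the window, so no
unintended pairing can arise. The defining test of the module is round-trip
exactness: `gene_pairing_set(realize_cds(S)) == S` for random targets in all
modes. Biological realism of the filler sequence is explicitly not a goal —
the simulator exists to give every pipeline stage a ground truth. Residues
with a single codon (M, W in the standard code) can never co-tRNA pair, so
the simulator excludes them from co-tRNA targets and `realize_cds()` refuses
them.

### Simulation defaults and what they emulate

The default study condition used by the acceptance checks is a 16-species
random tree with branch lengths uniform on [0.1, 1] (bounded away from zero
because a zero-length edge is unrecoverable by any method), 500 orthologs,
6 candidate symbols per ortholog, combined mode at window 9. A motif of `k`
symbols survives a path of length `t` intact with probability about
`exp(-2 k r t)`, so with `k = 6` and leaf-to-leaf paths of a few units the
flip rate `r` sets three qualitatively distinct regimes:

* `r = 0.05` — low noise: even the deepest pairs stay unsaturated and NJ
  recovers the generating topology almost perfectly;
* `r = 0.3` — partial saturation: deep structure degrades first;
* `r = 2` — near-total saturation: recovery collapses toward chance.

Topology-recovery and retention-index checks run at these three rates and
assert monotone degradation. The sizes (16 species, 500 orthologs, 200
permutations, 1000-gene oracle corpora) were chosen so the whole suite
completes in a few minutes on a single core while keeping the stochastic
assertions far from their thresholds.

What the simulation does *not* emulate: real codon-usage distributions,
selection on pairing, correlated evolution among symbols of one gene,
annotation noise in ortholog calls, and genome-scale profile sizes. Passing
tests therefore demonstrate correctness of the machinery and sensitivity of
the statistics under a known signal model — not that codon pairing carries
phylogenetic signal in any particular real clade.

## Numerical and degenerate-input choices

* Ratio guard fires on `<=` (inclusive), matching the "does not exceed"
  phrasing; the boundary case `min/max = 0.05` snaps to 1.0.
* Longest-isoform ties keep the record appearing first in file order —
  deterministic and idempotent.
* Internal stop codons drop the gene by default (mirroring the removal of
  annotation exceptions); `internal_stop = "keep"` retains the gene, and stop
  codons can never pair either way. The drop-keyword list for annotated
  exceptions defaults to `c("exception", "partial")` and is configurable,
  since header vocabularies vary by pipeline.
* NJ tie-breaking is delegated to the deterministic **ape** implementation;
  no RNG is ever consulted outside the simulator and the permutation test,
  and both require explicit seeds.
* An all-`?` character costs 0 parsimony steps; an empty matrix or an empty
  motif census is an explicit error, not a silent zero.
* `R²` is reported as `NA` (undefined sentinel) when either variable has zero
  variance.

## Known limitations

* Co-tRNA detection treats all synonymous codons as candidates; actual tRNA
  gene copy numbers and wobble rules are not modelled.
* Ortholog matching is exact string equality of the configured key; there is
  no sequence-based orthology inference.
* The ensemble-vs-mean RI ambiguity and the directional-vs-mean overlap
  ambiguity are resolved by reporting all variants rather than guessing a
  single convention.
* TNT is exported, never executed; Fitch scoring here evaluates fixed trees
  and does not search.
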