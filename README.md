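# codonpair

Phylogenetic signal from codon pairing bias.

When two codons that encode the same amino acid sit within one ribosome
footprint of each other, the ribosome can recharge and reuse the same tRNA
before it diffuses away ("codon pairing"), boosting translational efficiency.
Which codons pair in which genes turns out to be conserved enough to track
species relationships. `codonpair` detects **identical** (same codon),
**co-tRNA** (different codons, same amino acid) and **combined** pairing in a
sliding window of *w* codons (default 9 ≈ the 28-nt ribosome footprint,
sweep 2–11), encodes it binarily, and exploits it two ways:

* **Alignment-free**: each gene's alphabetized pairing set is a *motif*; a
  species' profile is its set of distinct motifs; the pairwise distance is

  ```
  Dist(A, B) = 1 − |a ∩ b| / min(|a|, |b|)
  ```

  snapped to the maximum 1.0 whenever the smaller profile does not exceed 5%
  of the larger (small-genome guard). Neighbor joining on the matrix gives
  the tree.
* **Parsimony**: a species × (ortholog, codon-or-residue) matrix over
  `{0, 1, ?}`, filtered to informative columns (ortholog in ≥ 4 species, both
  states present), species with ≥ 5% character coverage, and a ≥ 5%
  surviving-species viability rule, exported as a TNT `xread` block plus an
  ordered key file.

Tree evaluation ships alongside: percent bipartition (edge) overlap between
unrooted trees with polytomy support, retention index from exact Fitch
scoring (`RI = (g − s)/(g − m)`) with a leaf-label permutation null, and
distance-saturation diagnostics. A seeded simulator evolves binary pairing
states along a known tree (symmetric two-state Markov chain) and realizes
them as coding sequences whose pairing sets recover the states exactly, so
the whole pipeline is testable end to end.

Inputs are per-species CDS FASTA files (one file per species, one record per
gene, ortholog key parsed from the header) plus reference trees in newick;
any NCBI genetic-code table is supported.

## Worked example

Simulate eight species along a known tree, recover it alignment-free, and
test the parsimony signal:

```r
library(codonpair)
library(ape)

code <- genetic_code(1)
set.seed(1)
tr  <- rtree(8)
cfg <- simulation_config(tr, n_orthologs = 100, flip_rate = 0.1, seed = 7)
sets <- realize_sequences(evolve_states(cfg), cfg)

profiles <- lapply(sets, build_profile, mode = "combined", window = 9, code = code)
dm <- distance_matrix(profiles)
nj <- neighbor_joining(dm)
edge_overlap(nj, tr)
#> Edge overlap: 5 shared bipartitions (source 5, reference 5); mean 100.0%

m <- filter_species_coverage(filter_informative(
  assemble_raw_matrix(sets, "combined", 9, code)))
ri_permutation_test(tr, m, n_perm = 50, seed = 3)
#> RI permutation test: observed mean RI 0.7989 vs null mean 0.1555 (50 perms), p = 0.01961
```

The recovered NJ tree shares all five internal edges with the generating
tree, and the observed mean retention index (0.80) sits far above every
label-permutation null (mean 0.16), i.e. the simulated pairing states carry
strong phylogenetic signal — exactly what the binary-character model built
into the simulator should produce at a low flip rate.

A shell entry point wrapping the same functions lives at
`inst/cli/codonpair.R`:

```sh
Rscript inst/cli/codonpair.R matrix -id fasta_dir/ -o out.tnt -oc out.keys \
    --mode combined --window 9
Rscript inst/cli/codonpair.R af --input-dir fasta_dir/ \
    --out-matrix dist.phylip --out-tree nj.nwk
```

Exit codes: 0 success, 2 usage error, 3 group skipped by the 5% species rule,
4 data/I-O error.

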