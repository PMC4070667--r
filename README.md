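# otnsa — alignment-free 16S amplicon analysis with orthologous tri-nucleotides

`otnsa` analyzes 16S rRNA amplicon read sets without multiple sequence
alignment. It is aimed at microbial ecologists working on communities
dominated by uncharacterized organisms, where alignment against references
is slow and silently error-prone. The package implements a *de novo*
semi-alignment: each read is reduced to the trinucleotides it contains and
the positional region in which each occurs. A trinucleotide found in the
same region of different reads is an **orthologous tri-nucleotide (OTN)**
— one shared, binary evolutionary character.

The core quantities:

* **OTN matrix.** Positional trinucleotide histograms are built over the
  pooled, depth-normalized reads; peaks are detected per trinucleotide by a
  prominence scan and converted to half-open bins at peak midpoints. A read
  scores 1 for OTN *(t, bin)* if trinucleotide *t* occurs in that bin. Any
  OTN that occurs **twice in one bin of one read** — the signature of a
  homopolymer tract, the dominant pyrosequencing indel error source — is
  discharged globally.
* **Generation distance.** Shared OTNs decay exponentially with time under
  a constant per-generation mutation probability *r*, so the separation of
  two profiles *A*, *B* in generations is

  ```
  gen = [ln(shared) − ln(total)] / ln(1 − r),
  shared = 2|A ∩ B|,  total = |A| + |B|,  r = 0.5e−9 by default
  ```

  Trees are Saitou–Nei neighbor joining on these distances, with support
  from bootstrap resampling of OTN columns.
* **Diversity.** Unique OTN patterns act as OTUs (100% identity;
  singletons excluded as likely errors/chimeras). Alpha diversity is
  Shannon–Wiener *H* (nats) and inverse Simpson *D*; groups are compared
  with an exact, fully enumerated Mann–Whitney U test; beta diversity uses
  chord distances; ordination is centered PCA retaining components to 50%
  of variance.

A synthetic amplicon simulator with known tree structure, substitution
model and homopolymer-indel errors (`simulate_taxa()`, `emit_reads()`)
gives every stage a ground truth.

## Worked example

Simulate a six-taxon community on a known two-clade tree, run the pipeline,
and recover the tree:

```r
library(otnsa)

tr  <- ape::read.tree(text =
  "(((A:1e8,B:1e8):1e8,C:2e8):4e8,((D:1e8,E:1e8):1e8,F:2e8):4e8);")
cfg <- sim_config(tree = tr, insert_length = 460, reads_per_taxon = 8,
                  seed = 29)
fx    <- end_to_end_fixture(cfg)
clean <- preprocess_reads(fx$reads, filter_config(), depth = "min")
fit   <- otn_semialign(clean)
fit
#> OTN semi-alignment fit
#>   reads: 48   positions: 458
#>   peaks: 1345   OTNs kept: 1327   discharged: 18
#>   patterns (OTUs): 6 across 6 sample(s)
```

48 error-free reads collapse to exactly one OTN pattern per taxon; 18 OTNs
were discharged by the homopolymer multiplicity rule. Distances and a
bootstrapped tree:

```r
generation_dist(fit)
#> <gen_dist> 6 taxa; max distance 3.385e+09 generations (rate 5e-10)

pm <- fit$patterns$patterns
rownames(pm) <- apply(fit$patterns$counts, 1,
                      function(r) colnames(fit$patterns$counts)[r > 0])
ape::write.tree(bootstrap_support(pm, replicates = 100, seed = 1))
#> (D:266597834.9,E:339024073,(((A:315099416.1,B:418601127.7)100:415587210.9,
#>  C:706237323.4)100:1792189579,F:698960780.4)100:362225740.6);
```

The recovered topology matches the simulated tree — (A,B) with C against
(D,E) with F — with 100% support on every internal edge, and the distances
are on the simulated generation scale (maximum ≈ 3.4×10⁹).

Group comparison on published-style alpha-diversity triplicates (the
package ships the six soil-library index values under
`inst/extdata/soil_alpha_diversity.tsv`):

```r
tab  <- read.delim(system.file("extdata", "soil_alpha_diversity.tsv",
                               package = "otnsa"))
worm <- tab$earthworm == "yes"
mann_whitney_exact(tab$otn_shannon[!worm], tab$otn_shannon[worm],
                   alternative = "greater")$p.value
#> [1] 0.05
```

For triplicates, 0.05 = 1/C(6,3) is the smallest attainable one-sided
p-value: the groups separate completely.

A command-line front end over the same functions lives in
`inst/cli/otn.R` (subcommands `simulate`, `preprocess`, `histogram`,
`peaks`, `otn`, `distance`, `tree`, `diversity`, `pca`, all exchanging
plain TSV/FASTA/Newick artifacts).

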