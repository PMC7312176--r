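# pcnv

Alignment-free DNA sequence comparison with **positional correlation natural
vectors** (PCNV), for people who need whole-genome phylogenies or viral
genotype assignments without multiple sequence alignment — e.g. hundreds of
HCV/HBV/dengue/HPV genomes, or bacterial genomes too large to align.

## The descriptor

Each sequence of length *N* is mapped to an 18-dimensional vector. For each
nucleotide α ∈ {A, C, G, T} with occurrence positions
p<sub>α1</sub> < … < p<sub>αn<sub>α</sub></sub> (1-based, p<sub>α0</sub> = 0),
the *positional distribution* is the step function

    U_α(i) = p_αj / (p_α(j+1) − p_αj)      for p_αj ≤ i < p_α(j+1)
    U_α(i) = p_αn / (N − (p_αn − 1))       for p_αn ≤ i ≤ N

From it come the mean κ_α = Σ<sub>i</sub> U_α(i) / n_α (equal to the mean
occurrence position), the variance D²_α = cov(α, α), and the pairwise
covariances

    cov(α, β) = Σ_i (U_α(i) − Ū_α)(U_β(i) − Ū_β) / (n_α · n_β)

(note the denominator n_α·n_β, not N). The PCNV is

    (n_A, n_C, n_G, n_T, κ_A…κ_T, D²_A…D²_T,
     cov(A,C), cov(A,G), cov(A,T), cov(C,G), cov(C,T), cov(G,T))

Sequences are compared by Euclidean distance between vectors; trees are
built by neighbor joining; genotypes are predicted by leave-one-out
one-nearest-neighbor with per-class sensitivity, specificity and accuracy.

## Worked example

The 9-nt sequence `ACTGGCAAT`:

```r
library(pcnv)
v <- compute_pcnv("ACTGGCAAT")
round(v, 4)
#>      nA      nC      nG      nT      kA      kC      kG      kT     D2A     D2C
#>  3.0000  2.0000  2.0000  2.0000  5.3333  4.0000  4.5000  6.0000  5.8580  0.7222
#>     D2G     D2T   covAC   covAG   covAT   covCG   covCT   covGT
#>  3.0000 16.6250  1.4769  0.0000  3.4167  0.1250  1.4583  0.2500
```

Reading the output: A occurs 3 times (`nA`) at mean position 16/3 ≈ 5.33
(`kA`); T's occurrences (positions 3 and 9) are the most spread out
(`D2T` = 16.625); and the positional covariance of A and C is
`covAC` = 1.4769 — the standard hand-checked value for this sequence.

An end-to-end run on a simulated genotyping panel (4 unrelated ancestors,
10 descendants each at 1% per-site substitution, 5000 nt):

```r
ds <- make_clusters(n_clusters = 4, per_cluster = 10, length = 5000,
                    sub_rate = 0.01, seed = 42)
classify_dataset(ds)
#>     class  n sensitivity specificity accuracy
#>  cluster1 10           1           1        1
#>  cluster2 10           1           1        1
#>  cluster3 10           1           1        1
#>  cluster4 10           1           1        1
#>      Ave. 40           1           1        1
```

Every descendant's nearest neighbor lies in its own cluster, so all
per-class metrics are 100%.

## Command line

A thin CLI wraps the same functions (installed at `exec/pcnv` inside the
package library, or run via `Rscript -e 'pcnv::run_pcnv_cli()' --args ...`):

```sh
pcnv vectorize genomes.fa -o vectors.tsv [--ambiguity skip|strict]
pcnv dist vectors.tsv -o dm.phy [--strict-phylip]
pcnv tree genomes.fa -o tree.nwk [--distmat dm.phy] [--allow-negative]
pcnv classify genomes.fa --labels labels.tsv -o report.tsv [--json report.json]
pcnv simulate --clusters 4 --per-cluster 10 --length 5000 --rate 0.01 --seed 42 -o out_dir
```

Exit codes: 0 success, 2 invalid input, 1 unexpected failure. FASTA input
may be gzipped; distance matrices are written as PHYLIP square matrices;
trees as Newick.

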