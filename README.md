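# scentnet

Comparative transcriptomics of plant organs — flower (F), leaf (L) and bulb
scale (S) — for studies that ask which genes distinguish the organs, which
pathways they enrich, and which transcription factors co-express with scent
biosynthesis genes. The package reimplements the classic organ-comparison
analysis chain as tested, reusable R functions, and ships a synthetic-data
generator with planted ground truth so the whole pipeline can be validated
without sequencing data.

## What it computes

**Quantification.** Read counts become RPKM (reads per kilobase of
transcript per million mapped reads):

    RPKM(g, s) = 10^9 * C_gs / (N_s * L_g)

with `C` the count, `N_s` the sample's total mapped reads, `L_g` the
transcript length — removing both length and depth effects.

**Differential expression.** A nonparametric noise-distribution screen in
the style of the original NOISeq method. For each organ pair, every gene
gets two statistics from replicate-mean expression `x1`, `x2`:

    M = log2(x1 / x2)        D = |x1 - x2|

(zero expression is scored as 0.001 inside the ratio). An empirical null of
(M\*, D\*) values is pooled from all within-organ replicate pairs, and the
probability of differential expression is the fraction of null points a
gene strictly dominates in both coordinates:

    P = #{ |M*| < |M| and D* < D } / n_points

Genes with `P > 0.8` and `|M| > 2` are called up- or down-regulated by the
sign of M.

**Organ profile.** Organ-unique genes (replicate-mean expression zero in
two organs, positive in the third), up/down tallies per comparison and the
DEGs common to all three comparisons.

**Enrichment.** Hypergeometric over-representation of a DEG set against
GMT gene sets (`P(X >= k)` for `X ~ Hypergeom(N, K, n)`), with
Benjamini–Hochberg correction and significance at corrected p <= 0.05.

**Network.** Pearson correlation of every transcription factor against
designated scent structural genes over all replicate samples; edges kept at
`|PCC| >= 0.95` and `p < 0.01` (two-sided t-test on n-2 df), exported as
SIF/TSV with a TF-family breakdown and a hierarchical-clustering row order
(1 - PCC distance, average linkage) for heatmaps.

**qPCR concordance.** 2^-ddCt relative quantification from Ct tables and
per-gene Spearman rank agreement between RQ and RPKM across organs.

## Worked example

```r
library(scentnet)

gen  <- simulate_counts(n_genes = 500, de_fraction = 0.05,
                        unique_per_organ = 10, seed = 42)
expr <- rpkm(gen$counts)
screens <- pairwise_screen(expr)
updown_tally(screens)
#>     pair n_up n_down
#> 1 F-vs-L   11     14
#> 2 F-vs-S   10     12
#> 3 L-vs-S    8      8

head(subset(screens[["F-vs-L"]], call != "not_de"), 5)
#>      gene      m      d      p call
#> 1  g00001  2.871 4606.2 0.9817   up
#> 2  g00002 -3.183 1430.8 0.9390 down
#> 3  g00003 -4.158 2659.9 0.9707 down
#> 5  g00005  2.210  432.7 0.8237   up
#> 10 g00010 -3.282 1089.3 0.9217 down
```

25 genes are called in F-vs-L: `m` is the log2 fold change between the
organ means (positive = higher in flower), `d` the absolute RPKM
difference, and `p` the fraction of replicate-noise points the gene
dominates — g00001 beats 98.17% of them and clears both thresholds. The
planted organ-unique genes are recovered exactly:

```r
organ_summary(find_unique_genes(expr))
#>   organ n_unique
#> 1     F       10
#> 2     L       10
#> 3     S       10
```

and the planted annotation term surfaces from the planted DE set:

```r
tm <- simulate_annotation(gen$truth, n_terms = 20, term_size = 15,
                          enrichment_bias = 50, seed = 42)
de <- unique(unlist(lapply(gen$truth$de_genes, `[[`, "gene")))
head(enrich(de, tm), 3)
#>   term_id        term_name k  K  n   N    p_raw    p_adj significant
#> 1    T001 synthetic term 1 8 15 25 500 6.10e-08 1.22e-06        TRUE
#> 2    T002 synthetic term 2 2 15 25 500 1.69e-01 4.84e-01       FALSE
#> 3    T005 synthetic term 5 2 15 25 500 1.69e-01 4.84e-01       FALSE
```

`run_all(out_dir, simulate = TRUE)` chains every stage and writes all
tables plus a JSON run manifest; `exec/scentnet` exposes the same stages as
shell subcommands (`simulate`, `quantify`, `deg`, `profile`, `enrich`,
`network`, `run-all`, `validate`).

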