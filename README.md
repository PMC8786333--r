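# ironSplice

Joint calling of differential expression (DE) and differential
alternative splicing (DAS) from feature-level RNA-seq coverage, for
short-term stress time courses in which the two regulatory layers must
be separated and related to gene architecture.

## The problem

Nutrient-stress time courses (the motivating system is iron deficiency
in *Arabidopsis* roots and shoots, 3 treated vs 3 control replicates at
0.5 h, 6 h and 12 h) change transcript populations in two ways:
transcript abundance (DE) and transcript structure via intron retention
(IR), alternative donor/acceptor usage (DA) and exon skipping (ES).
ironSplice implements the full analysis chain:

1. **Read trimming** — per base, the Phred score is converted to an
   error probability and scored `v = 0.05 − p`; a running sum of `v` is
   reset at zero, and the read is trimmed to the region between the
   first positive value and the maximum of the running sum (reads
   < 35 bp discarded).
2. **Normalization** — TMM factors, logCPM
   `log2((y + 0.5)/(N·f + 1)·1e6)`, adjusted RPKM
   `2^logCPM / (length/1000)`, and the relevance filter
   `RPKM > sqrt(mean RPKM)`.
3. **DE calling** — per timepoint two-sample t-tests on RPKM with
   `p ≤ 0.05`, fold-change > 2, and relevant expression.
4. **DAS calling** — IR ratio = intron depth / mean flanking-exon
   depth; DA and ES read counts divided by gene counts as background;
   t-tests with `p < 0.05`, fold-change > 2, and presence of the raw
   signal in all replicates of at least one condition.
5. **Regulatory modes** — DE-only / DAS-only / both / neither, overlap
   enrichment against the independence expectation `|DE|·|DAS|/|U|`,
   and DE-vs-DAS fold-change correlations.
6. **Architecture** — average splice-site strength
   `ASS = (min 5′ + min 3′)/2`, intron-number bin enrichment normalized
   to the genome-wide background, two-way ANOVA + Tukey HSD across
   process groups, logistic regression of splicing-mode propensity on
   intron count and ASS.
7. **Consensus ("ferrome") voting** — a gene enters the consensus set
   when ≥ k of n independent datasets call it DE.

A ground-truth synthetic-data generator (negative-binomial counts,
gamma depth noise, injected DE/IR/DA/ES effects, logistic
architecture coupling) emulates the study design so every stage is
testable without any downloads. See the methods vignette
(`vignettes/ironSplice-methods.Rmd`) for the model, noise placement,
parameter defaults and limitations.

## Worked example

```r
library(ironSplice)

cfg  <- syntheticConfig(nGenes = 500, seed = 7,
                        timepoints = c("0.5h", "6h", "12h"))
ds   <- generateDataset(cfg)                      # models + coverage + truth
cov  <- combineCoverageTables(unname(ds$coverage))
expr <- normalizeExpression(cov, ds$models)
expr
#> NormalizedExpression: 500 genes x 18 samples
#> TMM factors: 0.900 0.916 0.943 1.050 1.035 1.040 0.871 0.934 ...
#> relevance threshold (RPKM): 41.050

de  <- callDE(expr)                                # per-timepoint DE calls
das <- callDas(extractEvents(cov, ds$models))      # per-timepoint DAS calls
length(deGenes(de))
#> [1] 119
dasTypeSummary(das)
#>   type n_genes  fraction
#> 1  DIR     110 0.5699482
#> 2  DDA      66 0.3419689
#> 3  DES      52 0.2694301

mc <- classifyModes(deGenes(de), dasGeneFlags(das)$gene_id,
                    rownames(rpkm(expr)))
attr(mc, "summary")
#>   n_universe n_de n_das n_both frac_das_also_de expected_both enrichment_both
#> 1        500  119   193     50        0.2590674        45.934        1.088518
```

The summary reads: of 500 expressed genes, 119 were DE and 193 DAS at
one or more timepoints; 50 genes carried both labels, close to the
45.9 expected if the two regulatory layers were assigned independently
(enrichment 1.09) — as they are in this simulation, where DE and DAS
effects are injected independently. The relevance threshold (41.05
RPKM) is the square root of the dataset's mean expression; the TMM
factors hover around 1 because no composition bias was injected.

Architecture association on the same run:

```r
arch <- buildArchitecture(ds$models, ds$spliceScores, ds$promoters)
intronBinEnrichment(dasGeneFlags(das)$gene_id, arch)
#>     bin n_set n_background enrichment
#> 1     0     0          101  0.0000000
#> 2   1-5   133          280  1.2305699
#> 3  6-10    42           81  1.3433122
#> 4 11-20    17           35  1.2583272
#> 5 21-50     1            3  0.8635579
#> 6   >50     0            0         NA
```

Intronless genes can never be DAS (enrichment 0); spliced genes are
mildly over-represented, uniformly across bins, because this run
injected splicing events independently of intron count (set
`couplingBeta` to couple them).

A whole run — trim → normalize → de → das → modes → architecture →
ferrome — is driven by `runPipeline(pipelineConfig(...))` or a YAML
config via `readPipelineConfig()`; outputs are deterministic TSVs plus
a manifest of row counts.

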