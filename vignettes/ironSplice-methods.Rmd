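---
title: "Methods: joint DE and DAS calling from feature-level coverage"
author: "ironSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint DE and DAS calling from feature-level coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironSplice)
```

# Scope and model

ironSplice implements an analysis chain for short-term stress RNA-seq
time courses in which gene activity is regulated both by transcription
(differential expression, DE) and by alternative splicing (differential
alternative splicing, DAS). The chain runs from raw read quality
trimming through normalization, per-timepoint DE and DAS calling,
classification of genes by regulatory mode, association of that mode
with gene architecture, and multi-dataset consensus voting. Every stage
can be exercised on synthetic data with known ground truth; no external
downloads are involved.

## Read trimming

Per base, the Phred score $Q$ is converted to an error probability
$p = 10^{-Q/10}$ and scored $v = c - p$ with cutoff $c = 0.05$, so
low-quality bases score negative. A running sum of $v$ is kept and reset
to zero whenever it would drop below zero. The retained region extends
from the first position where the running sum becomes positive to the
position attaining its maximum (first maximum on ties); reads whose
retained region is shorter than 35 bp are discarded.

When the running sum resets more than once, "first positive position" is
ambiguous. The default (`firstPositive = "segment"`) anchors the start
to the first positive position after the last reset preceding the
maximum, so exactly one contiguous region is retained; the literal
global reading (first positive position of the whole read) is available
as `firstPositive = "global"`. N bases carry whatever quality score the
file assigns them; no special-casing. Phred+33 is assumed, with an
offset switch for legacy encodings.

## Normalization and the relevance filter

Gene counts are normalized with the trimmed mean of M-values (TMM,
via edgeR, which implements the published algorithm exactly: reference
sample by upper-quartile fraction, trim fractions 0.30 on M and 0.05 on
A, inverse-asymptotic-variance weights, geometric-mean-1 rescaling).
Genes with zero counts in every sample are dropped first; they carry no
information and break the M/A computation. Whether the relevance
threshold should be computed before or after that drop is not
prescribed anywhere; we compute it after (the dropped genes would push
the threshold down without ever being callable).

logCPM is the closed form
$\log_2\!\big((y + 0.5)/(N\,f + 1)\cdot 10^6\big)$ with library size
$N$ and TMM factor $f$; adjusted RPKM divides $2^{\mathrm{logCPM}}$ by
the gene model length (summed exon length) in kb. The
expression-relevance threshold is $\sqrt{\overline{\mathrm{RPKM}}}$
over all genes and samples of the dataset under analysis — per tissue,
because tissues are analysed separately throughout; a gene must exceed
it in at least one condition's group mean to be callable
(`relevance = "either"`; a stricter `"both"` mode is available because
the original rule does not say which group must pass).

## DE calling

Per timepoint, treated and control RPKM values are compared with a
two-sided two-sample t-test. The pooled-variance Student's t is the
default — the unqualified "t-test" of the era — with Welch behind a
flag. Fold-change is the ratio of group mean RPKM; a zero control mean
with nonzero treated mean is an infinite fold-change and passes the
filter. A gene is DE when it is relevantly expressed, $p \le 0.05$ and
the fold-change exceeds 2-fold in either direction. Raw p-values are
used by default (the thresholds are joint filters, not a corrected
test); Benjamini–Hochberg adjustment is optional.

## AS events and DAS calling

Three event classes are considered. Intron retention (IR): the ratio of
the intron's mean read depth to the equal-weight mean depth of its two
flanking exons. Alternative donor/acceptor (DA): a junction whose
genomic (donor, acceptor) positions match the annotated exon boundaries
of the gene on exactly one side; junctions matching both sides of one
intron are annotated splicing, junctions matching neither side are
logged and ignored. Exon skipping (ES): reads joining boundaries of
non-adjacent annotated exons, keyed by the skipped exon. DA and ES
signals are divided by the gene's read count as background, removing
expression-level confounding; event discovery is junction-key driven
from the coverage table, not from an isoform catalogue.

Per timepoint, event ratios are compared by t-test. An event is DAS
when (i) its raw signal is present in all replicates of at least one
condition and its ratio defined in all samples — presence in *either*
condition so that both enhanced and reduced splicing are callable —
(ii) $p < 0.05$, and (iii) the ratio of group mean ratios exceeds
2-fold. Gene-level DAS of a type means at least one significant event
of that type; a gene may carry several types. Whether the upstream
feature counter's internal presence rule used raw or normalized depths
is not recoverable; raw depths are used and documented as an
assumption.

## Regulatory modes and architecture

Genes are partitioned into DE-only, DAS-only, both, and neither over
the expressed-gene universe; pooled mode takes the union over
timepoints of each call set before intersecting. The overlap is
summarized as observed/expected with the independence expectation
$|DE|\cdot|DAS|/|U|$. Fold-change relationships between DE and each DAS
type are quantified with Pearson and Spearman coefficients on signed
log2 fold-changes (the exact transformation used in the original
figures is not stated; log2 with sign from direction is our choice).

Per gene, architecture records carry the intron count and lengths, the
minimum 5' and minimum 3' splice-site strength over its introns, their
average ASS $= (\min 5' + \min 3')/2$ (scores taken as given, possibly
negative; single-exon genes get NA, never 0), and promoter length and
TFBS count joined from the regulatory-site table. Intron-number
enrichment of a gene set is its per-bin frequency normalized by the
genome-wide background frequency, with default bins 0, 1–5, 6–10,
11–20, 21–50, >50 reflecting the saturation of splicing regulation
between roughly 10 and 20 introns and the rarity of intron numbers
above 50; the normalization denominator (background fraction) is our
interpretation of the published "normalised to the average intron
number across the genome". Group comparisons use two-way ANOVA (process
group × tissue; one-way when a single tissue is present) with Tukey HSD
on the group factor's marginal means, and report group means and
medians. Genes missing a feature are excluded from that test, never
imputed.

## Consensus voting

A gene enters the consensus set when it is reported differentially
expressed in at least $k$ of $n$ independent datasets (e.g. $k=4$ of 7
in roots, 3 of 5 in shoots). Voting is direction-agnostic by default —
whether the original procedure required directional agreement is
unstated — with an optional direction-consistent mode. Identifiers are
normalized to uppercase locus ids. $k=1$ yields the union, $k=n$ the
intersection, and raising $k$ never adds genes.

# The synthetic-data generator

The generator emulates the target study design: 3 treated vs 3 control
replicates per timepoint at 0.5 h/6 h/12 h, ~4 introns per gene
(negative-binomially distributed, so single-exon and intron-rich genes
both occur), exon/intron lengths gamma-distributed around 250/160 bp,
mean exonic depth 50 reads/bp with log-normal gene-to-gene spread,
negative-binomial gene counts with dispersion $\alpha = 0.1$ (variance
$\mu + \alpha\mu^2$), baseline IR ratio 0.05, junction background rate
0.01 reads per gene read, and 4-fold injected effects for DE and for
each event class. Promoter lengths and TFBS counts are drawn around
1,595 bp and ~33 sites with the two coupled, mirroring genome-wide
regulatory-database averages.

Noise placement matters and is deliberate. Exon depths are gamma
around the gene's condition mean with $CV^2 = \alpha$. The intron depth
rides on the realized mean depth of its flanking exons times the
retention ratio times an independent gamma splicing-efficiency noise
($CV^2 = \alpha$): transcription-level fluctuations thus cancel from
the IR ratio, whose replicate variability is governed by the dispersion
alone — the property that makes IR ratios comparable across
expression changes. Junction and skip reads are Poisson with rate
proportional to the gene's *sampled* count, so DA/ES background ratios
are expression-normalized by construction but keep realistic counting
noise.

Gene-level propensity of IR injection follows
$\mathrm{logit}(p) = \mathrm{logit}(f_{IR}) + \beta_1 (n_{introns} -
\bar n) + \beta_2 (ASS - \overline{ASS})$; with $\beta_1 = \beta_2 = 0$
(the default) injections are architecture-independent and DE/DAS
injections are mutually independent, the null used for the
mutual-exclusivity calibration. What the generator does *not* emulate:
sequence-level read errors and alignment artefacts, isoform structure
beyond one representative model per gene, correlated event injection
within a gene, and library-composition biases beyond what TMM removes.
Passing tests therefore validate the statistical machinery under the
stated noise model, not robustness to alignment pathology.

# Numerical choices and degenerate inputs

* Coordinates are held in the Bioconductor range containers (1-based,
  closed; `GRanges`/`GRangesList`), with IRanges doing the interval
  arithmetic; GFF3 I/O is the identity on coordinates and strand.
  Strand affects only 5'/3' labelling, never interval math. One
  representative transcript per gene (first mRNA by id) is used for all
  feature statistics; how multi-isoform genes were collapsed originally
  is not documented, and this choice is flagged here.
* Zero-variance t-tests: equal means give $p = 1$, unequal means with
  zero pooled variance give $p = 0$. Events with fewer than two defined
  ratios in a group are skipped with the reason recorded. Undefined
  ratios (zero denominators) are NA, never 0.
* Ties at the running-sum maximum break to the first maximum (earliest
  end) — deterministic and conservative.
* Writers sort rows deterministically and serialize byte-identically
  for equal inputs; the whole simulate-and-analyse chain is
  reproducible from one integer seed.

# Calibration properties and their operating points

The acceptance suite checks, among exact identities, four stochastic
properties at the study-like conditions above. The problem sizes are
chosen to give the checks stable operating characteristics: trimming
oracle agreement on 10,000 random reads; DE null calibration on 2,000
genes (fraction of $p \le 0.05$ within $0.05 \pm 0.01$); IR recovery on
~500 injected 4-fold events among ~8,000 annotated introns of 2,000
genes (about 30% of spliced genes responding, the DAS prevalence scale
such stress time courses report) with sensitivity $\ge 0.8$ and
false-discovery proportion $\le 0.1$; overlap-enrichment null within
$1.0 \pm 0.1$ over 200 simulations of 300 genes; and coupling-sign
recovery in $\ge 95$ of 100 logistic fits on 2,000 genes.

The mutual-exclusivity null is evaluated on the DIR channel. The IR
ratio cancels expression exactly, so DE and DIR calls are independent
under independent injection. DA/ES background ratios are *unbiased*
under expression change but not *equivariant*: Poisson junction counts
give the scaled condition a different ratio variance, which inflates
false DDA/DES calls specifically on strongly DE genes at low junction
counts. That association is a genuine property of background-ratio
tests at shallow event coverage — worth knowing when interpreting
DE/DAS overlaps of the minority event classes — and is why the null
calibration uses the event class that is free of it (and that
dominates DAS genes in practice).

# Known limitations

* The pooled t-test at $n = 3$ has limited power; the stated recovery
  operating point (sensitivity ~0.85 at 4-fold IR effects) is close to
  the theoretical ceiling for this design.
* Background-ratio DA/ES tests at low junction counts are
  heteroscedastic across conditions with strong DE (see above); a
  count-model test would be more exact than the t-test the pipeline
  reproduces.
* The relevance filter, FC filter and raw-p threshold are joint ad hoc
  filters, not a coherent error-rate guarantee; the package reproduces
  them faithfully rather than improving on them.
* One representative transcript per gene ignores isoform-specific
  splicing; genuinely isoform-resolved analyses need a different event
  model (out of scope here).
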