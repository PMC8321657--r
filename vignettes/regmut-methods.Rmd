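---
title: "Methods: calling candidate functional noncoding mutations in TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling candidate functional noncoding mutations in TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmut)
```

## The problem and the model

Noncoding somatic mutations vastly outnumber coding ones, but almost all are
passengers.  `regmut` looks for the exceptions: mutations that land inside a
transcription factor (TF) motif, measurably change how well the site matches
the motif, sit in chromatin that is actually active in the matching tissue,
and recur across tumors beyond what the local mutation process explains.
The pipeline therefore combines four ingredients, each of which this
vignette describes along with the judgement calls made where the design was
genuinely open.

### A context-matched mutational null

Somatic mutation rates depend strongly on the trinucleotide context (the
mutated base plus its two neighbors) and vary along the genome at the tens-
of-kilobases scale.  The background model respects both: every observed
mutation is relocated to a position drawn uniformly among positions on the
same chromosome with an *identical* trinucleotide context, at a distance
between `shuffle_min_dist` (50 bp, so the site itself is vacated) and
`shuffle_window` (50 kb, so the local rate is preserved).  One hundred and
three such shuffled catalogs (`n_sim_sets = 103`) form the null; any
statistic computed on the observed catalog is ranked against the same
statistic on the simulated ones with the convention

\[ p \;=\; \max(k, 1)/n, \]

where \(k\) counts simulated values at least as extreme among \(n\).  The
convention never returns zero and puts the floor at \(1/103 = 0.0097\) — the
smallest p-value any enrichment test in the package can report.

Decisions taken here: indels, for which context matching is not defined, are
relocated uniformly within the same distance bounds with the reference
allele rewritten from the landing site, and flagged (`context_matched =
FALSE`); when a context has no eligible neighbor the window is doubled once
and the mutation is otherwise dropped with a warning, because silently
relocating it to a *different* context would corrupt the null, which is the
binding invariant.  Simulated positions may collide with observed ones — no
exclusion is applied.  Set \(k\) uses seed `base_seed + k`, so individual
sets are reproducible in isolation.

### Motif scanning and the regulatory score

PFM counts become probabilities with a FIMO-style pseudocount of 0.8 split
by the background frequencies (any small constant would do; the value is
logged in the function signature), and log-odds scores are taken against a
uniform background of 0.25 per nucleotide.  Scan p-values are exact: scores
are discretized to 1/1000 bit and the null score distribution under the
background is obtained by dynamic programming (convolution across motif
positions), so the retention gate `p <= 1e-4` involves no sampling and no
external tool.  Both strands are scanned; a palindromic motif legitimately
yields one hit per strand at a locus.

Within each TF, only instances scoring at least one *population* standard
deviation above that TF's mean instance score are kept (`Z-score > 1`).  Two
boundary cases are fixed by consistency: when every instance scores equally
the standard deviation is zero and none stands above the mean, so none is
kept; a single instance is kept because its standard deviation is undefined.
The comparison is inclusive (`>=`), which only matters at exact ties.

A mutation overlapping a retained instance (at least one mutated base inside
the motif interval) is scored twice over.  First, the matching-score change

\[ \Delta = |\mathrm{PPM}[j,\ \mathrm{ref}] - \mathrm{PPM}[j,\ \mathrm{alt}]| \in [0,1], \]

with alleles complemented and the offset mirrored on minus-strand instances.
Probabilities, not raw counts, are used — the published 0.3 threshold is
only meaningful against the 0.25 uniform background on the probability
scale.  Multi-nucleotide substitutions take the maximum per-base \(\Delta\)
over their overlapped positions; indels take \(\Delta = 1\) (maximal
disruption) by convention, flagged as such.  Second, a weighted regulatory
score \(\sum_f w_f x_f\) over binary annotation features from the cell types
matched to the tumor type — matching TF ChIP peak, DHS, collapsed chromatin
state (Tss/Enh/Tx/Repr/Quies), CAGE peak, replication-domain class, TF
expressed — plus \(\Delta\) itself as one weighted feature.  \(\Delta\)
deliberately appears both inside the score and as the hard threshold of the
regulatory definition below: the score ranks elements, the threshold
classifies mutations, and the two uses are independent.  Weights are
positive by construction: `fit_annotation_weights()` fits a logistic
regression of a functional label on the features and discards non-positive
coefficients (with a ridge fallback under separation); without training
data, `default_annotation_weights()` supplies a fixed positive vector in
which the peak and DHS dominate.

For tumor types with no matched cell type, a feature is imputed across the
other cell types — modal label for categorical features, arithmetic mean for
numeric ones — but only when at least four cell types carry it; otherwise it
is treated as absent.  Mutated motifs of TFs not expressed in any matched
cell type are discarded.

### Mutated elements and their two significance tests

Mutated motifs within `merge_gap = 200` bp merge into elements by
single-linkage clustering; the element score is the arithmetic mean of its
member scores.  Each element is tested twice:

1. **Local empirical test.**  The element score is ranked against simulated
   elements — the simulated sets pushed through the *same* merge-and-score
   path — within a +/- 50 kb window, using the `max(k,1)/n` convention.
   When fewer than ten simulated elements fall in the window, the background
   widens to the chromosome (logged); an element with no simulated
   background anywhere is dropped with a warning rather than given a
   fabricated p.  Calibration is monitored with a theoretical background
   (one simulated element per window ranked against the others) and the
   genomic inflation factor \(\lambda\), the ratio of median observed to
   median theoretical \(\chi^2_1\) quantiles; `autoplot()` on the QC object
   draws the QQ comparison.

2. **Burden test.**  A Poisson generalized linear model of mutation counts
   over a stratification of the +/- 50 kb window by collapsed trinucleotide
   context (32 strata; indels and multi-nucleotide substitutions share one
   extra stratum), with log-opportunity offsets (context positions in the
   region times retained samples) and an in-element indicator.  Significance
   is a one-sided likelihood-ratio test (enrichment only): half the
   \(\chi^2_1\) tail when the coefficient is positive.  Samples above 30
   mutations/Mb genome-wide are excluded first.  If the GLM fails to
   converge the code falls back to an exact Poisson tail at the pooled
   background rate, and says so.  This is a deliberately simplified burden
   model built around context cofactors and local opportunity; it is not a
   re-implementation of any published tool's internals.

Elements pass when empirical p < 0.05 and Benjamini–Hochberg FDR (computed
within the cohort, across its tested elements) on the burden p < 0.05.  They
must then contain at least one **regulatory mutation** — \(\Delta > 0.3\)
*and* a matching TF peak or DHS — are extended symmetrically to the typical
regulatory size (`element_extension = 200` bp) when shorter, re-intersected
with the full mutation catalog (recovering mutations that lacked motif
overlap), cleared of any coding-sequence overlap, and finally required to be
mutated in at least `min_recurrent_samples = 3` distinct samples.  Elements
from cohorts not flagged as lymphoma or melanoma groups merge into the
pan-cancer set (union of spans and sample sets, recurrence re-applied);
those two groups are analysed separately because of their extreme local
mutation rates.

### Per-TF and per-position burden

Counts of regulatory-mutated motifs per TF (and per aligned motif position,
position 1 being the motif's 5' end on the motif strand) are ranked against
the simulated sets with the same `max(k,1)/n` convention, plus a fold
enrichment over the simulated mean (flagged undefined when the mean is
zero).  The simulated arm mirrors the observed regulatory definition but
with an *inclusive* \(\Delta \ge 0.3\) — the two passages defining the arms
read naturally that way, and the difference only matters at exact ties — and
additionally drops simulated mutations scoring more than one population
standard deviation below the mean score of the observed regulatory
mutations of the same TF (skipped for TFs absent from the observed arm).

### Signatures and downstream association

SNVs map to the 96 pyrimidine-centered trinucleotide categories (purine
references are presented on the opposite strand); DNPs map to the
lexicographically smaller of their two strand presentations.  Profiles are
compared to a user-supplied signature catalog by cosine similarity with a
0.7 call threshold (inclusive); per-mutation signature contributions, also
supplied as input (the package never fits signatures de novo), are compared
between regulatory and remaining mutations by a two-sided two-sample
Kolmogorov–Smirnov test per signature, with the direction given by the
difference of means.

Elements map to genes by 2 kb extension (overlap wins; otherwise both the
nearest upstream and nearest downstream gene), with a feature type —
promoter (within 2 kb upstream of a TSS), 5'/3' UTR, intronic (noncoding
gene body), intergenic — resolved, when several apply, by the type
containing the most element mutations.  Expression differences between
mutated and non-mutated samples use a pooled-variance t statistic whose
significance comes from label permutations with the add-one convention
\((k+1)/(B+1)\) (`n_expr_permutations = 100000`; zero pooled variance gives
p = 1); samples whose element mutations sit inside 3-star CNV segments
intersecting a GISTIC peak are excluded beforehand.  Methylation analyses
use beta > 0.2 as the methylated-CpG criterion: a Fisher exact test on
mutation rates at methylated CpGs inside versus outside motifs (odds ratio
oriented so that OR > 1 means the outside CpGs are more mutated — the
orientation is a documented convention of this package, stated in the
output column names), and a Mann–Whitney comparison of methylation at a
designated motif position between ChIP-supported (active) and unsupported
(inactive) motifs.  Pathway enrichment is the upper-tail hypergeometric test
with BH adjustment; the universe defaults to the union of supplied pathway
genes, overridable.

## The synthetic-data generator

`synthetic_scenario()`/`simulate_scenario()` build every input the pipeline
reads — genome, PFMs, mutation catalog, per-cell-type tracks, expression,
methylation, CNVs, gene models, pathways, signature tables — with planted
truth, deterministically under one seed.  What it emulates, and the
parameters chosen where realism was a judgement call:

* Genome: i.i.d. bases at `gc_fraction = 0.41` (human-like).  No isochore or
  repeat structure.
* Motifs: one strong-consensus PFM per TF (85:5 counts, so the consensus
  column probability is ~0.85 and the largest attainable \(\Delta\) is
  ~0.8).  Planted instances are split into full-consensus copies and
  degraded copies carrying roughly one mismatch per 10 bp
  (`weak_instance_fraction = 0.7`): real genome scans produce a broad
  matching-score distribution, and without that spread the per-TF Z-score
  filter would face a degenerate single-score population and keep nothing.
  Hotspots always occupy full-strength instances.
* Mutations: per sample, Poisson counts at `background_mutation_rate`
  (units: mutations/bp/sample); each mutation samples a 96-context category
  from the scenario spectrum and then a genomic position carrying that
  context on either strand, so the signature machinery has known truth.
  Hotspots place one SNV per designated sample at the planted motif
  position, with the most disruptive alternate allele.
* Tracks: peaks/DHS appear exactly where hotspots declare them
  (`has_peak`/`has_dhs`) in the matched cell type; enhancer state blocks
  surround planted instances over a quiescent background; replication
  domains split each chromosome in half.  There is no realistic chromatin
  spatial correlation — passing tests therefore demonstrate the machinery's
  correctness on controlled overlap, not performance on real chromatin.
* Expression is log-normal with the planted cis effect additive on the log2
  scale for hotspot-mutated samples; methylation betas come from a
  two-component Beta mixture (Beta(1,9)/Beta(9,1), 30% methylated) so the
  beta > 0.2 criterion separates the components; genes live in a reserved
  tail region of each chromosome so planted hotspots stay noncoding.

## Problem sizes and numerical choices in the test suite

The suite exercises the shuffler at a 1 Mb genome with 10,000 mutations
times 5 sets (all context and distance invariants hold exactly) and 10,000
draws for the uniformity goodness-of-fit; scanner-versus-enumeration
equivalence for motifs of length 4–6 on multi-kilobase genomes; burden-GLM
calibration on 1,000 null windows of 20 kb (200 mutations each, a 2 kb
element, so the element expects 20 mutations) and power on a planted 5x
in-element rate; permutation-test calibration on 1,000 null genes at
B = 2,000; and two end-to-end scenarios of a 200 kb genome, 200 instances,
40 samples and 103 simulated sets.  These sizes make the default test run
complete in a few minutes while keeping every statistical check at a sample
size where its nominal behavior is testable.

Numerical conventions collected in one place: 0-based half-open coordinates
everywhere internally (BED written as-is, TSV positions written 1-based and
labeled `pos`); scan scores discretized to 1/1000 bit for the exact DP
p-value (the discretized score is the test statistic, so oracle comparisons
enumerate the same quantity); population (not sample) standard deviations
wherever a Z-score-style rule appears; modal labels with alphabetical
tie-break in imputation; `max(k,1)/n` for every empirical p;
\((k+1)/(B+1)\) for permutation p; one-sided half-\(\chi^2\) for the burden
LRT; degenerate inputs (zero variance, all-zero profiles, empty arms)
return the conservative answer (p = 1) or a typed error rather than NaN.

## Known limitations

The annotation weights shipped as defaults are plausible but not trained on
reporter-assay data; users with labeled functional motifs should refit with
`fit_annotation_weights()`.  The burden model ignores covariates such as
replication timing and expression that genome-wide nulls sometimes include —
the local 50 kb window absorbs much of that variation but not all.  The
synthetic genome's lack of repeat structure makes context shuffling easier
than on a real genome, where context indices are sparser near telomeres and
low-complexity regions.  Cohort assignment, cell-type matching and signature
contribution tables are all taken as supplied input; errors in those
mappings propagate silently.  The package's interface is its R functions —
there is no shell entry point — and figures are limited to QQ, per-position
and 96-profile plots.
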