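---
title: "Methods: quantification, permutation FDR and ontology summaries in dialfq"
author: "dialfq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, permutation FDR and ontology summaries in dialfq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialfq)
```

# Scope

`dialfq` covers the quantitative stage of a label-free DIA proteomics
experiment, *after* precursor extraction: it takes a precursor-by-sample
intensity table (the kind of matrix a DIA search engine emits, with blanks
for precursors not observed in a run) and carries it through protein
rollup, differential testing, significance filtering, and Gene Ontology
summaries. Everything upstream — acquisition, database search, spectral
libraries, cross-run normalization — is assumed done and is out of scope.

The reference design the package is built around is a small comparative
experiment on plant leaf tissue: two or three conditions (a wild type plus
overexpressor or knock-out lines) with five biological replicates each,
thousands of protein groups carrying one to a few dozen peptides.

# The data model

Intensities live on the linear scale on disk and in the `intensity` assay
of a `PeptideQuant` object; all computation happens in log2. Missing cells
are `NA`, never zero: in DIA data a missing precursor usually means the
signal fell below detection, so zeros would be both wrong on the log scale
and statistically misleading. A `ProteinQuant` object holds the rolled-up
protein-group × sample log2 matrix together with the per-protein peptide
count and the method tag.

# Protein rollup

## MaxLFQ-style least squares

For one protein with log2 peptide matrix $x_{js}$, every ordered sample
pair $(s,t)$ with at least `minShared` peptides observed in both
contributes a ratio estimate

$$ r_{st} = \mathrm{median}_j\,(x_{jt} - x_{js}), $$

which is robust to individual peptide interference. Samples are nodes of a
graph whose edges are the valid pairs; within each connected component the
profile $p$ minimizes $\sum_{(s,t)} (p_t - p_s - r_{st})^2$. The absolute
level of $p$ is not identified by ratios, so the component mean is anchored
at the mean of the observed log2 peptide intensities of those samples. This
anchor preserves the overall intensity level and makes the estimate exactly
shift-equivariant: multiplying one sample's intensities by $2^k$ moves that
sample's estimates by exactly $k$ on complete data.

Two deliberate choices where the MaxLFQ literature leaves room:

* `minShared` defaults to 1 rather than 2. Synthetic and small fixtures
  are shallow (single-peptide proteins are common), and requiring two
  shared peptides would silently disconnect many of them. It is an
  argument, not a constant.
* Samples outside the largest connected component are reported missing
  rather than chained through weaker evidence. Ratio information simply
  does not connect them; pretending otherwise would manufacture
  quantities. Ties between equally large components go to the component
  containing the lexicographically smallest sample name, so results do not
  depend on column order.

The solver adds the rank-one term $J/m$ to the graph Laplacian to pin the
component mean; because the right-hand side is orthogonal to the ones
vector this does not perturb the ratio fit. Tests compare it against an
independently written dense KKT solver on hundreds of random missingness
patterns at $10^{-8}$.

No additional cross-run normalization is applied by default — in the
workflow this package slots into, normalization happens upstream during
precursor extraction. An optional per-sample median-centering flag exists
for data that arrives unnormalized.

## Summing

`sumQuantify()` is the deliberately simple alternative: per sample, log2 of
the sum of observed linear intensities. It is the right tool for proteins
with *extreme* fold changes, where MaxLFQ's pairwise ratios break down
because the two conditions share almost no observed peptides. On complete
data with consistent peptide offsets the two methods agree up to a
per-protein constant.

# Differential testing

## Statistics

Pairwise contrasts use the Welch $t$ statistic with Welch–Satterthwaite
degrees of freedom (no equal-variance assumption, which biological
replicates rarely satisfy); three-condition designs add a one-way
fixed-effects ANOVA $F$. Both are implemented by formula — they must be
recomputed thousands of times under permutation, vectorized over proteins —
and are checked against `stats::t.test()` / `stats::oneway.test()` to
$10^{-10}$ in the test suite. Zero within-group variance with a non-zero
between-group difference yields an infinite statistic with the p-value
clamped to the smallest positive double. No $s_0$-style variance fudge
factor is used: the plain statistic keeps the permutation null exact.

## Permutation FDR

Condition labels are shuffled across whole samples (columns), preserving
each protein's peptide structure, and the statistic is recomputed for every
protein; all null statistics are pooled across proteins and permutations
(the SAM-style pooled null, the standard reading of "permutation-based FDR
correction" in proteomics). For a threshold $c$,

$$ \widehat{\mathrm{FDR}}(c) =
   \frac{\frac{1}{B}\,\#\{\text{null} \ge c\}}
        {\max(1, \#\{\text{observed} \ge c\})}, \qquad
   q_i = \min_{c \le |t_i|} \widehat{\mathrm{FDR}}(c), $$

the smallest estimated FDR of any rejection region containing protein $i$;
this is non-increasing in $|t_i|$ by construction and capped at 1. All
distinct label assignments are enumerated when there are at most `nPerm` of
them — $\binom{10}{5} = 252$ for the 5 vs 5 design, so pairwise contrasts
at $n = 5$ are always exhaustive — otherwise `nPerm` random shuffles are
drawn (the three-group ANOVA null at 5+5+5 has 756{,}756 assignments and is
sampled at the default `nPerm = 1000`). The identity labeling is included
among enumerated assignments, flooring the smallest attainable $q$ at
$1/B$; this keeps the estimate conservative and is why a pure-noise dataset
essentially never yields $q \le 0.01$ together with a large fold change.
Within a three-condition experiment, each pairwise contrast permutes only
its own ten samples.

## Significance cascades

Two filters mirror the two experiment designs:

* **Three conditions** (`filterOverexpression`): at least one pairwise
  Welch $q \le 0.01$, ANOVA $q \le 0.01$, at least a twofold difference in
  some inter-group comparison ($\max |\Delta \log_2| \ge 1$), and at least
  4 valid values in every condition. "Any of two-sample Welch test" is
  read as all three pairwise contrasts (WT–OE1, WT–OE2, OE1–OE2); the
  thresholds are arguments with these defaults.
* **Two conditions** (`filterKnockout`): Welch $q \le 0.01$ and
  $|\Delta \log_2| \ge 0.8$.

A "valid value" is a non-missing protein-level quantification before any
imputation, and fold changes are differences of condition means over valid
values only. The cascade is a pure conjunction: relaxing any criterion can
only grow the significant set, which the tests assert.

Proteins essentially absent in one condition cannot pass the valid-value
criterion and are instead routed to `summingExtremeCandidates()`: flagged
when a condition has zero valid values while another has at least four, or
when the summed-intensity fold change reaches $2^5$. The summed matrix
supplies both criteria because its missingness reflects detection, whereas
a MaxLFQ profile can be missing merely for graph-connectivity reasons. Each
candidate carries its peptide-level intensity submatrix — the automated
stand-in for inspecting peptide profiles by eye.

## Imputation is for pictures only

`imputeLeftCensored()` draws missing cells from
$N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$ per sample — the de facto
standard down-shifted-normal scheme for left-censored proteomics data. Its
output feeds volcano tables (where dropout proteins would otherwise have no
x-coordinate) and nothing else; every test and filter runs on the raw
matrix. In `volcanoTable()` the difference is recomputed on imputed data
only for proteins failing the valid-value criterion.

# Ontology summaries

Identifiers are translated through a two-column mapping (one-to-many
mappings expand; unmapped ids are reported, not silently dropped). The OBO
parser reads `[Term]` stanzas with `is_a` and `part_of` relations, drops
obsolete terms and rejects cycles. Annotation propagation to ancestors (the
GO true-path rule) is on by default and exposed as a flag, since published
custom pipelines do not always state whether they propagate.

Enrichment is a one-sided Fisher exact test (hypergeometric upper tail) of
the significant set against **all detected proteins** as background — not
the whole genome, which would confound detectability with regulation.
Benjamini–Hochberg correction is applied within each namespace separately,
mirroring how BP/MF/CC results are presented; a flag pools them. Each term
reports $k$, $n$, $K$, $N$ and the percentage $100k/n$ of significantly
regulated proteins among the term's detected proteins.

Quantitative term scores average member-protein log2 abundances per sample,
either unweighted or weighted by $-\log_{10}$ of the parametric ANOVA
p-value (clamped at $10^{-300}$; proteins without a defined ANOVA get
weight 0). Unweighted scores show terms whose members move together;
significance weighting highlights terms that are flat on average but
contain strongly regulated members. Rows are z-scored with the population
(n-denominator) standard deviation — the convention that makes a
three-point profile $(1,2,3)$ map to $(-1.22, 0, 1.22)$ — and zero-variance
rows map to zeros rather than NaN. Proteins missing in a sample are dropped
from that sample's average; terms with fewer than two detected members are
scored but flagged `low_support` rather than filtered, since no minimum
term size is part of the method definition.

# The synthetic-data generator

`simulateDataset()` draws, for protein $i$, peptide $j$, sample $s$ in
condition $c$:

$$ x = b_i + o_j + \Delta_{ic} + \varepsilon, \qquad
   b_i \sim N(20, 2^2),\ o_j \sim N(0, 1),\ \varepsilon \sim N(0, 0.25^2)
   \ \text{(log2 units)}, $$

with peptide counts $1 + \mathrm{Poisson}(4)$ truncated at 20 (typical DIA
depth), 5 replicates per condition, 5% of proteins regulated with one drawn
effect of magnitude 1.5, 2 or 3 (random sign) in one non-reference
condition. Each cell is censored with logistic probability
$1/(1+\exp((x - 16)/0.8))$ — cellwise missing-not-at-random, so that
left-censored imputation and the valid-value filters face the missingness
mechanism they were designed for, not MCAR noise. Intensities are emitted
as $2^x$. All randomness flows from one seed through one generator; the
same seed reproduces the dataset byte for byte.

These defaults were chosen once to make a realistic leaf-tissue DIA
experiment: base abundances around $2^{20}$ with 2 log2 units of spread
match typical DIA intensity reports, replicate noise of 0.25 log2 units is
a reproducible biological-replicate setting, and the censoring midpoint
four standard deviations below the mean abundance yields a single-digit
overall missingness percentage concentrated in low-abundance proteins.
What the generator deliberately does *not* emulate: shared (razor)
peptides, interference, retention-time drift, batch structure, or
correlated peptide noise. Passing recovery tests therefore demonstrates
the statistical machinery under its own assumptions, not robustness to
those real-data pathologies.

`simulateOntology()` grows a rooted `is_a` DAG (term $k$ attaches to one
or two earlier terms, so acyclicity holds by construction), gives each
protein a Poisson number of random direct annotations, and plants terms
whose members are drawn 80% from a caller-supplied significant set.
Planted terms are chosen among *leaves*: an internal node's propagated
membership is dominated by its descendants' random annotations, which
would make the planted signal unrecoverable by design rather than by
failure.

# Numerical and interface choices

* Log base 2 everywhere; linear intensities on disk, logs in memory.
* One tabular dialect: TSV, UTF-8, header row, empty field = missing.
  Numerics are serialized as `%.17g`, so every writer/reader pair
  round-trips exactly; readers reject ragged rows, duplicate keys and
  non-numeric intensities with the offending line number.
* `runPipeline()` validates all inputs before writing anything, logs
  protein counts in/out per stage (so bookkeeping like "6023 quantified,
  247 significant" is visible on any dataset), and emits a JSON manifest
  with the config snapshot, input checksums, row counts and stage
  timings. Data products are byte-identical across re-runs with the same
  config and seed; the manifest differs only in its timing fields.
* There is no shell executable: the exported functions, `runPipeline()`
  and the configuration file (YAML/JSON via `readPipelineConfig()`) are
  the interface, which suits an R package whose users work in scripts.

Problem sizes used by the shipped checks (chosen as the smallest sizes at
which the statistical claims are meaningful): 500 random fixtures for the
rollup-vs-oracle comparison, 50 null simulations of 2000 proteins for FDR
calibration, 10 simulations of 2000 proteins for recovery of planted
effects, 1000 random fixtures for primitive accuracy, and 20 ontology
simulations for planted-enrichment recovery.

# Known limitations

* Protein-group inference, razor-peptide reassignment and precursor-level
  normalization are upstream concerns and absent here.
* No moderated-variance (empirical Bayes) testing, paired designs or batch
  correction; designs are one-way.
* The permutation scheme is the pooled SAM-style null; per-protein nulls
  and $s_0$ fudge factors are deliberate non-features, documented rather
  than configurable.
* Enrichment treats annotations as flat sets after propagation; no
  semantic-similarity reduction or GO-slim mapping.

# A worked example

```{r example, eval = FALSE}
sim <- simulateDataset(simulationParams(nConditions = 2, nProteins = 500),
                       seed = 1)
pq  <- quantifyProteins(sim$peptides, "maxlfq")
res <- diffTest(pq, nPerm = 1000, seed = 1)
hit <- filterKnockout(res)
truth <- sim$truth$proteins
table(called = rownames(res) %in% hit,
      regulated = truth$regulated[match(rownames(res),
                                        truth$protein_group)])
```
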