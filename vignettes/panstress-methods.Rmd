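---
title: "Methods: models, parameters and design choices in panstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in panstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`panstress` packages the comparative-genomics and stress-transcriptomics
workflow used to separate tolerant from sensitive strains in a panel of
closely related bacteria. This vignette is the package's own account of
the science: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## Homology: alignment, statistics and the BSR criterion

All-vs-all protein (or CDS) similarity uses Smith–Waterman local
alignment with affine gaps, implemented in C++ for the all-vs-all scale.
Gap costs follow the BLAST convention (a gap of length $g$ costs
$o + g\,e$), and the traceback is deterministic: diagonal is preferred
over the vertical move over the horizontal, and the highest-scoring cell
first reached in row-major order ends the HSP. Co-optimal alignments can
therefore differ from other implementations by a column or two in HSP
length while the score is identical; tests compare scores against
`Biostrings::pairwiseAlignment` and a brute-force dynamic program.

Raw scores become bit scores via the Karlin–Altschul transform
$b = (\lambda S - \ln K)/\ln 2$ and E-values via $E = mn\,2^{-b}$.
The scheme defaults are the standard gapped BLOSUM62 set
($\lambda = 0.267$, $K = 0.041$, gap open 11 / extend 1) and, for
nucleotides, +2/−3 with gap 5/2 ($\lambda = 0.625$, $K = 0.41$); the
pipeline's conclusions rest on score *ratios* and fixed thresholds, so
the exact constants matter little, but all are configurable. The
effective search space is the query length times the total residue count
of the gene pool, with no edge correction; it is a documented constant
of the hit table, not a fitted quantity.

Two homology criteria are exposed, matching the two analyses they feed:
`E ≤ 1e-5` for MCL ortholog clustering, and the bit-score ratio
`BSR(a,b) = bit(a,b) / max(bit(a,a), bit(b,b)) ≥ 0.30` (inclusive at the
boundary) for the single-copy analyses. The BSR denominator is the
larger of the two self-scores: the source description ("the protein
match against itself") does not say which protein, and the maximum makes
the ratio symmetric and conservative.

A shared-k-mer prefilter (4-mers for proteins, 12-mers for DNA, at least
5 shared by default) limits the quadratic alignment work. At the
divergences the generator produces (sequence identity well above 70%)
family members share dozens to hundreds of k-mers, so the filter loses
nothing; for genuinely remote homolog detection near the 30% identity
floor it should be disabled (`prefilter = FALSE`), which every
oracle-comparison test does.

## Ortholog clustering and clade-specific genes

Markov clustering follows the canonical algorithm: self-loops (weight =
maximum incident weight), column normalization, then alternating
expansion (matrix squaring) and inflation (entrywise power, default 1.5,
renormalize) until the maximum entrywise change is below $10^{-8}$ or
200 iterations (non-convergence is an error, never a partial result).
Entries below $10^{-12}$ are pruned to keep the matrices sparse, and
components are clustered independently — expansion cannot cross a
disconnected boundary, so this is exact, and it keeps each matrix tiny.
Edge weights are $-\log_{10} E$ capped at 200 (raw bit scores are
available instead). Attractor rows that share support are merged, so the
output is always a partition; groups of size one are singletons, defined
as genes in no cluster of size ≥ 2.

The Venn partition assigns each cluster to the set of genomes it touches
(presence/absence; paralog copy counts are recorded but do not move a
cluster between cells), so Venn cells always sum to the cluster total.

Clade-exclusive single-copy families are connected components of the
BSR ≥ 0.30 graph restricted to the clade's genes that contain exactly
one gene per clade genome and have no BSR edge into the contrast
genomes. On simulated panels the recovered set equals the ground truth
exactly; note the ground truth is *not* only the planted block — genes
gained on the clade's stem branch, or ancestral genes lost in every
other lineage, are genuinely clade-exclusive and are counted by
`true_clade_exclusive()`.

## ANI, AAI, genome distance, species calls

Two-way ANI/AAI are means of alignment identities over reciprocal best
hits; the RBH filters (coverage ≥ 70% of the shorter sequence, identity
≥ 30%) are the common defaults of the two-way method, configurable.
ANI is computed over CDS-vs-CDS alignments of gene pairs rather than
fixed-length genome fragments, because annotated gene sets are this
package's unit of input; relative comparisons and the 95% threshold are
preserved, which is what the delineation call uses. The genome distance
is $1 - \sum \text{identities} / \sum \text{HSP length}$ over HSPs at
$E \le 10^{-5}$, reported ×1000 for display. The classical DDH ≥ 70%
species criterion is retained only as the documented constant
`DDH_SPECIES_THRESHOLD`; no regression from distance to DDH is
attempted.

## Maximum-parsimony phylogeny

Single-copy pan-ortholog families are aligned per family (center-star;
trivially, since the generator emits no indels by default) and
concatenated in family-id order. The Fitch engine encodes states as
bitmasks and sweeps all site patterns at once; a tip gap carries the
full state set (missing data), a common convention that never forces a
change. Fitch scores are invariant under re-rooting, which the tests
assert, and match `phangorn::fitch` as an independent cross-check.

Topology search is exhaustive up to 8 taxa — the optimum is certain —
and stepwise addition plus NNI hill-climbing with 5 seeded random
addition orders above that. Score ties break on the lexicographically
smallest canonical newick, making results deterministic. Branch support
is gene-tree concordance: the percentage of per-family parsimony trees
whose bipartition set contains each branch of the concatenated tree.
"Percent confidence" on a published tree of this kind is ambiguous
(bootstrap? concordance?); the concordance reading is implemented and
should be interpreted as such, not as a bootstrap.

## Read mapping and Baggerley's test

The mapper enforces the study's placement rules as a policy object:
at most 2 mismatches, at least 50% of the read aligned, at least 80%
identity, more than 10 distinct placements → unmapped, 2–10 → one chosen
uniformly at random under a fixed seed. Placements are ungapped and
end-to-end: with ≤ 2 mismatches on reads of ≥ 10 nt this automatically
satisfies the identity and length floors, and the policy constructor
refuses combinations the ungapped contract cannot honor. Candidates come
from a pigeonhole seed index (one of $k{+}1$ read segments must match
exactly if the read has ≤ $k$ mismatches) and are verified by Hamming
distance, so the scan is exact, not heuristic. Counting uses unique
placements only by default — the tabulated "unique reads" reading — with
`with_random_assignment` available, since the source pipeline describes
both behaviors without resolving which one fed the tables.

Normalization is plain total-count: proportion = count / library total.
Baggerley's test models replicate proportions beta-binomially: within a
group, weights $w_i \propto (1/n_i + \theta)^{-1}$ give the
variance-minimizing pooled proportion, $\theta$ is re-estimated by
moments from the weighted residual sum (floored at 0, ten iterations),
and the two-sample statistic
$(\hat p_A - \hat p_B)/\sqrt{V_A + V_B}$ is referred to the standard
normal — with two replicates per group there is no useful t reference,
and the normal choice is documented rather than hidden. Under the null
(negative-binomial counts, dispersion 0.05, 2+2 replicates at depth
$10^5$) the empirical type-I error sits near 0.06 at $\alpha = 0.05$:
slightly liberal, as expected from a moment estimate on two replicates.
Power at an 8-fold spike is assessed over genes whose expected control
count is at least 5 at the tested depth; below that floor no
two-replicate proportions test has meaningful power, and including
arbitrarily shallow genes would measure the baseline distribution, not
the test.

Fold changes use the signed convention (ratio $r \ge 1$ as $r$, else
$-1/r$) with a 0.5 pseudo-count added to the group mean counts for the
ratio only — never to the tested proportions. DE calls default to
$p \le 0.05$ and $|fold| \ge 2$; the source analysis never states its
thresholds, so these conventional values are explicit parameters. No
multiple-testing correction is applied by default (matching the source
tables); Benjamini–Hochberg is available behind `fdr = TRUE`.

## qPCR validation and phenotype calls

ΔΔCt folds share the signed convention and the normalizer cancels any
per-sample global Ct shift; significance is a t-test on per-replicate
ΔCt. The bundled 22-pair qPCR/RNA-seq fold table reproduces the
published platform correlation only once the signed folds are mapped
back to plain expression ratios ($s \le -1 \to -1/s$): correlating the
signed values as printed gives $r = 0.86$, the ratio scale gives
$r = 0.935$, matching the reported 0.95 within the tolerance such an
unstated normalization deserves. The ratio transform is therefore the
default of `fold_correlation()`, with `"signed"` and `"log2"` options;
one printed value of magnitude < 1 (an inconsistency in the source
table) is treated as already being a ratio.

MTC ("does not affect growth") is operationalized as the highest
concentration not significantly below the 0-mM control by a one-sided
t-test at $\alpha = 0.05$; MIC ("inhibits growth") as the lowest
concentration with mean yield ≤ 5% of control. The source defines both
phenotypes verbally, with no statistical rule; these operationalizations
are the package's, and both thresholds are parameters. Calls are
invariant under positive rescaling of all yields, and an MIC above the
tested range is reported as `Inf`.

## The synthetic-data generator

The generator's defaults are the study conditions the test-suite runs
under, chosen once:

- **Panel**: 6 strains on a fixed rooted tree with branch lengths
  0.01–0.04 expected substitutions/site; 300 ancestral genes of 80–250
  aa; a 10-gene block planted at the MRCA of the two designated tolerant
  strains. Gain/loss/duplication at 0.02/0.02/0.01 events per gene per
  branch give per-strain singleton counts of a few dozen, matching the
  singleton-rich panels such analyses see.
- **Evolution**: Jukes–Cantor on CDS nucleotides, proteins by
  translation; substitutions creating in-frame stops are resampled; no
  indels by default (an in-frame indel rate is available but off), so
  per-family alignment is trivial and the expected identity after total
  divergence $t$ has the closed form $\tfrac14 + \tfrac34 e^{-4t/3}$,
  used as the ANI oracle.
- **Counts**: two replicates per condition (control/salt/osmotic) at
  deliberately unequal depths (2.14M / 0.85M / 2.5M mapped-read scale);
  gamma-distributed baselines summing to 80% of each library (the rest
  standing in for reads outside annotated CDSs); gamma-Poisson replicate
  noise with dispersion 0.05, the overdispersion regime Baggerley's
  test models; default spikes 20 salt-only + 20 osmotic-only + 10
  shared, half up (×4) and half down (×¼).
- **Reads**: single-end, fixed 100 nt, uniform over start positions,
  i.i.d. substitution errors at 1%. Paired-end structure is not
  emulated; the mapper contract is per-read.
- **Ct tables**: $Ct = 12 - \log_2(\text{proportion})$ plus Gaussian
  technical noise (sd 0.15), technical triplicates; with zero noise the
  ΔΔCt fold equals the counts' normalized ratio exactly, which is the
  identity the qPCR tests exploit.
- **Growth**: mean yield 100 µg/ml up to the true MTC, cubic-smoothstep
  (sigmoidal) decline to 0 at the true MIC, Gaussian replicate noise
  (sd 5) on a 0–1000 mM grid in steps of 125.

What passing tests on these data do **not** show: robustness to indels
and rearrangements, codon-usage and compositional bias, operon
structure, rRNA contamination, adapter artifacts, or paralog
interference beyond the simple duplication model. The generator is a
ground-truth harness, not a genome simulator.

## Problem sizes and numerical notes

The shipped suite runs 20 six-strain panels for clade-exclusive
recovery, 50 ten-node graphs against an exhaustive modularity oracle,
200 five-taxon columns against brute-force Fitch, 40 six-taxon
recoveries at ≥ 5000 concatenated columns, 5000-gene null and power
simulations for the test statistics, and 100 noisy dose-response
recoveries — sizes chosen so the whole suite completes in a few minutes
on one core while keeping every Monte-Carlo margin wide. MCL uses
sparse matrices with pruning at $10^{-12}$; Fitch compresses site
patterns before scoring; alignment scores are integer throughout, so no
floating-point tie ambiguity enters the tracebacks.
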