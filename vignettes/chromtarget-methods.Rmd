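---
title: "Predicting TF targets from chromatin modifications and binding motifs: methods"
author: "chromtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF targets from chromatin modifications and binding motifs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Transcription factors (TFs) recognise short, degenerate sequence motifs, so
motif matching alone over-predicts binding: most genomic matches of a
position-specific scoring matrix (PSSM) are not bound in vivo. In compact
genomes like *Saccharomyces cerevisiae*, where targets can be defined as
genes with binding sites in their upstream regions, the chromatin context of
a potential site carries complementary information — bound sites sit in
nucleosome-depleted regions flanked by characteristic histone modifications.
`chromtarget` implements an integrative predictor: for each TF, a
radial-kernel SVM combines a motif channel (the cumulative PSSM matching
score of each gene's promoter) with a chromatin channel (mean histone
modification signals in fixed windows around each gene's ATG start codon),
trained against ChIP-derived target labels. Downstream of prediction, the
package profiles each TF's targets across modifications and splits factors
into histone-sensitive and -insensitive classes, with a battery of
comparative statistics (condition specificity, TF-TF cooperativity,
co-regulation, group attribute contrasts).

## Motif channel

A PSSM stores per-position nucleotide probabilities $p_{i,j}$. Its
information content against background frequencies $p_b(j)$ is the relative
entropy $\mathrm{IC} = \sum_{i,j} p_{i,j}\log_2(p_{i,j}/p_b(j))$, in bits;
we use the standard positive convention under which informative motifs score
high and a background-matching motif scores exactly 0. The background is
built from a GC fraction (0.37 for the yeast genome), so $A=T$ and $C=G$.
Similarity between two PSSMs is the averaged per-position dot product
$\frac1n\sum_{i,j} p_{1,i,j}\,p_{2,i,j}$; for unequal lengths all ungapped
alignments are scored over their overlap (at least 3 shared positions) and
the maximum is kept.

Scanning scores every window of motif length on both strands with
pseudocount-regularised log-odds, $\sum_i \log_2(\tilde p_{i,b_i}/p_b(b_i))$
(pseudocount 0.01, renormalised per row, so absent bases score finitely).
Windows containing `N` are skipped. A window is an occurrence when its score
reaches a threshold; no public threshold accompanies the published motif
scans, so the package defaults to 60% of the motif's maximum achievable
score, records the resolved value in its run manifest, and exposes it as a
parameter. The **cumulative matching score** of a gene is the sum of the bit
scores of all occurrences in its promoter (the region from the start codon
to 800 bp upstream); overlapping occurrences all count. Summing bit scores
(rather than, say, $-\log_{10}$ match P-values) is a deliberate choice where
the source method is ambiguous; it is monotone in both the number and the
quality of occurrences, which is what the classifier needs.

## Chromatin channel

Probe-level tracks (bedGraph-style intervals with one value per
modification) are aggregated into per-gene region signals as the unweighted
mean of all probes overlapping the region by at least 1 bp; a region with no
probe is missing. Regions are anchored at the ATG: upstream and downstream
windows of 500 and 1000 bp (mirrored on the minus strand around the stored
ATG base), plus the upstream intergenic region (IR) and the ORF itself for
the acetylation set. Two feature families mirror the published data
structure: 14 "windowed" modifications (occupancy and
methylation/acetylation marks assayed genome-wide) and 11 intergenic/ORF
acetylation marks. Because tiling arrays cover only part of the genome
(~85% here), genes missing more than half of their feature columns are
dropped from model fitting and the remaining missing values are mean-imputed
per column.

## Classifier and evaluation

Features (selected groups among chromatin, motif score, and optionally
log-expression) are assembled per TF; target labels come from ChIP binding
P-values with a strict cutoff (`P < 0.01` by default; exactly 0.01 is a
non-target). The learner is `e1071`'s C-classification SVM with radial
kernel, cost 1 and kernel width $1/d$. One deliberate departure from the
bare library defaults: classes are weighted inversely to their frequencies.
Target genes are a small minority (~5% of genes at the usual cutoff), and
with equal weights the minority class can fall entirely inside the margin,
degenerating the decision function — most visibly for the one-dimensional
motif-only model, which otherwise scores at chance while its single feature
ranks targets well. Inverse-frequency weights restore the feature-level
ranking without touching kernel, cost or width. Scores are decision values
passed through a logistic link: a strictly monotone map to $[0,1]$, so
ROC/AUC and PPV are identical to what any calibrated probability would give,
while keeping evaluation deterministic and fast.

Evaluation is repeated two-fold cross-validation: the genes are split in
half at random, the model trains on one half (feature standardisation uses
training-fold statistics only — the test fold never leaks into the
transform) and scores the other; the AUC is computed per held-out fold and
averaged over 50 repeats by default (tests and the acceptance script use 2–3
repeats to keep runtimes proportionate; the estimator is the same). AUC is
computed from ranks (Mann–Whitney form, ties counted half), which equals the
trapezoidal area under the ROC. PPV is the fraction of true targets among
the top-$k$ predictions, $k$ defaulting to the number of positives. Folds
lacking a class are redrawn (up to 100 times); TFs with fewer than 10
positives are refused.

## Sensitivity profiling

Each profiled TF gets a target modification profile: the mean signal of its
target genes over 25 features (the 1-kb upstream window of the 14 windowed
marks plus the IR signal of the 11 acetylations), z-normalised per
modification across TFs. k-means with $k=2$ (Euclidean, best of 50 seeded
restarts) splits the TFs; the cluster with the larger mean absolute
normalised signal — more high and low values around its targets — is
labelled histone-sensitive. Mean |z| operationalises "larger variation"
robustly; a variance criterion gives the same split on well-separated
profiles. Differential profiles contrast targets against non-targets per
modification with Welch's t (unequal variances; the sign is target mean
minus non-target mean), and the modification correlation network connects
modification pairs whose differential profiles correlate beyond |r| > 0.5
across TFs.

## Comparative analyses

*Cross-PSSM cooperativity*: every TF's targets are predicted with every
other TF's motif score (chromatin features included, CV splits shared within
a row so differences are paired); a pair is flagged when another factor's
PSSM beats the TF's own by more than 0.02 AUC — the margin sits below the
0.03–0.04 improvements the approach is meant to catch while staying above
split noise at these sample sizes. *Condition comparison*: the same labels
(condition-B targets) are predicted once with condition-matched chromatin
features and once with mismatched ones, same splits. *Verified vs
non-verified sites*: genomic motif matches are split by ChIP evidence
(bound: gene P < 0.01; clearly unbound: P > 0.4, and at least 2 kb from any
verified site), per-site signals are the mean of covering probes (sites
without probe coverage widen to the nearest probe), and each modification is
contrasted by Welch's t. Because several sites in one promoter share most of
their chromatin context, treating them as independent observations inflates
the t-statistics; `classify_tfbs(dedupe_per_gene = TRUE)` keeps the
best-scoring site per gene and restores nominal calibration (the package's
null-calibration tests use it). No multiple-testing correction is applied by
default (the
published convention reports raw P < 0.01; a Benjamini–Hochberg flag exists
on the caller's side via `p.adjust`). *Binning*: contigs are tiled into
100-bp bins labelled by ≥1 bp peak overlap, and the same feature/CV
machinery runs at bin resolution. *Enrichment statistics*: one-sided
(greater) Fisher's exact tests for 2×2 enrichment and target-set overlap
(co-regulation, P < 0.05), two-sided Wilcoxon rank-sum for group attribute
contrasts.

## The synthetic world

Real ChIP-chip compendia are not bundled; a seeded generator builds worlds
with the same structure and known truth. Geometry: tandem cassettes of
intergenic spacer (200 bp), promoter (800 bp, matching the scan region) and
ORF (1000 bp) on one contig, ~2 kb per gene as in yeast; strands are random.
Background sequence is i.i.d. at 37% GC — sufficient for scanner validation,
though it lacks the low-complexity and dinucleotide structure of real
promoters. Each TF gets a PSSM with one dominant base per position
(probability 0.85 by default; 1.0 gives deterministic motifs). Targets are
independent Bernoulli draws (prevalence 0.05); target promoters of
direct-binding TFs receive a motif instance sampled from the PSSM, uniform
position and strand, with probability 0.8 (collisions between plants are
avoided by rejection). ChIP P-values are Beta(0.1, 1) for true targets and
Uniform(0, 1) otherwise, so the strict/loose cutoff trade-off of real target
calling (purer but fewer positives at stricter cutoffs) emerges naturally.

Chromatin tracks assign each (gene zone, modification) a unit-variance
Gaussian value — the upstream/IR zone and the ORF zone separately — and
probes (60 bp, tiling 85% of the genome with uniformly random gaps) read
their zone's value plus N(0, 0.25) probe noise. Targets of histone-sensitive
TFs (35% of factors) are shifted by +1 SD on an affected subset of 10
modifications (6 windowed + 4 IR). The first two windowed features play the
role of H3/H4 occupancy: they are excluded from the sensitivity shift and
instead lose 1.5 SD at probes covering planted binding sites, emulating
nucleosome depletion at bound sites. Under the two-condition design,
condition-specific TFs redraw their targets in condition B; each condition's
tracks carry the shifts of that condition's targets, while planted motifs
follow condition-A targets (binding specificity is condition-invariant).
The generator also guarantees that the sensitive and condition-specific sets
intersect when both are nonempty, so the condition analysis always has a
usable factor. For the cooperativity worlds the package's tests set
`sensitive_fraction = 0`, isolating the motif channel so that the indirect
binder's improvement comes only from its partner's PSSM.

What passing these simulations does *not* show: robustness to correlated
modifications, nucleosome-positioning structure, sequence composition bias,
probe-intensity artefacts, or indirect binding mediated by chromatin rather
than a partner motif. The generator's additive Gaussian world is the
intended validation substrate, not a claim about real chromatin.

## Numerical choices and degenerate inputs

Row-stochastic PSSMs are validated to 1e-9 (file input renormalised within
1e-6, rejected beyond); IC treats $0\log 0$ as 0 so a zero pseudocount is
safe; scanning uses pseudocount 0.01. Ties in PPV are broken by stable input
order; tied scores share average ranks in the AUC. k-means falls back to an
all-insensitive labelling (with a warning) when profiles are too degenerate
to cluster. Welch t is missing when a group has fewer than 2 members or both
variances vanish; constant columns are excluded from correlation networks.
All coordinates are 0-based half-open throughout; annotation input may
declare `# coords: 1-based` and is converted on read. Problem sizes in the
test suite (2000 genes × 20 TFs for model recovery, 900 × 60 for
clustering, 600 × 4 for cooperativity and site contrasts, 2–3 CV repeats)
were chosen as the smallest scales at which the planted effects are
comfortably detectable.

## Known limitations

The IR region approximates the array design of the original acetylation
data as the upstream intergenic interval per gene. Motif occurrence
P-values are not calibrated against a genome-wide score distribution (the
threshold is relative to the maximum achievable score). The pipeline's
`run_pipeline()` covers simulate/scan/signals/train/profiles/sensitivity;
the comparative analyses are exported functions composed directly. Expression,
hierarchy-level and PPI-degree attributes are accepted as given tables —
the package does not construct regulatory hierarchies or interaction
networks.
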