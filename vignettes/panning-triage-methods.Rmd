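---
title: "Models and methods behind panscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panscreen)
```

panscreen implements the computational side of a VHH phage-display discovery
campaign: simulated panning with known ground truth, read annotation,
liability screening, clonotype enrichment, two machine-learning triage
workflows, and the quantitative analyses attached to downstream assays
(epitope binning, footprinting protection, tumor growth inhibition). This
vignette explains the models, the defaults, and what the synthetic data can
and cannot tell you about real campaigns.

## The selection model

Panning enriches clones whose phage survive antigen capture and washing. We
model one round as a weighted multinomial resampling: a clone present at
count $n_i$ with dissociation constant $K_{D,i}$ receives selection weight

$$w_i = n_i \left( \frac{C}{C + K_{D,i}} + r \right),$$

where $C$ is the molar antigen concentration of the round and $r$ is a
non-specific wash-retention probability. The first term is Langmuir
fractional occupancy — the simplest physically grounded description of
equilibrium capture — and the additive $r$ models carry-over of non-binders
that survive washing. Next-round counts are a multinomial draw with
probabilities $w_i / \sum_j w_j$ at fixed sequencing depth. Two limits make
the model easy to reason about: as $C \to \infty$ every clone is captured and
weights become proportional to counts alone; as $C$ falls below the binder
$K_D$ range, relative occupancy differences — and hence selection — sharpen.

Defaults mirror a four-round campaign with rising stringency: $C$ =
100/50/25/10 nM and $r$ decreasing geometrically from $10^{-2}$ to
$10^{-4}$. Binder $K_D$ is drawn log-uniformly from 0.1–10 nM, non-binders
from 1–100 µM, with the binder cutoff at 100 nM; the gap between the class
ranges keeps labels unambiguous. The default sequencing depth is 50,000
reads per round: at 2,000 clones this gives round-3 binder counts of a few
hundred reads, so multinomial noise in the round-3-to-4 log-ratio stays well
below the $K_D$-driven signal. These are desk-scale stand-ins for
instrument-scale data; all are configurable.

## The synthetic library

Clones are combinatorial assemblies of fixed humanized frameworks (with a
camelid FR2) and random CDRs, prefixed by the amplicon anchor used to orient
reads. Two deliberate design choices make ground truth exact:

* **Liability-free by construction.** Random CDRs are drawn from an
  alphabet excluding Asn, Asp, Cys and Trp, and every CDR variant is
  rejected if its nucleotide sequence — in the context of its flanking
  frameworks — contains a nucleotide-level liability motif. A real library
  design screens its CDR diversities the same way; the consequence here is
  that a clone contains a disqualifying motif *iff* one was planted, so the
  liability screen can be tested at precision = recall = 1.
* **Sequence-determined binding.** Real binder labels derive from sequence
  through structure; a synthetic campaign must inject that dependence
  explicitly. `assign_affinities(binder_motif = "WGWG")` plants a short
  motif at a random interior CDR3 position of every binder. Because Trp is
  excluded from the background alphabet, binder labels become recoverable
  from sequence alone — by composition descriptors (KNN workflow) and by
  positional motif detectors (convolutional workflow).

What the generator does **not** emulate: PCR chimeras and indels, quality
score degradation, paired-end structure, clonal lineages and somatic
variants, affinity maturation within clonotypes, and avidity effects.
Passing tests therefore demonstrate the correctness of the pipeline's logic
under the model above, not its performance on any particular instrument run.

Sequencing is emulated as per-base substitution errors (default 0.1%) with a
constant quality string, plus an optional fraction of anchor-less random
reads standing in for spike-in diversity material; both only exercise the
filtering and fuzzy-matching paths, not base-caller realism.

## Read annotation

Reads are oriented by exact anchor search on both strands (reads whose
anchor itself is hit by an error are counted as anchor-less, exactly as a
real amplicon pipeline would drop them). The payload is translated in frame
0 and frameworks are located in order — exact match first, then fuzzy
matching tolerating up to 2 substitutions per framework, which absorbs the
translated substitution errors expected at a 0.1% nucleotide error rate
over 11–32-residue frameworks. CDRs are the inter-framework gaps;
annotation fails (flagged, never silently dropped) on missing or ambiguous
frameworks, empty CDR gaps, or when the frameworks do not tile the
sequence. Coordinates are 0-based half-open throughout.

## Liability screen

The registry covers the developability categories a library design screens
for: deamidation (N[GST]), isomerization (D[GST]), the N-glycosylation
sequon (N[^P][ST]), unpaired CDR cysteines (flagged when the CDR cysteine
count is odd), the N-terminal pyroglutamate precursor (E/Q at position 1 —
reported but never disqualifying, since virtually every VHH begins with
E/Q), cryptic splice-site consensus motifs (donor GGT[AG]AG; acceptor
[CT]{6}NCAG), and restriction sites, with SfiI (GGCCN5GGCC, the cloning
enzyme) in the default set and EcoRI/NotI as optional extras. Protein-level
scanning is CDR-restricted by default because the frameworks are fixed and
pre-screened. The patterns are transparent literal/regex consensus rules; a
position-weight-matrix splice scorer is deliberately out of scope.

## Enrichment workflow

Clonotypes are keyed on exact CDR3 amino-acid identity — with a single
fixed framework there is no V-gene component to the key. The enrichment
statistic is a pseudocount-regularized log2 frequency ratio between rounds
3 and 4,

$$s = \log_2 \frac{f_4 + p_4}{f_3 + p_3}, \qquad p_r = \frac{c}{N_r},$$

with pseudocount $c = 0.5$ reads. The log-ratio is standard, antisymmetric
under swapping rounds, and finite for clonotypes absent from one round.
Candidates are the top 20 clonotypes by score (configurable; ranking by
round-4 abundance instead of ratio is a one-line change on the sorted
table), taking up to the three most round-4-abundant variants of each. All
tie-breaks are deterministic and documented on each function.

## ML triage workflows

**Descriptors + PCA + KNN.** The descriptor set is small and interpretable:
20 amino-acid frequencies, length, mean Kyte–Doolittle hydropathy, net
side-chain charge at pH 7 (D/E −1, K/R +1, H +0.1), aromaticity, and CDR3
length when annotation is available. Features are z-scored with population
standard deviations (constant columns map to 0 and are flagged), projected
by PCA with a deterministic sign convention, and classified by k-nearest
neighbours. Hyperparameters (components ∈ {2, 5, 10, 15}, odd k ∈ {3, 5, 7,
9}) are tuned by 5-fold stratified cross-validation on the F-beta score
with β = 1 by default — the weighting between precision and recall is a
campaign-level economics decision, so β is exposed rather than fixed.
Normalization and PCA are refit inside every fold, keeping validation
scores honest.

**Convolutional classifier.** Sequences are one-hot encoded over the
20-letter alphabet (realised as integer lookups: with one-hot inputs a
convolution is a sum of weight-row gathers, which keeps pure-R training
fast) with a 21st zero-pinned padding symbol. The architecture is the
smallest that reliably solves motif-separable fixtures: one convolutional
layer of 16 motif detectors of width 5, global max pooling, ReLU, a dense
hidden layer of 32, and a sigmoid output. Training is mini-batch Adam
(batch 64, 30 epochs, step 0.02) on binary cross-entropy; full-batch
training was rejected because 30 epochs then means only 30 gradient
updates, too few to converge. After every epoch the model is scored on a
stratified validation split (20%) and the checkpoint with the best
validation F1 is returned — earliest epoch on ties, so the selected
checkpoint is deterministic given the seed. The contract of these defaults
is recovery of planted structure, not any particular weight values.

Training sets combine simulated SPR labels (class-balanced, with a default
5% label-flip rate emulating borderline-affinity miscalls), enriched
round-4 variants supplementing the positive class (default: variants of the
top-20 clonotypes), and a seeded random library sample as negatives;
conflicting labels resolve to binder and are counted. Predicted binders are
thresholded on probability (default 0.5) and diversified by k-medoids (PAM)
on normalized Levenshtein distance, taking each cluster's
highest-probability member (ties lexicographic).

## Assay analyses

**Epitope binning.** Relative competition responses below 0.30 of the
no-competitor control (configurable; instrument software adjusts this
per-campaign) are called blocked; the matrix is symmetrized by logical OR
of the two injection orientations, and antibodies with identical
symmetrized blocking rows share a bin (Hamming ≤ 1 grouping is available
via `max_mismatch`). Missing cells are excluded from row comparisons. Bins
are numbered by size, so bin numbering — though not membership — can differ
from a bench report's ordering.

**Footprinting.** Per-peptide modification fractions are modified-over-total
XIC areas. The percent fold-change between bound and unbound states is the
signed difference over baseline, $100(\bar{m}_b - \bar{m}_u)/\bar{m}_u$; a
ratio convention is exposed via `method = "ratio"` since the phrase
"percent fold-change" is used both ways in practice. Significance is a
two-sided two-sample Student's t with pooled variance (the classical
Student form, not Welch), and calls are protected/deprotected by the sign
of the change at p < α. No multiple-testing correction is applied by
default — identification-level FDR control belongs to the upstream
peptide-ID step — but Benjamini–Hochberg is available.

**Tumor growth inhibition.** $\mathrm{TGI} = [1 - (T_t - T_0)/(C_t - C_0)]
\times 100\%$ on group-mean volumes; undefined when the control group did
not change, and invariant under common rescaling of all four volumes.

## Numerical and engineering choices

* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; pipeline stages derive their seeds from a master seed
  and the stage name, so a rerun of the same configuration is
  byte-identical (asserted on file checksums in the tests).
* Degenerate inputs fail loudly: all-zero selection weights, empty rounds,
  single-class folds or splits, zero unbound means, and unchanged control
  volumes are errors, not NaNs.
* Formula-level operations (F-beta, enrichment log-ratio, modification
  fraction, percent fold-change, pooled t, TGI) are tested against
  independent closed-form oracles at $10^{-9}$ tolerance.
* Test and example problem sizes (2,000-clone campaigns, 50,000 reads per
  round, 20-seed enrichment replicates, 3-seed ML medians) were chosen as
  the smallest scales at which the selection signal, and not sampling
  noise, determines the outcomes.

## Known limitations

Annotation is substitution-only (no indel-tolerant framework alignment);
clonotyping is exact-CDR3 (no distance-based clustering or lineage
inference); the conv classifier is a motif detector, not a protein language
model, and will not capture long-range epistasis; the selection model has
no amplification bias, no phage-competition saturation, and no round-level
bottleneck variance beyond multinomial sampling; and epitope-bin numbering
depends on bin sizes, not on any biological ordering.
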