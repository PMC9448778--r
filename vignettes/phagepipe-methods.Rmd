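---
title: "Discovering and profiling gut phages from bulk metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and profiling gut phages from bulk metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepipe)
```

## The problem

Most sequencing reads in a whole (bulk) gut metagenome come from
bacterial chromosomes and plasmids, not from viruses. Recovering a
trustworthy catalogue of double-stranded DNA phage genomes from such
data therefore hinges on *specificity*: a discovery rule tuned to admit
as few bacterial or plasmid contigs as possible, even at some cost in
sensitivity. `phagepipe` implements that discovery rule, the catalogue
construction around it (species-level vOTUs, family-level viral
clusters), CRISPR-based host prediction, hallmark-gene abundance
profiling, and the downstream ecology and metadata-association
statistics — all exercised end to end on synthetic communities in which
the true answer is planted and therefore known.

## The discovery model

A contig is called a phage only if it passes **all six** of the
following criteria, evaluated in a fixed order (the first failure is
reported for diagnostics, but all six are always computed):

1. **Size** — at least 10 kb; typical dsDNA phage genomes are larger.
2. **Viral k-mer signal** — a per-contig p-value at most 0.05. In
   production this comes from a k-mer–based viral classifier; the
   synthetic generator supplies p ~ U(0, 0.05) for phages and
   U(0.05, 1) for everything else, through the same table interface an
   external tool would use.
3. **Hallmark genes** — at least one viral hallmark gene (terminase,
   capsid, portal, ...) and no plasmid hallmark gene.
4. **Bacterial housekeeping** — no single-copy bacterial marker gene
   and no rRNA gene.
5. **Database comparison** — not more genes hitting a plasmid protein
   database than a viral one. Ties keep the contig: exclusion requires
   strictly more plasmid hits.
6. **Provirus fraction** — at least 80% of the contig must lie in its
   viral region (see below).

Thresholds printed with a strict inequality ("> 130 bp", "> 97%",
"> 20% of clusters") are implemented strictly; boundary values fail.

**Circularity.** Complete genomes are recognised by terminal
redundancy: the longest ungapped suffix–prefix overlap longer than
130 bp with identity above 97%. The search is substitution-only; an
assembler that duplicated a genome terminus will reproduce it nearly
verbatim, and allowing indels would buy little while making the scan
quadratic in a second dimension. The scan is capped at a 5 kb overlap
(`max_overlap`), far above any real terminal repeat.

**Provirus fraction.** As a stand-in for database-driven provirus
annotation, the fraction is the span from the first to the last
viral-evidence gene (hallmark or viral-database hit) within the widest
marker-free run, extended to a contig end only when the boundary gene
itself is viral, divided by contig length. A fully viral contig scores
1; a 30 kb prophage island inside a 100 kb host contig scores about
0.3 and the whole contig is (correctly) rejected.

**Linear recovery.** Draft genomes that are not circular are recovered
by comparison against complete genomes: a linear contig is a candidate
when more than 40% of its genes align (protein level, alignment score
at least 100 under BLOSUM62, a stand-in for an E-value cutoff) to the
genes of some complete genome and its length is >70% and at most 120%
of that genome. The reference set is the pipeline's own completes plus
an external database of known complete phage genomes — the synthetic
generator emits the planted species as that database, playing the role
a public collection of complete viral genomes plays in production.
Candidates must still pass all six criteria on their own annotation.
Completeness is the length ratio to the matched complete genome, with
conventional tiers (high ≥ 90%, medium 50–90%, low < 50%); low-quality
calls and calls with contamination (fraction of marker/rRNA genes)
above 10% are dropped.

## Catalogue construction

**vOTUs.** Genomes are clustered greedily: sort by quality tier then
length, and join the first established centroid matched at ANI ≥ 95%
with ≥ 85% of the genome aligned, else seed a new cluster. ANI is
estimated by cutting the query into 1 kb fragments and placing each on
the target by exact 15-mer seeding plus ungapped extension (both
orientations); fragments aligning at ≥ 80% identity contribute. The
production pipelines this emulates use two tools for the same
thresholds (a dereplication pass and a reference re-clustering); one
greedy pass with one algorithm is simpler and testable against an
exhaustive all-pairs clustering.

**Protein clusters and viral clusters.** All-vs-all protein alignment
(prescreened by shared amino-acid 6-mers) builds a score-weighted
graph; Markov clustering (MCL, inflation 2, expansion 2) partitions it.
The MCL implementation is the canonical one: self-loops at the column
maximum, column normalization, then alternating expansion (matrix
squaring) and inflation (elementwise squaring with renormalization and
pruning below 1e-5) until the matrix change falls under 1e-8; clusters
are the connected components of the attractor's non-zero structure.
vOTU pairs sharing strictly more than 20% of their protein clusters —
shared fraction |A ∩ B| / min(|A|, |B|), the symmetric choice among the
candidates (union or per-phage directional are the alternatives) — are
linked, and viral clusters are the single-linkage components of that
graph.

**Taxonomy and lifestyle.** A family is voted when the most common
per-protein best-hit family covers strictly more than 20% of the
phage's proteins; ties or lower shares give "unclassified". A phage is
temperate when its temperate score exceeds 0.8 — here an
annotation-based score (integrase-like marker present), with any
externally computed score accepted through the same argument — or when
it aligns to a bacterial genome over more than 1000 bp at more than
95% identity.

## Host prediction

CRISPR arrays are detected by a greedy seed-and-extend rule: an exact
20-mer occurring at least three times with consecutive spacings of
40–160 bp seeds an array; repeat boundaries extend while the column is
unanimous across copies; repeats must stay within 20–50 bp and spacers
within 20–110 bp. Stronger seeds (more copies) are claimed first,
which prevents a chance 3-copy seed from truncating a true 5-copy
array. Spacers of 25–100 bp are matched to phage genomes on both
strands at edit distance ≤ 1 (one mismatch *or* one indel) with more
than 95% of the spacer aligned; a 1-indel hit on a 30 bp spacer covers
29/30 = 0.967 and is accepted. Host genera are the source genera of
matching arrays minus a fixed exclusion list of non-intestinal genera;
exactly one genus makes a specialist, several a generalist. Contigs
without a taxonomy label can receive one by alignment to labelled
reference genomes (> 90% identity over > 70% of the contig).

## Abundance quantification

Reads are mapped only to the viral hallmark genes of vOTU
representatives — deliberately, so that reads from horizontally
transferred or host-derived genes cannot inflate viral abundance. The
mapper is seed-and-extend (21-mer seeds, both orientations) and
accepts hits at ≥ 95% identity over ≥ 90% of the read; equal-best hits
in different vOTUs discard the read rather than splitting it, again to
avoid over-counting. Abundance is RPKM: count / (VHG kb) / (million
total reads); VC-level profiles sum member vOTUs; detection is at
least one mapped read (no threshold is printed anywhere for this, so
the weakest defensible rule is used); relative abundance divides by
the per-sample sum.

## The synthetic benchmark

`generate_community()` plants, by default: 10 circular phage species
(20–40 kb, 2–4 hallmark genes, 40% temperate, 150–300 bp terminal
repeats), 20 linear drafts (75–100% truncations of the species at 1%
nucleotide / 1% protein divergence), 20 plasmids, and 30 bacterial
contigs of which 5 carry an embedded prophage and 10 carry CRISPR
arrays whose spacers are lifted (with at most one planted edit) from
the phage species matching the contig's genus. Annotation evidence is
written by the generator itself — this is the pluggable-table contract:
the discovery module consumes annotation flags and a k-mer p-value,
never raw homology searches.

**Noise model.** With probability 2% (per contig) one uniformly chosen
gene flag in one uniformly chosen evidence channel is flipped, and
independently with probability 2% the contig's k-mer p-value is
redrawn from the opposite class. This emulates a single upstream tool
occasionally misclassifying one gene or one contig. A per-gene,
per-flag Bernoulli model at the same nominal rate would corrupt
essentially every contig (a 25-gene contig would gain a spurious flag
with probability ≈ 40%), which matches no real annotation stack and
leaves no usable dynamic range between clean and noisy conditions.

**Cohort model.** `generate_cohort()` draws genus abundances
log-normally (genus-specific means, sd 0.6 on the log10 scale), forms
each vOTU's abundance as α·(host genus abundance) + (1 − α)·independent
log-normal noise with α = 0.8 for specialists and 0.2 for generalists,
multiplies in planted metadata effects as 10^(β·x) (β on the log10
scale, x standardized), and zero-inflates at a per-sample detection
probability of 0.6 — mirroring the sparsity of real per-individual
virome profiles. Defence-system abundance is a monotone affine
function of the realized virome Shannon diversity plus Gaussian noise
(sd 0.15), so the tertile comparison and per-system correlations have
a planted positive answer.

The expected phage–host correlation at a given α
(`expected_coupling_correlation()`) is a Monte-Carlo reference value:
the same generative model and the same correlation procedure run on a
large internally seeded cohort. A closed form for the Spearman
correlation of a zero-inflated log-normal mixture after compositional
normalization is not tractable, and a reference value computed by the
definition itself is the honest alternative.

**What the generator does not emulate.** Read errors are
substitution-only (no indels or quality scores), genes do not overlap,
proteomes of unrelated species share no homology, and there is no
strain-level microdiversity or assembly artefact. Passing tests
therefore demonstrate that the *rules* are implemented correctly and
are recoverable under controlled noise — not that the pipeline's
sensitivity on real assemblies equals the synthetic one.

## Statistics

Shannon diversity uses the natural logarithm (the convention of the
standard community-ecology software). Bray–Curtis is
1 − 2·Σmin(a,b)/(Σa+Σb). Phage–host Spearman correlations include
vOTUs above 0.01% and genera above 0.5% mean relative abundance; a
sample is excluded for a pair when **both** members are zero
(co-absence); the stricter either-zero rule is available as a switch
since the underlying prescription is ambiguous. Group comparisons use
the two-sided rank-sum test, exact by enumeration up to a pooled n of
12 (midranks make this valid under ties), otherwise the tie-corrected
normal approximation.

The association workflow log10-transforms relative abundance with a
pseudocount of half the smallest non-zero value (zeros map to a finite
floor just below the observed range; excluding zero samples is the
documented alternative), runs one OLS slope test per (feature,
variable) pair, applies Benjamini–Hochberg correction jointly over all
pairs, then fits each feature on its gated variables and prunes them
by bidirectional stepwise AIC starting from the full model (the
default behaviour of the standard `step()` tooling); survivors are
significant at coefficient p < 0.05. PERMANOVA uses the
McArdle–Anderson formulation — Gower-centred G = −½·J·D²·J, hat matrix
from the intercept-plus-variable design (dummy-coded for categorical,
regression form for continuous variables), pseudo-F from the trace
decomposition — with p-values from label permutations,
(1 + #{F* ≥ F}) / (n_perm + 1). Per-variable explained variance is
reported as PERMANOVA R²; a stepwise distance-based redundancy
analysis is out of scope and this R² is the provided analogue.

## Numerical and design choices

* Strict inequalities wherever the rule is printed as strict;
  boundary fixtures (130 bp overlap, 0.20 shared fraction, 0.20
  taxonomy share, 24/101 bp spacers) are tested to fail.
* Criterion 5 ties (equal database hit counts) keep the contig.
* Greedy clustering order (tier, then length, descending) makes
  clustering deterministic; MCL tie-breaking is deterministic because
  expansion/inflation are deterministic and components are read in
  column order.
* Tertile boundaries use empirical quantiles with ties assigned to the
  lower group.
* All generators are pure functions of their seed; `run_pipeline()`
  writes byte-identical outputs on reruns with the same seed.
* Problem sizes in the test-suite and acceptance runs (default
  community of 80 contigs, cohorts of 500 samples, 100-sample
  PERMANOVA at 9999 permutations, calibration over 20 seeds) were
  chosen to exercise every rule at meaningful statistical power on a
  single CPU.

## Known limitations

* The six criteria consume annotation *flags*; the quality of a real
  run depends entirely on the upstream annotation tools plugged into
  those tables.
* ANI estimation is ungapped after exact seeding, which under-aligns
  highly indel-divergent genome pairs; at the 95% species threshold
  this is immaterial, but the estimator should not be used near the
  80% fragment-identity floor.
* CRISPR detection assumes near-identical repeat copies (unanimous
  column extension, Hamming-compatible seeding); heavily degenerate
  arrays are better supplied from an external prediction table, which
  every host-prediction entry point accepts.
* PERMANOVA here handles one variable at a time (plus intercept);
  covariate-adjusted multi-term designs are out of scope.
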