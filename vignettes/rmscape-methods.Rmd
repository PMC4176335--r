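---
title: "Detecting restriction-modification systems from gene neighborhoods: models and methods"
author: "rmscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting restriction-modification systems from gene neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Restriction-modification (R-M) systems pair a restriction endonuclease
(REase), which cleaves DNA at a recognition site, with a methyltransferase
(MTase) that protects the host's own sites; Type I systems add a
DNA-specificity (S) subunit, Type IIC fuses both activities into one
polypeptide, and Type IV REases cleave *methylated* sites and need no
cognate MTase. Because the two activities must be co-inherited to avoid
self-restriction, the genes of one system are almost always adjacent, which
makes gene-neighborhood co-localization a reliable detection signal in
annotated genomes. `rmscape` implements that comparative-genomics pipeline
end to end: role assignment against a labeled reference library, neighborhood
assembly of systems, solitary-component calling, association with mobile
genetic elements (MGEs), competence machinery, CRISPR spacers, positional
core-/pan-genomes, integration-region sizes, and pairwise dN/dS screening.

The package also ships a deterministic simulator that generates every input
with a machine-readable truth table. All quantitative claims made by the test
suite and the acceptance script are computed on those synthetic study
conditions, never asserted from literature values.

## Distance semantics and the three-band classification

All neighborhood rules operate on *gene-rank offsets*: adjacent genes are 1
apart; circular replicons take the shorter arc, linear replicons the plain
difference; strand is ignored throughout. Printed thresholds map directly
onto comparisons:

* components less than 4 genes apart (offset ≤ 3) chain into one system;
* an unassigned MTase/REase whose nearest cognate is at least 10 genes away
  is *solitary*;
* the band in between — cognate at offset 4 to 9 — is reported as
  *ambiguous*, a category we make explicit because the two printed
  thresholds leave it undefined. Nothing is silently dropped: every
  REase/MTase/S gene ends in exactly one of {system member, solitary,
  ambiguous}, and the test suite asserts this partition.

An alternative reading of "N genes apart" counts intervening genes rather
than rank offsets; we adopt rank offsets (`max_gap` and `solitary_gap` are
ordinary function arguments, so the alternative is one integer away).

Curation of redundant detections is handled by the chaining itself: extra
same-role genes within reach of an existing cluster are absorbed as
additional components rather than emitted as second systems, and clusters
that mix R-M types are flagged `mixed` and excluded from the census rather
than guessed at. Completeness means REase + MTase present; Type IIC genes
(both functions on one polypeptide) and Type IV REases (no cognate MTase
exists by definition) are complete as single genes — we extend the
completeness flag to Type IV deliberately, since a Type IV entry cannot
acquire any further component. M+S-only Type I clusters are recorded as
incomplete systems and excluded from complete-system counts; both tallies
are exported. Ambiguity between Type II and Type IV REases is resolved from
genomic context — a compatible MTase within the assembly range makes the
gene a Type II REase, otherwise a Type IV entry — and is only triggered when
the two reference classes score within a factor of two of each other, so a
confident call is never overturned by an incidental weak cross-hit. The same
concern shapes the multi-signal rules: the Type IIC dual-function call and
the integron integrase flags only consider hits at or above 40% identity —
the identity of the reference library's own most divergent members — because
two faint chance similarities on one long protein must never combine into a
positive call.

## Similarity searches

Profile-HMM searches are replaced by best-hit similarity against a labeled
reference library (FASTA headers carry `role=` and `rm_type=` tags), with a
pluggable hit-table contract: BLAST outfmt-6 tables can be ingested in place
of the built-in aligner (`readBlastTab()`), preserving every downstream
threshold. The built-in aligner is Biostrings dynamic programming under
BLOSUM62 with affine gaps 10/0.5, in two modes: Smith-Waterman local
(BLASTP-like searches) and end-gap-free global (bidirectional best hits).
Statistics are defined over alignment columns: identity is matches over
columns, similarity additionally counts positive-scoring substitutions —
this is the operational definition behind the "80% similarity" ortholog
filter, which is otherwise matrix-dependent and not derivable from the rule
itself. The e-value surrogate is a Karlin-Altschul-style transform of the
raw score scaled by the pair's search space, with fixed constants; it is
only ever compared against thresholds (10^-3 for role calls, 10^-4 for
pan-genome edges), so any monotone surrogate yields identical decisions.
Role thresholds additionally require 50% reference coverage for Type II/IIC
REase and Type IV REase hits, the divergent families for which alignment
coverage is the operative quality control.

All-vs-all searches are seeded by a shared-k-mer prefilter (two distinct
4-mers). Unrelated random proteins essentially never pass it, homologs above
roughly 60% identity essentially always do; the simulator keeps planted
homolog identities well above that regime, and the limitation (remote
homologs below ~50% identity may be missed by the prefilter, unlike a full
BLAST search) is a deliberate trade of sensitivity for a fully self-contained
and fast pipeline.

## Clustering

Two family-building algorithms are provided. Markov clustering iterates
expansion and inflation on the column-stochastic similarity matrix
(self-loops at the maximum incident weight, convergence at 1e-6 change,
at most 200 iterations, non-convergence is an error); it is used for
reference-family granularity exploration (inflation near 1.4 mirrors the
regime where curated REase/MTase families are recovered). Single-linkage
clustering takes connected components over edges passing an identity
threshold with coverage of more than 80% of the smaller protein; it builds
the stringent (80% identity) and relaxed (40%) pan-genomes and the
80%-identity families used for dN/dS pairing. Because stringent edges are a
subset of relaxed edges on the same hit table, stringent families always
refine relaxed ones; the acceptance suite checks this on every seed.

## Core genomes and integration regions

Orthologs between two strains are bidirectional best hits (end-gap-free
global alignment; hits below 80% similarity or above 20% length difference
discarded; ties broken lexicographically and flagged), retained as
*positional* orthologs only when at least 4 other BBH pairs lie within 5
genes upstream or downstream of both members. Requiring support around both
members is the stricter of the two possible readings; it is a single
config switch. With the support threshold below half the neighborhood
diameter, orthologs at rearrangement-block edges survive: the clade
simulator plants one inversion per strain and the planted core is still
recovered exactly. The core genome is the intersection over all
pivot-versus-strain positional-ortholog lists (pivot = lexicographically
first genome id by default); below 7 strains the function warns.

Integration regions measure acquired-segment sizes: for each R-M element
(complete system or solitary gene) the flanking pair of consecutive core
genes is found and the region length L is the number of genes strictly
between the flanks, so a planted k-gene insertion yields L = k exactly.
Regions whose flanks are not consecutive core genes in at least one other
strain sit at rearrangement breakpoints; they are flagged and excluded from
size statistics (the clade simulator plants "probe" insertions at pairs
disrupted by another strain's inversion precisely to exercise this rule).
The species-level direction test — are complete systems in smaller regions
than solitary genes? — is a sign test: one-sided binomial on the number of
species with median(complete) < median(solitary), ties dropped.

## Mobilome analyses

MGE spans (prophage/ICE/IME) are inputs, consumed as rank-interval tables;
their de novo detection is out of scope. A system is inside an MGE only if
*all* its components fall within the span; straddling systems count as
chromosomal (conservative) and are flagged. Observed/expected enrichment
follows the construction: expected(type, category) = total systems of the
type × fraction of all systems in the category, so expected counts per type
sum to the type total by construction, and a chi-square goodness-of-fit
p-value accompanies each category. Chromosomal solitary tallies exclude
prophage-resident genes, which are tallied with their prophage. Plasmids are
MOB+ with at least a relaxase (or a complete conjugation gene set, a
config-visible list), else MOB-. Integron integrases require the
simultaneous tyrosine-recombinase and integron-signature signals on one
gene. Competence loci are maximal runs of competence-component genes with
consecutive offsets of at most 5 and at least 6 members whose mandatory
component set (all but PilU/ComC) is complete.

CRISPR spacers are matched by ungapped local alignment (gaps priced out of
the dynamic program) on both strands; identity is computed over the aligned
span and the length difference is the unaligned fraction of the spacer.
Matches with identity ≥ 0.9 and length difference < 0.1 are retained, with
the exact (identity 1, full span) tier flagged separately. A 32-nt spacer
therefore tolerates 3 mutations (29/32 ≈ 0.906) but not 4 (0.875), and a
spacer whose terminal quarter does not match fails on length. The BLASTN
e-value gate of the original protocol has no exact analogue in an ungapped
scorer; the two retention thresholds are treated as the operative filters.

## dN/dS estimation

Within-family pairs (single-linkage at 80% identity, singletons dropped) are
back-threaded from protein alignments to codon alignments (every protein gap
becomes a triplet gap; terminal stop codons are stripped; any translation
mismatch is an error naming the codon). Two pairwise estimators are
implemented from their published descriptions:

* **NG86 counting**: per-codon synonymous-site fractions with
  stop-codon-producing changes excluded from the opportunity count,
  differences averaged over all substitution pathways that avoid stop
  codons (equal weighting), Jukes-Cantor correction. An exhaustive
  pathway-enumeration oracle in the test suite reproduces it exactly.
* **Yang-Nielsen approximate method**: transition/transversion ratio
  estimated from fourfold-degenerate and nondegenerate site classes with
  K80 correction; site and pathway counting weighted by kappa and F3x4
  position-specific codon usage; K80-style distance correction applied
  separately to the synonymous and nonsynonymous classes; omega updated
  iteratively to convergence (1e-8, at most 100 rounds). Pathway weights are
  averaged over both sequence orientations so the estimator is exactly
  symmetric.

Estimates with dS > 1 are saturated and discarded from summaries; dS exactly
1 is retained under the strict "greater than" reading. Omega is undefined
(NA) at dS = 0 and such pairs are excluded rather than imputed. Proportions
outside the distance-correction domain flag `saturated_overflow` with an
infinite distance. In simulations at 300 codons, t = 0.3, kappa = 2, the
counting estimator recovers the mean omega within ±20% across omega in
{0.1, 0.5, 1.0}; the Yang-Nielsen estimator is noisier near neutrality at
this length because its kappa ratio estimate is convex in the underlying
proportions (it is consistent: the bias vanishes by 2000 codons). The
acceptance recovery check therefore reports the counting estimator, and the
two agree within 5% on dS and dN in the kappa = 1 neutral parameterization.

## The simulator as the study conditions

`simulateDataset()` builds 20 genomes in two clades of 10 (so per-clade
summaries, which require at least 10 genomes, keep both clades). Every
genome carries Type II systems; Type I/III/IIC/IV systems, solitary genes,
an ambiguous-band pair, a prophage (with a resident solitary MTase), an ICE
(with a resident complete system), integron/competence/argo/cas markers and
MOB+/MOB- plasmids are planted on overlapping subsets so that every
co-occurrence test has both groups. Planted genes are founder copies at 90%
identity; solitary lineages use founders distinct from system founders so
pan-genome families separate cleanly. Background genes are random-codon ORFs
*rejection-sampled against the reference library*, so a background gene that
would pass any role-call threshold is redrawn at generation time — false
positive role calls on background are structurally impossible, and feature
blocks are separated by at least 12 background genes so planted spacings are
the only spacings. The generator re-verifies every planted constraint
against the emitted genome and aborts on violation.

`simulateClade()` (7 strains, 64 ancestral genes of 60-90 aa, divergence
t = 0.04 per strain at kappa = 2, omega = 0.2) plants per strain: one
complete-system insertion (2-4 genes), one solitary insertion (5-8 genes),
one background insertion, one deletion, one inversion (4 genes,
strain-specific position, non-overlapping across strains) and one breakpoint
probe. Insertion sizes are the true region lengths; the core truth is the
ancestor minus all genes deleted anywhere. Inversion blocks are deliberately
non-overlapping: overlapping inversions genuinely destroy positional
orthology in the overlap, so exact planted-core recovery would no longer be
a property of the method but of luck. Sequence lengths and clade size are
chosen so a 20-seed recovery study completes in minutes on one CPU; they are
small relative to real genomes, which is the main fidelity limit (below).

CRISPR spacers are 32-nt copies from a planted R-M gene: exact, 3-mutation,
4-mutation, reverse-complement and truncated-match variants, with interior
mutation positions so the ungapped local alignment cannot trim them away.

All randomness flows through R's Mersenne-Twister stream seeded per call
(the caller's RNG state is restored afterwards), which is deterministic
across platforms for a given R version; byte-identical reruns are asserted
by the determinism test.

## What passing tests do and do not show

The synthetic conditions give exact ground truth and demonstrate that the
implementation applies every rule precisely: perfect recovery on planted
features is a property of rule-consistency between generator and detector,
*not* evidence of real-world sensitivity. Real data add pseudogenes,
frameshifts, annotation errors, compositional bias, paralogy and remote
homology below the prefilter regime — none of which the simulator emulates
(deliberately: see Non-goals in each module). Numbers from real genome
collections would also depend on the reference library used; ours is
synthetic and labeled by construction.

## Numerical and degenerate-input choices

Tolerances: MCL convergence 1e-6; Yang-Nielsen omega iteration 1e-8;
Jukes-Cantor/K80 corrections return infinity outside their domains and flag
the estimate. Ties: best hits and family representatives break
lexicographically, with BBH ties flagged in the output. Empty replicons are
kept with a warning; empty result tables export as header-only TSVs with a
manifest row count of 0. Exact small-sample modes (full enumeration) are
used for the Spearman and Mann-Whitney tests up to n = 8 per group —
enumeration beyond that is combinatorially infeasible and the
t/normal approximations are accurate there — and the binomial test is always
an exact tail sum. Two-sided alternatives are the default everywhere except
the directional species-size binomial test. A Benjamini-Hochberg column is
emitted alongside raw p-values for transparency but never gates any result.

## Problem sizes used by the checks

The shipped study conditions are: one 20-genome dataset (about 290 genes per
genome including two plasmids) for detection, census, mobilome and
determinism checks; 20 independent 7-strain clades for core/pan-genome
recovery; 100 seeded 10-species region studies for the direction test; 100
seeded 300-codon pairs per omega level for estimator recovery; 1000 null
simulations per statistical test for type-I error calibration. These sizes
were chosen as the smallest at which each property is statistically
unambiguous.

## Known limitations

* The k-mer prefilter bounds sensitivity below ~50-60% identity; a real
  screen would use profile HMMs or full BLAST for remote homologs.
* Trans-acting (non-co-localized) R-M systems are not inferred, by design.
* The reference library is synthetic; role labels on real genomes are only
  as good as the library supplied.
* No phylogenetic correction in the association tests; counts from related
  genomes are not independent.
* Maximum-likelihood codon models (codeml-style) and site-specific omega are
  out of scope; only pairwise counting estimators are provided.
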