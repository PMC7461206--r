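---
title: "Models and methods behind pgfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pgfam analyses the expansion and expression divergence of a plant gene
family across two species: a diploid reference ("species A") and a
descendant whose genome was triplicated and then fractionated
("species B"). This vignette explains the models, the tunable parameters and
their defaults, the synthetic-data generator, and the numerical choices, so
that a user knows exactly what a green test does and does not establish.

## Family identification

A protein is a family member if it carries at least one of the four
conserved domains (I `SPNTDGI`, II `GDDC`, III `CGPGHGIS`, IV `RIK`).
Matching is Hamming distance over sliding windows — no indels — with a
per-domain mismatch tolerance defaulting to 1 for the long motifs (I, III)
and 0 for the short ones (II, IV). The asymmetry is deliberate: a 3–4 residue
motif at tolerance 1 matches essentially everywhere, so short motifs are
held exact while long motifs absorb one substitution. Motif strings and
tolerances are configuration (`pg_domain_motifs()`), not code.

Molecular weight uses average residue masses minus one water (18.02 Da) per
peptide bond. The isoelectric point solves net charge = 0 by bisection on
[0, 14] to |charge| < 1e-4, using an Expasy-style pKa set over the termini
and D/E/C/Y/H/K/R side chains. Signal peptides are consumed as an input
annotation column — predicting secretion signals is out of scope.

## Gene structure

Intron phases are computed from coding (CDS) exons only, in transcription
order: the phase of intron k is the cumulative coding length of exons 1..k
mod 3. UTR exons are excluded because phase is defined relative to codons;
this also resolves the common off-by-one between "exon count" and "phase
count" seen when a 5' UTR intron is present. A total coding length not
divisible by 3 raises a warning but still returns phases, since annotation
truncation is common in real gene sets.

## Phylogeny

Distances are Poisson-corrected protein distances with pairwise deletion:
for each pair, columns where either sequence has a gap/unknown (`-`, `X`,
`?`) are dropped, p = mismatches/compared, d = −ln(1 − p). p ≥ 1 produces an
infinite entry that tree building refuses — saturation is surfaced, not
patched.

Neighbor joining is the standard Saitou–Nei agglomeration. Two choices make
it deterministic and robust:

* ties in the Q criterion are broken by the lowest (row, column) index pair;
* negative estimated branch lengths are clamped to zero with the deficit
  moved onto the sister edge (the behaviour users know from MEGA), which
  preserves the path length between the joined nodes.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree per replicate, and attach to each internal bipartition of the
full-data tree the percentage of replicates containing it. Supports go on
the full-data tree rather than a consensus tree, matching how published
family trees display values. The default is 1000 replicates, configurable
down for tests.

Rooting is at the midpoint of the longest tip-to-tip path (backed by
phangorn's midpoint implementation, with node labels carried as supports).
The published analyses this package models do not state their rooting; the
midpoint is a neutral, deterministic choice and an outgroup can be used
instead by rooting before calling the ancestry step.

Clade assignment uses anchored reference tips: an unanchored tip inherits
the clade of the smallest clan that (i) has bootstrap support at or above
the threshold (50 by default; clans without a recorded support, such as the
root, are treated as trustworthy since there is nothing to test) and
(ii) contains anchors of exactly one clade. Clans mixing anchors of two
clades leave the tip unassigned rather than guessing.

## Ancestral-gene counting

On the rooted two-species gene tree, each node is labelled bottom-up:
*speciation* if its two child subtrees split cleanly into one all-A and one
all-B set, *pure* if only one species occurs below it, *duplication*
otherwise. Non-binary nodes are resolved deterministically (leftmost
pairing) first.

The minimal ancestral-gene count `n_total` is the number of speciation nodes
plus the number of maximal pure clades lying outside all speciation clades.
A maximal pure clade is a lineage whose counterpart in the other species is
absent — a loss there or a gain here; the ambiguity is flagged (the clade is
reported as an A-only or B-only branch), not resolved. `n_high` keeps only
speciation nodes with support strictly above the threshold (default 50),
reproducing the "at least N ancestral genes" reading of a bootstrap tree;
pure clades never enter `n_high` because the high-confidence count keys on
supported speciation nodes. Per clade c and species X the bookkeeping is
`loss_X = n_anc(c) − lineages_with_X` and
`gain_X = extant_X(c) − lineages_with_X`, which guarantees
`extant = n_anc − loss + gain`.

Whether published "at least N" counts include single-species clades as
ancestral lineages is generally figure-implicit; here the rule is explicit
and is recovery-tested against simulator truth (exact over 50 seeded
histories) rather than against any published figure.

## Tandem duplicates and Ka/Ks

Two family genes form a tandem pair if they lie on the same chromosome,
separated by at most one intervening family gene or at most 100 kb
(both configurable — "closely linked" is rarely quantified in the
literature), and their sequences align globally with identity > 80% and
coverage > 80% of the longer gene. For equal-length candidate pairs an
ungapped comparison is used as a fast path: at ≥80% identity an affine-gap
alignment of equal-length sequences never opens a gap under the default
scoring, and far below the threshold no realignment can bridge a 20-point
deficit; borderline or unequal-length pairs always get the full alignment.

Ka/Ks is Nei–Gojobori (1986), chosen because it is the classic
counting-method standard and fully reproducible: per-codon synonymous site
fractions from the standard code averaged over both sequences; codons
differing at 2–3 positions averaged over all minimal substitution pathways
with unweighted means, excluding pathways through stop codons (all pathways
are used if every one is blocked); Jukes–Cantor correction
d = −¾ ln(1 − 4p/3); p ≥ 3/4 flags saturation (NA). Mutations that would
create a stop codon count toward neither site class, matching a substitution
process that never fixes premature stops — this keeps the simulator and the
estimator consistent. Ka/Ks is the undefined sentinel (NA, rendered "——" in
TSV output) exactly when Ks = 0. Pairs needing alignment are codon-aligned
by back-threading the protein alignment onto the CDS.

## Subgenome retention

After a triplication, each reference-family gene is expected in three
subgenome copies, so the default retention percentage for subgenome s is
100·count(s)/(3·reference_family_size). This denominator is not always
stated in published work but is the one consistent with typical printed
values; the per-copy alternative 100·count(s)/reference_family_size is
reported alongside. Percentages are rounded half-up to one decimal —
base R's round-half-even would disagree with published tables.

## Expression

Relative expression is 2^−ΔΔCt with a reference gene and a calibrator
sample; Ct = "ND" (no amplification) maps to 0. A gene undetected in the
calibrator has no within-gene calibrator ΔCt; its ΔCt_calibrator is taken
as 0 (values become 2^−ΔCt), a documented convention that keeps such genes
comparable without inventing a Ct.

Paralog pairs are categorized with expressed set E(g) = tissues at or above
τ (default 0.05 on the relative scale) and fold threshold f = 2 — neither is
quantified in the literature this models; both are configuration. Rules in
order: both E empty → I; exactly one empty → IV; equal sets with all
per-tissue fold ratios < f → I; equal sets otherwise → II; different
non-empty sets → III. The partition is total, exclusive and symmetric
(property-tested on random matrices). Tissue-pattern groups are produced as
rule-based labels (silent / tissue-specific at dominance σ = 0.8 /
ubiquitous / multi-tissue) rather than by replaying anyone's manual reading
of a heatmap. Clustering is average-linkage on euclidean distances of
log2(x+1) profiles, which is deterministic.

## Promoter cis-elements

Promoters are scanned for IUPAC consensus motifs on both strands; every
match is reported with its 1-based plus-strand position, and summaries count
promoters containing an element (not hit counts), because "N promoters
contained element E" is the standard reporting unit. The shipped dictionary
holds literature-standard consensus strings for the commonly scanned plant
elements; consensus strings vary between database versions, so the
dictionary is data (a TSV) that users can replace with their own export, and
no attempt is made to reproduce database-specific counts.

## The synthetic-data generator

The simulator emulates the stated world of the family it models: 68
ancestral genes at the species split; species B receives three subgenome
copies each lost independently with probabilities (0.515, 0.662, 0.706) —
derived from observed retained counts 33/68, 23/68, 20/68 and ordered
LF ≤ MF1 ≤ MF2; a tandem rate of 0.08 per retained gene (≈7 tandem pairs in
a ~90-gene family); post-split duplication 0.05 (A) and 0.08 (B); a 0.08
chance that a lineage dies out in the diploid as well; branch scale 0.06
substitutions/site so paralog pairs stay above 80% identity; target dN/dS
0.2 (the middle of the observed paralog-pair range); five tissues with
category mix 5:7:1:8 (categories I–IV over 21 pairs); 2-kb promoters. No
generative model is published for any of this — all distributions are
stand-ins chosen once, and documented here, to produce data of realistic
shape.

Design points worth knowing:

* Biased fractionation is independent Bernoulli loss per subgenome copy;
  real fractionation is block-structured along chromosomes, which this does
  not emulate.
* Codon evolution is proposal + accept/reject (synonymous always accepted,
  nonsynonymous with probability ω, stop-creating changes rejected) rather
  than a rate-matrix exponential; at desk scale it is exact enough that the
  NG86 median over simulated pairs recovers ω within ±0.1.
* The four family domains are planted at fixed protein positions and frozen
  against mutation, so domain-scan recall is 100% by construction — a green
  identification test validates the scanner, not domain conservation in
  nature.
* Tandem copies are placed adjacently with a <10 kb gap; all other
  same-lineage copies are spread across chromosomes and all other neighbours
  sit >100 kb apart, so tandem recovery has an unambiguous truth.
* Expression categories are planted per gene; a gene can therefore belong to
  only one planted pair, and the emitted pair table is a maximal disjoint
  subset of the true duplicate pairs.
* The combined true gene tree joins lineage subtrees in a ladder that starts
  with a two-species lineage, so every single-species lineage remains its
  own maximal pure clade; if every lineage lost one species the counts would
  merge, a configuration the default parameters make vanishingly rare.
* "ND" is the missing-Ct sentinel throughout.

Everything is driven by one integer seed (per-emitter offsets of +1/+2/+3
keep the streams independent); identical config and seed give byte-identical
outputs.

## What the tests establish

Green tests establish: exact recovery of ancestral-lineage counts,
gains/losses and tandem pairs from simulator truth over 50 seeded histories;
NJ exactness on additive matrices up to 6 taxa against an exhaustive
topology enumeration with least-squares fitting; NG86 agreement with
hand-enumerated pathway counts and ω recovery within ±0.1 at Ks ≤ 0.5;
total/exclusive expression categorization and exact planted-category
recovery; and the published summary arithmetic (retention 16.2/11.3/9.8,
synteny 80.9/76.8, divergence 76.2%, the zero-substitution Ka/Ks row, the
87-gene chromosome total). They do not establish performance on real
genomes: the simulator has no indels in coding sequence, no intron
evolution, no block-structured fractionation, and its gene trees are true
trees — published genome-scale counts that depend on a real assembly are
deliberately out of the test surface.

## Known limitations

* Two species only; no reconciliation against a dated species tree.
* No multiple sequence alignment — gapped FASTA is consumed as-is, and
  simulated families are alignment-free by construction.
* NG86 only (no maximum-likelihood Ka/Ks); no sliding windows, no divergence
  dating from Ks.
* The promoter scanner is consensus-based; no position weight matrices and
  no motif discovery.
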