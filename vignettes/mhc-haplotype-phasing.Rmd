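---
title: "Pedigree-based phasing of MHC IIβ amplicon genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based phasing of MHC IIβ amplicon genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcseg)
```

## The problem

MHC class II β genes in the small-spotted catshark (*Scyliorhinus
canicula*) form a multigene family whose exon-2 alleles cluster into three
allelic lineages, A, B and C. Two primer sets genotype them by amplicon
sequencing: one co-amplifies A and B alleles, the other targets C. Because
amplicon genotyping is presence/absence — read counts do not resolve
dosage — an individual's genotype is an allele *set*, typically 3–6
alleles, and the assignment of alleles to chromosomes (the haplotype) is
unobserved. The questions this package addresses are those of the
underlying study design: do alleles of the three lineages co-segregate as
blocks from parent to offspring (tight linkage), how many distinct
parental haplotypes circulate in a set of families, is the C-locus copy
sometimes absent from a chromosome entirely (hemizygosity), and how
divergent are the alleles that travel together on one haplotype?

The package implements every computational stage: post-denoising filtering
of the variant-by-amplicon count table, lineage assignment, microsatellite
parentage, exhaustive pedigree-based haplotype phasing, haplotype
cataloguing with architecture checks, and within-haplotype diversity.
A seeded simulator generates all inputs with known ground truth.

## Genotype and haplotype model

A genotype records the observed A/B allele set, the C allele set, and a C
observation status: `present`, `absent` (the C amplicon worked but yielded
no allele — evidence the individual carries no C copy) or `missing` (no C
amplicon — never evidence of absence). A haplotype carries up to two A/B
alleles and at most one C allele. These capacities encode the study's
architecture conclusion — lineages A and B segregate in the same loci (one
region with up to two allele slots per chromosome) while C occupies a
separate locus — and are arguments (`ab_cap`, `c_cap`) so other
architectures can be explored. Whether the A/B region is one locus with
two copies or two adjacent loci is deliberately left open; the capacity
model covers both readings.

## Filtering and artifact classification

The filter chain runs in a fixed order: amplicon coverage (< 100 reads
removes the amplicon), variant maximum coverage (< 10 reads everywhere
removes the variant), off-target removal (best global-alignment identity
to the reference panel below 0.80), per-amplicon frequency (< 1% is an
artifact *in that amplicon* only), then artifact classification. All
thresholds are strict inequalities, so boundary values survive. Within an
amplicon, variants are visited in decreasing frequency: a variant one
substitution away from an already-accepted variant is an `artifact_1bp`; a
single-breakpoint concatenation of two distinct accepted variants is an
`artifact_chimera`. Multi-breakpoint chimeras are out of scope — the
upstream denoiser removes most chimeras, and single crossovers dominate
what remains.

The cross-amplicon rule demotes a variant in amplicons where its frequency
is below 25% of its median frequency in the amplicons where it is a true
allele *and* below an absolute cap of 10%. The absolute cap matters: an
allele legitimately co-amplified with three others sits near 25%
frequency, and without the cap it would be demoted wherever its carriers
elsewhere happen to be single-allele amplicons (median near 100%). The cap
encodes "low-frequency variant found at higher frequencies elsewhere"
without penalising balanced co-amplification. Both knobs
(`minor_fraction`, `minor_absolute`) are configurable.

The off-target identity floor of 0.80 is our choice: the original
workflow inspected alignments in a GUI and states no number. It sits well
below within-family allele divergence (p ≤ 0.37 implies identity ≥ 0.63
between true alleles — but each true allele is close to *some* reference)
and well above random-sequence identity (~0.45–0.55 after alignment).

Replicate discordance is reported, never auto-dropped; the decision to
exclude a sample stays with the analyst.

## Lineage assignment

Reference panels carry lineage labels. Diagnostic columns — fixed within a
lineage, absent from all other lineages at that column — are derived from
the aligned panel; a query matching all diagnostic bases of exactly one
lineage is assigned on that evidence. Otherwise the nearest reference by
nucleotide p-distance decides; an exact tie across lineages yields
`unassigned` with a warning. The original study's second evidence line
(phylogenetic networks) is replaced by nearest-reference distance: for
well-separated lineages (between-lineage divergence at least twice the
within-lineage divergence, as here) the decision boundary is the same, and
the rule is deterministic and testable. Assignment is to lineage only,
never to locus, since A and B share loci.

## Parentage

Parentage uses the classical likelihood-ratio (LOD) framework over
co-dominant microsatellites: per locus, the probability of the offspring
genotype given the candidate parent (Mendelian transmission times a random
draw for the other allele) over its unconditional Hardy–Weinberg
probability, natural-log-summed over loci. Allele frequencies come from
direct counting. The genotyping-error model is a simple mixture: with
probability `error_rate` the observed offspring locus is a random
Hardy–Weinberg draw, which turns exclusions into finite penalties. The
full simulation-based confidence machinery of dedicated parentage software
(Delta criteria, simulated genotype distributions) is intentionally not
reproduced; assignments require positive LODs consistent across the
single-mother, single-father and parent-pair analyses, and two same-sex
candidates within 0.1 LOD are flagged ambiguous rather than resolved.
Families are mother-defined because multiple paternity (sperm storage) is
the norm in this system; the minimum number of unsampled fathers per
family is the ceiling of half the largest per-locus count of non-maternal
alleles among offspring.

## Phasing by exhaustive bipartition search

For each parent the package enumerates every unordered pair of haplotypes
whose union is the observed allele set, respecting capacities. Because
dosage is unobserved, an allele may be placed on both haplotypes
(homozygosity), and a parent with a single C allele generates homozygous
and hemizygous placements. The search space is tiny (a parent has at most
4 A/B and 2 C alleles, giving at most a few dozen bipartitions), so the
per-family search over all combinations of parental bipartitions is exact.

An offspring is *explained* by a bipartition combination when its allele
set equals the union of one maternal and one paternal haplotype; C
evidence participates according to the observation status (`missing` C is
ignored, `absent` requires both contributions to be C-less). When the
father is unsampled, the offspring is explained when the remainder after
removing a maternal haplotype is itself capacity-valid; remainders are the
inferred external paternal haplotypes, clustered by content, with the
minimum external father count `ceiling(k/2)` for `k` distinct remainders.

Solutions maximise explained offspring, then minimise recombination
events. A recombination event is a single exchange at the A/B–C boundary
between a parent's two haplotypes — the only boundary observable at this
marker resolution — and an offspring explainable only through such an
exchanged haplotype costs one event. `multiplicity` counts the optima at
this level; when it exceeds 1 the phase is not fully identified and all
optimal mother pairs are reported (`alt_solutions`), so downstream
consumers can see the ambiguity rather than trust a silent pick.

Among equally optimal solutions the reported representative is chosen by
two further preferences, in order: (i) pairs in which both distinct
haplotypes are actually received by some offspring — a haplotype no
offspring could have received is a sign the pair is an artefact of the
search rather than of the data (this also makes true homozygous parents,
where both "haplotypes" are identical, preferred over subset variants);
and (ii) minimal total allele copies, i.e. an allele is placed on both
haplotypes only when the data force it. Remaining ties break on
lexicographic haplotype-key order, which makes every run byte-for-byte
reproducible.

### Recombinant frequency and eligibility

The recombinant frequency divides events by the offspring of *eligible*
parents only: a parent needs at least `min_offspring` (default 5) assigned
offspring, and its two haplotypes must differ in the C slot — a parent
whose haplotypes carry identical C content cannot reveal a C-boundary
exchange, mirroring the study's rule that the different-composition
condition applies to the C lineage. Unsampled external fathers are never
eligible (only one of their haplotypes is constrained by data).

### Hemizygosity

A parental haplotype with no C allele is marked `ABSENT` when at least one
offspring assigned that haplotype has C status `absent` — possible only
when the other parental contribution is also C-less, so the chromosome
demonstrably transmitted no C copy. If all such offspring are `missing`,
or a single C allele reached every offspring (homozygote and hemizygote
indistinguishable), the slot stays `UNKNOWN`. `missing` status never
counts as evidence.

### Catalog

The catalog collects unique haplotypes (by allele content) from every
parent with at least five assigned offspring, summed across families for
parents appearing in several, plus external haplotypes individually
observed in at least five offspring. Composition classes are `AB`, `AC`,
`BC`, `B-only` and `other`. The five-offspring reporting threshold
matches the study's exclusion of parents with fewer offspring.

## Diversity metrics

Within-haplotype diversity for haplotypes of two or more alleles is the
mean over allele pairs of (i) nucleotide p-distance, (ii) amino-acid
p-distance of the exon translations and (iii) Grantham functional
distance. p-distances use pairwise deletion: columns with a gap or
ambiguity in either sequence are excluded. Translation requires a
per-panel reading-frame offset (`auto_frame()` picks the first stop-free
frame); an internal stop codon is an error, not a silent skip.

The Grantham model is rebuilt from the published residue properties
(composition, polarity, molecular volume) and weights
(α = 1.833, β = 0.1018, γ = 0.000399), with the scale factor calibrated so
the mean of the 190 inter-residue distances is 100 — the convention under
which the classical integer matrix was tabulated. This yields the familiar
anchor values (minimum 5 for Leu–Ile, maximum 215 for Cys–Trp) after
integer rounding; a handful of published entries are known to differ by
±1 from any faithful recomputation due to rounding in the original
tabulation, and the formula is treated as authoritative. Functional
distance is the *mean* Grantham distance per compared site (not the sum),
which is the convention consistent with the study's reported magnitudes
(values 15–37 against a 5–215 matrix); a sum mode and a
peptide-binding-region site restriction are available but off by default.

UTR identity for the locus-architecture comparison is computed from
global pairwise alignment (match 1, mismatch −1, gap open 2, extend 1,
Biostrings conventions) as identical columns over aligned columns with
gap columns counted as mismatches.

## The simulator

`simulate_dataset()` generates, under one seed: a three-lineage allele
pool (defaults 5 A, 20 B, 4 C — the study's allele counts) with
between-lineage divergence 0.35 and within-lineage divergence 0.10
substitutions per site (chosen to bracket the study's within-haplotype
p-distances of 0.11–0.37); a haplotype pool of 14 haplotypes with 60%
lacking a C allele (the catalog's 9/14); mother-defined families with
Dirichlet-weighted multiple paternity; amplicon tables with multinomial
reads and injected chimeras, single-substitution errors, cross-sample
bleed-through (only alleles carried by other co-sequenced individuals can
leak in) and C-amplicon dropout (default study-like 0.30 where enabled);
and 11 microsatellite loci with six alleles each. Artifacts are injected
at within-amplicon frequencies of 1.5–4%: above the 1% frequency filter,
below any parent allele, so they must be caught by classification, not by
thresholds. The simulator never recombines haplotypes, which is what makes
"zero recombinants on simulator output" a meaningful end-to-end check.
Sequences are substitution-only by default (the study's exon-2 alleles are
length-conserved).

What the simulator does *not* emulate: read-level quality profiles, PCR
stochasticity beyond multinomial sampling, allele-specific amplification
bias, and indel variation. Passing the end-to-end tests therefore shows
the pipeline's logic is correct under the stated noise model, not that the
thresholds are optimal for any particular sequencing run.

## Worked-example fixtures

The printed study catalog (14 haplotypes with family provenance, offspring
counts and diversity metrics) ships as a plain-text table
(`study_haplotypes()`), and `study_families()` reconstructs the five
families implied by it: each listed parent carries its two listed
haplotypes and offspring are unions of one haplotype per parent at the
printed counts. Lineage labels not printed for the group-1 haplotypes were
inferred so that composition-class totals match the printed AB:3 / AC:2 /
BC:3 / B-only:6 and so that exactly the printed statements hold (C-bearing
haplotypes show the highest functional distances; four C alleles exist in
total). One typeset-ambiguous offspring count (haplotype H7) was resolved
to the value that makes every other printed count internally consistent.
Parents below the five-offspring threshold (mother 2, father 2, the minor
group-1 fathers) carry private synthetic haplotypes so that the catalog's
exclusion rule is exercised rather than assumed. The family #5 subset
(`family5_fixture()`) reproduces the study's worked example: mother 4 =
{17(B),11(A)} / {06(A),55(C)}, father 1 = {35(B),41(B)} / {03(A),16(B)},
father 3 = {68(B),69(B)} / {67(B),45(C)}, zero recombinants.

```{r family5}
fx <- family5_fixture()
phase_family(fx$family, fx$genotypes)
```

## Problem sizes and numerical choices

The test-suite simulations use 2–6 families of 4–13 offspring and read
depths of 300–3000; the phasing-recovery properties run over 100+ seeded
families, and parentage power over 200 simulated trios with 8 informative
loci. These sizes were chosen to match the study's scale (five families,
5–20 offspring each) while keeping the whole suite comfortably
reproducible on a laptop. Frequencies are compared with strict
inequalities throughout; alignment scores use match 1 / mismatch −1 / gap
open 2 / extend 1 everywhere an alignment is needed; all randomness flows
from a single user-supplied seed.

Two sequence-level checks (the H1 allele-pair distances and the A-vs-B
3′-UTR identity) require the deposited GenBank sequences, which are not
redistributed here; `analysis/00_download_genbank.R` fetches them when a
network is available, and the corresponding acceptance tests look for the
fetched files under `inst/extdata/genbank/`.

## Known limitations

Phasing identifies haplotypes only up to what presence/absence segregation
can resolve: parents sharing alleles with their mates, families with few
offspring, and truly homozygous parents leave residual ambiguity that is
surfaced through `multiplicity` rather than resolved by fiat. The
recombination model sees only the A/B–C boundary; exchanges within the
A/B region are invisible at this marker resolution. Parentage confidence
is positive-LOD-plus-consistency, deliberately weaker than simulation-
calibrated confidence levels. Population haplotype frequencies and
selection analyses are out of scope.
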