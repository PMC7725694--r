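---
title: "mhcfkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mhcfkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcfkit)
```

## The biological setting

*HLA-F* and its primate orthologues are nonclassical MHC class I genes: the
mRNA lacks exon 7, polymorphism is low, and sequence evolution is dominated
by purifying selection. Most species carry one F gene per haplotype, so an
animal shows one or two full-length transcripts. The common marmoset is the
exception: the region is duplicated into several paralogous F genes, about
half of them pseudogenes that are nonetheless transcribed, and Callitrichid
twins are bone-marrow chimeric, so blood-derived cDNA can expose a twin's
alleles on top of an animal's own. mhcfkit packages the analysis chain for
this setting — allele calling from barcoded amplicon reads, heterozygote
resolution from direct Sanger consensus data, pseudogene and splice-isoform
annotation, phylogenetic lineage assignment, and Nei–Gojobori dN/dS — next
to a generator that simulates cohorts with exactly these properties and a
truth table for validation.

## The mock reference and its exon map

All simulations and annotations are anchored on a packaged synthetic
("mock") F coding sequence rather than on any real allele. The great-ape
template is a 1041-nt CDS with exon lengths 72 / 270 / 276 / 276 / 117 /
24 / 6 (exons 1–6 and 8; exon 7 is absent from the mRNA, as in the real
gene). These lengths were chosen so that the two exon partitions used in
macaque selection analysis come out at their published codon counts once
the OWM 6-nt exon-2 insertion is applied: complete exons 2–3 = 552 nt =
184 codons, exons 1-4-5-6-8 = 495 nt = 165 codons. Only exon 2's length
(270 nt in great apes, 276 in OWM) is externally fixed; the remaining exon
proportions follow typical class I architecture and are a package choice.

Clade-defining structural variants are expressed in ancestral coordinates,
all codon-aligned so they never disturb the reading frame:

| clade | exon 2 | exon 5 |
|---|---|---|
| great ape | 270 | 117 |
| OWM | 276 (+6 insertion, adds Arg+Tyr) | 117 |
| tamarin | 276 | 114 (−12 deletion, +9 extension) |
| night monkey | 267 (+6, −9) | 102 (−12, −3) |
| marmoset | 267 (+6, −9) | 114 (−12, +9) |

The night monkey ends up with the shortest transmembrane exon of the set,
and the marmoset/tamarin extension restores most of the NWM deletion —
the cross-species length pattern the real alleles show. Each clade
additionally carries 3% of fixed point substitutions away from the
(unobserved) common ancestor, so clades form proper, well-supported clades
in trees rather than a paraphyletic core; within-species allele
polymorphism (default 0.5%) stays an order of magnitude below that, which
is what makes lineage assignment clean (the package property tests demand
recovery when between-lineage divergence is at least five times the
within-lineage divergence).

Because every variant has known coordinates, cross-clade alignments are
*constructed* (`align_by_exon_map()`) rather than estimated: each clade
position maps to a unique column of a 1056-column master grid. No MSA
heuristic, hence no alignment noise in the phylogenetic tests.

## The generator as a model of the study design

`generate_repertoire()` derives alleles from one ancestral CDS per gene by
point mutations. Candidate substitutions are uniform over sites and bases;
a nonsynonymous candidate is accepted with probability equal to the
`dnds_target` (synonymous candidates always, stop-creating ones never, for
functional genes). Because the Nei–Gojobori site normalization uses the
same uniform-neighbour logic, the post-hoc dN/dS of a repertoire lands near
the target without simulating an explicit mutation-selection model; the
acceptance checks verify recovery at targets 0.15 and 0.3 within two
bootstrap SEs. Pseudogene paralogues get an ORF-disrupting lesion
(alternating a 1-nt frameshifting deletion in exon 3 and a premature stop
in exon 4 — the two lesion classes seen in marmoset F pseudogenes) and
mutate without selection or stop avoidance.

`generate_cohort()` draws founder haplotypes uniformly per gene (a
haplotype is one allele of every gene, inherited as a block — the
duplicated marmoset genes are linked on the chromosome), applies Mendelian
inheritance down an acyclic pedigree, and pairs a configurable fraction of
animals as chimeric twins whose *detectable* allele set is the union of
both twins' own alleles. Reads are
`barcode + forward primer + allele + revcomp(reverse primer)` with iid
substitution errors, random orientation, and a configurable fraction of
single-breakpoint two-allele PCR chimeras; the primer motifs are the
published clade-specific inner primer pairs, including their degenerate
IUPAC positions, so trimming is exercised realistically. Sanger consensus
data are modelled directly as IUPAC strings (no chromatogram traces): a
length-discordant heterozygote is readable only up to the first indel,
after which frame-offset peak superposition destroys base identity.

What the generator does **not** emulate: indel sequencing errors,
quality-score structure, depth variation between alleles (the tenfold
expression differences real transcripts show), barcode cross-talk, and
recombinant (gene-conversion) alleles. Passing tests therefore demonstrate
algorithmic correctness under substitution noise and chimera formation,
not robustness to every artifact class of a real PacBio run.

## Allele calling

Calling applies, in order: demultiplexing (unique nearest barcode within
`max_barcode_mismatch = 1`; the manifest must keep barcodes at Hamming
distance ≥ 2·mismatch+1, which makes assignment unambiguous), primer
trimming (each motif within 2 mismatches, IUPAC degeneracy respected,
either orientation), library mapping, de novo clustering, and replicate
confirmation.

De novo calling clusters reads greedily by substitution distance
(radius 3% of read length) to separate paralogous genes, then phases each
cluster on its polymorphic columns — columns whose minor-base frequency
exceeds 0.25, far above what a 0.5% error rate can produce at the depths
used — and takes a column-majority consensus per haplotype pattern,
merging rare patterns into their unique nearest core. Ties in the majority
vote break lexicographically (the model is not quality-aware, a stated
non-goal). Candidates below `min_cluster_size = 5` reads are noise; the
threshold is a free parameter because no read-count acceptance rule is
published for this assay.

Two deliberate design points:

- **Discovery always runs on all trimmed reads of an animal/replicate.**
  F alleles differ by scattered point mutations (~1%), so a read of a
  still-undiscovered allele typically lies within sequencing-error distance
  (≥ 98% identity) of a known allele; splitting reads into mapped/unused
  first and clustering only the unused would silently absorb novel alleles
  into their known neighbours. Mapping instead supplies per-replicate read
  support and the known/novel label of each consensus candidate.
- **Chimera rejection beyond replicate confirmation.** A candidate that is
  a single-breakpoint mosaic of two other confirmed calls is demoted to
  `rejected_artifact`. Replicate confirmation alone cannot catch a chimera
  that recurs in both PCRs; the mosaic test can, and on
  point-mutation-divergent alleles the chance that a real allele looks like
  an exact mosaic of two others is negligible.

## Sanger deconvolution

Resolution is homozygote-first, then iterative subtraction to a fixed
point. Anchors shared with a resolved parent or child are exhausted before
any resolution by bare library compatibility, and the two classes are
labelled (`subtraction_pedigree` vs `subtraction`): a pedigree-shared
anchor is Mendelian evidence, whereas a merely compatible library allele
can coincide with the consensus by chance, so only the former class (plus
homozygotes and single-ambiguity splits, which are logically forced) is
guaranteed to recover the truth. A heterozygote with k ≥ 2 ambiguous
positions and no anchor has 2^(k−1) consistent pairs; the module reports
that count and flags the animal for cloning rather than guessing.
Length-discordant consensi are always unresolved. Pedigree-incompatible
resolved genotypes (child sharing no allele with a parent) are surfaced as
conflicts, not auto-corrected, because no adjudication rule is published.

## Annotation

Transcript-to-reference alignment uses affine gaps with match +1,
mismatch −2, gap open −5, gap extend −1 — a scoring that prefers one long
gap block over scattered small ones, matching how the real events present
(single-block deletions of 38, 63, 118 nt and so on). Gap placement inside
repeats is ambiguous, so gaps are first shifted to their 5'-most
score-equivalent position (deterministic coordinates), and a deletion is
then snapped to an exon boundary if one of its equivalent placements is
flush with it — that is what makes "First part exon 2" labels stable.
Insertion events matching a supplied intron at an exon 3' boundary (up to
rotation, the same equivalence) are intron retentions; deletions spanning
exactly one exon are skips. Coordinates are 0-based half-open internally
and reported 1-based inclusive. Absolute coordinate equality with any
externally published event table is not claimed — only size, exon context
and frame effect, since published coordinates depend on a specific
alignment that is not machine-readable.

ORF classification translates from the initiator codon: a stop before the
final codon is a premature stop (located by exon through the alignment),
a net indel length not divisible by three is a frameshift, and the "N"
name suffix follows the verdict. Paralogue assignment requires ≥ 98%
gap-excluded identity *and* a 1-point margin over the runner-up; two genes
within the margin yield an explicit `ambiguous` report (the case of two
recently duplicated, near-identical genes), and a transcript below
threshold against all genes founds the next free gene number.

## Phylogenetics and nomenclature

Distances are p or Jukes–Cantor with pairwise deletion of gap/ambiguous
columns. The Jukes–Cantor model replaces the Maximum-Composite-Likelihood
distance some tree programs default to: MCL is not specified outside those
programs' internals, and at F-gene divergences (< 10%) lineage-level
clustering is topology-robust to this substitution; the model is a flag
(`model = "p"` or `"jc"`) so the choice is visible. Trees are
neighbor-joining (via ape) with negative branch lengths clamped to zero;
supports come from resampling alignment columns and counting bipartitions.

Lineage assignment walks from the query tip rootward to the smallest
enclosing clade that is bootstrap-supported (threshold 70, the common
convention) and contains named references: one reference lineage there
assigns the query; mixed lineages make it a new-lineage candidate. A
divergence guard (query farther than 3× the largest within-lineage
reference divergence from its nearest reference) also reports a candidate
new lineage regardless of topology — this is what keeps a genuinely novel
clade (the night-monkey situation) from being absorbed into whichever
named lineage happens to be topologically adjacent.

## Nei–Gojobori dN/dS

Synonymous site fractions per codon are computed from the universal code
with substitutions into stop codons excluded from the denominator, so
S + N = 3 × (codons compared) exactly — an invariant the tests assert to
1e−9. Codon differences at 2–3 positions are averaged over all minimal
substitution pathways with equal weights; pathways through stop codons are
excluded and their weight redistributed (unweighted averaging is used
because no transition/transversion weighting is specified for the original
method). The whole 61×61 sense-codon table is checked exactly against an
independent brute-force enumeration written on a different translation
backend. Distances are Jukes–Cantor corrected; p ≥ 3/4 is an explicit
saturation error (or NA on request, for counting-only uses).

Cohort summaries average dN and dS over all unordered pairs on an exon
partition that preserves codon frame across junctions. The reported ratio
is **mean(dN)/mean(dS)** — the ratio of means, not the mean of ratios;
this convention is self-consistent with published per-partition tables
whose printed ratios equal the quotient of their printed means at two
decimals on all six columns. Standard errors come from B = 1000 bootstrap
resamples of codon columns, recomputing the full mean statistic per
replicate (the SE is attached to the means, so the resampling unit is the
codon column, not the sequence pair). A partition with mean dS = 0
reports an undefined (NA) ratio, never 0 or infinity.

## Reproducibility and problem sizes

Every stochastic function takes a single integer seed; one global seed
fans out to stage seeds through `derive_seed()` (a fixed integer-hash
derivation, always below 2³¹), and all internal deterministic objects
(the mock reference, clade backbones) are generated under temporarily
swapped RNG state so they never perturb a caller's stream. Reruns at a
fixed seed are byte-identical down to artifact file hashes.

The shipped validation runs at deliberately desk-scale sizes — cohorts of
30 animals at depth 50 with 2 replicates over 20 generator seeds for
calling recovery, 500 random additive matrices for tree recovery, the
complete 61×61 codon-pair oracle, 10,000 synonymous-edit trials, and
25-allele repertoires for selection-parameter recovery — sizes chosen so
the whole suite completes in minutes while still exercising every code
path at realistic divergences.

## Known limitations

- Substitution-only error model; no indel errors, so de novo clustering
  can key on read length. Real long-read data would need length-tolerant
  clustering.
- Heterozygote resolution by bare library compatibility can, in principle,
  return a consistent-but-wrong pair when an uncarried allele coincides
  with the consensus; such resolutions are labelled and the logically
  forced classes are separated (see above).
- Intron retention is detected only against a supplied intron library; no
  splice-site prediction from genomic DNA.
- The lineage walk assumes the reference set spans the named lineages
  reasonably densely; a single reference per lineage disables the
  divergence guard.
- dN/dS assumes the universal genetic code and unweighted pathways; no
  maximum-likelihood (codon-model) estimation.
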