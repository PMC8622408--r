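---
title: "Methods: annotating and classifying cyclovirus genomes"
author: "cycloscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying cyclovirus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloscan)
```

## The problem

Cycloviruses (genus *Cyclovirus*, family *Circoviridae*) have small
(~1.7–1.9 kb) circular ssDNA genomes with an unusual amount of annotation
ambiguity packed into very little sequence: the two genes run in opposite
directions from a shared 5′-intergenic region, the replication-associated
protein (Rep) may require a non-standard genetic code, an alternative
initiation codon, or reconstruction across a spliced intron, and the whole
coordinate system is only defined once the origin of replication has been
located. This vignette documents how cycloscan resolves each of these
steps, the tunable parameters and their defaults, what the synthetic-genome
generator does and does not emulate, and the numerical and design choices a
maintainer should know about.

## Coordinates and the position-one convention

All coordinates are 1-based inclusive on the virion-sense strand.
Antisense features are reported `start > end` and read descending, matching
the field's "nt 1541–nt 846" style; ORF coordinates include the stop codon.
The origin of replication is marked by a nonanucleotide motif (consensus
`NAGTATTAC`, `N` matching any base) at the apex of a stem–loop; following
ICTV practice the first nucleotide of the motif is genome position one, and
`orient_and_rotate()` reverse-complements and/or rotates every genome into
that frame before any other analysis. This makes coordinates and
genome-wide identities comparable across inputs.

## Ori discovery

`find_nonanucleotide()` scans every circular window on both strands and
scores mismatches against the consensus (default `max_mismatch = 1`, which
accommodates the naturally occurring one-off variant `TACTATTAC`). An `N`
in the genome matches nothing — a deliberate choice, since an ambiguous
base should never *create* an origin call. When several hits tie on
mismatches the one supported by the best stem–loop (longest complementary
arms) wins, then the lowest position; a motif is only meaningful at the
ori, so hairpin support is the natural tie-breaker.

The stem–loop itself is found by a deterministic complementary-arm search
(`predict_stem_loop()`): all loop placements keeping the motif inside a
loop of at most `max_loop = 13` nt are combined with all arm lengths up to
a cap, requiring arms to be reverse complements within
`max_arm_mismatch = 1`, and the structure maximizing arm length (ties:
smaller loop, fewer mismatches) is reported; `min_arm = 5` filters noise.
Thermodynamic folding is intentionally *not* used: the folding step in this
workflow only ever serves to exhibit a hairpin with the motif at its apex,
which an exhaustive combinatorial search reproduces verifiably and
deterministically. No free energies are computed.

## ORF enumeration on a circle

`enumerate_orfs()` scans all six frames of the circular genome by doubling
the sequence, so ORFs that wrap position one are found in one piece; each
ORF is *stop-anchored* (delimited by in-frame stop codons) and reported
once, deduplicated by its virion coordinates. The start codon is chosen by
a fixed policy: the 5′-most ATG in the stop-delimited segment, or, if none
exists, the 5′-most occurrence of any configured alternative initiator
(default set ATG, ATA, TTG, GTG). We read the alternative list as defining
*membership*, with genomic position breaking ties — position, not list
order, decides — because the policy must reproduce both "TTG initiates when
no ATG is upstream" and "the longest compatible ORF" behaviors at once.
Start codons falling inside the ori motif (nt 1–9) are rejected. Proteins
render the initiator as methionine regardless of its elongation meaning.

Translation tables 1 (standard), 4 (mold mitochondrial) and 5 (invertebrate
mitochondrial) are supported, via the NCBI code tables shipped with
Biostrings. The annotator tries tables in the configured order (default
1, 4, 5) and stops at the lowest-numbered table whose best Rep candidate
carries all six conserved motifs, recording the scores of every table it
visited. One subtlety: tables 4 and 5 share stop-codon behavior (TGA reads
through as Trp) and differ only at AGA/AGG (Arg vs Ser) and in ATA
initiation, so genomes distinguishing table 5 from table 4 must do so
through residues, not stops — exactly what motif-completeness scoring
detects when an AGA codon sits at a motif-critical serine.

## Splice-aware Rep reconstruction

`find_spliced_rep()` considers every donor `GT` / acceptor `AG` pair on the
antisense strand with an intron of 4 to `max_intron = 200` nt (typical
cyclovirus introns are tens of nt), excises the intron, and tests whether
an in-frame, stop-free ORF crosses the splice junction, using precomputed
per-frame stop/start indices so the search stays fast. Candidates are
ranked by (conserved-motif score, then protein length).

A spliced candidate replaces the unspliced Rep only if it **strictly
improves the motif score**. Ranking ties by length here would be wrong: a
splice can excise the upstream stop codon and extend an already
motif-complete ORF into the intergenic region, imputing an intron the
genome does not have. Requiring strict score improvement reproduces the
real use case — an unspliced reading that is motif-incomplete under every
code, rescued by one intron — while guaranteeing that unspliced genomes
never gain a spurious intron.

The search treats the ori-rotated antisense reading as linear. In
cyclovirus organization the ori sits in the intergenic region between the
two genes, so *rep* cannot span position one after rotation; this is an
assumption of the spliced search only (unspliced enumeration handles
wrapping ORFs).

## Conserved motifs and the arginine-rich terminus

`scan_rep_motifs()` matches six degenerate consensus patterns — RCR I
(`[FW]T[LIV]NN`), RCR II (`.[HPA][LIV][QH]G`), RCR III (`Y[CLV][SK]K`),
Walker A (`G[PIAK][PST]GTGKS`), Walker B (`[LIVM][LIVM][FD]DD`) and motif C
(`[LIVM]T[SN]N`) — drawn from the circovirus/CRESS literature and fully
overridable, since different labs use slightly different consensi. Each
motif is sought leftmost within its expected zone (endonuclease motifs in
the N-terminal half, helicase motifs in the C-terminal half; the constraint
is disableable) to suppress spurious cross-matches. The score counts
distinct motifs found; profile/HMM search is out of scope.

`arg_rich_score()` is simply the R+K fraction of the N-terminal window
(default 20 aa; the denominator truncates with short proteins so a short
Arg-rich peptide can reach 1.0).

## Identities and demarcation

Pairwise identities use optimal global alignment with affine gaps
(`Biostrings::pairwiseAlignment`; nucleotides +5/−4 with gap open 10 and
extension 0.5, proteins BLOSUM62 with the same gaps). Percent identity is
identical residue pairs over all alignment columns except dual-gap and
terminal-gap columns ("SDT-like" mode; internal gap-vs-residue columns
count in the denominator). An alternative mode excluding all gap columns is
selectable, because the exact gap convention of the desktop tools in common
use is not standardized. `N` never matches, not even `N` vs `N`. Genome
identities are computed on ori-rotated virion-sense sequences so the
linearization is consistent; for near-identical pairs the result is
alignment-method independent, while for deeply divergent pairs (~60 %)
different aligners legitimately differ by a point or two — a tolerance any
downstream comparison should allow.

Species demarcation is single-linkage clustering at a percent-identity
threshold (ICTV: 80 % genome-wide for species), implemented as connected
components of the thresholded identity graph. The genus call combines the
organization criterion (ori on the Cp-encoding strand, decided by which
strand's ORF carries the Rep motifs), identity above the genus threshold
(55 %) to references, Rep motif-completeness and Cp arginine-richness: a
cyclovirus-like call requires the organization criterion plus at least one
other positive; motif-bearing Rep on the ori strand yields circovirus-like;
no motif, unclassified.

## Phylogeny stand-in

Full maximum-likelihood inference is out of scope; the package's
phylogenetic claims are limited to coarse topology, which distance methods
recover. `nj_tree()` wraps `ape::nj`, then clamps the occasional negative
NJ branch to zero while shifting the deficit to the sibling edge (path
lengths through the parent are preserved). `bootstrap_support()` resamples
alignment columns, rebuilds NJ trees from p-distances, and reports percent
bipartition support; taxa are sorted before resampling so supports do not
depend on input label order, and all resampling is seed-deterministic.
`sliding_window_identity()` provides a lightweight mosaic screen (default
200-nt windows, 50-nt step; windows under 50 nt warn as noisy) — it flags
crossovers, it does not test recombination statistically.

## The synthetic generator: what it emulates

`generate_genome()` assembles, from position one: the motif inside a
stem–loop (default 8-nt arms, 11-nt loop), the 5′-intergenic spacers, a
virion-sense Cp with an exact planted R+K count in its N-terminal window
(default target fraction 0.55 in 20 aa — a typical strongly basic Cp
terminus), an optional 3′-intergenic region (default 4 nt), and an
antisense Rep carrying all six motif instances at fixed relative offsets
(6/15/30/60/75/88 % of protein length), optionally split by a canonical
GT/AG intron. Genome length defaults to a uniform draw over 1700–1910 nt,
the natural cyclovirus range; Rep/Cp default to 280/258 aa. Each CDS is
preceded by an in-frame stop on its own strand so the planted start is the
unambiguous policy choice, intron interiors avoid internal GT/AG
dinucleotides so boundaries are unambiguous, and assembly is rejected and
resampled whenever a second one-mismatch motif hit appears anywhere on
either strand. Mitochondrial-code genomes plant TGA-read-through
tryptophans (breaking the standard-code reading) and, for table 5, an AGA
serine inside Walker A (breaking table 4), so the table-search policy is
exercised for real. A random rotation and strand flip are applied and
recorded in the truth object.

What the generator does **not** emulate: indels and alignment ambiguity
(mutation is substitution-only, so identity calibrates exactly to
100·(1−r) when one copy is mutated at per-site rate r), codon-usage and
compositional bias, overlapping or nested genes, multiple introns, and
recombination beyond the two-parent chimera used to exercise the
sliding-window screen. Passing the round-trip tests therefore demonstrates
the pipeline's logic is correct on architecturally faithful genomes; it
does not certify performance on noisy real sequence, where motif consensi
and alignment dialects dominate.

`generate_species_panel()` derives species founders as independent heavily
mutated copies (default rate 0.35, giving ~45–55 % pairwise identity, well
below the 80 % threshold) of one base genome and members as lightly mutated
copies of their founder (default 0.002, ~99.6–99.8 % identity, well above
it), recording the true partition.

## Problem sizes and numerical choices

The test suite validates ORF enumeration against a brute-force six-frame
oracle on 500 random 0.3–2 kb sequences; planted-feature recovery (ori
rotation, table choice, Rep/Cp coordinates, intron boundaries, intergenic
regions) on 200 genomes (140 standard-code, 60 mitochondrial-code spliced);
species-partition recovery on 100 simulated panels; NJ metric recovery on
random additive trees up to 12 taxa; and the mutation/identity calibration
on 100 draws at two rates, against the exact expectation, within ±1.5
points. The acceptance script re-runs the same machinery at reduced counts
(60 genomes, 30 panels) plus the published three-genome identity table,
which ships as a plain TSV.

Degenerate-input behavior: empty sequences, non-IUPAC characters and
length-violating CDSs raise errors naming the record and offset; a genome
with no motif hit is annotated as unclassified with a warning rather than
aborting a batch; a missing strand yields an incomplete annotation flag.
Ties are broken deterministically everywhere (documented per function), so
identical inputs, configuration and seed give byte-identical outputs.

## Known limitations

- Motif patterns are consensus regexes, not profiles; unusual Reps may
  need custom patterns via `scan_config(rep_patterns = ...)`.
- The spliced-Rep search assumes one intron and no ori-spanning *rep*.
- Identity values for deeply divergent pairs carry an alignment-dialect
  uncertainty of roughly ±2 percentage points.
- The NJ tree is a stand-in for likelihood methods: suitable for sibling
  /cluster statements, not for publication-grade phylogenies.
- GenBank parsing reads sequence only; feature tables are ignored.
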