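---
title: "Designing and analysing bivalent traffic-light CRISPR reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing bivalent traffic-light CRISPR reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betle)
```

## The reporter model

A bivalent traffic-light reporter encodes several readout proteins in
different reading frames of one transcript. The main open reading frame is
mCherry — P2A — SOI (the *sequence of interest*, the editing target),
translated constitutively. Downstream of the SOI sit two further
cassettes: a P2A-linked blue fluorophore (mTagBFP2) offset so that a net
−2 frameshift upstream brings it into frame, and a T2A-linked secreted
luciferase (NanoLuc) in the −1 frame. A Cas-induced indel in mCherry or
the SOI therefore selects a readout by its net length modulo 3:

| net indel (mod 3) | class | in-frame cassette | readout |
|---|---|---|---|
| 0, no indel | `UNEDITED` / `SUBSTITUTION_ONLY` | main ORF | mCherry |
| −1 (i.e. net ≡ 2) | `N1` | T2A–NanoLuc | luminescence |
| −2 (i.e. net ≡ 1) | `N2` | P2A–mTagBFP2 | blue fluorescence |
| 0 with an indel | `N3_INFRAME` | main ORF | position-dependent |
| template repair | `HDR` | main ORF | mCherry + moxGFP |

Insertions and deletions with the same net residue are one class: a 1-bp
deletion and a 2-bp insertion both activate NanoLuc. `frame_class()`
implements exactly this modular definition, and the package's tests check
it against an independent oracle that shifts the synthetic construct's
cassette coordinates and asks which cassette lands in the main frame.

Two deliberate conventions, where the architecture alone does not force an
answer:

* **In-frame indels in mCherry** are predicted mCherry-negative by
  default: an in-frame lesion inside a fluorophore generally destroys the
  chromophore region it hits. Because small in-frame indels can in
  principle be tolerated, `predict_phenotype()` exposes
  `inframe_disrupts_function` (default `TRUE`).
* **In-frame indels in the SOI** leave mCherry positive — the upstream P2A
  has already released mCherry, so this is forced by the architecture, not
  an assumption.
* **Substitution-only haplotypes** count as unedited for phenotype
  purposes: the reporter readout depends on reading frame only. They are
  nevertheless reported as their own class so that sequencing error is
  visible rather than silently folded into "unedited".

For multi-integrant cells the phenotype is the elementwise OR over
integrants (`cell_phenotype()`): any integrant that underwent HDR makes
the cell moxGFP-positive, any N−2 integrant makes it mTagBFP2-positive,
and only cells with at least two integrants can be double-positive. With
one integrant per cell the double-positive fraction is structurally zero —
the property that lets the reporter distinguish single- from
multi-integrant clones.

## The SOI design rules

Because two further ORFs overlap the main frame downstream, the SOI must
contain no stop codon (TAA, TAG, TGA) in *any* of the three frames, no
internal Esp3I recognition site on either strand, and a length divisible
by 3. `optimize_cds()` recodes a protein under these constraints.

An out-of-frame stop triplet spans at most two adjacent codons, and the
6-nt Esp3I motif at most three; a dynamic programme whose states are
adjacent codon *pairs* is therefore exact for every constraint up to 9 nt
and runs in linear time. It maximizes the summed log codon-usage weight
(uniform by default — no organism table is assumed; a usage table can be
loaded from TSV) and breaks ties by the lexicographically smallest CDS, so
output is reproducible across platforms. Scores under the uniform table
are not comparable to any commercially optimized sequence; only the
stop-free property is.

Not every protein is feasible: methionine's only codon is ATG, and
ATG followed by any A-starting codon creates a frame+1 TGA, so proteins
with Met before Ile/Lys/Asn/Thr/Met cannot be recoded stop-free.
`optimize_cds()` reports the first residue at which no assignment
survives. The bundled synthetic construct avoids internal Met in its
stand-in proteins for this reason.

## The bundled synthetic construct

The package ships no real fluorophore or luciferase sequence. Instead
`synthetic_reporter()` deterministically assembles a construct with the
exact architecture above from synthetic stand-in proteins recoded with the
package's own optimizer: a 150-nt promoter region, an 80-aa mCherry
stand-in, two 24-nt P2A-like linkers carrying the two Esp3I sites (with
distinct 4-nt overhangs, TTGG and CCTC), an SOI derived from a 100-aa
protein by carving out a 39-bp in-frame deletion (the "defective" target),
the −2 and −1 frame cassettes, and a terminal in-frame stop. The deletion
window is chosen so the defective SOI remains stop-free in all frames; the
removed 39-mer is recorded and, flanked by two 80-nt homology arms copied
from the construct, yields the canonical 199-nt single-stranded HDR
template (`build_hdr_template()`).

Coordinates are 0-based half-open throughout; the GenBank reader/writer
converts to and from 1-based inclusive locations.

## What the simulators emulate — and what they do not

`simulate_molecules()` / `simulate_population()` draw per-integrant
outcomes: unedited, an indel from a configurable spectrum at the guide's
cut site, or an exact template repair. The default spectrum is
geometric-tailed deletions (p = 0.5, lengths 1–30) mixed 4:1 with 1-nt
insertions — a fixture chosen to resemble typical NHEJ outcome tables, not
a fitted model; any spectrum can be supplied via TSV. Deletions are
centred on the cut site and insertions placed at it.

`simulate_amplicon_reads()` produces paired 250-bp reads between a primer
pair with i.i.d. substitution errors (default 0.001) and constant Q30
qualities. `simulate_integrations()` plants a transgene at uniform
positions and random orientations in a toy multi-contig genome, and
`simulate_junction_reads()` generates tagmentation-style 150-nt reads
anchored at the transgene–genome junctions, mirroring the enrichment step
of junction PCR rather than whole-genome shotgun coverage.

Not modelled, deliberately: PCR amplification bias and chimeras, indel
sequencing errors, quality-score structure, sorting-gate impurity,
transfection and selection efficiency, and 2A cleavage or protein
stability. Passing tests therefore demonstrate that the analysis recovers
the truth of *this* generative model — clean substitution noise over known
molecule mixtures — not that it is robust to every artefact of real
amplicon data.

## The amplicon classification pipeline

`classify_amplicons()` runs trim → merge → align → call → count:

1. **Quality trim** (`quality_trim`): Trimmomatic-style 5′→3′ sliding
   window (4 bases, mean Q < 20 cuts), reads below 40 nt dropped;
   idempotent.
2. **Merge** (`merge_pairs`): reverse-complement read 2, choose the
   overlap (≥ 10 nt) minimizing the mismatch fraction, merge when ≤ 0.25,
   higher-quality base at conflicts.
3. **Align** (`align_to_reference`): affine-gap alignment, global in the
   read, free end gaps on the reference; match +2, mismatch −3, gap open
   −6, gap extend −1 (a length-L gap costs −6 − L). Ties prefer deletions
   over insertions, then leftmost; indels are left-aligned within
   homopolymers before event reporting. The C++ implementation is checked
   against a plain-R DP oracle and against Biostrings' aligner score.
4. **Call** (`call_events`): indel ops intersecting the analysis window
   become events; reads not spanning the window are excluded with a reason
   code, never partially counted.
5. **Count** (`summarize_haplotypes`): unique windowed sequences with read
   counts; class fractions over classified reads always sum to 1.

**HDR calling.** A haplotype is `HDR` when its windowed sequence aligns to
the repaired reference window with *no indel ops* — i.e. the repair
restored the template's indel structure exactly. Substitutions are treated
as sequencing error, mirroring how `UNEDITED` versus `SUBSTITUTION_ONLY`
treats the defective reference: the classes are defined by indel
structure, which is what the reporter's frame logic responds to. (A
byte-exact window rule would instead reclassify every HDR read carrying a
single sequencing error elsewhere in the 100-nt window, deflating the HDR
class by ~10% at a 0.1% error rate for no biological reason.) A
consequence: a non-template insertion of exactly the restored segment's
length at the same position would be called HDR; at 39 bp this is
vanishingly unlikely under any realistic spectrum.

Analysis windows are user-supplied (name, 0-based half-open interval,
region); `guide_window()` centres a 100-nt window on a guide's predicted
cut site. Window coordinates supplied in 1-based inclusive form (the
GenBank convention) are converted on input.

## Integration mapping

Junction reads are filtered for the transgene's terminal 15-mers at
Levenshtein distance ≤ 2 (`terminal_kmer_filter`) — "edit distance" is
read literally as Levenshtein, and both strands are searched since
library orientation is arbitrary. For each passing read the
transgene-matching segment is masked and the genomic flank (≥ 20 nt) is
located by exact 20-mer seeding from the junction-proximal end with
mismatch-tolerant verification (≤ 3) — adequate for desk-scale toy
genomes; no external aligner is involved. Junction hits within 10 nt (Tn5
positional jitter) merge into one call; calls need ≥ 2 supporting reads
(chimera suppression); both knobs are exposed. Orientation falls out of
which transgene end matched and the strand of the flank hit, and
left/right-end calls collapse into per-site records via
`integration_sites()`.

## Problem sizes and determinism

All randomness flows through explicit seeds; identical seeds give
byte-identical FASTQ. The shipped analyses use: 5,000 read pairs for
sorted-population classification and 10,000 for mixtures (at these depths
the 3-SD multinomial band around a 4.5% class is ±0.6 percentage points);
500–2,000-molecule pools; toy genomes of three contigs (75 kb total) with
≥ 50 junction reads per integration site. The acceptance script
(`scripts/acceptance.R`) regenerates every one of these from a single
`--seed`.

## Known limitations

* The aligner is quadratic per haplotype; it is meant for amplicon-scale
  references (kilobases), not genomes.
* HDR calling requires the repaired reference; partial or mosaic repair is
  reported as the indel class its net length implies, by design (no
  partial-HDR class).
* The integration mapper's seeded flank search assumes essentially unique
  flanks; repetitive genomic contexts would need a real genome aligner.
* Windows for the analysis are taken as given; the published interval
  lists label regions A, C and D, and no assumption is made about any
  other region.
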