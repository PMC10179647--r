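# betle

Design and analysis toolkit for **bivalent traffic-light CRISPR
reporters** — constructs that read out genome-editing outcomes by encoding
several reporter proteins in different reading frames of one transcript.

A traffic-light reporter of this architecture expresses
mCherry – P2A – SOI (an exchangeable *sequence of interest*, the editing
target) as its main open reading frame, followed by a P2A-linked mTagBFP2
cassette in the −2 frame and a T2A-linked secreted NanoLuc cassette in the
−1 frame. A Cas-induced indel upstream selects the readout by its net
length *n* modulo 3:

* *n* ≡ 0, no indel — mCherry only (unedited);
* *n* ≡ −1 (class **N−1**) — NanoLuc luminescence;
* *n* ≡ −2 (class **N−2**) — mTagBFP2 fluorescence;
* *n* ≡ 0 with an indel (class **N−3**) — in-frame lesion;
* template repair (**HDR**) — mCherry and restored moxGFP.

The package covers the complete in-silico workflow around such reporters:

* **Codon design** (`optimize_cds`): recode an SOI so that no stop codon
  (TAA/TAG/TGA) occurs in *any* of the three frames and no Esp3I site
  anywhere, by an exact dynamic programme over adjacent-codon pairs
  maximizing codon-usage weight.
* **Construct model** (`reporter_cassette`, `validate_cassette`,
  `swap_soi`): annotated cassettes with frame arithmetic, Esp3I site and
  overhang checks, and Golden-Gate-style SOI exchange; GenBank I/O.
* **Editing simulation** (`simulate_population`, `simulate_molecules`,
  `simulate_amplicon_reads`, `simulate_integrations`): per-integrant
  NHEJ/HDR outcomes, configurable indel spectra, paired amplicon reads
  with substitution error, transgene-bearing toy genomes and junction
  reads — everything needed to test the analyses without downloads.
* **Amplicon classification** (`classify_amplicons`): trim → merge →
  affine-gap align → haplotype counting over guide windows → per-class
  fractions (UNEDITED, SUBSTITUTION_ONLY, N1, N2, N3_INFRAME, HDR).
* **Phenotype prediction** (`predict_phenotype`, `cell_phenotype`):
  per-integrant traffic-light readouts and the OR-logic of
  multi-integrant cells.
* **Integration mapping** (`terminal_kmer_filter`,
  `call_integration_sites`): transgene junction reads filtered by
  terminal 15-mers at edit distance ≤ 2, flanks located by seeded search,
  orientation-aware site calls.

## Worked example

Build the bundled synthetic reporter (its SOI is a defective target with
a 39-bp in-frame deletion), design a guide at the deletion site, simulate
a mixed edited population, and classify the reads:

```r
library(betle)

cassette <- synthetic_reporter()
cassette
#> <reporter_cassette> synthetic_tlr (1098 nt, 7 features)
#>                   name start  end frame_shift strand
#> 1             promoter     0  150           0      +
#> 2              mCherry   150  390           0      +
#> 3                P2A_1   390  414           0      +
#> 4                  SOI   414  675           0      +
#> 5                P2A_2   675  699           0      +
#> 6    mTagBFP2_cassette   701  881          -2      +
#> 7 T2A_NanoLuc_cassette   883 1063          -1      +

guide   <- design_guide(cassette, "SOI")
window  <- guide_window(cassette, guide)      # 100 nt around the cut site
primers <- design_primers(cassette, window)

spectrum  <- condition_spectrum(default_indel_spectrum(), 1L)  # net = -2 class
molecules <- simulate_molecules(cassette, guide, 500,
                                spectrum = spectrum, edit_frac = 0.85,
                                hdr_frac = 0.05, seed = 42)
reads <- simulate_amplicon_reads(molecules, primers,
  read_sim_params(n_pairs = 4000, substitution_error = 0.001, seed = 43))

tab <- classify_amplicons(reads$r1, reads$r2, cassette, window,
                          repaired = TRUE)
tab
#> <haplotype_table> window SOI_window [460,560): 4000 reads, 372 haplotypes, 0 excluded
#>   UNEDITED            9.68%
#>   N2                 84.70%
#>   HDR                 4.70%
#>   SUBSTITUTION_ONLY   0.92%
```

The recovered fractions match the simulated mixture: 85% of molecules
carried an N−2 indel (read back as 84.7% + part of the substitution-only
mass), 5% carried the exact template repair (4.7%), and the rest were
unedited. Every percentage is a read-weighted fraction over unique
haplotypes in the window; fractions always sum to 1. An N−2 call predicts
mTagBFP2-positive cells, HDR predicts mCherry+/moxGFP+ cells
(`predict_phenotype("SOI", "N2")`, etc.).

The 199-nt HDR template for the defective SOI is the construct's two
80-nt homology arms around the missing 39-mer:

```r
nchar(build_hdr_template(cassette)$seq)
#> [1] 199
```

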