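# spellpeg

Design and evaluation toolkit for prime editing guide RNAs (pegRNAs) that
weaken the inhibitory intramolecular complementarity between the spacer
and the primer binding site (PBS).

## The problem

A pegRNA extends an SpCas9 guide with a reverse-transcription template
(RTT) and a PBS. Because the PBS is built as the complement of the
non-target strand just 5′ of the nick, and the spacer is a copy of the
protospacer on that same strand, the PBS is intrinsically complementary to
the PAM-proximal part of the spacer: with the nick 3 nt from the PAM, PBS
position *p* pairs spacer position *p* + 3 (position 1 = PAM-proximal).
This intramolecular spacer:PBS duplex competes with both target
recognition and primer annealing and is a major reason long PBSs
underperform. The register saturates at 17 paired nucleotides for a 20-nt
spacer, so PBS lengths of 18–20 add primer-annealing length *without*
adding inhibitory complementarity.

`spellpeg` implements the design strategies that exploit this geometry:

* **SPELL pegRNAs** — a fixed 17–20-nt PBS carrying a single-nucleotide
  deletion (default at PBS position 13, leaving a 12-nt intact 5′
  segment). One fixed recipe instead of per-target PBS-length screening.
* **Variant generators** — spacer mismatches (transitions/transversions
  with placement-rule warnings), PBS mismatches, 1–4-nt PBS deletion
  grids with duplicate-product flagging, seeded PBS-end scrambles, and
  combinations, all with provenance and an explicit complementarity
  register model (`complementarity_map()`).
* **Duplex thermodynamics** — nearest-neighbor Tm and ΔG°37 for the
  PBS:non-target-strand heteroduplex (Sugimoto 1995 RNA:DNA table; Freier
  1986 RNA:RNA available), ranked against the 37 °C design guideline.
* **Cloning outputs** — two-step Golden Gate linker oligos (spacer, then
  RTT–PBS extension) with in-silico assembly round trips, plus T7
  in-vitro-transcription template primers.
* **Amplicon quantification** — alignment, ±2 bp windowed indel calls
  around the nick sites, intended-edit detection anchored by 5+5 exactly
  matching flanks, aligned-reads denominators, untransfected-control
  background subtraction, transfection-efficiency normalization, and
  two-motif gene-specific demultiplexing that excludes template-switch
  chimeras.
* **Read simulator** — a deterministic synthetic amplicon read generator
  with exact class counts and a truth table, so the whole quantification
  stack is testable without external data.

## Worked example

```r
library(spellpeg)

# a seeded synthetic locus: 20-nt protospacer + NGG PAM with context
locus <- with_seed(7, random_locus())
edit  <- edit_spec(nick_distance = 1, ref = "A", alt = "C")

design_report(locus, edit, pbs_lengths = c(7, 10, 13, 17, 20),
              spell = TRUE, u6_mode = FALSE)[, c(
  "candidate", "pbs_length", "tm_celsius", "n_paired", "covered")]
#> # A tibble: 6 x 5
#>   candidate          pbs_length tm_celsius n_paired covered
#>   <chr>                   <int>      <dbl>    <int> <chr>
#> 1 PBS7                        7      -2.02        7 4-10
#> 2 PBS10                      10      22.6        10 4-13
#> 3 PBS13                      13      42.9        13 4-16
#> 4 PBS17                      17      55.8        17 4-20
#> 5 PBS20                      20      59.4        17 4-20
#> 6 SPELL(PBS20,del13)         19      55.6        16 4-20
```

Reading the rows: `n_paired` is the number of Watson–Crick spacer:PBS
pairs (the inhibitory burden — note it saturates at 17), `covered` the
spacer positions the PBS register reaches, and `tm_celsius` the
PBS:non-target-strand melting temperature (PBS13 lands closest to the
37 °C guideline on this locus). The SPELL row keeps the long PBS's annealing
length but its deletion interrupts the register (16 pairs) while its
first 12 nt stay identical to a plain 12-nt PBS:

```r
spell <- make_spell(locus, edit, u6_mode = FALSE)
substr(spell$pbs, 1, 12) == as.character(build_pbs(locus, 12))
#> TRUE
```

Simulate reads and quantify them back:

```r
spec <- amplicon_spec(locus$reference, nick_site(locus), edit)
sim  <- simulate_amplicon_reads(spec, n_reads = 10000,
                                edit_fraction = 0.125, seed = 1)
quantify(call_reads(align_reads(sim, spec), spec), spec)[,
         c("total_reads", "edit_pct", "indel_pct")]
#> # A tibble: 1 x 3
#>   total_reads edit_pct indel_pct
#>         <int>    <dbl>     <dbl>
#> 1       10000     12.5         0
```

A command-line surface wraps the same functions
(`exec/spellpeg design|variants|oligos|simulate|quantify|aggregate`).

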