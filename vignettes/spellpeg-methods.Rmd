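---
title: "Designing pegRNAs with reduced spacer:PBS complementarity"
author: "spellpeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing pegRNAs with reduced spacer:PBS complementarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spellpeg)
```

## The geometric model

Everything in this package rests on one piece of coordinate bookkeeping.
The non-target strand carries the 20-nt protospacer and the NGG PAM; the
nickase cuts that strand `nick_offset` nucleotides 5′ of the PAM (default
3, configurable everywhere). We number spacer/protospacer positions from
the PAM: position 1 is PAM-proximal, position 20 (21 for a 21G spacer)
is the 5′-most. The PBS is the reverse complement, as RNA, of the
primer's 3′-terminal nucleotides, and PBS position 1 — its 5′ end,
adjacent to the RTT — pairs the nick-adjacent primer base.

Because the spacer is an RNA copy of the protospacer and the PBS is a
complement of the same strand, PBS position $p$ is register-paired with
spacer position $p + \mathrm{nick\_offset}$. Three facts follow
mechanically and are checked by the acceptance suite:

* a 7-nt PBS covers spacer positions 4–10 (with the default offset);
* the register saturates at $20 - 3 = 17$ pairs for a 20-nt spacer, so
  PBS 18–20 add primer-annealing length without adding intramolecular
  complementarity;
* deleting PBS position 13 from a 20-nt PBS leaves a 12-nt intact 5′
  segment identical to a plain 12-nt PBS, with everything 3′ of the
  deletion shifted one register position.

A caveat on numbering: descriptions of this geometry sometimes quote a
7-nt PBS as covering spacer positions "3–10". That count includes one
more PAM-proximal position than 7 nucleotides can pair; with our
convention (nick between positions 4 and 3) the covered set is 4–10.
`nick_offset` is exposed if a different frame is wanted.

`complementarity_map()` computes the register generically: deletions
shift everything downstream by their length, mismatches break individual
pairs (evaluated base-by-base on the actual sequences, Watson–Crick
only, no G·U wobble), and an appended 5′ G simply occupies position 21
and is reached by PBSs of 18 nt or more — computed, not special-cased.
Its correctness is established against a brute-force string oracle over
all PBS lengths × mismatch positions on random loci.

## Variant classes and their warnings

The variant generators encode placement rules as *advisory* warnings,
never hard errors, because measured behaviour has exceptions in both
directions:

* spacer mismatches at PAM-proximal positions (≤ 10) warn that
  efficiency frequently drops — disrupting target recognition there
  costs more than the relieved self-complementarity gains;
* spacer mismatches outside the PBS-covered region warn that no benefit
  is expected — they cannot relieve what is not paired;
* PBS mismatches on short (≤ 13 nt) PBSs warn that they mostly hurt —
  the primer duplex is already marginal;
* 21G spacers warn of possibly reduced mismatch tolerance;
* deletion lengths outside the characterized 1–4-nt range warn but
  proceed.

Deletion grids flag variants whose product coincides with an earlier
one (inevitable in homopolymer runs) via `duplicate_of`. The SPELL
constructor is a thin fixed recipe over the same machinery: PBS 17–20
(warning outside that range), single deletion, default position 13.

Where a substitution must be invented, the tie-break is deterministic:
transitions are unique; for transversions we pick the candidate that
also cannot re-pair the opposing base, alphabetically first on ties.
Published designs made specific choices we cannot derive, so every
generator accepts explicit `alt_bases` overrides. Combinations apply
deletions first and interpret all positions in the original part's
coordinates, which makes `combine_variants()` order-insensitive and
matches how combined designs are usually described ("deletion at 13 plus
a mismatch at 15", both in unmodified numbering). PBS-end scrambles use
seeded rejection sampling — the permutation must differ from the
original and retain zero Watson–Crick pairs in register — and fail
loudly after a bounded retry count for degenerate segments.

## Duplex thermodynamics

`duplex_tm()` is a two-state nearest-neighbor summation. Parameter
tables are data, not code: annotated TSVs under `inst/extdata`
(RNA:DNA heteroduplex, Sugimoto et al. 1995, the default for
PBS:non-target strand; RNA:RNA, Freier et al. 1986), each addressed by a
`parameter_set_id` recorded in every report so results are reproducible.
Defaults: 50 mM monovalent salt, 250 nM total strand concentration —
values must be fixed *somewhere* to be reproducible, and both are
configurable and recorded. The salt correction
$\Delta S' = \Delta S + 0.368\,(N{-}1)\ln[\mathrm{Na}^+]$ enters the
melting temperature
$T_m = \Delta H / (\Delta S' + R \ln(C_T/4)) - 273.15$; ΔG is reported
at 37 °C at the tables' 1 M standard state, which keeps it strictly
additive in stacks (a longer perfect duplex is always more negative — a
tested invariant). Mismatched positions are excluded from the summation
and counted, not modeled; the model is for perfect or near-perfect
duplexes, which is what PBS design needs. Duplexes shorter than 2 bp
have no stacks and are an error. The implementation was verified against
an independent nearest-neighbor calculator at identical conditions;
those values are frozen in the test-suite.

The 37 °C guideline enters only as a ranking hint
(`abs_tm_minus_37` / `rank_tm37` in `design_report()`); the package
deliberately makes no efficiency predictions.

## The synthetic read generator

`simulate_amplicon_reads()` emulates exactly the read categories the
quantifier must distinguish: unedited reads, intended-edit reads, an
arbitrary indel spectrum around the nick (offset, type, length,
fraction), and optional combined edit-plus-indel classes. Class counts
are exact by largest-remainder rounding, so with zero sequencing error
the pipeline must recover every class frequency *exactly* — that
separates classifier correctness from error robustness. Sequencing error
is uniform per-base substitution; by default errors are kept out of the
flanked edit motif of edit-carrying reads so the zero-error exactness
property extends to the edit caller (`protect_flanks = FALSE` lifts
this). Reads are single-ended and span the whole amplicon; qualities are
constant Q37; the seed is mandatory and output is byte-identical per
seed.

What the generator does **not** model — PCR bias and chimeras, quality
degradation, paired-end structure, indel sequencing errors, real indel
spectra around a nick — bounds what green tests mean: they certify the
bookkeeping (windows, flanks, denominators, subtraction, demux logic) on
reads whose truth is known, not performance on real libraries. Chimera
exclusion is exercised with explicitly constructed two-reference
fixtures rather than a chimera model.

## Quantification rules

The quantifier implements a specific, documented bookkeeping:

* **Denominator** — aligned reads are the total reads. Alignment is
  global with affine gaps (match +2, mismatch −3, open −8, extend −1,
  ≥ 70 % identity to count as aligned; all configurable and recorded).
* **Indel window** — an indel counts if its reference span overlaps the
  closed ±2 bp window around any nick site; insertions carry the
  between-base coordinate of their insertion point. "Overlap" rather
  than "starts within" is the more conservative reading of a ±window
  rule; the window audit test pins the flip boundary exactly.
* **Intended edit** — exact substring match of the edited allele flanked
  by 5+5 exactly matching reference nucleotides. Strict: an error inside
  a flank disqualifies the read.
* **Denominators by edit type** — substitutions: intended-edit reads
  *without* a window indel; insertions/deletions: all intended-edit
  reads, with the indel background drawn from reads whose window indels
  differ from the intended one.
* **Background and normalization** — the untransfected control's
  percentages are subtracted (negatives reported as-is, flagged), then
  the transfection-efficiency division is applied. The order
  (subtract, then divide) is fixed and documented here since it is not
  otherwise forced.
* **Demultiplexing** — a read is assigned to a gene only when both of
  that gene's motifs match inside their position windows; one-of-each
  reads are excluded as chimeras, double-full matches as ambiguous.

Two exact shortcuts keep alignment honest and fast: unique read
sequences are aligned once, and equal-length reads with ≤ 3 mismatches
take a gap-free fast path — under the default scoring a substitution
costs 5 while the cheapest gapped detour costs 2 × (8+1) = 18, so the
gap-free alignment is provably optimal there, making this an exact
optimization rather than a heuristic. Single-indel alignments are read
directly off the aligner's indel ranges; alignments with multiple indels
go through an explicit gapped-string walker.

## Cloning encodings

Golden Gate linkers mirror two-step pegRNA cloning: a spacer linker
first, then an RTT–PBS extension linker. The 4-nt overhangs ship as a
documented *convention* (`inst/extdata/default_overhangs.yaml`) because
acceptor backbones differ — verify them against your plasmid's digestion
products. The module's correctness check is an in-silico round trip:
annealing and ligating the emitted oligos into a virtual backbone must
reconstruct `peg_full_sequence()` byte-exactly, which the test-suite
does for 1000 random designs including SPELL and scrambled PBSs.
Modified PBSs are encoded verbatim — no silent repair. Inserts
containing the cloning enzyme's recognition site trigger a warning only.
T7 template primers warn when the first transcribed base is not G.

## Tabular analyses

The aggregation helpers mirror how pegRNA screen tables are summarized:
ids with conflicting efficiency records (different values outside the
replicate structure) are excluded entirely, exact duplicates collapse;
group means by PBS length (optionally NGG-PAM-only) report n, mean, SD
with single-observation groups flagged; fold changes are ratios of
replicate means with a near-zero-control flag (default floor 0.5 %).
Only Welch's two-sample t-test ships — the broader ANOVA /
Kruskal–Wallis / post-hoc battery used around such screens is routine
and available in standard statistics facilities, and re-wrapping it
would add surface without substance.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand; for `-`
  strand loci `protospacer_start` is the forward-strand footprint start,
  the one unambiguous interval convention.
* `U` in DNA context and `T` in RNA context are rejected, never
  silently converted; IUPAC codes are allowed in PAM patterns only.
* RTT default length is `nick_distance + |alt| + 10` — a modest right
  homology arm when none is specified, always overridable; the RTT must
  reach at least one nucleotide past the edit.
* Every stochastic operation (scramble, simulation, `random_locus()`
  draws) takes or consumes an explicit seed; `with_seed()` provides a
  private RNG stream that leaves the caller's RNG state untouched.
* Problem sizes in the test-suite — 100 random loci for the exhaustive
  register check, 1000 designs for the assembly round trip, 10⁴ reads
  for the exactness check and 100 × 5·10⁴ reads for the noise-recovery
  check — were chosen to make the properties sharp (binomial standard
  errors small relative to the asserted tolerances) while keeping the
  default test run comfortable on a laptop.

## Known limitations

No editing-efficiency prediction, no scaffold or RTT secondary-structure
modeling, no PE3 nicking-guide design, no UMI handling or paired-end
merging, no modeling of the epegRNA 3′ motif beyond carrying it as an
opaque configured sequence. The thermodynamic model is two-state and
mismatch-agnostic by design. Warnings encode observed *tendencies*, not
guarantees; for any individual target the measured exceptions run in
both directions, which is precisely why the generators never block a
requested design.
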