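---
title: "Wristwatch-primer genome walking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wristwatch-primer genome walking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wwpcr)
```

## The problem

Genome walking retrieves unknown DNA flanking a known anchor sequence.
Wristwatch PCR does this with a set of *wristwatch primers* (WWPs):
25-nt walking primers that share a 12-nt 5' part and a 3-nt 3' part around
mutually mismatched 10-nt spacers. Because of the shared overlaps, any two
WWPs can anneal to each other's incorporated locus at a sufficiently low
temperature, pairing at both ends with the spacer looped out — a
"wristwatch" structure. Each walk runs three nested PCRs (primary,
secondary, tertiary), each pairing one WWP with one of three nested
gene-specific primers (GSPs) in the known region. Every round has three
annealing stages: a few high-stringency cycles in which only the GSP
primes, exactly **one** low- or reduced-stringency cycle in which the WWP
(partially) anneals, and the high-stringency amplification cycles. The
single partial-annealing cycle is the selectivity mechanism: a non-target
single strand made in that cycle never acquires a second perfect primer
site, so it cannot become double-stranded in the high-stringency cycles
and is diluted away. `wwpcr` implements primer design and validation for
this architecture and a simulator that predicts which amplicons survive
the three rounds and why.

## Thermodynamic model

Duplex stability uses the unified nearest-neighbor parameters
(SantaLucia's 1998 consolidation) with the monovalent-salt entropy
correction $\Delta S_{salt} = \Delta S + 0.368\,(N_{bp}-1)\ln[\mathrm{Na}^+]$
and the primer-excess two-state melting temperature

$$T_m = \frac{\Delta H}{\Delta S_{salt} + R \ln C_T} - 273.15,$$

with defaults 50 mM monovalent salt and $C_T$ = 200 nM primer (1 uL of a
10 uM stock in a 50 uL reaction). The primer-excess convention (rather
than $C_T/4$) is appropriate for primer–template annealing and places the
published WWP set at 60.7–62.2 °C, inside its specified 60–65 °C window.
Divalent cations are deliberately not modeled; see the stringency offset
below.

### The bipartite (wristwatch) duplex

For a primer annealed to a same-length site with only some positions
paired, paired blocks contribute nearest-neighbor stacks and each internal
unpaired region contributes a tabulated internal-loop penalty (loop size =
unpaired bases on both strands; sizes between tabulated values use
Jacobson–Stockmayer extrapolation). A naive all-or-none sum over the whole
structure, however, substantially underestimates the melting temperature
of asymmetric structures: for the 12 + 3 wristwatch, the weak 3-bp block
plus the 20-nt loop *cost* more free energy than they contribute, and the
all-or-none estimate lands near 28 °C even though the 12-bp core alone
melts near 40 °C. Physically the structure frays: the weak outer block
melts first and the stability of the complex tracks its most stable core.
`tm_wristwatch_duplex()` therefore evaluates every contiguous run of
paired blocks as a two-state sub-duplex (stacks, terminal penalties, and
the loops it spans) and reports the maximum Tm — 40.1 °C for the bundled
set, matching the ~40 °C inter-primer annealing temperature the protocol
is built around, while a full-length mask reduces *exactly* to the
perfect-duplex Tm.

One caveat documented by the test suite: strict monotonicity of Tm in
added paired content does not hold for any standard nearest-neighbor
parameterization (appending a terminal A/T pair to a short duplex can
lower Tm slightly through the terminal-penalty swap). The working
guarantee is bounded — growing the paired region never costs more than
about 1 °C, and the method-relevant ordering (3' block alone << wristwatch
< full duplex) is strict and large.

### Annealing gates and the stringency offset

A primer is taken to prime productively at stage temperature $T$ when (a)
its `min_3prime_match` 3'-terminal bases (default 3, the WWP 3'-overlap
length; at least 2 are required for function) pair contiguously and (b)
the duplex Tm reaches $T$ − `stringency_offset`. The offset (default
10 °C) absorbs what the monovalent-only model leaves out: PCR buffer
contains ~2 mM Mg²⁺, worth roughly 8–12 °C of duplex stabilization, which
is why primers with a 50 mM-monovalent Tm of 58–63 °C routinely prime in
65 °C annealing steps. The offset preserves all the separations the
method needs with the default profiles: the high-stringency gate (55 °C)
admits full primer sites (~58–65 °C) and rejects the wristwatch duplex
(40.1 °C) and planted partial sites; the reduced-stringency gate (30 °C)
admits the wristwatch; the low-stringency gate (15 °C) admits partial
sites of roughly 10 or more well-paired bases.

## Design rules and their defaults

`validate_wwp_set()` checks, against `wwp_architecture()`:

* **Layout** — each primer 25 nt; longest common prefix exactly 12;
  longest common suffix exactly 3.
* **Spacer dissimilarity** — no shared 6-mer between any two spacers and
  pairwise Hamming distance at least `spacer_len/2`. This operationalizes
  "mutually mismatched" so that each WWP anneals at its own loci in the
  primary round.
* **Self-Tm window** — each WWP within [60, 65] °C.
* **Tm gap** — min(self-Tm) − max(pairwise wristwatch Tm) at least
  20 °C, confining inter-primer annealing to the one reduced-stringency
  cycle. The bundled set measures 20.6 °C.
* **Base balance** — no base's count may deviate from `total_len/4` by
  more than 4.5. The tolerance is deliberately loose: the published,
  wet-lab-validated WWP1 itself carries only two A's (deviation 4.25), so
  the check flags only severe skew.
* **Structure screens** — hairpin stems of 5+ bp (loop ≥ 3 nt) and
  antiparallel complementary runs of 8+ bp (self- or cross-dimer) fail.
  The published nine primers score at most stem 3 / run 6 within any
  co-used pair, so these thresholds encode "no obvious dimer or hairpin"
  while letting all validated primers pass.

GSP nests are chosen on the strand pointing into the unknown flank, GSP1
farthest from the junction and GSP3 nearest (so each successive round's
product is slightly shorter), with each GSP's self-Tm within ±5 °C of its
paired WWP (the published pairs differ by up to ~4 °C under this model,
so the conventional ±3 °C would wrongly reject them) and screens against
the paired WWP clean.

## The simulator

`simulate_round()` tracks single-stranded species explicitly, each with
its actual sequence (primers are incorporated, so a partially matched
locus becomes a perfect site in the copy — the mechanism that turns an
arbitrary annealing event into a heritable primer site), reference
coordinates, and 5'/3' primer provenance.

* **Stage 1**: the GSP extends from every high-stringency site on every
  species, toward the template 5' end, capped at
  `elongation_rate × extension_time` (defaults 33.3 nt/s × 120 s = 4 kb,
  consistent with the longest observed walking products).
* **Stage 2** (one cycle, enforced): the WWP anneals at the reduced gate
  over **whole** single strands, not just the expected wristwatch locus —
  internal annealing to a well-matched site inside the unknown region is
  modeled, and its observed rarity is an emergent result, not an
  assumption.
* **Stage 3**: a species is `exponential` only if its 5' terminus is a
  current primer and a current primer has a high-stringency site on it
  from which extension reaches its 5' end; the defining amplicon is
  emitted on both strands. Species with one usable perfect site are
  `linear`; the rest `none`. Amplification is tracked as a class, not as
  molecule counts: the method's argument is the presence or absence of
  perfect primer sites, and band intensity is out of scope.

Products are classified by their terminal provenance: `target` (GSP at
its authentic locus + WWP), `typeI` (GSP at both ends), `typeII` (GSP at
an off-target locus + WWP), `typeIII` (WWP at both ends). The central
suppression property — no type III and no decoy-derived type II species
ever exponential after the primary round — is asserted across twenty
seeded fixtures in the test suite.

Carry-over between rounds copies the full deduplicated pool (dilution of
non-amplifiable species is implied by the class system rather than
modeled). Coordinates are 0-based half-open on the input plus strand;
minus-strand species store their plus-strand projection with a strand
flag. All results are deterministic given inputs.

## Synthetic fixtures: what they emulate and what they do not

In a real genome (megabases), a 25-nt walking primer finds partial
3'-anchored matches in any few-kilobase flank by chance. A 10-kb test
genome is far too small for that, so `make_walk_fixture()` *plants* them:
3'-terminal fragments of the primary WWP's complement (the fragment
length is chosen per primer so the partial duplex falls strictly between
the low- and high-stringency gates), at seeded positions in the unknown
flank. It also plants decoy GSP1 loci — exact complements carrying one or
two mismatches against the GSP 5' terminus, each with a downstream
walking-primer site — which demonstrably produce exponential type II
background in the primary round that the secondary round then removes.
The fixture's ground truth is enumerated by `enumerate_truth_amplicons()`,
an exhaustive offset scan written independently of the simulator: a
coordinate yields a tertiary band of `j + 25 − gsp3_start` nt exactly
when some round's walking primer clears its stage-2 gate there, the
footprint clears GSP3, and the extension cap is respected.

The fixtures use i.i.d. background sequence: no repeats, no GC isochores,
no gene structure. Passing the fixture suite therefore shows that the
*logic* of staged-stringency selection is implemented correctly — it does
not certify performance on repeat-rich genomes, nor predict band
intensities or amplification efficiency, which depend on kinetics this
model abstracts away.

## Problem sizes and numerical choices

The shipped tests run 10-kb genomes with 1-kb known regions across 20
fixture seeds, 50 scan-oracle templates of up to 5 kb, and 100
generator/validator seeds — sizes at which every check is exhaustive yet
the whole suite runs in under two minutes on one core. Site scanning is
seed-and-verify (exact 3'-terminal k-mer, then full ungapped mask), which
is proven equal to the exhaustive-offset oracle on every tested template.
Ties in site reporting are broken by ascending template coordinate.
Degenerate bases are rejected everywhere rather than wildcarded: the
method's primers are fully specified, and inventing IUPAC semantics for
the Tm model would add unverifiable behavior.

## Known limitations

* Monovalent-only salt model with a fixed stringency offset; no explicit
  Mg²⁺ or dNTP correction.
* Two-state (per sub-duplex) melting; no partition-function ensemble.
* No amplification kinetics: band presence, not intensity.
* Ungapped annealing only (no bulged primer sites).
* The wet-lab band patterns of the published gadA and hyg walks depend on
  the real genomes and reaction kinetics and are not reproduced here; the
  simulator is validated on properties of seeded synthetic fixtures
  instead.
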