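---
title: "Designing beta-sheet-rich spidroin mimics and scoring their self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing beta-sheet-rich spidroin mimics and scoring their self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidroinr)
library(dplyr)
```

Spider silk owes its strength to poly-alanine (A~6~--A~14~) blocks in the
repetitive core of major ampullate spidroins (MaSp1). Those same blocks make
recombinant expression miserable: GC-rich, repetitive templates, premature
termination, inclusion bodies. One design strategy replaces the poly-alanine
crystalline blocks with short beta-sheet-forming motifs mined from
water-soluble proteins, keeping the beta-sheet stacking that carries load
while improving solubility. `spidroinr` implements that workflow as three
composable stages — mine, design, analyze — plus deterministic synthetic-data
generators that make every stage testable offline.

## Motif mining

Strand segments are the unit of evidence. `parse_ss_records()` accepts DSSP
files or a simplified two-line dialect (`>id chain`, sequence line, secondary
structure line) and extracts every maximal run of residues in the extended
state `E`. Isolated beta-bridges (`B`) are excluded by default: a lone
bridge is not a sheet. Runs are per chain, and identical chains contribute
independently — frequency counts are per occurrence, which is the only
convention under which published per-motif frequencies can exceed the number
of contributing database entries.

`harvest_kmers()` counts every overlapping window of length 4--8 inside those
segments (windows touching an `X` are skipped). The default `k` range spans
the motif lengths of practical interest, from 5-mers like ITVQQ to 7-mers
like SVSVSVS. `screen_motifs()` then applies explicit, inspectable criteria:

* a frequency floor (default 10 occurrences);
* composition rescue flags — an AA dipeptide, a QQ dipeptide, a strict V/S
  alternation of length >= 4, or valine fraction >= 0.5 — any of which lets a
  rarer motif pass, because these patterns mark beta-sheet-competent
  chemistry (compact Ala side chains, hydrogen-bonding Gln pairs,
  hydrophobic/hydroxyl V/S interfaces, Val's strand preference);
* an optional mean strand-propensity floor, disabled by default. Propensity
  (the shipped Chou--Fasman P~beta~ scale; any complete table can be
  substituted) is used to *rank*, not to gate: well-attested motifs such as
  KTAAWN sit just below 1.0 on that scale and gating would discard them.

Ranking is frequency, then propensity, then motif string — a total order, so
screening output is reproducible to the byte.

```{r mining}
corp <- make_strand_corpus(corpus_plan(
  c(GVLEGV = 26, KTAAWN = 37, ITVQQ = 3, SVSVSVS = 2, VVVKI = 10),
  n_entries = 40, seed = 7
))
parse_ss_records(paste(corp$entries$text, collapse = "\n")) |>
  harvest_kmers() |>
  screen_motifs() |>
  filter(motif %in% c("GVLEGV", "KTAAWN", "ITVQQ", "SVSVSVS", "VVVKI")) |>
  select(motif, frequency, propensity, verdict, reason)
```

## Construct design

A repeat unit is edited in one of two ways: `shorten_polyA()` rewrites every
qualifying poly-A run (threshold 5, just below the native A~6~ floor so a
shortened 7-A design still counts) to a fixed length, and
`substitute_motif()` replaces each run with one copy of a screened motif.
Replacement is a direct block swap with no length-preserving padding; the
length identity `len_out = len_in - sum(run lengths) + n_runs * len(motif)`
is asserted in the tests. `assemble_protein()` concatenates
tag + NT + rep x n + CT (His6 at the N-terminus by default — six histidines
is the Ni-NTA convention; the tag is configurable and movable to the C
terminus) and computes the average-mass molecular weight.

DNA follows the protein. `codon_optimize()` reverse-translates with the
most-preferred codon per residue from a highly-expressed *E. coli* K-12
usage table, deterministically falling back to the next-ranked codon at any
position that would complete a forbidden restriction site on either strand.
Determinism makes the output bit-stable; the round trip
`translate(codon_optimize(p)) == p` always holds and an unsatisfiable
constraint (single-codon residues completing a site) raises an error naming
the offending window.

Repeat doubling uses the NheI/SpeI isocaudomer pair. Both enzymes leave the
same 5' CTAG overhang, so the repeat block excised with both enzymes ligates
into the SpeI-opened cassette; the junction duplex — GCTAGT on one strand,
ACTAGC on the other — is recognized by neither enzyme. Each round therefore
doubles the repeat count while keeping exactly one live NheI and one live
SpeI site for the next round: 3rep to 6rep to 12rep to 24rep in three
doublings, with `2^k - 1` inert scars. On the coding strand the scar reads
ACTAGC and translates in frame as Thr-Ser (the GCTAGT reading of the same
duplex belongs to the complementary strand); the flanking sites themselves
translate as Ala-Ser and Thr-Ser linkers, and the cassette keeps the reading
frame because every element is a multiple of three. DNA is modelled as a
linear top strand with 4-nt cohesive ends; `digest()`/`ligate()` make the
cohesive-end model explicit and round-trip any product.

```{r design}
tpl <- make_template(seed = 11) # synthetic template: three 15-A runs
sub <- substitute_motif(tpl$rep, "ITVQQ")
cassette <- design_cassette(assemble_protein(tpl$nt, sub, 3, tpl$ct))
multimerize(cassette, n_doublings = 3, repeat_count_in = 3)[c("repeat_count", "n_scars")]
```

## Assembly metrics

`analyze_assembly()` reduces a coarse-grained two-chain trajectory to the
four observables used to argue self-assembly, in the units the field plots
them:

* **Rg** (Angstrom): mass-weighted radius of gyration per chain, averaged
  over chains. A decreasing Rg means compaction.
* **SASA** (nm^2^): Shrake--Rupley quadrature over all beads. Each bead gets
  a deterministic golden-spiral point set (no RNG, so SASA is bit-stable) on
  its probe-expanded sphere; a point is exposed when outside every
  neighbour's expanded sphere, with neighbour pairs pruned at
  `r_i + r_j + 2 probe`. 960 points keep the isolated-sphere error under 1%.
* **COMD** (nm): distance between the two chains' centres of mass;
  approach indicates association.
* **RMSD/RMSF** (Angstrom): deviation from the first frame and per-residue
  fluctuation about the time-mean, both after mass-weighted Kabsch
  superposition (proper rotations only; reflections excluded by the
  determinant correction). The RMSF reference is the first frame in a single
  pass — the simplest deterministic convention.

Defaults: bead radius 0.235 nm (half the 0.47 nm regular coarse-grained bead
diameter), probe 0.14 nm (water), bead mass 72 amu (the 4-heavy-atoms-per-
bead mapping); all per-bead configurable through the bead table. Coordinates
are stored in nm; there is no periodic-boundary handling — trajectories are
assumed whole-molecule, and PBC unwrapping is out of scope.

The *assembly verdict* needs a concrete rule for "the curves decrease". A
series counts as decreasing when (i) more than half of all ordered pairs
decrease — a Kendall-style sign statistic over the whole series, chosen
because consecutive-step signs are a coin flip whenever per-frame drift is
smaller than the frame-to-frame noise — and (ii) the fitted linear drop over
the series exceeds twice its standard error. The fitted drop replaces a raw
first-minus-last delta for the same reason: endpoints are two noisy points,
while the slope uses all of them. With zero noise both conditions reduce to
"the series actually goes down", so a static trajectory is never called
assembled. The verdict is "assembly" only when Rg, SASA and COMD all pass.
Reported deltas remain first-vs-last (`percent_change()`, `series_delta()`)
because that is how endpoint summaries are quoted.

```{r analyze}
sim <- make_assembly_traj(trajectory_plan(n_frames = 20, jitter_sigma = 0.05, seed = 1))
am <- analyze_assembly(sim$traj, n_points = 96)
glance(am)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(am)
```

## What the synthetic generators emulate — and what they do not

The generators exist so every pipeline stage has provable ground truth:

* `make_strand_corpus()` plants each motif occurrence as its own strand
  segment, with all background text drawn from an alphabet disjoint from the
  motifs' residues. Exact-count recovery is therefore a theorem, not a
  probability; the plan is rejected if a planted motif is a substring of
  another or the background alphabet clashes. The cost is realism: corpus
  composition statistics are nothing like real strand databases, so passing
  recovery tests says the counter is correct, not that real mining is easy.
* `make_template()` reproduces the native architecture (NT, repeat region
  with poly-A runs at recorded positions, CT) with alanine-free flanks, so
  run bookkeeping is exact. Domain lengths default to the published NT
  (137 aa) and CT (98 aa) domain sizes; sequences are synthetic stand-ins,
  not accession sequences.
* `make_assembly_traj()` ramps the COM separation (default 24.95 to
  18.887 nm) and per-chain Rg (default 14.2 to 13.46 Angstrom) linearly over
  1000 ns with i.i.d. Gaussian jitter (default sigma 0.05 nm) on otherwise
  rigid 30-bead chains. Thirty beads per chain makes the clusters dense
  enough that compaction increases bead overlap and SASA genuinely falls, as
  it does for a folding chain; a much sparser cluster would be a set of
  disjoint spheres whose SASA is constant. The chains are rigid between
  scale steps — there is no conformational model, no force field, no
  thermostat — so recovery tests validate the metrics, not any physics.

Seeds are mandatory everywhere; every generator is a pure function of its
plan, and reruns are byte-identical.

## Numerical choices and degenerate inputs

* Kabsch superposition warns on near-collinear point sets (the rotation is
  ill-conditioned) and requires at least three points.
* SASA validates radii, probe (> 0) and point count (>= 32); quadrature
  error for an isolated sphere shrinks as points double and is asserted
  below 1% at 960 points.
* `percent_change()` refuses a zero first value; RMSF refuses single-frame
  trajectories; COMD refuses missing chains with a selection error naming
  the chain.
* Screening ties cannot survive the three-key comparator for distinct
  motifs, so ranking is a total order.
* Codon choice is argmax-with-fallback, never sampled; SASA points are a
  fixed lattice — the only randomness in the package lives in the
  generators, behind mandatory seeds.

## Problem sizes

The shipped tests mine corpora of up to 10^4^ entries (about 3 x 10^5^
background residues) in a few seconds, and analyze 50-frame, 60-bead
trajectories with 96--960 quadrature points per bead. These sizes were
chosen to exercise every code path at comfortable interactive speed; all
functions scale to larger inputs linearly in frames and near-linearly in
beads (SASA neighbour pruning is the only quadratic term).

## Known limitations

* The screening engine is the explicit criteria above; it does not attempt
  to reproduce any learned model, and the published 68.4% valine-content
  figure for VVVKI is not reproducible from the motif alone (3/5 = 60%; the
  context window behind the published number is unknown).
* Molecular weights of published constructs are reference points only:
  tag/linker details of the originals are unstated, so equality is not
  asserted anywhere.
* Trajectory analysis trusts its input to be whole-molecule; wrapped
  periodic images will corrupt Rg and COMD silently.
* `multimerize()` models the top strand of a linear duplex; circular
  plasmids, partial digests and star activity are out of scope.
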