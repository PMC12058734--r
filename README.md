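# spidroinr

Design toolkit for **recombinant spider silk proteins (spidroins)** and the
computational verification of their self-assembly.

Native major ampullate spidroin (MaSp1) gets its tensile strength from
poly-alanine blocks (A_n, n = 6–14) that stack into β-sheet nanocrystals —
and those same blocks make the protein nearly unexpressible in *E. coli*.
`spidroinr` implements the design loop that works around this:

1. **Mine** β-strand motifs from secondary-structure-annotated sequence data
   (DSSP or a simple two-line dialect), counting every overlapping k-mer
   (k = 4–8) inside strand segments and screening candidates by frequency,
   composition flags (AA / QQ dipeptides, V/S alternation, valine content)
   and mean Chou–Fasman strand propensity Pβ.
2. **Design** chimeric constructs: shorten poly-A runs (15 → 7) or replace
   them with a screened motif, assemble His6–NT–repⁿ–CT, codon-optimize for
   *E. coli* with restriction sites forbidden, and double the repeat count
   iteratively with the NheI/SpeI isocaudomer strategy (both enzymes leave
   CTAG cohesive ends; their hybrid junction GCTAGT/ACTAGC is cut by
   neither, so 3rep → 6rep → 12rep → 24rep while the flanking sites stay
   live).
3. **Analyze** coarse-grained bead trajectories of the designed proteins:
   radius of gyration `Rg = sqrt(Σ mᵢ|rᵢ − r_com|² / Σ mᵢ)` (Å), per-residue
   RMSF and RMSD after mass-weighted Kabsch superposition (Å), Shrake–Rupley
   solvent-accessible surface area `Σᵢ 4π(rᵢ+probe)² · exposedᵢ/total` (nm²),
   inter-chain centre-of-mass distance (nm), and an explicit assembly
   verdict (all three of Rg, SASA, COMD trending down).

Seeded synthetic-data generators (strand corpora with exactly planted motif
counts, architecture-faithful template sequences, two-chain trajectories
with scripted compaction/approach ramps) make the whole pipeline testable
without any downloads.

## Worked example

```r
library(spidroinr)
library(dplyr)

# --- mine: corpus with the published motif frequencies planted -------------
corp <- make_strand_corpus(corpus_plan(
  c(GVLEGV = 26, KTAAWN = 37, ITVQQ = 3, SVSVSVS = 2, VVVKI = 10),
  n_entries = 40, seed = 7
))
db <- parse_ss_records(paste(corp$entries$text, collapse = "\n")) |>
  harvest_kmers() |>
  screen_motifs()
db |> filter(motif == "KTAAWN") |> select(motif, frequency, propensity, reason)
#> # A tibble: 1 × 4
#>   motif  frequency propensity reason
#>   <chr>      <int>      <dbl> <chr>
#> 1 KTAAWN        37      0.975 frequency 37 times; contains AA

# --- design: replace poly-A with ITVQQ, double the cassette three times ----
tpl <- make_template(seed = 11)               # synthetic NT/rep/CT template
con <- assemble_protein(tpl$nt, substitute_motif(tpl$rep, "ITVQQ"),
                        n_rep = 3, ct = tpl$ct) |> construct_dna()
con
#> <spidroin_construct 3rep-rep-ITVQQ>
#>   430 aa (3 x 63-aa repeat), MW 47.4 kDa, DNA 1293 nt
m <- multimerize(design_cassette(con), n_doublings = 3, repeat_count_in = 3)
c(m$repeat_count, m$n_scars,
  length(find_sites(m$dna, "NheI")), length(find_sites(m$dna, "SpeI")))
#> [1] 24  7  1  1

# --- analyze: scripted two-chain trajectory, default study conditions ------
sim <- make_assembly_traj(trajectory_plan(seed = 1))
am <- analyze_assembly(sim$traj, n_points = 96)
am
#> <assembly_metrics>  51 frames, chains A/B
#>   verdict: assembly
#>   - Rg compacts (delta 0.847 Angstrom, 92% of ordered pairs decreasing)
#>   - SASA decreases (reduction 4.88%)
#>   - COM distance closes (delta 6.053 nm)
autoplot(am)   # four-panel Rg / SASA / COMD / RMSD time series
```

The mined frequencies equal the planted counts exactly (the corpus
background alphabet is disjoint from the motif residues, so recovery is
provable); the multimerization numbers are the `n₀·2^k` doubling algebra
with `2^k − 1` inert scars; and the analysis verdict reports which of the
three observables genuinely trend downward and by how much.

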