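# shared helpers for the test suite

# brute-force k-mer counter over explicit segment strings: the independent
# oracle for harvest_kmers
brute_count_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (!grepl("X", w, fixed = TRUE)) out <- c(out, w)
    }
  }
  table(out)
}

segments_tbl <- function(seqs, source_id = "s1", chain_id = "A") {
  tibble::tibble(
    source_id = rep_len(source_id, length(seqs)),
    chain_id = rep_len(chain_id, length(seqs)),
    start = 1L,
    end = nchar(seqs),
    sequence = seqs
  )
}

# minimal DSSP-layout text: one residue line per element of aa/ss/chain
dssp_text <- function(aa, ss, chain) {
  c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d %4d %s %s  %s          0   0  100",
            seq_along(aa), seq_along(aa), chain, aa, ss)
  )
}

# two-chain static trajectory: chains separated by `sep` nm along x
static_two_chain_traj <- function(n_frames = 3, n_beads = 4, sep = 5) {
  base <- matrix(seq_len(n_beads * 3) / 10, ncol = 3)
  base <- sweep(base, 2, colMeans(base))
  coords <- array(NA_real_, dim = c(n_frames, 2 * n_beads, 3))
  for (f in seq_len(n_frames)) {
    coords[f, seq_len(n_beads), ] <- sweep(base, 2, c(-sep / 2, 0, 0), `+`)
    coords[f, n_beads + seq_len(n_beads), ] <- sweep(base, 2, c(sep / 2, 0, 0), `+`)
  }
  beads <- tibble::tibble(
    bead = sprintf("%s%02d", rep(c("A", "B"), each = n_beads),
                   rep(seq_len(n_beads), 2)),
    chain = rep(c("A", "B"), each = n_beads),
    residue = rep(seq_len(n_beads), 2),
    mass = 72, radius = 0.235
  )
  cg_trajectory(coords, beads)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
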