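test_that("poly-A runs are located as maximal qualifying intervals", {
  runs <- find_polyA_runs("GGAAAAAAAGG", 5)
  expect_equal(runs$start, 3L)
  expect_equal(runs$end, 9L)

  expect_equal(nrow(find_polyA_runs("GAGAGA", 5)), 0)

  two <- find_polyA_runs("AAAAAGAAAAAA", 5)
  expect_equal(nrow(two), 2)
  expect_equal(two$length, c(5L, 6L))
  # sub-threshold runs are ignored
  expect_equal(nrow(find_polyA_runs("AAAAGAAAA", 5)), 0)
})

test_that("poly-A shortening truncates every run to the target", {
  ru <- repeat_unit(paste0("GGQ", strrep("A", 15), "QGG"), name = "wt")
  out <- shorten_polyA(ru, 7)
  expect_equal(out$polyA_runs$length, 7L)
  expect_equal(nchar(out$sequence), nchar(ru$sequence) - 8L)

  # already at target: identity
  ru7 <- repeat_unit(paste0("GG", strrep("A", 7), "GG"))
  expect_equal(shorten_polyA(ru7, 7)$sequence, ru7$sequence)

  # several runs, all rewritten
  ru2 <- repeat_unit(paste0("Q", strrep("A", 10), "Q", strrep("A", 15), "Q"))
  out2 <- shorten_polyA(ru2, 7)
  expect_equal(out2$polyA_runs$length, c(7L, 7L))

  # no run: warn + identity by default, error on request
  none <- repeat_unit("GQGQGQGQ")
  expect_warning(same <- shorten_polyA(none, 7), "no poly-A run")
  expect_equal(same$sequence, none$sequence)
  expect_error(shorten_polyA(none, 7, on_missing = "error"), "no poly-A run")
})

test_that("motif substitution replaces each run with one motif copy", {
  out <- substitute_motif(repeat_unit("GGAAAAAAAGG"), "ITVQQ")
  expect_equal(out$sequence, "GGITVQQGG")
  expect_equal(nrow(out$polyA_runs), 0)

  # identity substitution
  same <- substitute_motif(repeat_unit("GGAAAAAAAGG"), "AAAAAAA")
  expect_equal(same$sequence, "GGAAAAAAAGG")

  # two runs: length bookkeeping len_out = len_in - sum(runs) + n_runs*len(motif)
  seq_in <- paste0("Q", strrep("A", 10), "Q", strrep("A", 15), "Q")
  out2 <- substitute_motif(repeat_unit(seq_in), "KTAAWN")
  expect_equal(nchar(out2$sequence), nchar(seq_in) - 25L + 2L * 6L)

  expect_error(substitute_motif(repeat_unit("GQGQ"), "ITVQQ"), "no poly-A run")
})

test_that("length bookkeeping holds across random repeat units", {
  set.seed(31)
  for (i in 1:10) {
    n_runs <- sample(1:3, 1)
    parts <- "G"
    lens <- integer()
    for (r in seq_len(n_runs)) {
      len <- sample(5:15, 1)
      lens <- c(lens, len)
      parts <- paste0(parts, strrep("A", len),
                      paste(sample(c("G", "Q", "S"), 3, replace = TRUE),
                            collapse = ""))
    }
    motif <- paste(sample(c("I", "T", "V", "Q"), sample(4:7, 1), replace = TRUE),
                   collapse = "")
    out <- substitute_motif(repeat_unit(parts), motif)
    expect_equal(nchar(out$sequence),
                 nchar(parts) - sum(lens) + n_runs * nchar(motif))
  }
})

test_that("protein assembly concatenates tag, NT, repeats, CT", {
  con <- assemble_protein(nt = "M", rep = "AG", n_rep = 3, ct = "Y", tag = "")
  expect_equal(con$protein, "MAGAGAGY")

  one <- assemble_protein("M", "AG", 1, "Y", tag = "")
  two <- assemble_protein("M", "AG", 2, "Y", tag = "")
  expect_equal(nchar(two$protein) - nchar(one$protein), 2L)

  tagged <- assemble_protein("M", "AG", 1, "Y")
  expect_equal(tagged$protein, "HHHHHHMAGY")
  ctag <- assemble_protein("M", "AG", 1, "Y", tag_terminus = "C")
  expect_equal(ctag$protein, "MAGYHHHHHH")

  expect_error(assemble_protein("M", "", 1, "Y"), "empty")
  expect_match(assemble_protein("M", repeat_unit("AG", "x"), 3, "Y")$name,
               "^3rep-x$")
})

test_that("construct tidier and glance summarize the architecture", {
  con <- assemble_protein("MNT", repeat_unit("GAV", "r"), 2, "CT")
  td <- tidy(con)
  expect_equal(td$segment, c("tag", "nt", "rep", "rep", "ct"))
  expect_equal(sum(td$length), nchar(con$protein))
  expect_equal(td$end[nrow(td)], nchar(con$protein))
  g <- glance(con)
  expect_equal(g$n_rep, 2L)
  expect_equal(g$mw_kda, con$mw_da / 1000)
})

test_that("molecular weight uses average residue masses plus one water", {
  expect_equal(protein_mw(""), 18.0153)
  expect_equal(protein_mw("G"), 75.0672, tolerance = 1e-6)
  expect_equal(protein_mw("GG"), 132.1191, tolerance = 1e-6)
  # additivity: mw(a+b) == mw(a) + mw(b) - water
  expect_equal(protein_mw("GVLEGV"),
               protein_mw("GVL") + protein_mw("EGV") - 18.0153)
  expect_error(protein_mw("GZ"), "non-canonical")
})

test_that("molecular weight agrees with the seqinr oracle", {
  seqs <- c("ITVQQ", "HHHHHHMGVLEGV", "KTAAWNSVSVSVS")
  for (s in seqs) {
    oracle <- seqinr::pmw(strsplit(s, "")[[1]])
    expect_equal(protein_mw(s), oracle, tolerance = 1e-3)
  }
})
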