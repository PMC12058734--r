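test_that("generators are pure functions of plan + seed", {
  cp <- corpus_plan(c(GVLEGV = 5, ITVQQ = 2), n_entries = 4, seed = 7)
  expect_identical(make_strand_corpus(cp), make_strand_corpus(cp))
  cp2 <- corpus_plan(c(GVLEGV = 5, ITVQQ = 2), n_entries = 4, seed = 8)
  expect_false(identical(make_strand_corpus(cp)$entries,
                         make_strand_corpus(cp2)$entries))

  expect_identical(make_template(seed = 3), make_template(seed = 3))

  tp <- trajectory_plan(n_frames = 4, jitter_sigma = 0.1, seed = 5)
  expect_identical(make_assembly_traj(tp)$traj$coords,
                   make_assembly_traj(tp)$traj$coords)
})

test_that("seeds are mandatory for every generator", {
  expect_error(corpus_plan(c(GVLEGV = 1), n_entries = 1), "seed")
  expect_error(make_template(), "seed")
  expect_error(trajectory_plan(), "seed")
})

test_that("planted motif counts are recovered exactly across seeds", {
  planted <- c(GVLEGV = 26, KTAAWN = 37, ITVQQ = 3, SVSVSVS = 2, VVVKI = 10)
  for (seed in c(1, 7, 42)) {
    corp <- make_strand_corpus(corpus_plan(planted, n_entries = 25, seed = seed))
    segs <- parse_ss_records(paste(corp$entries$text, collapse = "\n"))
    db <- harvest_kmers(segs)
    for (m in names(planted)) {
      expect_equal(db$frequency[db$motif == m], unname(planted[[m]]),
                   info = sprintf("motif %s seed %d", m, seed))
    }
  }
})

test_that("the corpus never contains unplanted occurrences of planted motifs", {
  planted <- c(GVLEGV = 4, ITVQQ = 1)
  corp <- make_strand_corpus(corpus_plan(planted, n_entries = 3, seed = 13))
  whole <- paste(corp$entries$text, collapse = "")
  for (m in names(planted)) {
    hits <- gregexpr(m, whole, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), unname(planted[[m]]))
  }
})

test_that("manifest ground truth suffices to predict harvested counts", {
  corp <- make_strand_corpus(corpus_plan(c(VVVKI = 6), n_entries = 2, seed = 2))
  expect_equal(corp$manifest$planted$VVVKI, 6)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_identical(readLines(file.path(dir, "entry1.ss")),
                   strsplit(corp$entries$text[[1]], "\n")[[1]])
})

test_that("overlapping or clashing plans are rejected", {
  expect_error(corpus_plan(c(SVSV = 1, SVSVSVS = 2), n_entries = 1, seed = 1),
               "substring")
  expect_error(
    corpus_plan(c(GVLEGV = 1), n_entries = 1,
                background_alphabet = c("G", "D"), seed = 1),
    "shares residue"
  )
})

test_that("synthetic templates carry exact poly-A ground truth", {
  tpl <- make_template(polyA_runs = c(15, 15), seed = 21)
  runs <- find_polyA_runs(tpl$rep$sequence)
  expect_equal(runs$length, c(15L, 15L))
  expect_equal(runs$start, tpl$manifest$polyA_runs$start)

  short <- shorten_polyA(tpl$rep, 7)
  expect_equal(find_polyA_runs(short$sequence)$length, c(7L, 7L))

  tpl3 <- make_template(polyA_runs = c(7, 7, 7), seed = 21)
  expect_equal(nrow(find_polyA_runs(tpl3$rep$sequence)), 3)

  # FASTA round trip
  f <- withr::local_tempfile(fileext = ".fasta")
  write_template_fasta(tpl, f)
  back <- read_template_fasta(f)
  expect_equal(back$nt, tpl$nt)
  expect_equal(back$rep$sequence, tpl$rep$sequence)
})

test_that("jitter-free trajectories follow the scripted ramps exactly", {
  sim <- make_assembly_traj(trajectory_plan(
    n_frames = 6, n_beads_per_chain = 7, comd_start = 25, comd_end = 18,
    jitter_sigma = 0, seed = 9
  ))
  comd <- vapply(seq_len(6), function(f) {
    com_distance(frame_coords(sim$traj, f), sim$traj$beads, "A", "B")
  }, numeric(1))
  expect_equal(comd, seq(25, 18, length.out = 6), tolerance = 1e-9)
  expect_equal(sim$manifest$truth$comd, comd, tolerance = 1e-9)

  # constant-Rg plan: compaction verdict component is false
  flat <- make_assembly_traj(trajectory_plan(
    n_frames = 6, n_beads_per_chain = 7, rg_start = 14, rg_end = 14,
    jitter_sigma = 0, seed = 9
  ))
  am <- analyze_assembly(flat$traj, n_points = 64)
  expect_equal(am$deltas$rg_delta, 0, tolerance = 1e-9)
  expect_false(am$trend$rg$decreasing)
  expect_false(am$verdict)
})

test_that("per-chain Rg hits the scripted endpoints", {
  sim <- make_assembly_traj(trajectory_plan(
    n_frames = 3, n_beads_per_chain = 10, rg_start = 14.2, rg_end = 13.46,
    jitter_sigma = 0, seed = 6
  ))
  for (ch in c("A", "B")) {
    sel <- sim$traj$beads$chain == ch
    rg1 <- radius_of_gyration(frame_coords(sim$traj, 1)[sel, ],
                              sim$traj$beads$mass[sel]) * 10
    rg3 <- radius_of_gyration(frame_coords(sim$traj, 3)[sel, ],
                              sim$traj$beads$mass[sel]) * 10
    expect_equal(rg1, 14.2, tolerance = 1e-9)
    expect_equal(rg3, 13.46, tolerance = 1e-9)
  }
})
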