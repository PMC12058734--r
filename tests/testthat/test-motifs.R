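test_that("harvest counts overlapping windows per occurrence", {
  db <- harvest_kmers(segments_tbl("GVLEGV"), 6, 6)
  expect_equal(db$motif, "GVLEGV")
  expect_equal(db$frequency, 1L)

  db4 <- harvest_kmers(segments_tbl("SVSVSVS"), 4, 4)
  expect_equal(db4$frequency[db4$motif == "SVSV"], 2L)
  expect_equal(db4$frequency[db4$motif == "VSVS"], 2L)

  # identical chains double-count occurrences but share one source
  two <- harvest_kmers(segments_tbl(c("GVLEGV", "GVLEGV")), 6, 6)
  expect_equal(two$frequency, 2L)
  expect_equal(two$n_sources, 1L)
})

test_that("windows containing X are skipped", {
  db <- harvest_kmers(segments_tbl("GVXEGV"), 4, 4)
  expect_equal(nrow(db), 0)
  db2 <- harvest_kmers(segments_tbl("GVVVVXEG"), 4, 4)
  expect_false(any(grepl("X", db2$motif)))
  expect_equal(sum(db2$frequency), 2L) # GVVV, VVVV survive
})

test_that("harvest matches a brute-force window enumeration", {
  set.seed(101)
  for (rep in 1:5) {
    seqs <- vapply(1:6, function(i) {
      paste(sample(c("G", "V", "S", "A", "X"), sample(3:12, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    db <- harvest_kmers(segments_tbl(seqs), 4, 5)
    for (k in 4:5) {
      oracle <- brute_count_kmers(seqs, k)
      got <- db[db$k == k, ]
      expect_equal(sort(got$motif), sort(names(oracle)))
      expect_equal(got$frequency[match(names(oracle), got$motif)],
                   as.integer(oracle), ignore_attr = TRUE)
    }
  }
})

test_that("window conservation: total frequency equals window count minus X windows", {
  set.seed(7)
  seqs <- vapply(1:10, function(i) {
    paste(sample(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"),
                 sample(2:15, 1), replace = TRUE), collapse = "")
  }, character(1))
  for (k in c(4L, 6L)) {
    db <- harvest_kmers(segments_tbl(seqs), k, k)
    n_windows <- sum(pmax(0L, nchar(seqs) - k + 1L))
    n_x <- sum(vapply(seqs, function(s) {
      if (nchar(s) < k) return(0L)
      sum(vapply(seq_len(nchar(s) - k + 1L), function(i) {
        grepl("X", substr(s, i, i + k - 1L), fixed = TRUE)
      }, logical(1)))
    }, integer(1)))
    expect_equal(sum(db$frequency), n_windows - n_x)
  }
})

test_that("composition features flag the screening patterns", {
  f <- composition_features(c("VVVKI", "KTAAWN", "ITVQQ", "SVSVSVS", "GVLEGV"))
  expect_equal(f$val_fraction[f$motif == "VVVKI"], 0.6)
  expect_true(f$has_AA[f$motif == "KTAAWN"])
  expect_true(f$has_QQ[f$motif == "ITVQQ"])
  expect_true(f$vs_alternating[f$motif == "SVSVSVS"])
  expect_false(any(f$vs_alternating[f$motif != "SVSVSVS"]))
  expect_equal(f$hydrophobic_fraction[f$motif == "VVVKI"], 4 / 5)
})

test_that("composition features are pure and case-insensitive", {
  expect_identical(composition_features("itvqq"), composition_features("ITVQQ"))
  expect_identical(composition_features("KTAAWN"), composition_features("KTAAWN"))
  expect_false(composition_features("VSV")$vs_alternating) # too short
  expect_false(composition_features("VVSS")$vs_alternating) # adjacent equal
  expect_error(composition_features("VB1"), "non-canonical")
})

test_that("propensity is the mean of per-residue table entries", {
  tbl <- chou_fasman_beta()
  expect_equal(beta_propensity("V"), tbl[["V"]])
  expect_equal(beta_propensity("AAAA"), tbl[["A"]])
  # oracle: direct means from the shipped table
  expect_equal(beta_propensity("VVVKI"),
               mean(tbl[c("V", "V", "V", "K", "I")]))
  expect_gt(beta_propensity("VVVKI"), beta_propensity("GGGGG"))
  expect_error(beta_propensity("V", scale = c(A = 1)), "lacks residue")
})

table1_db <- function() {
  tibble::tibble(
    motif = c("GVLEGV", "KTAAWN", "ITVQQ", "SVSVSVS", "VVVKI"),
    frequency = c(26L, 37L, 3L, 2L, 10L)
  )
}

test_that("all five reference motifs pass screening with matching reasons", {
  out <- screen_motifs(table1_db())
  expect_true(all(out$verdict == "pass"))
  expect_match(out$reason[out$motif == "GVLEGV"], "frequency 26 times")
  expect_match(out$reason[out$motif == "KTAAWN"], "contains AA")
  expect_match(out$reason[out$motif == "KTAAWN"], "frequency 37 times")
  expect_match(out$reason[out$motif == "ITVQQ"], "contains QQ")
  expect_match(out$reason[out$motif == "SVSVSVS"], "V/S alternation")
  expect_match(out$reason[out$motif == "VVVKI"], "high V content")
  expect_match(out$reason[out$motif == "VVVKI"], "frequency 10 times")
})

test_that("unflagged low-frequency motifs fail; rescue can be disabled", {
  db <- dplyr::bind_rows(table1_db(),
                         tibble::tibble(motif = "GGGG", frequency = 1L))
  out <- screen_motifs(db)
  expect_equal(out$verdict[out$motif == "GGGG"], "fail")
  expect_match(out$reason[out$motif == "GGGG"], "below floor")

  no_rescue <- screen_motifs(db, screening_criteria(pattern_flags_rescue = FALSE))
  expect_equal(no_rescue$verdict[no_rescue$motif == "ITVQQ"], "fail")
  expect_equal(no_rescue$verdict[no_rescue$motif == "GVLEGV"], "pass")
})

test_that("ranking is frequency desc, propensity desc, then motif, with no ties", {
  db <- tibble::tibble(
    motif = c("GGGGG", "VVVVV", "AAAA", "NNNN"),
    frequency = c(5L, 5L, 9L, 2L)
  )
  out <- screen_motifs(db, screening_criteria(min_frequency = 1))
  expect_equal(out$motif, c("AAAA", "VVVVV", "GGGGG", "NNNN"))
  # total order: distinct motifs never compare equal on all three keys
  key <- paste(out$frequency, out$propensity, out$motif)
  expect_equal(anyDuplicated(key), 0)
})

test_that("screening is idempotent", {
  once <- screen_motifs(table1_db())
  twice <- screen_motifs(once[names(table1_db())])
  expect_equal(once$motif, twice$motif)
  expect_equal(once$verdict, twice$verdict)
  expect_equal(once$reason, twice$reason)
})

test_that("motif database round-trips through the TSV writer", {
  out <- screen_motifs(table1_db())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_db(out, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$motif, out$motif)
  expect_equal(back$frequency, out$frequency)
  expect_equal(back$verdict, out$verdict)
})
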