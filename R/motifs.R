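#' Count k-mers inside beta-strand segments
#'
#' Builds the motif frequency database: every overlapping window of length
#' `k_min..k_max` that lies fully inside a strand segment is counted once per
#' occurrence, so identical chains contribute separately; the set of distinct
#' `source_id`s per motif is kept alongside. Windows containing `X` are
#' skipped.
#'
#' @param segments Tibble of strand segments as produced by
#'   [parse_ss_records()] (columns `source_id`, `chain_id`, `sequence`).
#' @param k_min,k_max Window length range (inclusive).
#' @return Tibble with columns `motif`, `k`, `frequency`, `n_sources` and a
#'   list-column `sources`.
#' @export
#' @examples
#' segs <- tibble::tibble(source_id = "s1", chain_id = "A", sequence = "SVSVSVS")
#' harvest_kmers(segs, k_min = 4, k_max = 4)
harvest_kmers <- function(segments, k_min = 4L, k_max = 8L) {
  stopifnot(is.data.frame(segments), k_min >= 1L, k_max >= k_min)
  if (nrow(segments) == 0) {
    return(tibble(
      motif = character(), k = integer(), frequency = integer(),
      n_sources = integer(), sources = list()
    ))
  }
  seqs <- toupper(segments$sequence)
  lens <- nchar(seqs)
  occ <- list()
  for (k in seq.int(k_min, k_max)) {
    idx <- which(lens >= k)
    if (length(idx) == 0) next
    n_win <- lens[idx] - k + 1L
    seg_of <- rep.int(idx, n_win)
    starts <- sequence(n_win)
    kmers <- substring(seqs[seg_of], starts, starts + k - 1L)
    keep <- !grepl("X", kmers, fixed = TRUE)
    if (!any(keep)) next
    occ[[length(occ) + 1L]] <- tibble(
      motif = kmers[keep],
      k = k,
      source_id = segments$source_id[seg_of][keep]
    )
  }
  if (length(occ) == 0) {
    return(tibble(
      motif = character(), k = integer(), frequency = integer(),
      n_sources = integer(), sources = list()
    ))
  }
  list_rbind(occ) |>
    summarise(
      frequency = dplyr::n(),
      n_sources = dplyr::n_distinct(.data$source_id),
      sources = list(sort(unique(.data$source_id))),
      .by = c("motif", "k")
    )
}

#' Composition features of a candidate motif
#'
#' Computes the screening features used alongside raw frequency: valine
#' fraction, hydrophobic fraction over a configurable residue set, presence
#' of the AA and QQ dipeptides, and whether the motif is a strict V/S
#' alternation of length >= 4.
#'
#' @param motif Character vector of motifs (canonical residues only).
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @return Tibble with one row per motif: `motif`, `val_fraction`,
#'   `hydrophobic_fraction`, `has_AA`, `has_QQ`, `vs_alternating`.
#' @export
#' @examples
#' composition_features(c("KTAAWN", "ITVQQ", "SVSVSVS"))
composition_features <- function(motif, hydrophobic_set = hydrophobic_residues()) {
  motif <- vapply(motif, assert_protein, character(1), arg = "motif",
                  USE.NAMES = FALSE)
  n <- nchar(motif)
  if (any(n == 0)) abort("`motif` must be non-empty")
  count_in_set <- function(m, set) {
    sum(strsplit(m, "")[[1]] %in% set)
  }
  tibble(
    motif = motif,
    val_fraction = vapply(motif, count_in_set, numeric(1), set = "V",
                          USE.NAMES = FALSE) / n,
    hydrophobic_fraction = vapply(motif, count_in_set, numeric(1),
                                  set = hydrophobic_set, USE.NAMES = FALSE) / n,
    has_AA = str_detect(motif, fixed("AA")),
    has_QQ = str_detect(motif, fixed("QQ")),
    vs_alternating = n >= 4 &
      grepl("^[VS]+$", motif) &
      !grepl("VV", motif, fixed = TRUE) &
      !grepl("SS", motif, fixed = TRUE)
  )
}

#' Mean beta-strand propensity of a motif
#'
#' Arithmetic mean of per-residue propensities under a configurable scale
#' (default [chou_fasman_beta()]).
#'
#' @param motif Character vector of motifs.
#' @param scale Named numeric vector mapping residues to propensities.
#' @return Numeric vector of mean propensities.
#' @export
#' @examples
#' beta_propensity("VVVKI") > beta_propensity("GGGGG")
beta_propensity <- function(motif, scale = chou_fasman_beta()) {
  vapply(motif, function(m) {
    m <- assert_protein(m, arg = "motif")
    letters <- strsplit(m, "")[[1]]
    missing <- setdiff(unique(letters), names(scale))
    if (length(missing) > 0) {
      abort(sprintf("propensity scale lacks residue(s): %s",
                    paste(missing, collapse = ", ")))
    }
    mean(scale[letters])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Screening criteria for candidate motifs
#'
#' Encodes the screening policy as explicit thresholds: a frequency floor,
#' an optional propensity floor (disabled at 0 by default, since composition
#' and frequency — not propensity — decide selection; propensity orders the
#' ranking), and a rescue rule under which motifs flagged by composition
#' (AA or QQ dipeptide, V/S alternation, valine fraction >= 0.5) pass even
#' below the frequency floor.
#'
#' @param min_frequency Frequency floor for an unflagged motif.
#' @param min_propensity Minimum mean strand propensity (0 disables).
#' @param pattern_flags_rescue Let composition flags bypass the floor.
#' @param k_range Length-2 integer vector, motif lengths mined.
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @return A list of class `screening_criteria`.
#' @export
screening_criteria <- function(min_frequency = 10L,
                               min_propensity = 0,
                               pattern_flags_rescue = TRUE,
                               k_range = c(4L, 8L),
                               hydrophobic_set = hydrophobic_residues()) {
  stopifnot(
    length(k_range) == 2, k_range[[1]] >= 4, k_range[[2]] >= k_range[[1]],
    min_frequency >= 1
  )
  structure(
    list(
      min_frequency = as.integer(min_frequency),
      min_propensity = min_propensity,
      pattern_flags_rescue = isTRUE(pattern_flags_rescue),
      k_range = as.integer(k_range),
      hydrophobic_set = hydrophobic_set
    ),
    class = "screening_criteria"
  )
}

#' Screen and rank a motif frequency database
#'
#' Annotates each motif with composition features and mean strand propensity,
#' assigns a pass/fail verdict with a human-readable reason, and ranks by
#' frequency (desc), propensity (desc), then motif (asc) — a total order for
#' distinct motifs.
#'
#' A motif passes when its frequency reaches `min_frequency`, or (with
#' `pattern_flags_rescue`) when any composition flag fires: contains AA,
#' contains QQ, strict V/S alternation, or valine fraction >= 0.5. A positive
#' `min_propensity` additionally gates passing motifs.
#'
#' @param db Motif table from [harvest_kmers()] (needs `motif`, `frequency`;
#'   `k`/`n_sources`/`sources` are carried through when present).
#' @param criteria A [screening_criteria()] object.
#' @param scale Propensity scale passed to [beta_propensity()].
#' @return The annotated, ranked tibble with `verdict` (`"pass"`/`"fail"`)
#'   and `reason` columns.
#' @export
#' @examples
#' db <- tibble::tibble(
#'   motif = c("GVLEGV", "ITVQQ"), frequency = c(26L, 3L)
#' )
#' screen_motifs(db)
screen_motifs <- function(db, criteria = screening_criteria(),
                          scale = chou_fasman_beta()) {
  stopifnot(is.data.frame(db), nrow(db) > 0,
            all(c("motif", "frequency") %in% names(db)),
            inherits(criteria, "screening_criteria"))
  feats <- composition_features(db$motif, criteria$hydrophobic_set)
  out <- db |>
    mutate(
      val_fraction = feats$val_fraction,
      hydrophobic_fraction = feats$hydrophobic_fraction,
      has_AA = feats$has_AA,
      has_QQ = feats$has_QQ,
      vs_alternating = feats$vs_alternating,
      propensity = beta_propensity(.data$motif, scale)
    )
  freq_ok <- out$frequency >= criteria$min_frequency
  high_v <- out$val_fraction >= 0.5
  flagged <- out$has_AA | out$has_QQ | out$vs_alternating | high_v
  rescue <- criteria$pattern_flags_rescue & flagged
  prop_ok <- out$propensity >= criteria$min_propensity
  pass <- (freq_ok | rescue) & prop_ok

  reason <- vapply(seq_len(nrow(out)), function(i) {
    bits <- character()
    if (pass[[i]]) {
      if (freq_ok[[i]]) {
        bits <- c(bits, sprintf("frequency %d times", out$frequency[[i]]))
      }
      if (out$has_AA[[i]]) bits <- c(bits, "contains AA")
      if (out$has_QQ[[i]]) bits <- c(bits, "contains QQ")
      if (out$vs_alternating[[i]]) bits <- c(bits, "V/S alternation")
      if (high_v[[i]]) {
        bits <- c(bits, sprintf("high V content (%.1f%%)",
                                100 * out$val_fraction[[i]]))
      }
      paste(bits, collapse = "; ")
    } else if (!prop_ok[[i]]) {
      sprintf("mean propensity %.2f below floor %.2f",
              out$propensity[[i]], criteria$min_propensity)
    } else {
      sprintf("frequency %d below floor %d with no rescuing composition flag",
              out$frequency[[i]], criteria$min_frequency)
    }
  }, character(1))

  out |>
    mutate(
      verdict = ifelse(pass, "pass", "fail"),
      reason = reason
    ) |>
    arrange(desc(.data$frequency), desc(.data$propensity), .data$motif)
}

#' Write a screened motif database to TSV or JSON
#'
#' @param db Tibble from [screen_motifs()] (or [harvest_kmers()]).
#' @param path Output file; format chosen by `format`.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_motif_db <- function(db, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- db
  if ("sources" %in% names(flat)) {
    flat$sources <- map_chr(flat$sources, paste, collapse = ",")
  }
  flat <- mutate(flat, across(where(is.numeric), ~ signif(.x, 6)))
  if (format == "tsv") {
    write_tsv(flat, path)
  } else {
    write_json(flat, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
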