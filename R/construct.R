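#' Locate poly-alanine runs
#'
#' Finds every maximal run of `A` residues of at least `run_threshold`
#' residues. These runs are the beta-sheet nanocrystal-forming blocks of the
#' native repeat that the designer shortens or replaces.
#'
#' @param sequence Amino-acid string.
#' @param run_threshold Minimum run length to report (default 5, just below
#'   the native A6-A14 range so shortened 7-A designs still qualify).
#' @return Tibble with 1-based inclusive columns `start`, `end`, `length`,
#'   sorted by position.
#' @export
#' @examples
#' find_polyA_runs("GGAAAAAAAGG", run_threshold = 5)
find_polyA_runs <- function(sequence, run_threshold = 5L) {
  sequence <- assert_protein(sequence)
  stopifnot(run_threshold >= 1)
  m <- gregexpr("A+", sequence)[[1]]
  if (m[[1]] == -1) {
    return(tibble(start = integer(), end = integer(), length = integer()))
  }
  len <- attr(m, "match.length")
  keep <- len >= run_threshold
  tibble(
    start = as.integer(m[keep]),
    end = as.integer(m[keep] + len[keep] - 1L),
    length = as.integer(len[keep])
  )
}

#' Repeat unit of a spidroin core
#'
#' Bundles a repeat-region sequence with its qualifying poly-alanine run
#' intervals, the unit edited by [shorten_polyA()] and [substitute_motif()]
#' and multimerized into the chimeric core.
#'
#' @param sequence Amino-acid string of one repeat block.
#' @param name Label used in construct naming.
#' @param run_threshold Poly-A run threshold (see [find_polyA_runs()]).
#' @return An object of class `repeat_unit` with fields `name`, `sequence`,
#'   `polyA_runs`, `run_threshold`.
#' @export
repeat_unit <- function(sequence, name = "rep", run_threshold = 5L) {
  if (inherits(sequence, "repeat_unit")) {
    return(sequence)
  }
  sequence <- assert_protein(sequence)
  structure(
    list(
      name = name,
      sequence = sequence,
      polyA_runs = find_polyA_runs(sequence, run_threshold),
      run_threshold = as.integer(run_threshold)
    ),
    class = "repeat_unit"
  )
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat(sprintf("<repeat_unit %s>  %d aa, %d poly-A run(s)\n",
              x$name, nchar(x$sequence), nrow(x$polyA_runs)))
  invisible(x)
}

# apply per-run replacements right-to-left so earlier coordinates stay valid
replace_runs <- function(sequence, runs, replacement) {
  for (i in rev(seq_len(nrow(runs)))) {
    sequence <- paste0(
      substr(sequence, 1L, runs$start[[i]] - 1L),
      replacement,
      substr(sequence, runs$end[[i]] + 1L, nchar(sequence))
    )
  }
  sequence
}

#' Shorten every poly-alanine run to a fixed length
#'
#' Rewrites each qualifying run to exactly `target_len` alanines (the
#' wild-type 15-A runs become the expression-friendly 7-A design), leaving
#' flanks untouched and recomputing run intervals.
#'
#' @param rep A [repeat_unit()] (or plain sequence, coerced).
#' @param target_len Alanines to keep per run.
#' @param on_missing `"warn"` (default) returns the unit unchanged with a
#'   warning when it has no qualifying run; `"error"` aborts.
#' @return The edited `repeat_unit`.
#' @export
#' @examples
#' ru <- repeat_unit("GGQGAAAAAAAAAAAAAAAGQGG", name = "wt")
#' shorten_polyA(ru, 7)$sequence
shorten_polyA <- function(rep, target_len = 7L, on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  rep <- repeat_unit(rep)
  stopifnot(target_len >= 1)
  if (nrow(rep$polyA_runs) == 0) {
    msg <- sprintf("repeat unit %s has no poly-A run of length >= %d",
                   rep$name, rep$run_threshold)
    if (on_missing == "error") abort(msg)
    warn(paste0(msg, "; returning unchanged"))
    return(rep)
  }
  new_seq <- replace_runs(rep$sequence, rep$polyA_runs,
                          strrep("A", target_len))
  repeat_unit(new_seq, name = rep$name, run_threshold = rep$run_threshold)
}

#' Replace every poly-alanine run with a screened motif
#'
#' Substitutes one copy of `motif` for each qualifying run (applied
#' right-to-left), turning the wild-type crystalline blocks into the screened
#' beta-sheet motif. Run intervals are recomputed and are empty afterwards
#' unless the motif is itself poly-A.
#'
#' @param rep A [repeat_unit()] (or plain sequence, coerced).
#' @param motif Replacement amino-acid string (e.g. `"ITVQQ"`).
#' @return The edited `repeat_unit`, renamed `<old>-<motif>`.
#' @export
#' @examples
#' substitute_motif(repeat_unit("GGAAAAAAAGG"), "ITVQQ")$sequence
substitute_motif <- function(rep, motif) {
  rep <- repeat_unit(rep)
  motif <- assert_protein(motif, arg = "motif")
  if (nchar(motif) == 0) abort("`motif` must be non-empty")
  if (nrow(rep$polyA_runs) == 0) {
    abort(sprintf("repeat unit %s has no poly-A run to replace", rep$name))
  }
  new_seq <- replace_runs(rep$sequence, rep$polyA_runs, motif)
  repeat_unit(new_seq, name = paste0(rep$name, "-", motif),
              run_threshold = rep$run_threshold)
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da). Additive up to
#' one water per peptide-bond condensation.
#'
#' @param protein Amino-acid string (may be empty; canonical residues only).
#' @return Mass in Daltons.
#' @export
#' @examples
#' protein_mw("G") # 75.07 Da
protein_mw <- function(protein) {
  vapply(protein, function(p) {
    p <- assert_protein(p, arg = "protein")
    if (nchar(p) == 0) {
      return(MASS_WATER)
    }
    sum(AA_RESIDUE_MASS[strsplit(p, "")[[1]]]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble a chimeric spidroin construct
#'
#' Concatenates purification tag, N-terminal domain, `n_rep` copies of the
#' repeat unit and C-terminal domain into the full protein
#' (tag placement configurable; His6 at the N-terminus by default), and
#' computes its average molecular weight.
#'
#' @param nt N-terminal domain sequence (may be empty).
#' @param rep [repeat_unit()] or repeat sequence.
#' @param n_rep Number of tandem repeat copies (>= 1).
#' @param ct C-terminal domain sequence (may be empty).
#' @param tag Affinity tag sequence (default His6; `""` for none).
#' @param tag_terminus `"N"` or `"C"`.
#' @param name Construct name; default `"{n_rep}rep-{rep$name}"` style.
#' @return An object of class `spidroin_construct` with fields `name`, `nt`,
#'   `rep_unit`, `n_rep`, `ct`, `tag`, `tag_terminus`, `protein`, `dna`
#'   (`NULL` until [construct_dna()]), `mw_da`.
#' @export
#' @examples
#' ru <- substitute_motif(repeat_unit("GGQAAAAAGQG", name = "rep"), "ITVQQ")
#' assemble_protein(nt = "M", rep = ru, n_rep = 3, ct = "SRLSS")
assemble_protein <- function(nt, rep, n_rep, ct, tag = "HHHHHH",
                             tag_terminus = c("N", "C"), name = NULL) {
  tag_terminus <- match.arg(tag_terminus)
  rep <- repeat_unit(rep)
  stopifnot(n_rep >= 1)
  nt <- assert_protein(nt, arg = "nt")
  ct <- assert_protein(ct, arg = "ct")
  tag <- assert_protein(tag, arg = "tag")
  if (nchar(rep$sequence) == 0) abort("repeat unit sequence is empty")
  core <- paste0(nt, strrep(rep$sequence, n_rep), ct)
  protein <- if (tag_terminus == "N") paste0(tag, core) else paste0(core, tag)
  name <- name %||% sprintf("%drep-%s", n_rep, rep$name)
  structure(
    list(
      name = name, nt = nt, rep_unit = rep, n_rep = as.integer(n_rep),
      ct = ct, tag = tag, tag_terminus = tag_terminus,
      protein = protein, dna = NULL,
      mw_da = protein_mw(protein)
    ),
    class = "spidroin_construct"
  )
}

#' @export
print.spidroin_construct <- function(x, ...) {
  cat(sprintf(
    "<spidroin_construct %s>\n  %d aa (%d x %d-aa repeat), MW %.1f kDa%s\n",
    x$name, nchar(x$protein), x$n_rep, nchar(x$rep_unit$sequence),
    x$mw_da / 1000,
    if (is.null(x$dna)) "" else sprintf(", DNA %d nt", nchar(x$dna))
  ))
  invisible(x)
}

#' @rdname assemble_protein
#' @param x A `spidroin_construct`.
#' @param ... Unused.
#' @export
tidy.spidroin_construct <- function(x, ...) {
  segs <- tibble(
    segment = c("tag", "nt", rep("rep", x$n_rep), "ct"),
    sequence = c(x$tag, x$nt, rep(x$rep_unit$sequence, x$n_rep), x$ct)
  )
  if (x$tag_terminus == "C") {
    segs <- segs[c(2:nrow(segs), 1L), ]
  }
  segs |>
    filter(nchar(.data$sequence) > 0) |>
    mutate(
      length = nchar(.data$sequence),
      end = cumsum(.data$length),
      start = .data$end - .data$length + 1L,
      .after = "segment"
    )
}

#' @rdname assemble_protein
#' @export
glance.spidroin_construct <- function(x, ...) {
  tibble(
    name = x$name,
    n_rep = x$n_rep,
    protein_length = nchar(x$protein),
    mw_kda = x$mw_da / 1000,
    has_dna = !is.null(x$dna),
    gc_fraction = if (is.null(x$dna)) NA_real_ else gc_fraction(x$dna)
  )
}
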