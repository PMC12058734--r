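# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Plan for a synthetic strand corpus
#'
#' Describes a corpus of secondary-structure-annotated entries with exact
#' planted motif counts. The background alphabet is chosen (or validated)
#' to be disjoint from every residue used by the planted motifs, so planted
#' counts are recovered exactly rather than probabilistically; planted
#' motifs must not be substrings of one another for the same reason.
#'
#' @param planted Named integer vector, motif -> corpus-wide occurrence
#'   count (counts >= 0).
#' @param n_entries Number of entries (>= 1).
#' @param background_length Approximate residues of background per entry.
#' @param background_alphabet Residues for background text; auto-chosen
#'   disjoint set when `NULL`.
#' @param seed RNG seed (mandatory: generators are pure functions of
#'   plan + seed).
#' @return A list of class `corpus_plan`.
#' @export
corpus_plan <- function(planted, n_entries, background_length = 40L,
                        background_alphabet = NULL, seed) {
  stopifnot(n_entries >= 1, background_length >= 10)
  if (missing(seed)) abort("`seed` is mandatory")
  planted <- planted[order(names(planted))]
  if (any(planted < 0)) abort("planted counts must be >= 0")
  motifs <- names(planted)
  if (length(motifs) > 0) {
    motifs <- vapply(motifs, assert_protein, character(1), arg = "motif",
                     USE.NAMES = FALSE)
    names(planted) <- motifs
    for (a in motifs) {
      for (b in motifs) {
        if (a != b && grepl(a, b, fixed = TRUE)) {
          abort(sprintf("plan error: planted motif %s is a substring of %s", a, b))
        }
      }
    }
  }
  motif_res <- unique(unlist(strsplit(motifs, "")))
  if (is.null(background_alphabet)) {
    pool <- c("D", "E", "N", "P", "R", "H", "C", "M", "F", "Y")
    background_alphabet <- head(setdiff(pool, motif_res), 4)
    if (length(background_alphabet) < 2) {
      abort("plan error: cannot pick a background alphabet disjoint from the motifs")
    }
  } else {
    clash <- intersect(background_alphabet, motif_res)
    if (length(clash) > 0) {
      abort(sprintf(
        "plan error: background alphabet shares residue(s) %s with planted motifs",
        paste(clash, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      planted = planted, n_entries = as.integer(n_entries),
      background_length = as.integer(background_length),
      background_alphabet = background_alphabet, seed = as.integer(seed)
    ),
    class = "corpus_plan"
  )
}

#' Generate a strand corpus with exact planted motif counts
#'
#' Emits `n_entries` records in the simplified sequence/SS dialect. Each
#' planted motif occurs inside `E`-labelled strand regions exactly its
#' planted count corpus-wide (occurrences dealt round-robin over entries,
#' each as its own strand segment flanked by coil); background strand and
#' coil stretches are drawn from the disjoint background alphabet, so no
#' accidental occurrences can arise. Byte-identical under the same plan.
#'
#' @param plan A [corpus_plan()].
#' @return List of class `strand_corpus`: `entries` (tibble `source_id`,
#'   `text`) and `manifest` (ground truth: planted counts, alphabet, seed).
#' @export
#' @examples
#' cp <- corpus_plan(c(GVLEGV = 3), n_entries = 2, seed = 7)
#' corp <- make_strand_corpus(cp)
#' cat(corp$entries$text[[1]])
make_strand_corpus <- function(plan) {
  stopifnot(inherits(plan, "corpus_plan"))
  with_seed(plan$seed, {
    alpha <- plan$background_alphabet
    bg <- function(len) {
      paste(sample(alpha, len, replace = TRUE), collapse = "")
    }
    instances <- rep(names(plan$planted), times = plan$planted)
    entry_of <- if (length(instances)) {
      ((seq_along(instances) - 1L) %% plan$n_entries) + 1L
    } else {
      integer()
    }
    texts <- character(plan$n_entries)
    for (i in seq_len(plan$n_entries)) {
      seq_parts <- character()
      ss_parts <- character()
      add <- function(txt, state) {
        seq_parts <<- c(seq_parts, txt)
        ss_parts <<- c(ss_parts, strrep(state, nchar(txt)))
      }
      add(bg(sample(4:10, 1)), "C")
      add(bg(sample(6:9, 1)), "E") # background strand segment
      add(bg(sample(4:10, 1)), "C")
      for (m in instances[entry_of == i]) {
        add(m, "E")
        add(bg(sample(4:8, 1)), "C")
      }
      remaining <- plan$background_length - sum(nchar(seq_parts))
      if (remaining > 0) add(bg(remaining), "C")
      texts[[i]] <- paste0(
        ">entry", i, " A\n",
        paste(seq_parts, collapse = ""), "\n",
        paste(ss_parts, collapse = "")
      )
    }
    structure(
      list(
        entries = tibble(
          source_id = paste0("entry", seq_len(plan$n_entries)),
          text = texts
        ),
        manifest = list(
          planted = as.list(plan$planted),
          n_entries = plan$n_entries,
          background_alphabet = alpha,
          seed = plan$seed
        )
      ),
      class = "strand_corpus"
    )
  })
}

#' @rdname make_strand_corpus
#' @param corpus A `strand_corpus`.
#' @param dir Output directory (created if needed); one `.ss` file per
#'   entry plus `manifest.json`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "strand_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$entries))) {
    writeLines(corpus$entries$text[[i]],
               file.path(dir, paste0(corpus$entries$source_id[[i]], ".ss")))
  }
  write_json(corpus$manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic spidroin template
#'
#' Stand-in for an accession-derived template with the native architecture:
#' an N-terminal domain, a repeat region whose poly-alanine runs have the
#' requested lengths at recorded positions, and a C-terminal domain.
#' Background residues are glycine/glutamine-rich and exclude alanine so
#' the recorded run intervals are exact ground truth.
#'
#' @param polyA_runs Integer vector of poly-A run lengths (>= 1 each),
#'   default three 15-A runs.
#' @param flank_len Residues of amorphous (GGX-style) linker around each run.
#' @param nt_len,ct_len Domain lengths (defaults match the published
#'   MaSp1 NT and MiSp CT domain sizes).
#' @param seed RNG seed (mandatory).
#' @return List of class `spidroin_template`: `nt`, `rep` (a
#'   [repeat_unit()]), `ct`, `manifest` (ground-truth run intervals, seed).
#' @export
make_template <- function(polyA_runs = c(15L, 15L, 15L), flank_len = 12L,
                          nt_len = 137L, ct_len = 98L, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  stopifnot(all(polyA_runs >= 1), flank_len >= 1, nt_len >= 0, ct_len >= 0)
  with_seed(seed, {
    amorphous <- c("G", "G", "Q", "S", "Y", "P", "N", "L") # A excluded
    domain <- c("G", "S", "Q", "N", "L", "E", "R", "D", "T", "K")
    draw <- function(alpha, len) {
      paste(sample(alpha, len, replace = TRUE), collapse = "")
    }
    parts <- draw(amorphous, flank_len)
    runs <- tibble(start = integer(), end = integer(), length = integer())
    for (len in polyA_runs) {
      start <- nchar(parts) + 1L
      parts <- paste0(parts, strrep("A", len), draw(amorphous, flank_len))
      runs <- bind_rows(runs, tibble(
        start = start, end = start + len - 1L, length = as.integer(len)
      ))
    }
    structure(
      list(
        nt = draw(domain, nt_len),
        rep = repeat_unit(parts, name = "rep"),
        ct = draw(domain, ct_len),
        manifest = list(
          polyA_runs = runs, flank_len = as.integer(flank_len),
          nt_len = as.integer(nt_len), ct_len = as.integer(ct_len),
          seed = as.integer(seed)
        )
      ),
      class = "spidroin_template"
    )
  })
}

#' @rdname make_template
#' @param template A `spidroin_template`.
#' @param path Output FASTA (records `NT`, `REP`, `CT`).
#' @export
write_template_fasta <- function(template, path) {
  stopifnot(inherits(template, "spidroin_template"))
  seqs <- Biostrings::AAStringSet(c(
    NT = template$nt, REP = template$rep$sequence, CT = template$ct
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname make_template
#' @export
read_template_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  need <- c("NT", "REP", "CT")
  if (!all(need %in% names(seqs))) {
    abort("template FASTA must contain records NT, REP and CT")
  }
  list(
    nt = as.character(seqs[["NT"]]),
    rep = repeat_unit(as.character(seqs[["REP"]]), name = "rep"),
    ct = as.character(seqs[["CT"]])
  )
}

#' Plan for a synthetic two-chain assembly trajectory
#'
#' Two internally rigid bead clusters whose centre-of-mass separation ramps
#' linearly from `comd_start` to `comd_end` and whose per-chain radius of
#' gyration ramps from `rg_start` to `rg_end`, with i.i.d. Gaussian
#' positional jitter. Defaults mirror the reported study conditions: COM
#' distance 24.95 -> 18.887 nm and Rg 14.2 -> 13.46 Angstrom over 1000 ns.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_beads_per_chain Beads per chain.
#' @param comd_start,comd_end COM separation endpoints (nm, > 0).
#' @param rg_start,rg_end Per-chain Rg endpoints (Angstrom, > 0).
#' @param jitter_sigma Gaussian jitter SD per coordinate (nm, >= 0).
#' @param t_end Final frame time (ns); frames evenly spaced from 0.
#' @param seed RNG seed (mandatory).
#' @return A list of class `trajectory_plan`.
#' @export
trajectory_plan <- function(n_frames = 51L, n_beads_per_chain = 30L,
                            comd_start = 24.95, comd_end = 18.887,
                            rg_start = 14.2, rg_end = 13.46,
                            jitter_sigma = 0.05, t_end = 1000, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  stopifnot(
    n_frames >= 2, n_beads_per_chain >= 2, jitter_sigma >= 0,
    comd_start > 0, comd_end > 0, rg_start > 0, rg_end > 0, t_end > 0
  )
  structure(
    list(
      n_frames = as.integer(n_frames),
      n_beads_per_chain = as.integer(n_beads_per_chain),
      comd_start = comd_start, comd_end = comd_end,
      rg_start = rg_start, rg_end = rg_end,
      jitter_sigma = jitter_sigma, t_end = t_end, seed = as.integer(seed)
    ),
    class = "trajectory_plan"
  )
}

#' Generate a two-chain trajectory with scripted assembly trends
#'
#' @param plan A [trajectory_plan()].
#' @return List of class `assembly_sim`: `traj` (a [cg_trajectory()]) and
#'   `manifest` (per-frame ground-truth tibble `time`, `comd`, `rg`, plus
#'   the plan fields).
#' @export
#' @examples
#' sim <- make_assembly_traj(trajectory_plan(n_frames = 5, jitter_sigma = 0, seed = 1))
#' sim$traj
make_assembly_traj <- function(plan) {
  stopifnot(inherits(plan, "trajectory_plan"))
  with_seed(plan$seed, {
    nb <- plan$n_beads_per_chain
    base <- lapply(1:2, function(i) {
      b <- matrix(rnorm(nb * 3), ncol = 3)
      sweep(b, 2, colMeans(b)) # centred rigid cluster
    })
    base_rg <- vapply(base, radius_of_gyration, numeric(1))
    frac <- seq(0, 1, length.out = plan$n_frames)
    comd_t <- plan$comd_start + frac * (plan$comd_end - plan$comd_start)
    rg_t <- (plan$rg_start + frac * (plan$rg_end - plan$rg_start)) / 10 # A -> nm
    coords <- array(NA_real_, dim = c(plan$n_frames, 2L * nb, 3L))
    for (f in seq_len(plan$n_frames)) {
      offsets <- list(c(-comd_t[[f]] / 2, 0, 0), c(comd_t[[f]] / 2, 0, 0))
      for (ch in 1:2) {
        xyz <- base[[ch]] * (rg_t[[f]] / base_rg[[ch]])
        xyz <- sweep(xyz, 2, offsets[[ch]], `+`)
        coords[f, seq_len(nb) + (ch - 1L) * nb, ] <- xyz
      }
    }
    if (plan$jitter_sigma > 0) {
      coords <- coords + array(rnorm(length(coords), sd = plan$jitter_sigma),
                               dim = dim(coords))
    }
    beads <- tibble(
      bead = sprintf("%s%03d", rep(c("A", "B"), each = nb), rep(seq_len(nb), 2)),
      chain = rep(c("A", "B"), each = nb),
      residue = rep(seq_len(nb), 2),
      mass = 72,
      radius = 0.235
    )
    times <- seq(0, plan$t_end, length.out = plan$n_frames)
    structure(
      list(
        traj = cg_trajectory(coords, beads, times),
        manifest = c(
          list(truth = tibble(
            time = times, comd = comd_t, rg = rg_t * 10
          )),
          unclass(plan)
        )
      ),
      class = "assembly_sim"
    )
  })
}

#' @rdname make_assembly_traj
#' @param sim An `assembly_sim`.
#' @param dir Output directory: `traj.pdb`, `beads.tsv`, `manifest.json`.
#' @export
write_assembly_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "assembly_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_pdb(sim$traj, file.path(dir, "traj.pdb"))
  write_bead_table(sim$traj$beads, file.path(dir, "beads.tsv"))
  write_json(sim$manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
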