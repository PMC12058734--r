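#' Coarse-grained bead trajectory
#'
#' Container for an ordered sequence of frames of bead coordinates together
#' with per-bead metadata. Coordinates are stored uniformly in nanometres;
#' reporting units (Angstrom for Rg/RMSF/RMSD, nm^2 for SASA, nm for COM
#' distance) are applied by the metric functions.
#'
#' @param coords Numeric array `n_frames x n_beads x 3`, nm.
#' @param beads Tibble with columns `bead` (unique name), `chain`,
#'   `residue`, `mass` (amu, > 0), `radius` (nm, > 0).
#' @param times Per-frame times in ns, strictly increasing.
#' @return An object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, beads, times = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[[3]] == 3)
  n_frames <- dim(coords)[[1]]
  n_beads <- dim(coords)[[2]]
  beads <- as_tibble(beads)
  required <- c("bead", "chain", "residue", "mass", "radius")
  missing <- setdiff(required, names(beads))
  if (length(missing) > 0) {
    abort(sprintf("`beads` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(beads) != n_beads) {
    abort(sprintf("coords have %d beads but `beads` has %d rows",
                  n_beads, nrow(beads)))
  }
  if (anyDuplicated(beads$bead)) abort("bead names must be unique")
  if (any(!is.finite(coords))) abort("coordinates must be finite")
  if (any(beads$mass <= 0)) abort("bead masses must be > 0")
  if (any(beads$radius <= 0)) abort("bead radii must be > 0")
  times <- times %||% as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    abort("`times` must be one strictly increasing value per frame")
  }
  structure(
    list(coords = coords, beads = beads, times = as.numeric(times)),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory>  %d frames x %d beads, %d chain(s), t = %g..%g ns\n",
    n_frames(x), nrow(x$beads), length(unique(x$beads$chain)),
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' @rdname cg_trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[[1]]

#' @rdname cg_trajectory
#' @param frame Frame index.
#' @return `frame_coords()`: an `n_beads x 3` matrix (nm).
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3,
         dimnames = list(traj$beads$bead, c("x", "y", "z")))
}

#' Read a bead metadata table
#'
#' TSV with columns `bead_name`, `chain`, `residue`, `mass_amu`,
#' `radius_nm`. Missing masses default to 72 amu (the 4-to-1 CG mapping
#' convention) and missing radii to 0.235 nm (half the regular CG bead
#' diameter of 0.47 nm).
#'
#' @param path TSV file path.
#' @return Tibble with columns `bead`, `chain`, `residue`, `mass`, `radius`.
#' @export
read_bead_table <- function(path) {
  tb <- read_tsv(path, show_col_types = FALSE)
  required <- c("bead_name", "chain", "residue")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    abort(sprintf("bead table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tibble(
    bead = as.character(tb$bead_name),
    chain = as.character(tb$chain),
    residue = as.integer(tb$residue),
    mass = if ("mass_amu" %in% names(tb)) as.numeric(tb$mass_amu) else 72,
    radius = if ("radius_nm" %in% names(tb)) as.numeric(tb$radius_nm) else 0.235
  )
}

#' @rdname read_bead_table
#' @param beads Bead tibble (columns `bead`, `chain`, `residue`, `mass`,
#'   `radius`).
#' @export
write_bead_table <- function(beads, path) {
  write_tsv(
    tibble(
      bead_name = beads$bead, chain = beads$chain, residue = beads$residue,
      mass_amu = beads$mass, radius_nm = beads$radius
    ),
    path
  )
  invisible(path)
}

parse_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_id <- integer(length(lines))
  cur <- 0L
  seen_model_kw <- any(startsWith(lines, "MODEL"))
  if (!seen_model_kw) {
    model_id[] <- 1L
  } else {
    for (i in seq_along(lines)) {
      if (startsWith(lines[[i]], "MODEL")) cur <- cur + 1L
      model_id[[i]] <- cur
    }
  }
  atoms <- which(is_atom)
  if (length(atoms) == 0) abort("no ATOM records found in PDB input")
  tibble(
    model = model_id[atoms],
    name = trimws(substr(lines[atoms], 13, 16)),
    x = as.numeric(substr(lines[atoms], 31, 38)) / 10, # Angstrom -> nm
    y = as.numeric(substr(lines[atoms], 39, 46)) / 10,
    z = as.numeric(substr(lines[atoms], 47, 54)) / 10
  )
}

parse_gro_frames <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[[i]]) == "") {
      i <- i + 1L
      next
    }
    title <- lines[[i]]
    if (i + 1L > length(lines)) abort("truncated GRO input: missing atom count")
    n <- suppressWarnings(as.integer(trimws(lines[[i + 1L]])))
    if (is.na(n)) abort(sprintf("GRO frame at line %d: bad atom count", i + 1L))
    if (i + 1L + n + 1L > length(lines)) {
      abort(sprintf("GRO frame at line %d: truncated (expected %d atoms)", i, n))
    }
    atom_lines <- lines[seq.int(i + 2L, i + 1L + n)]
    t_match <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    frames[[length(frames) + 1L]] <- list(
      name = trimws(substr(atom_lines, 11, 15)),
      xyz = cbind(
        as.numeric(substr(atom_lines, 21, 28)),
        as.numeric(substr(atom_lines, 29, 36)),
        as.numeric(substr(atom_lines, 37, 44))
      ),
      time = if (length(t_match)) as.numeric(sub("t=\\s*", "", t_match)) else NA_real_
    )
    i <- i + 1L + n + 2L # title + count + atoms + box line
  }
  if (length(frames) == 0) abort("no frames found in GRO input")
  frames
}

#' Read a coarse-grained trajectory
#'
#' Reads either a multi-model PDB (MODEL/ENDMDL blocks) or a sequence of GRO
#' frames (one or more files, each holding one or more concatenated frames;
#' the box line is parsed past and ignored — no periodic-boundary handling).
#' Bead identity is taken from the atom-name field and every bead must
#' resolve in the bead table, which supplies chain, residue, mass and
#' radius. Coordinates are converted to nm internally.
#'
#' @param path File path (PDB) or character vector of paths (GRO sequence).
#' @param format `"pdb"` or `"gro"`.
#' @param bead_table Bead tibble (see [read_bead_table()]) or TSV path.
#' @param times Optional per-frame times (ns); otherwise GRO `t=` stamps
#'   are used when present, else `0, 1, 2, ...`.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb", "gro"), bead_table,
                            times = NULL) {
  format <- match.arg(format)
  if (is.character(bead_table) && length(bead_table) == 1 && file.exists(bead_table)) {
    bead_table <- read_bead_table(bead_table)
  }
  beads <- as_tibble(bead_table)
  if (format == "pdb") {
    lines <- unlist(lapply(path, readLines))
    atoms <- parse_pdb_models(lines)
    split_models <- split(atoms, atoms$model)
    names_ref <- split_models[[1]]$name
    frames <- lapply(seq_along(split_models), function(i) {
      m <- split_models[[i]]
      if (!identical(m$name, names_ref)) {
        abort(sprintf("format error: model %d bead set differs from model 1", i))
      }
      cbind(m$x, m$y, m$z)
    })
    frame_times <- times
  } else {
    lines <- unlist(lapply(path, readLines))
    parsed <- parse_gro_frames(lines)
    names_ref <- parsed[[1]]$name
    frames <- lapply(seq_along(parsed), function(i) {
      if (!identical(parsed[[i]]$name, names_ref)) {
        abort(sprintf("format error: frame %d bead set differs from frame 1", i))
      }
      parsed[[i]]$xyz
    })
    stamped <- vapply(parsed, function(f) f$time, numeric(1))
    frame_times <- times %||% (if (!anyNA(stamped)) stamped else NULL)
  }
  unknown <- setdiff(names_ref, beads$bead)
  if (length(unknown) > 0) {
    abort(sprintf("mapping error: bead name(s) not in bead table: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  beads <- beads[match(names_ref, beads$bead), ]
  coords <- array(NA_real_, dim = c(length(frames), length(names_ref), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  cg_trajectory(coords, beads, frame_times)
}

#' Write a trajectory as a multi-model PDB (plus bead table)
#'
#' Coordinates are written in Angstrom with one MODEL block per frame; bead
#' names go in the atom-name field so [read_trajectory()] round-trips.
#'
#' @param traj A [cg_trajectory()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  chains <- traj$beads$chain
  chain_char <- substr(chains, 1, 1)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f) * 10 # nm -> Angstrom
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(xyz)), traj$beads$bead, "BEA", chain_char,
      traj$beads$residue, xyz[, 1], xyz[, 2], xyz[, 3]
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
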