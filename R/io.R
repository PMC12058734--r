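format_sig <- function(df, digits = 6) {
  mutate(df, across(where(is.double), ~ signif(.x, digits)))
}

#' Write a result payload to TSV or JSON
#'
#' Data frames are written with stable column order; doubles are rounded to
#' 6 significant digits so repeated runs are byte-identical.
#' [analyze_assembly()] results serialize as JSON with a `deltas` block
#' (`rg_delta`, `sasa_pct_reduction`, `comd_delta`) plus verdict and series,
#' or as the series table in TSV.
#'
#' @param x Data frame or `assembly_metrics` object.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "assembly_metrics")) {
    if (format == "tsv") {
      write_tsv(format_sig(x$series), path)
    } else {
      payload <- list(
        deltas = lapply(x$deltas, signif, 6),
        verdict = if (x$verdict) "assembly" else "no assembly",
        reasons = x$reasons,
        chains = x$chains,
        series = format_sig(x$series),
        rmsf = format_sig(x$rmsf)
      )
      write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    return(invisible(path))
  }
  stopifnot(is.data.frame(x))
  x <- format_sig(as_tibble(x))
  if (format == "tsv") {
    write_tsv(x, path)
  } else {
    write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

write_run_manifest <- function(dir, command, params, outputs) {
  manifest <- list(
    command = command,
    package = "spidroinr",
    version = as.character(utils::packageVersion("spidroinr")),
    params = params,
    outputs = outputs
  )
  path <- file.path(dir, paste0(command, "-manifest.json"))
  write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the motif-mining pipeline on a directory of SS files
#'
#' Parses every `*.ss`/`*.dssp` file, harvests strand k-mers, screens them
#' and writes the motif database TSV plus a run manifest.
#'
#' @param ss_dir Directory of secondary-structure files.
#' @param out Output TSV path.
#' @param k_min,k_max Window range.
#' @param min_frequency Frequency floor for screening.
#' @param scale Propensity scale (named numeric vector) or path to a
#'   two-column TSV `residue`, `propensity`.
#' @param include_bridges Treat DSSP `B` as strand.
#' @return The screened motif tibble, invisibly.
#' @export
run_mine <- function(ss_dir, out, k_min = 4L, k_max = 8L,
                     min_frequency = 10L, scale = chou_fasman_beta(),
                     include_bridges = FALSE) {
  if (!dir.exists(ss_dir)) abort(sprintf("input directory %s does not exist", ss_dir))
  if (is.character(scale)) {
    tb <- read_tsv(scale, show_col_types = FALSE)
    scale <- setNames(tb[[2]], tb[[1]])
  }
  files <- list.files(ss_dir, pattern = "\\.(ss|dssp)$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no .ss/.dssp files under %s", ss_dir))
  segments <- list_rbind(map(files, function(f) {
    parse_ss_records(readLines(f),
                     source_id = tools::file_path_sans_ext(basename(f)),
                     include_bridges = include_bridges)
  }))
  criteria <- screening_criteria(min_frequency = min_frequency,
                                 k_range = c(k_min, k_max))
  db <- harvest_kmers(segments, k_min, k_max) |>
    screen_motifs(criteria, scale = scale)
  write_motif_db(db, out, "tsv")
  write_run_manifest(
    dirname(out), "mine",
    params = list(ss_dir = ss_dir, k_min = k_min, k_max = k_max,
                  min_frequency = min_frequency,
                  include_bridges = include_bridges),
    outputs = out
  )
  invisible(db)
}

#' Run the construct-design pipeline
#'
#' Edits the template repeat (motif substitution when `motif` is given,
#' otherwise poly-A shortening to `polyA_target`), assembles the tagged
#' NT-rep(n)-CT protein, codon-optimizes its DNA, builds the NheI/SpeI
#' cassette and applies `doublings` rounds of repeat doubling, then writes
#' protein FASTA, cassette DNA FASTA and a JSON design report.
#'
#' @param template Path to a template FASTA with `NT`/`REP`/`CT` records
#'   (see [make_template()]), or a list with fields `nt`, `rep`, `ct`.
#' @param out_prefix Path prefix for outputs.
#' @param motif Screened motif to substitute for the poly-A runs (optional).
#' @param polyA_target Poly-A shortening target when no motif is given.
#' @param n_rep Tandem repeat copies assembled at the protein level.
#' @param doublings NheI/SpeI doubling rounds applied to the cassette.
#' @param tag Affinity tag (default His6).
#' @param usage_table Codon preference table.
#' @return List with the construct, the multimerization result and the
#'   report (also written to `<out_prefix>-report.json`), invisibly.
#' @export
run_design <- function(template, out_prefix, motif = NULL, polyA_target = NULL,
                       n_rep = 3L, doublings = 0L, tag = "HHHHHH",
                       usage_table = ecoli_codon_table()) {
  tpl <- if (is.character(template)) read_template_fasta(template) else template
  ru <- repeat_unit(tpl$rep)
  if (!is.null(motif)) {
    ru <- substitute_motif(ru, motif)
  } else if (!is.null(polyA_target)) {
    ru <- shorten_polyA(ru, polyA_target)
  }
  construct <- assemble_protein(tpl$nt, ru, n_rep, tpl$ct, tag = tag) |>
    construct_dna(usage_table = usage_table)
  cassette <- design_cassette(construct, usage_table = usage_table)
  multi <- multimerize(cassette, n_doublings = doublings,
                       repeat_count_in = construct$n_rep)
  report <- c(
    as.list(glance(construct)),
    list(
      doublings = doublings,
      repeat_count_final = multi$repeat_count,
      cassette_length_nt = nchar(multi$dna),
      n_scars = multi$n_scars,
      live_nhei_sites = length(find_sites(multi$dna, "NheI")),
      live_spei_sites = length(find_sites(multi$dna, "SpeI")),
      gc_fraction_cassette = gc_fraction(multi$dna)
    )
  )
  writeLines(c(paste0(">", construct$name), construct$protein),
             paste0(out_prefix, "-protein.fasta"))
  writeLines(c(paste0(">", construct$name, "_cassette_",
                      multi$repeat_count, "rep"), multi$dna),
             paste0(out_prefix, "-cassette.fasta"))
  write_json(lapply(report, function(v) if (is.double(v)) signif(v, 6) else v),
             paste0(out_prefix, "-report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_manifest(
    dirname(paste0(out_prefix, "-report.json")), "design",
    params = list(motif = motif, polyA_target = polyA_target, n_rep = n_rep,
                  doublings = doublings, tag = tag),
    outputs = paste0(out_prefix, c("-protein.fasta", "-cassette.fasta",
                                   "-report.json"))
  )
  invisible(list(construct = construct, multimer = multi, report = report))
}

#' Build the NheI/SpeI multimerization cassette for a construct
#'
#' Lays out the coding DNA as `[tag+NT] GCTAGC [rep x n] ACTAGT [CT+stop]`,
#' each segment codon-optimized with both sites forbidden so the flanking
#' sites are unique. The in-frame site codons add Ala-Ser / Thr-Ser linkers
#' at the domain boundaries.
#'
#' @param construct A [assemble_protein()] result.
#' @param usage_table Codon preference table.
#' @return Cassette DNA string (validated: exactly one site per enzyme).
#' @export
design_cassette <- function(construct, usage_table = ecoli_codon_table()) {
  stopifnot(inherits(construct, "spidroin_construct"))
  forbidden <- c("GCTAGC", "ACTAGT")
  up <- paste0(
    if (construct$tag_terminus == "N") construct$tag else "", construct$nt
  )
  down <- paste0(
    construct$ct, if (construct$tag_terminus == "C") construct$tag else ""
  )
  dna <- paste0(
    if (nchar(up)) codon_optimize(up, usage_table, forbidden, add_stop = FALSE) else "",
    "GCTAGC",
    codon_optimize(strrep(construct$rep_unit$sequence, construct$n_rep),
                   usage_table, forbidden, add_stop = FALSE),
    "ACTAGT",
    codon_optimize(down, usage_table, forbidden, add_stop = TRUE)
  )
  validate_cassette(dna, restriction_enzyme("NheI"), restriction_enzyme("SpeI"))
  dna
}

#' Run the trajectory-analysis pipeline
#'
#' Reads a coarse-grained trajectory, computes the assembly observables and
#' writes per-metric TSV series, per-residue RMSF TSV and a JSON summary.
#'
#' @param traj_path Trajectory file path(s).
#' @param beads Bead table path or tibble.
#' @param out_prefix Path prefix for outputs.
#' @param format `"pdb"` or `"gro"`.
#' @inheritParams analyze_assembly
#' @param times Optional per-frame times (ns).
#' @return The `assembly_metrics` object, invisibly.
#' @export
run_analyze <- function(traj_path, beads, out_prefix, format = c("pdb", "gro"),
                        chains = NULL, probe = 0.14, n_points = 960L,
                        times = NULL) {
  format <- match.arg(format)
  traj <- read_trajectory(traj_path, format, beads, times = times)
  metrics <- analyze_assembly(traj, chains = chains, probe = probe,
                              n_points = n_points)
  write_report(metrics$series, paste0(out_prefix, "-series.tsv"), "tsv")
  write_report(metrics$rmsf, paste0(out_prefix, "-rmsf.tsv"), "tsv")
  write_report(metrics, paste0(out_prefix, "-summary.json"), "json")
  write_run_manifest(
    dirname(paste0(out_prefix, "-summary.json")), "analyze",
    params = list(traj = traj_path, format = format, probe = probe,
                  n_points = n_points, chains = metrics$chains),
    outputs = paste0(out_prefix, c("-series.tsv", "-rmsf.tsv", "-summary.json"))
  )
  invisible(metrics)
}

#' Run a synthetic-data generator from a JSON plan
#'
#' @param what `"corpus"`, `"template"` or `"traj"`.
#' @param plan Path to a JSON plan file or a plan list; fields mirror
#'   [corpus_plan()], [make_template()] and [trajectory_plan()].
#' @param out_dir Output directory.
#' @return The generated object, invisibly.
#' @export
run_fixtures <- function(what = c("corpus", "template", "traj"), plan, out_dir) {
  what <- match.arg(what)
  if (is.character(plan)) plan <- read_json(plan, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- switch(what,
    corpus = {
      cp <- corpus_plan(
        planted = unlist(plan$planted),
        n_entries = plan$n_entries,
        background_length = plan$background_length %||% 40L,
        background_alphabet = plan$background_alphabet,
        seed = plan$seed
      )
      corp <- make_strand_corpus(cp)
      write_corpus(corp, out_dir)
      corp
    },
    template = {
      tpl <- make_template(
        polyA_runs = plan$polyA_runs %||% c(15L, 15L, 15L),
        flank_len = plan$flank_len %||% 12L,
        nt_len = plan$nt_len %||% 137L,
        ct_len = plan$ct_len %||% 98L,
        seed = plan$seed
      )
      write_template_fasta(tpl, file.path(out_dir, "template.fasta"))
      write_json(list(polyA_runs = tpl$manifest$polyA_runs, seed = plan$seed),
                 file.path(out_dir, "manifest.json"),
                 auto_unbox = TRUE, digits = NA, pretty = TRUE)
      tpl
    },
    traj = {
      tp_args <- plan[intersect(names(plan), names(formals(trajectory_plan)))]
      sim <- make_assembly_traj(do.call(trajectory_plan, tp_args))
      write_assembly_fixture(sim, out_dir)
      sim
    }
  )
  write_run_manifest(out_dir, paste0("fixtures-", what),
                     params = plan, outputs = out_dir)
  invisible(obj)
}
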