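#' Reverse complement of a DNA string
#' @param dna DNA string over ACGT.
#' @return Reverse complement string.
#' @export
revcomp <- function(dna) {
  dna <- assert_dna(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' GC fraction of a DNA string
#' @param dna DNA string over ACGT.
#' @return Fraction of G+C in `[0, 1]`.
#' @export
gc_fraction <- function(dna) {
  dna <- assert_dna(dna)
  if (nchar(dna) == 0) {
    return(NA_real_)
  }
  chars <- strsplit(dna, "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Translate DNA to protein
#'
#' Standard-code translation of the top strand from position 1; internal and
#' terminal stops appear as `*`.
#'
#' @param dna DNA string, length a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna) {
  dna <- assert_dna(dna)
  if (nchar(dna) %% 3 != 0) abort("`dna` length is not a multiple of 3")
  if (nchar(dna) == 0) {
    return("")
  }
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Find restriction sites
#'
#' All (overlapping) top-strand matches of an enzyme's recognition sequence.
#' For palindromic sites such as NheI's GCTAGC and SpeI's ACTAGT a
#' bottom-strand scan would return the same positions, so a single-strand
#' scan is complete.
#'
#' @param dna DNA string.
#' @param enzyme A [restriction_enzyme()] object or its name.
#' @return Integer vector of 1-based match start positions.
#' @export
#' @examples
#' find_sites("GCTAGCTAGC", "NheI")
find_sites <- function(dna, enzyme = restriction_enzyme("NheI")) {
  dna <- assert_dna(dna)
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  if (nchar(dna) < nchar(enzyme$site)) {
    return(integer())
  }
  m <- gregexpr(paste0("(?=", enzyme$site, ")"), dna, perl = TRUE)[[1]]
  if (m[[1]] == -1) integer() else as.integer(m)
}

#' Find NheI/SpeI hybrid ligation scars
#'
#' The junction formed by ligating a SpeI cohesive end into an NheI cohesive
#' end reads GCTAGT on one strand and ACTAGC on the other, and is cut by
#' neither enzyme. Both strand readings are matched.
#'
#' @param dna DNA string (top strand).
#' @return Tibble with columns `position` (1-based, top strand) and
#'   `reading` (`"ACTAGC"` or `"GCTAGT"` as it appears on the top strand).
#' @export
find_scars <- function(dna) {
  dna <- assert_dna(dna)
  hit <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), dna, perl = TRUE)[[1]]
    if (m[[1]] == -1) integer() else as.integer(m)
  }
  out <- tibble(
    position = c(hit("ACTAGC"), hit("GCTAGT")),
    reading = c(rep("ACTAGC", length(hit("ACTAGC"))),
                rep("GCTAGT", length(hit("GCTAGT"))))
  )
  arrange(out, .data$position)
}

#' Deterministic codon optimization with restriction-site avoidance
#'
#' Reverse-translates a protein using the most-preferred codon per residue
#' (default: highly expressed E. coli K-12 usage, [ecoli_codon_table()]),
#' falling back deterministically to the next-ranked synonymous codon
#' whenever the head choice would complete a forbidden restriction site
#' (either strand). The output always re-translates to the input protein.
#'
#' @param protein Amino-acid string.
#' @param usage_table Named list residue -> codons in preference order.
#' @param forbidden_sites Character vector of site sequences to exclude
#'   (default the NheI and SpeI sites used for multimerization).
#' @param add_stop Append a stop codon (chosen under the same policy).
#' @return DNA string (coding sequence, plus stop when `add_stop`).
#' @export
#' @examples
#' codon_optimize("MAS")
codon_optimize <- function(protein,
                           usage_table = ecoli_codon_table(),
                           forbidden_sites = c("GCTAGC", "ACTAGT"),
                           add_stop = TRUE) {
  protein <- assert_protein(protein, arg = "protein")
  forbidden_sites <- vapply(forbidden_sites, assert_dna, character(1),
                            USE.NAMES = FALSE)
  # include bottom-strand readings so either-strand sites are avoided
  patterns <- unique(c(forbidden_sites,
                       vapply(forbidden_sites, revcomp, character(1))))
  residues <- strsplit(protein, "")[[1]]
  if (add_stop) residues <- c(residues, "*")
  missing <- setdiff(unique(residues), names(usage_table))
  if (length(missing) > 0) {
    abort(sprintf("usage table lacks residue(s): %s",
                  paste(missing, collapse = ", ")))
  }
  max_site <- if (length(patterns)) max(nchar(patterns)) else 0L
  dna <- ""
  for (i in seq_along(residues)) {
    placed <- FALSE
    for (codon in usage_table[[residues[[i]]]]) {
      cand <- paste0(dna, codon)
      tail_seq <- str_sub(cand, -(max_site + 2L))
      clean <- !any(vapply(patterns, function(p) {
        grepl(p, tail_seq, fixed = TRUE)
      }, logical(1)))
      if (clean) {
        dna <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        paste0("no synonymous codon for %s at protein position %d avoids ",
               "the forbidden site(s) ending in ...%s"),
        residues[[i]], i, str_sub(dna, -max_site)
      ))
    }
  }
  dna
}

#' Attach a codon-optimized coding sequence to a construct
#'
#' Runs [codon_optimize()] on the construct's full protein and stores the
#' DNA (with stop codon) on the object; the protein/DNA consistency
#' invariant `translate(dna) == protein + "*"` is checked.
#'
#' @param construct A [assemble_protein()] result.
#' @inheritParams codon_optimize
#' @return The construct with its `dna` field set.
#' @export
construct_dna <- function(construct,
                          usage_table = ecoli_codon_table(),
                          forbidden_sites = c("GCTAGC", "ACTAGT")) {
  stopifnot(inherits(construct, "spidroin_construct"))
  dna <- codon_optimize(construct$protein, usage_table, forbidden_sites,
                        add_stop = TRUE)
  stopifnot(identical(translate_dna(dna), paste0(construct$protein, "*")))
  construct$dna <- dna
  construct
}

validate_cassette <- function(cassette_dna, nhe, spe) {
  pos_n <- find_sites(cassette_dna, nhe)
  pos_s <- find_sites(cassette_dna, spe)
  if (length(pos_n) != 1L || length(pos_s) != 1L) {
    abort(sprintf(
      "cassette topology error: need exactly one %s and one %s site, found %d and %d",
      nhe$name, spe$name, length(pos_n), length(pos_s)
    ))
  }
  if (pos_n >= pos_s) {
    abort(sprintf("cassette topology error: %s site must lie upstream of %s",
                  nhe$name, spe$name))
  }
  list(nhe = pos_n, spe = pos_s)
}

#' Iterative repeat doubling via compatible cohesive ends
#'
#' Simulates the NheI/SpeI digestion-ligation strategy: the cassette carries
#' one NheI site upstream and one SpeI site downstream of the repeat block;
#' each doubling excises the block with both enzymes and ligates it into the
#' SpeI-opened cassette. Because both enzymes leave the same CTAG 5'
#' overhang, the insert's NheI end seals against the vector's SpeI end into
#' a hybrid junction — GCTAGT on one strand, ACTAGC on the coding strand —
#' that neither enzyme recuts, so the flanking sites stay unique and usable
#' for the next round. Repeat count doubles each round.
#'
#' @param cassette_dna Top-strand cassette DNA containing the two sites.
#' @param n_doublings Number of doubling rounds (>= 0).
#' @param repeat_count_in Repeat copies in the starting block (e.g. 3 for a
#'   3rep cassette).
#' @param enzymes List of two [restriction_enzyme()]s, upstream then
#'   downstream; their cohesive ends must match.
#' @return List with `dna`, `repeat_count` (`repeat_count_in * 2^n`),
#'   `n_scars` (`2^n - 1`), and `scars` (tibble from [find_scars()]).
#' @export
#' @examples
#' cas <- paste0("ATG", "GCTAGC", "GGTTCTGGC", "ACTAGT", "TAA")
#' multimerize(cas, n_doublings = 1, repeat_count_in = 3)$repeat_count
multimerize <- function(cassette_dna, n_doublings,
                        repeat_count_in = 1L,
                        enzymes = list(restriction_enzyme("NheI"),
                                       restriction_enzyme("SpeI"))) {
  dna <- assert_dna(cassette_dna)
  stopifnot(n_doublings >= 0, repeat_count_in >= 1, length(enzymes) == 2)
  nhe <- enzymes[[1]]
  spe <- enzymes[[2]]
  if (!identical(nhe$overhang, spe$overhang)) {
    abort(sprintf("ligation error: %s (%s) and %s (%s) overhangs are incompatible",
                  nhe$name, nhe$overhang, spe$name, spe$overhang))
  }
  validate_cassette(dna, nhe, spe)
  for (round in seq_len(n_doublings)) {
    pos <- validate_cassette(dna, nhe, spe)
    cut_n <- pos$nhe + nhe$cut_offset - 1L # last base of upstream fragment
    cut_s <- pos$spe + spe$cut_offset - 1L
    block <- substr(dna, cut_n + 1L, cut_s) # CTAG... block ...A
    dna <- paste0(substr(dna, 1L, cut_s), block,
                  substr(dna, cut_s + 1L, nchar(dna)))
  }
  pos <- validate_cassette(dna, nhe, spe) # post: exactly one live site each
  scars <- find_scars(dna)
  internal <- scars[scars$position > pos$nhe & scars$position < pos$spe, ]
  list(
    dna = dna,
    repeat_count = as.integer(repeat_count_in * 2^n_doublings),
    n_scars = nrow(internal),
    scars = internal
  )
}

#' Digest DNA at every live site of the given enzymes
#'
#' Cuts the top strand at each enzyme's 5' cut position and records the
#' cohesive end generated at every junction. Fragments concatenate exactly
#' to the input, so [ligate()] on the unmodified output reproduces it.
#'
#' @param dna DNA string.
#' @param enzymes List of [restriction_enzyme()]s.
#' @return Tibble with columns `fragment`, `left_overhang`, `right_overhang`
#'   (`NA` at the outer ends of a linear molecule).
#' @export
digest <- function(dna, enzymes = list(restriction_enzyme("NheI"),
                                       restriction_enzyme("SpeI"))) {
  dna <- assert_dna(dna)
  cuts <- list_rbind(map(enzymes, function(e) {
    pos <- find_sites(dna, e)
    tibble(cut_after = pos + e$cut_offset - 1L, overhang = e$overhang)
  }))
  cuts <- arrange(cuts, .data$cut_after)
  bounds <- c(0L, cuts$cut_after, nchar(dna))
  tibble(
    fragment = map_chr(seq_len(length(bounds) - 1L), function(i) {
      substr(dna, bounds[[i]] + 1L, bounds[[i + 1L]])
    }),
    left_overhang = c(NA_character_, cuts$overhang),
    right_overhang = c(cuts$overhang, NA_character_)
  )
}

#' Ligate digested fragments back together
#'
#' Joins fragments in the order given, requiring each junction's cohesive
#' ends to match; the identity round trip `ligate(digest(x)) == x` holds for
#' any linear molecule.
#'
#' @param fragments Tibble as returned by [digest()].
#' @return DNA string.
#' @export
ligate <- function(fragments) {
  stopifnot(is.data.frame(fragments), nrow(fragments) >= 1)
  if (nrow(fragments) > 1) {
    for (i in seq_len(nrow(fragments) - 1L)) {
      a <- fragments$right_overhang[[i]]
      b <- fragments$left_overhang[[i + 1L]]
      if (is.na(a) || is.na(b) || !identical(a, b)) {
        abort(sprintf("ligation error at junction %d: overhangs %s / %s",
                      i, a %||% "blunt", b %||% "blunt"))
      }
    }
  }
  paste(fragments$fragment, collapse = "")
}
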