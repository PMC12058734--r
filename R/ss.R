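#' Extract beta-strand segments from secondary-structure annotations
#'
#' Parses either a DSSP file or a simplified two-line dialect and returns
#' every maximal run of residues assigned to the extended-strand state.
#'
#' Two input dialects are accepted and auto-detected:
#' \describe{
#'   \item{DSSP}{The classic fixed-column layout. Residue lines are read from
#'     the line after the `#  RESIDUE AA STRUCTURE ...` header; chain breaks
#'     (`!` rows) terminate runs. Lowercase amino-acid codes (half-cystines)
#'     are mapped to `C`.}
#'   \item{simplified}{FASTA-like records: a header `>source_id chain_id`
#'     (chain defaults to `"A"`), one sequence line, then one secondary
#'     structure line of equal length using DSSP state letters.}
#' }
#'
#' Only `E` (extended strand) residues are harvested by default; isolated
#' beta-bridges (`B`) are included when `include_bridges = TRUE`. Positions
#' are 1-based inclusive indices into the chain as read.
#'
#' @param text Character scalar (whole file) or character vector of lines.
#' @param source_id Identifier recorded for DSSP input (defaults to
#'   `"dssp"`); the simplified dialect carries ids in its headers.
#' @param include_bridges Also treat `B` residues as strand.
#' @return A tibble with columns `source_id`, `chain_id`, `start`, `end`,
#'   `sequence` — one row per strand segment, in file order.
#' @export
#' @examples
#' txt <- c(">1abc A", "GGITVQQGG", "CCEEEEECC")
#' parse_ss_records(txt)
parse_ss_records <- function(text, source_id = "dssp", include_bridges = FALSE) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  non_blank <- lines[trimws(lines) != ""]
  if (length(non_blank) == 0) {
    return(empty_segments())
  }
  if (any(grepl("^\\s*#\\s+RESIDUE\\s+AA\\s+STRUCTURE", lines))) {
    parse_dssp_lines(lines, source_id, include_bridges)
  } else if (startsWith(trimws(non_blank[[1]]), ">")) {
    parse_simple_ss_lines(lines, include_bridges)
  } else {
    abort("input is neither DSSP (no residue header) nor the simplified '>' dialect")
  }
}

empty_segments <- function() {
  tibble(
    source_id = character(), chain_id = character(),
    start = integer(), end = integer(), sequence = character()
  )
}

DSSP_STATES <- c("H", "B", "E", "G", "I", "T", "S", "P", " ", "~", "-", "C", ".")

strand_states <- function(include_bridges) {
  if (include_bridges) c("E", "B") else "E"
}

# maximal runs of strand-state residues within one chain
segments_from_ss <- function(seq_chars, ss_chars, source_id, chain_id,
                             include_bridges, offset = 0L) {
  is_strand <- ss_chars %in% strand_states(include_bridges)
  if (!any(is_strand)) {
    return(empty_segments())
  }
  r <- rle(is_strand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(
    source_id = source_id,
    chain_id = chain_id,
    start = starts[keep] + offset,
    end = ends[keep] + offset,
    sequence = map_chr(keep, function(i) {
      paste(seq_chars[starts[i]:ends[i]], collapse = "")
    })
  )
}

parse_simple_ss_lines <- function(lines, include_bridges) {
  keep <- which(trimws(lines) != "")
  n <- length(keep)
  if (n == 0) {
    return(empty_segments())
  }
  is_hdr <- startsWith(trimws(lines[keep]), ">")
  # every record is exactly header + sequence + SS
  expected_hdr <- seq_along(keep) %% 3L == 1L
  if (n %% 3L != 0L || !identical(is_hdr, expected_hdr)) {
    bad <- keep[which(is_hdr != expected_hdr)[1] %||% n]
    abort(sprintf(
      "line %d: malformed record (expected '>' header followed by one sequence and one SS line)",
      bad
    ))
  }
  h <- keep[seq.int(1L, n, 3L)]
  s <- keep[seq.int(2L, n, 3L)]
  q <- keep[seq.int(3L, n, 3L)]
  hdr_txt <- sub("^>\\s*", "", trimws(lines[h]))
  if (any(hdr_txt == "")) {
    abort(sprintf("line %d: empty record header", h[which(hdr_txt == "")[1]]))
  }
  sid <- sub("\\s.*$", "", hdr_txt)
  chain <- ifelse(grepl("\\s", hdr_txt),
                  sub("^\\S+\\s+(\\S+).*$", "\\1", hdr_txt), "A")
  seqs <- toupper(trimws(lines[s]))
  sss <- toupper(trimws(lines[q]))
  mismatch <- nchar(seqs) != nchar(sss)
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    abort(sprintf("line %d: sequence (%d) and SS (%d) lengths differ for %s",
                  q[i], nchar(seqs[i]), nchar(sss[i]), sid[i]))
  }
  bad_seq <- grepl(sprintf("[^%sX]", paste(AA_CANONICAL, collapse = "")), seqs)
  if (any(bad_seq)) {
    i <- which(bad_seq)[1]
    abort(sprintf("line %d: non-canonical residue(s) in %s", s[i], sid[i]))
  }
  bad_ss <- grepl("[^HBEGITSPC~. -]", sss)
  if (any(bad_ss)) {
    i <- which(bad_ss)[1]
    abort(sprintf("line %d: unknown SS letter in %s", q[i], sid[i]))
  }
  pattern <- if (include_bridges) "[EB]+" else "E+"
  m <- gregexpr(pattern, sss)
  starts <- lapply(m, function(x) if (x[[1]] == -1) integer() else as.integer(x))
  lens <- lapply(m, function(x) {
    if (x[[1]] == -1) integer() else as.integer(attr(x, "match.length"))
  })
  n_seg <- lengths(starts)
  rec <- rep.int(seq_along(seqs), n_seg)
  seg_start <- unlist(starts, use.names = FALSE)
  seg_len <- unlist(lens, use.names = FALSE)
  if (length(rec) == 0) {
    return(empty_segments())
  }
  tibble(
    source_id = sid[rec],
    chain_id = chain[rec],
    start = seg_start,
    end = seg_start + seg_len - 1L,
    sequence = substring(seqs[rec], seg_start, seg_start + seg_len - 1L)
  )
}

parse_dssp_lines <- function(lines, source_id, include_bridges) {
  hdr <- grep("^\\s*#\\s+RESIDUE\\s+AA\\s+STRUCTURE", lines)[[1]]
  body <- lines[seq.int(hdr + 1L, length(lines))]
  body_lnos <- seq.int(hdr + 1L, length(lines))
  out <- list()
  cur_chain <- NA_character_
  seq_chars <- character()
  ss_chars <- character()
  flush <- function() {
    if (length(seq_chars) > 0) {
      out[[length(out) + 1L]] <<-
        segments_from_ss(seq_chars, ss_chars, source_id, cur_chain, include_bridges)
    }
    seq_chars <<- character()
    ss_chars <<- character()
  }
  for (j in seq_along(body)) {
    line <- body[[j]]
    if (trimws(line) == "") next
    if (nchar(line) < 17) {
      abort(sprintf("line %d: DSSP residue line too short", body_lnos[[j]]))
    }
    aa <- substr(line, 14, 14)
    if (aa == "!") { # chain break / terminus
      flush()
      cur_chain <- NA_character_
      next
    }
    chain <- substr(line, 12, 12)
    ss <- substr(line, 17, 17)
    if (!(toupper(ss) %in% DSSP_STATES)) {
      abort(sprintf("line %d: unknown SS letter %s", body_lnos[[j]], shQuote(ss)))
    }
    if (aa %in% letters) aa <- "C" # SS-bonded half-cystine convention
    aa <- toupper(aa)
    if (!(aa %in% c(AA_CANONICAL, "X"))) {
      abort(sprintf("line %d: unknown amino-acid code %s", body_lnos[[j]], shQuote(aa)))
    }
    if (!identical(chain, cur_chain)) {
      flush()
      cur_chain <- chain
    }
    seq_chars <- c(seq_chars, aa)
    ss_chars <- c(ss_chars, toupper(ss))
  }
  flush()
  if (length(out) == 0) empty_segments() else list_rbind(out)
}
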