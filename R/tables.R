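#' Chou-Fasman beta-strand propensity scale
#'
#' Per-residue beta-sheet conformational propensities (P-beta). Values above 1
#' mark strand formers (V 1.70, I 1.60, Y 1.47), values well below 1 strand
#' breakers (E 0.37, D 0.54, P 0.55). Used as the default scale for
#' [beta_propensity()]; any complete named numeric vector can replace it.
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
#' @examples
#' chou_fasman_beta()[["V"]]
chou_fasman_beta <- function() {
  c(
    A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
    Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
    L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
    S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
  )
}

#' Default hydrophobic residue set
#'
#' Conventional hydrophobic core set (Kyte-Doolittle-positive residues) used
#' for the `hydrophobic_fraction` composition feature.
#'
#' @return Character vector of one-letter residue codes.
#' @export
hydrophobic_residues <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "C")
}

# average (not monoisotopic) residue masses in Da, i.e. amino acid minus water
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

MASS_WATER <- 18.0153

#' Ranked E. coli codon preference table
#'
#' Synonymous codons per residue, ordered by usage in highly expressed
#' E. coli K-12 genes (most frequent first). [codon_optimize()] walks each
#' list head-first, falling back to lower-ranked codons only to avoid
#' forbidden restriction sites, so output DNA is deterministic.
#'
#' @return Named list: residue one-letter code (plus `"*"` for stop) to a
#'   character vector of codons in preference order.
#' @export
#' @examples
#' ecoli_codon_table()[["M"]]
ecoli_codon_table <- function() {
  list(
    A = c("GCG", "GCC", "GCA", "GCT"),
    R = c("CGT", "CGC", "CGG", "CGA", "AGA", "AGG"),
    N = c("AAC", "AAT"),
    D = c("GAT", "GAC"),
    C = c("TGC", "TGT"),
    Q = c("CAG", "CAA"),
    E = c("GAA", "GAG"),
    G = c("GGC", "GGT", "GGG", "GGA"),
    H = c("CAT", "CAC"),
    I = c("ATT", "ATC", "ATA"),
    L = c("CTG", "TTA", "TTG", "CTC", "CTT", "CTA"),
    K = c("AAA", "AAG"),
    M = "ATG",
    F = c("TTT", "TTC"),
    P = c("CCG", "CCA", "CCT", "CCC"),
    S = c("AGC", "TCT", "TCC", "TCG", "AGT", "TCA"),
    T = c("ACC", "ACG", "ACT", "ACA"),
    W = "TGG",
    Y = c("TAT", "TAC"),
    V = c("GTG", "GTT", "GTC", "GTA"),
    `*` = c("TAA", "TGA", "TAG")
  )
}

#' Restriction enzymes used for repeat multimerization
#'
#' NheI (G^CTAGC) and SpeI (A^CTAGT) both leave 5' CTAG cohesive ends, so an
#' NheI end ligates to a SpeI end; the hybrid junction (GCTAGT on one strand,
#' ACTAGC on the other) is cut by neither enzyme. This isocaudomer pair
#' drives the iterative repeat-doubling strategy in [multimerize()].
#'
#' @param name `"NheI"` or `"SpeI"`.
#' @return A list with fields `name`, `site` (6-mer recognition sequence,
#'   top strand), `cut_offset` (5' cut position within the site) and
#'   `overhang` (the 4-nt 5' cohesive end).
#' @export
#' @examples
#' restriction_enzyme("NheI")$site
restriction_enzyme <- function(name = c("NheI", "SpeI")) {
  name <- match.arg(name)
  switch(name,
    NheI = list(name = "NheI", site = "GCTAGC", cut_offset = 1L, overhang = "CTAG"),
    SpeI = list(name = "SpeI", site = "ACTAGT", cut_offset = 1L, overhang = "CTAG")
  )
}
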