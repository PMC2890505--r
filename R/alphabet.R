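# IUPAC nucleotide codes, amino-acid alphabet and conservation groups.

#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Base sets of the 15 IUPAC nucleotide codes (concrete bases A/C/G/T).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# Bitmask encoding (A=1, C=2, G=4, T=8) for fast set-intersection tests.
IUPAC_BITS <- vapply(IUPAC_SETS, function(s) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[s])
}, integer(1))

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

AA_LETTERS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Hydrophobic residue set used by the motif-VII / motif-X window scans.
HYDROPHOBIC_AA <- c("V", "L", "I", "M", "F", "Y", "W", "A")

#' Validate and normalise a nucleotide sequence
#'
#' Input is case-insensitive; the canonical form is uppercase. Every character
#' must be one of the 15 IUPAC nucleotide codes.
#'
#' @param seq A character string of IUPAC nucleotide codes.
#' @return The uppercased sequence string.
#' @export
validate_nuc <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), IUPAC_CODES)
  if (length(bad) > 0L) {
    stop("invalid IUPAC nucleotide code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seq
}

#' Validate and normalise a protein sequence
#'
#' The 20 standard amino acids plus `X` (unknown, e.g. an unidentified Edman
#' cycle) are accepted; input is case-insensitive.
#'
#' @param seq A character string of amino-acid letters.
#' @return The uppercased sequence string.
#' @export
validate_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c(AA_LETTERS, "X"))
  if (length(bad) > 0L) {
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seq
}

#' Complement a single IUPAC nucleotide code
#'
#' Complementation acts on the base set: the complement of R = \{A,G\} is
#' \{T,C\} = Y, and N (all four bases) is self-complementary. Vectorised over
#' codes.
#'
#' @param base Character vector of single IUPAC codes.
#' @return Character vector of complemented codes.
#' @examples
#' complement_iupac(c("A", "R", "N"))
#' @export
complement_iupac <- function(base) {
  base <- toupper(base)
  bad <- setdiff(unique(base), IUPAC_CODES)
  if (length(bad) > 0L) {
    stop("invalid IUPAC nucleotide code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(IUPAC_COMPLEMENT[base])
}

#' Reverse-complement a (possibly degenerate) nucleotide sequence
#'
#' @param seq A character string of IUPAC nucleotide codes.
#' @return The reverse complement as a string.
#' @examples
#' reverse_complement("TGGGNTTYTTRGCNGAY")
#' @export
reverse_complement <- function(seq) {
  seq <- validate_nuc(seq)
  if (nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' Default conservation-group scheme
#'
#' The six residue groups used for similarity scoring and consensus
#' annotation: (E,D,Q,N), (V,L,I,M), (F,Y,W), (G,P,A), (K,R) and (S,T).
#' Cysteine and histidine belong to no group, so the groups cover exactly 18
#' of the 20 residues.
#'
#' @return A named list of character vectors (one residue set per group).
#' @export
conservation_groups <- function() {
  list(
    acidic_amide = c("E", "D", "Q", "N"),
    aliphatic    = c("V", "L", "I", "M"),
    aromatic     = c("F", "Y", "W"),
    small        = c("G", "P", "A"),
    basic        = c("K", "R"),
    hydroxyl     = c("S", "T")
  )
}

#' Are two residues in the same conservation group?
#'
#' Identity is *not* similarity: `same_group("A", "A")` is `FALSE` (an
#' identical pair is reported separately by the alignment statistics). `X`
#' is never similar to anything.
#'
#' @param a,b Single residue letters.
#' @param scheme A conservation scheme, as from [conservation_groups()].
#' @return Logical flag.
#' @export
same_group <- function(a, b, scheme = conservation_groups()) {
  a <- toupper(a); b <- toupper(b)
  if (a == b) return(FALSE)
  if (a == "X" || b == "X") return(FALSE)
  for (g in scheme) {
    if (a %in% g && b %in% g) return(TRUE)
  }
  FALSE
}

#' Expand a degenerate IUPAC sequence to its concrete base sequences
#'
#' @param seq IUPAC nucleotide string.
#' @param max_expand Guard against combinatorial explosion (default 1e5).
#' @return Character vector of concrete A/C/G/T sequences.
#' @export
expand_iupac <- function(seq, max_expand = 1e5) {
  seq <- validate_nuc(seq)
  if (nchar(seq) == 0L) return(character(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sets <- IUPAC_SETS[ch]
  n <- prod(vapply(sets, length, integer(1)))
  if (n > max_expand) {
    stop("degeneracy ", n, " exceeds max_expand = ", max_expand, call. = FALSE)
  }
  grid <- do.call(expand.grid, c(rev(sets), list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(sets)), drop = FALSE]
  apply(grid, 1L, paste, collapse = "")
}
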