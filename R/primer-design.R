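# Degenerate back-translation and inverse-PCR primer design.
#
# A degenerate codon table maps each amino acid to one or more IUPAC codons
# whose *entire* concrete expansion translates to that amino acid; this is
# verified exhaustively when the table is built. Six-fold degenerate residues
# (L, R, S) cannot be covered by a single unambiguous IUPAC codon, so codon
# choice there is a genuine design parameter exposed via `overrides`.

#' Default degenerate codon table
#'
#' One row per (amino acid, codon) with `rank` ordering alternatives; the
#' rank-1 entry is the default used by [back_translate()]. Defaults:
#' L = YTR, R = CGN, S = TCN; everything else is the unique family codon.
#'
#' @return A tibble with columns `aa`, `codon`, `rank`.
#' @export
degenerate_codon_table <- function() {
  tab <- tibble::tribble(
    ~aa, ~codon, ~rank,
    "A", "GCN", 1L,
    "R", "CGN", 1L, "R", "AGR", 2L,
    "N", "AAY", 1L,
    "D", "GAY", 1L,
    "C", "TGY", 1L,
    "Q", "CAR", 1L,
    "E", "GAR", 1L,
    "G", "GGN", 1L,
    "H", "CAY", 1L,
    "I", "ATH", 1L,
    "L", "YTR", 1L, "L", "CTN", 2L, "L", "TTR", 3L,
    "K", "AAR", 1L,
    "M", "ATG", 1L,
    "F", "TTY", 1L,
    "P", "CCN", 1L,
    "S", "TCN", 1L, "S", "AGY", 2L,
    "T", "ACN", 1L,
    "W", "TGG", 1L,
    "Y", "TAY", 1L,
    "V", "GTN", 1L
  )
  validate_codon_table(tab)
}

#' Validate a degenerate codon table
#'
#' Checks that every amino acid has at least one entry, every entry is a
#' 3-letter IUPAC codon, and — exhaustively — that every concrete expansion
#' of every entry translates to exactly its amino acid under the standard
#' genetic code.
#'
#' @param tab A tibble with columns `aa`, `codon`, `rank`.
#' @return `tab`, invisibly usable, or an error.
#' @export
validate_codon_table <- function(tab) {
  stopifnot(all(c("aa", "codon", "rank") %in% names(tab)))
  missing_aa <- setdiff(AA_LETTERS, tab$aa)
  if (length(missing_aa) > 0L) {
    stop("codon table lacks entries for: ", paste(missing_aa, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(tab$codon) != 3L)) stop("codons must be 3 nt", call. = FALSE)
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(tab))) {
    aas <- unique(unname(gc[expand_iupac(tab$codon[i])]))
    if (!identical(aas, tab$aa[i])) {
      stop("codon ", tab$codon[i], " expands to ", paste(aas, collapse = "/"),
           ", not exclusively ", tab$aa[i], call. = FALSE)
    }
  }
  tab
}

codon_for <- function(aa, table, overrides) {
  if (aa %in% names(overrides)) {
    codon <- validate_nuc(overrides[[aa]])
    if (nchar(codon) != 3L) stop("override codon for ", aa, " must be 3 nt",
                                 call. = FALSE)
    aas <- unique(unname(Biostrings::GENETIC_CODE[expand_iupac(codon)]))
    if (!identical(aas, aa)) {
      stop("override codon ", codon, " does not encode only ", aa,
           call. = FALSE)
    }
    return(codon)
  }
  hit <- table[table$aa == aa, , drop = FALSE]
  if (nrow(hit) == 0L) stop("no codon table entry for residue ", aa,
                            call. = FALSE)
  hit$codon[which.min(hit$rank)]
}

#' Back-translate a peptide to a degenerate IUPAC nucleotide sequence
#'
#' One degenerate codon per residue, concatenated; the result has length
#' `3 * nchar(peptide)`. `X` (unknown residue) back-translates to `NNN` with
#' a warning.
#'
#' @param peptide Peptide string.
#' @param table Degenerate codon table (default [degenerate_codon_table()]).
#' @param overrides Named character vector of per-residue codon choices,
#'   e.g. `c(L = "TTR")`. Each override must itself encode only that residue.
#' @return IUPAC nucleotide string.
#' @examples
#' back_translate("YDEINE")
#' back_translate("MGFLAD", overrides = c(L = "TTR"))
#' @export
back_translate <- function(peptide, table = degenerate_codon_table(),
                           overrides = NULL) {
  peptide <- validate_protein(peptide)
  if (nchar(peptide) == 0L) stop("peptide must be non-empty", call. = FALSE)
  overrides <- overrides %||% character(0)
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  codons <- vapply(ch, function(aa) {
    if (aa == "X") {
      warning("residue X back-translated to NNN", call. = FALSE)
      return("NNN")
    }
    codon_for(aa, table, as.list(overrides))
  }, character(1))
  paste(codons, collapse = "")
}

#' Design a degenerate (inverse-)PCR primer from a peptide
#'
#' The peptide is back-translated; surplus bases beyond `target_len` are
#' trimmed from the 3' end for sense primers and from the 5' end for
#' antisense primers, which are then reverse-complemented. This trimming
#' convention generalises dropping the initiator base of the first codon on
#' the antisense side and the last wobble base on the sense side.
#'
#' @param peptide Source peptide string.
#' @param strand `"sense"` or `"antisense"`.
#' @param target_len Desired primer length (nt); must be positive and at most
#'   `3 * nchar(peptide)`.
#' @param table,overrides Passed to [back_translate()].
#' @param phospho5 Logical: carries a 5'-phosphate (as synthesised for
#'   ligation-free inverse PCR)?
#' @param name Primer label.
#' @return A one-row tibble: `name`, `seq`, `strand`, `phospho5`,
#'   `source_peptide`, `degeneracy`.
#' @examples
#' design_primer("YDEINE", "sense", 17)
#' design_primer("MGFLAD", "antisense", 17, overrides = c(L = "TTR"))
#' @export
design_primer <- function(peptide, strand = c("sense", "antisense"),
                          target_len = NULL, table = degenerate_codon_table(),
                          overrides = NULL, phospho5 = FALSE, name = NA_character_) {
  strand <- match.arg(strand)
  bt <- back_translate(peptide, table, overrides)
  target_len <- target_len %||% nchar(bt)
  if (target_len <= 0L) stop("target_len must be positive", call. = FALSE)
  if (target_len > nchar(bt)) {
    stop("target_len ", target_len, " exceeds back-translation length ",
         nchar(bt), call. = FALSE)
  }
  seq <- if (strand == "sense") {
    substr(bt, 1L, target_len)
  } else {
    reverse_complement(substr(bt, nchar(bt) - target_len + 1L, nchar(bt)))
  }
  tibble(
    name = name, seq = seq, strand = strand, phospho5 = phospho5,
    source_peptide = toupper(peptide), degeneracy = degeneracy(seq)
  )
}

#' Degeneracy of an IUPAC oligonucleotide
#'
#' The number of concrete sequences in the mixture: the product of per-position
#' IUPAC base-set sizes.
#'
#' @param primer A primer tibble (from [design_primer()]) or an IUPAC string.
#' @return Integer count.
#' @examples
#' degeneracy("TAYGAYGARATHAAYGA") # 48
#' @export
degeneracy <- function(primer) {
  seq <- if (is.data.frame(primer)) primer$seq[1] else primer
  seq <- validate_nuc(seq)
  if (nchar(seq) == 0L) return(1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  prod(vapply(IUPAC_SETS[ch], length, integer(1)))
}

# Integer bitmask vector for an IUPAC string.
iupac_bits <- function(seq) {
  unname(IUPAC_BITS[strsplit(seq, "", fixed = TRUE)[[1]]])
}

#' Find binding sites of a degenerate primer on a template
#'
#' A position matches when the concrete-base sets of the primer and template
#' intersect (degenerate-vs-degenerate comparison by set-intersection
#' emptiness); a placement is reported when at most `max_mismatch` positions
#' fail. Both strands are scanned; for circular templates, placements across
#' the origin are included. Reported positions are 1-based template
#' coordinates of the primer's 5' end on the given strand (for `-` strand
#' hits this is the rightmost template base covered).
#'
#' @param primer Primer tibble or IUPAC string.
#' @param template Template IUPAC string.
#' @param max_mismatch Maximum mismatching positions (default 0).
#' @param circular Is the template circular?
#' @return A tibble: `pos`, `strand` (`+`/`-`), `mismatches`.
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 0L,
                               circular = FALSE) {
  pseq <- if (is.data.frame(primer)) primer$seq[1] else primer
  pseq <- validate_nuc(pseq)
  template <- validate_nuc(template)
  L <- nchar(template); k <- nchar(pseq)
  empty <- tibble(pos = integer(0), strand = character(0),
                  mismatches = integer(0))
  if (k == 0L || L == 0L) return(empty)
  if (!circular && k > L) return(empty)
  tmpl <- if (circular) paste0(template, substr(template, 1L, min(k - 1L, L)))
          else template
  if (k > nchar(tmpl)) return(empty)
  tbits <- iupac_bits(tmpl)
  scan_one <- function(qbits) {
    n_off <- nchar(tmpl) - k + 1L
    vapply(seq_len(n_off), function(s) {
      sum(bitwAnd(qbits, tbits[s:(s + k - 1L)]) == 0L)
    }, integer(1))
  }
  fwd <- scan_one(iupac_bits(pseq))
  rev <- scan_one(iupac_bits(reverse_complement(pseq)))
  keep_f <- which(fwd <= max_mismatch)
  keep_r <- which(rev <= max_mismatch)
  out <- dplyr::bind_rows(
    tibble(pos = keep_f, strand = "+", mismatches = fwd[keep_f]),
    # minus-strand 5' end sits at the rightmost covered template base
    tibble(pos = keep_r + k - 1L, strand = "-", mismatches = rev[keep_r])
  )
  if (circular && nrow(out) > 0L) {
    out$pos <- ((out$pos - 1L) %% L) + 1L
    out <- dplyr::distinct(out)
  }
  dplyr::arrange(out, .data$pos, .data$strand)
}
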