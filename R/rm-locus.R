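# Restriction-modification locus arithmetic: ORF lengths, gene layout,
# recognition-site mapping, methylation-sensitive cleavage, in-silico
# inverse PCR and the methylation-type evidence classifier.

#' Protein length encoded by a complete ORF
#'
#' An ORF of `orf_bp` base pairs (start codon through stop codon) encodes
#' `orf_bp / 3 - 1` amino acids (the stop codon encodes none).
#'
#' @param orf_bp Integer vector of ORF lengths in bp; each must be >= 6 and
#'   divisible by 3.
#' @return Integer vector of encoded protein lengths (aa).
#' @examples
#' orf_protein_length(c(804, 660)) # 267, 219
#' @export
orf_protein_length <- function(orf_bp) {
  stopifnot(is.numeric(orf_bp))
  if (any(orf_bp < 6 | orf_bp %% 3 != 0)) {
    stop("not a complete ORF: length must be >= 6 bp and divisible by 3",
         call. = FALSE)
  }
  as.integer(orf_bp / 3 - 1)
}

#' Construct an enzyme specification
#'
#' Cut offsets are between-base positions counted from the recognition-site
#' start: offset 3 on a 6-bp site cuts between bases 3 and 4. Equal top and
#' bottom offsets mean blunt ends.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (IUPAC; may be degenerate).
#' @param cut_top,cut_bottom Cut offsets for the top and bottom strand.
#' @return A list of class `ma_enzyme`.
#' @export
enzyme_spec <- function(name, recognition, cut_top, cut_bottom = cut_top) {
  recognition <- validate_nuc(recognition)
  stopifnot(nchar(recognition) > 0L)
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top),
                 cut_bottom = as.integer(cut_bottom)),
            class = "ma_enzyme")
}

#' Built-in enzymes: NruI and Sbo13I
#'
#' Isoschizomers recognising the palindrome TCGCGA and cleaving between the
#' G and C in both strands (TCG/CGA), leaving blunt ends. They differ in
#' methylation sensitivity, not in recognition or cut position (see
#' [default_methylation_rules()]).
#'
#' @return An `ma_enzyme` object.
#' @export
nrui <- function() enzyme_spec("NruI", "TCGCGA", 3L, 3L)

#' @rdname nrui
#' @export
sbo13i <- function() enzyme_spec("Sbo13I", "TCGCGA", 3L, 3L)

#' Overhang length of an enzyme's cut
#'
#' @param enzyme An `ma_enzyme`.
#' @return Integer; 0 means blunt ends.
#' @export
overhang <- function(enzyme) enzyme$cut_bottom - enzyme$cut_top

#' Find recognition sites on the plus strand
#'
#' IUPAC-aware; for the palindromic sites handled here a plus-strand scan
#' covers both strands. Circular sequences include origin-spanning sites.
#'
#' @param dna DNA sequence string.
#' @param enzyme An `ma_enzyme`.
#' @param circular Is the sequence circular?
#' @return A tibble with column `pos` (1-based site starts).
#' @export
find_sites <- function(dna, enzyme, circular = FALSE) {
  hits <- find_binding_sites(enzyme$recognition, dna, max_mismatch = 0L,
                             circular = circular)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  tibble(pos = hits$pos)
}

#' Positions of Dam-methylated adenines (GATC sites)
#'
#' Helper that auto-marks Dam methylation: returns the plus-strand positions
#' of the A in every GATC occurrence.
#'
#' @param dna DNA sequence string.
#' @return Integer vector of methylated-A positions.
#' @export
dam_marks <- function(dna) {
  hits <- find_binding_sites("GATC", dna, max_mismatch = 0L)
  hits$pos[hits$strand == "+"] + 1L
}

#' Default methylation-sensitivity rules for NruI and Sbo13I
#'
#' When the recognition site overlaps a Dam site (context TCGCGATC with the
#' Dam-methylated A at context position 6), NruI cleavage is blocked but
#' Sbo13I cleavage proceeds.
#'
#' @return A tibble: `enzyme`, `context` (IUPAC pattern containing the
#'   recognition site), `site_offset` (where the site starts within the
#'   context), `meth_offset` (the context position that must carry the
#'   methyl mark), `blocked`.
#' @export
default_methylation_rules <- function() {
  tibble::tribble(
    ~enzyme, ~context,   ~site_offset, ~meth_offset, ~blocked,
    "NruI",   "TCGCGATC", 1L,           6L,           TRUE,
    "Sbo13I", "TCGCGATC", 1L,           6L,           FALSE
  )
}

site_blocked <- function(dna, site_pos, enzyme, marks, rules) {
  rules <- rules[rules$enzyme == enzyme$name & rules$blocked, , drop = FALSE]
  if (nrow(rules) == 0L || length(marks) == 0L) return(FALSE)
  for (r in seq_len(nrow(rules))) {
    ctx_start <- site_pos - (rules$site_offset[r] - 1L)
    ctx_end <- ctx_start + nchar(rules$context[r]) - 1L
    if (ctx_start < 1L || ctx_end > nchar(dna)) next
    window <- substr(dna, ctx_start, ctx_end)
    wb <- iupac_bits(window); cb <- iupac_bits(rules$context[r])
    if (any(bitwAnd(wb, cb) == 0L)) next
    if ((ctx_start + rules$meth_offset[r] - 1L) %in% marks) return(TRUE)
  }
  FALSE
}

#' Digest a DNA sequence with a restriction enzyme
#'
#' Cuts at `site_start + cut_top - 1` (between-base) at every recognition
#' site not blocked by a methylation rule. For linear DNA, concatenating the
#' fragments reproduces the input exactly.
#'
#' @param dna DNA sequence string.
#' @param enzyme An `ma_enzyme`.
#' @param marks Integer positions of methylated bases (plus strand), e.g.
#'   from [dam_marks()].
#' @param rules Methylation rules (default [default_methylation_rules()]).
#' @param circular Is the input circular? Circular DNA with one cut yields
#'   one linear fragment starting at the cut.
#' @return A tibble: `fragment`, `start`, `end`, `seq` (start/end are
#'   coordinates on the input; for circular inputs a fragment may wrap, in
#'   which case `end < start`).
#' @export
cleave <- function(dna, enzyme, marks = integer(0),
                   rules = default_methylation_rules(), circular = FALSE) {
  dna <- validate_nuc(dna)
  L <- nchar(dna)
  sites <- find_sites(dna, enzyme, circular = circular)$pos
  sites <- sites[!vapply(sites, site_blocked, logical(1),
                         dna = dna, enzyme = enzyme, marks = marks,
                         rules = rules)]
  cuts <- sort(unique(((sites + enzyme$cut_top - 1L) - 1L) %% L + 1L))
  # `cuts` are the last base positions before each cut point
  if (!circular) {
    cuts <- cuts[cuts >= 1L & cuts < L]
    bounds <- c(0L, cuts, L)
    frags <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
      tibble(start = bounds[i] + 1L, end = bounds[i + 1L])
    }) |> dplyr::bind_rows()
  } else {
    if (length(cuts) == 0L) {
      frags <- tibble(start = 1L, end = L)
    } else {
      frags <- tibble(
        start = cuts %% L + 1L,
        end = c(cuts[-1L], cuts[1L])
      )
    }
  }
  frags$fragment <- seq_len(nrow(frags))
  frags$seq <- vapply(seq_len(nrow(frags)), function(i) {
    s <- frags$start[i]; e <- frags$end[i]
    if (s <= e) substr(dna, s, e)
    else paste0(substr(dna, s, L), substr(dna, 1L, e)) # wrapped
  }, character(1))
  frags[, c("fragment", "start", "end", "seq")]
}

#' Report pairwise gene layout of an R-M locus
#'
#' For each adjacent gene pair (by start coordinate): the intergenic gap
#' (bases strictly between the translated extents) and the orientation —
#' `tandem` (same strand), `divergent` (transcribed apart: `-` then `+`) or
#' `convergent` (transcribed toward each other: `+` then `-`). Overlapping
#' genes report gap 0 with an overlap flag.
#'
#' @param genes A data frame with columns `name`, `role` (`R`/`M`/`C`),
#'   `start`, `end`, `strand` (`+`/`-`), 1-based inclusive.
#' @return A tibble: `gene_a`, `gene_b`, `orientation`, `gap_bp`,
#'   `overlap`.
#' @export
locus_layout <- function(genes) {
  stopifnot(all(c("name", "start", "end", "strand") %in% names(genes)),
            nrow(genes) >= 2L)
  g <- dplyr::arrange(as_tibble(genes), .data$start)
  purrr::map(seq_len(nrow(g) - 1L), function(i) {
    a <- g[i, ]; b <- g[i + 1L, ]
    gap <- b$start - a$end - 1L
    orientation <- if (a$strand == b$strand) "tandem"
      else if (a$strand == "-" && b$strand == "+") "divergent"
      else "convergent"
    tibble(gene_a = a$name, gene_b = b$name, orientation = orientation,
           gap_bp = max(gap, 0L), overlap = gap < 0L)
  }) |>
    dplyr::bind_rows()
}

#' Simulate inverse PCR on digested, self-ligated DNA
#'
#' Digests the genome, circularises every fragment (ligation junction between
#' the fragment's last and first base), and enumerates primer placements: a
#' product arises from a plus-strand binding site of one primer and a
#' minus-strand site of the other on the same circle, extending forward from
#' the plus primer's 5' end around the circle to the minus primer's 5' end.
#' Products that span the ligation junction (`crosses_junction`) are the
#' informative inverse-PCR amplicons that read into unknown flanking
#' sequence.
#'
#' @param genome DNA sequence string.
#' @param enzyme An `ma_enzyme` used for the digest.
#' @param primer_a,primer_b Primer tibbles ([design_primer()]) or IUPAC
#'   strings.
#' @param circular Is the genome circular?
#' @param max_mismatch Mismatches tolerated in primer binding (default 0).
#' @param junction_only Keep only junction-spanning products (default
#'   `FALSE`: all orientation-consistent products are reported).
#' @return A tibble: `fragment`, `plus_primer`, `minus_primer`, `start`,
#'   `end`, `length`, `crosses_junction`, `seq`. Coordinates are on the
#'   circularised fragment (1 = fragment's first base).
#' @export
simulate_inverse_pcr <- function(genome, enzyme, primer_a, primer_b,
                                 circular = FALSE, max_mismatch = 0L,
                                 junction_only = FALSE) {
  # no recognition site -> no restriction fragments to self-ligate
  if (nrow(find_sites(genome, enzyme, circular = circular)) == 0L) {
    return(ipcr_empty())
  }
  frags <- cleave(genome, enzyme, circular = circular)
  pa_seq <- if (is.data.frame(primer_a)) primer_a$seq[1] else primer_a
  pb_seq <- if (is.data.frame(primer_b)) primer_b$seq[1] else primer_b
  pa_name <- if (is.data.frame(primer_a)) primer_a$name[1] else "primer_a"
  pb_name <- if (is.data.frame(primer_b)) primer_b$name[1] else "primer_b"
  primers <- tibble(name = c(pa_name, pb_name), seq = c(pa_seq, pb_seq))
  out <- list()
  for (fi in seq_len(nrow(frags))) {
    circ <- frags$seq[fi]
    L <- nchar(circ)
    hits <- purrr::map(primers$seq, find_binding_sites, template = circ,
                       max_mismatch = max_mismatch, circular = TRUE)
    for (pi in 1:2) {
      qi <- 3L - pi
      plus <- hits[[pi]][hits[[pi]]$strand == "+", , drop = FALSE]
      minus <- hits[[qi]][hits[[qi]]$strand == "-", , drop = FALSE]
      if (nrow(plus) == 0L || nrow(minus) == 0L) next
      for (p in plus$pos) {
        for (q in minus$pos) {
          len <- (q - p) %% L + 1L
          if (len < nchar(primers$seq[pi]) + nchar(primers$seq[qi])) next
          seq <- substr(paste0(circ, circ), p, p + len - 1L)
          out[[length(out) + 1L]] <- tibble(
            fragment = frags$fragment[fi],
            plus_primer = primers$name[pi], minus_primer = primers$name[qi],
            start = p, end = ((q - 1L) %% L) + 1L, length = len,
            crosses_junction = p + len - 1L > L,
            seq = seq
          )
        }
      }
    }
  }
  if (length(out) == 0L) return(ipcr_empty())
  res <- dplyr::bind_rows(out) |> dplyr::distinct()
  if (junction_only) res <- res[res$crosses_junction, , drop = FALSE]
  res
}

ipcr_empty <- function() {
  tibble(fragment = integer(0), plus_primer = character(0),
         minus_primer = character(0), start = integer(0), end = integer(0),
         length = integer(0), crosses_junction = logical(0),
         seq = character(0))
}

#' Call the methylation type from enumerated evidence
#'
#' Transparent vote over the paper-style evidence fields: a positive
#' N6mA dot blot votes N6mA, a positive N4mC dot blot votes N4mC;
#' restriction by Mrr (which restricts adenine-methylated DNA) votes N6mA
#' and non-restriction leans N4mC; a Dam-overlap site that is *not* cleaved
#' leans N6mA (the blocking methyl mark sits on the shared adenine) while
#' cleavage leans N4mC; a homology hint votes its type. Majority wins; a tie
#' is inconclusive.
#'
#' @param dotblot_n6ma,dotblot_n4mc `"pos"`, `"neg"` or `"untested"`.
#' @param mrr_restricted,dam_overlap_cleaved `"yes"`, `"no"` or
#'   `"untested"`.
#' @param homology_hint `"N6mA"`, `"N4mC"` or `"none"`.
#' @return A list: `call` (`"N6mA"`, `"N4mC"` or `"inconclusive"`),
#'   `votes` (tibble of every vote), `rationale` (character vector).
#' @examples
#' call_methylation_type(dotblot_n6ma = "pos", dam_overlap_cleaved = "no")
#' @export
call_methylation_type <- function(dotblot_n6ma = "untested",
                                  dotblot_n4mc = "untested",
                                  mrr_restricted = "untested",
                                  dam_overlap_cleaved = "untested",
                                  homology_hint = "none") {
  dotblot_n6ma <- match.arg(dotblot_n6ma, c("untested", "pos", "neg"))
  dotblot_n4mc <- match.arg(dotblot_n4mc, c("untested", "pos", "neg"))
  mrr_restricted <- match.arg(mrr_restricted, c("untested", "yes", "no"))
  dam_overlap_cleaved <- match.arg(dam_overlap_cleaved,
                                   c("untested", "yes", "no"))
  homology_hint <- match.arg(homology_hint, c("none", "N6mA", "N4mC"))
  if (dotblot_n6ma == "untested" && dotblot_n4mc == "untested" &&
      mrr_restricted == "untested" && dam_overlap_cleaved == "untested" &&
      homology_hint == "none") {
    stop("cannot call methylation type: every evidence field is untested",
         call. = FALSE)
  }
  votes <- list()
  add <- function(field, value, vote) {
    votes[[length(votes) + 1L]] <<- tibble(field = field, value = value,
                                           vote = vote)
  }
  if (dotblot_n6ma == "pos") add("dotblot_n6ma", "pos", "N6mA")
  if (dotblot_n4mc == "pos") add("dotblot_n4mc", "pos", "N4mC")
  if (mrr_restricted == "yes") add("mrr_restricted", "yes", "N6mA")
  if (mrr_restricted == "no") add("mrr_restricted", "no", "N4mC")
  if (dam_overlap_cleaved == "no") add("dam_overlap_cleaved", "no", "N6mA")
  if (dam_overlap_cleaved == "yes") add("dam_overlap_cleaved", "yes", "N4mC")
  if (homology_hint != "none") add("homology_hint", homology_hint,
                                   homology_hint)
  votes <- if (length(votes)) dplyr::bind_rows(votes) else
    tibble(field = character(0), value = character(0), vote = character(0))
  n6 <- sum(votes$vote == "N6mA"); n4 <- sum(votes$vote == "N4mC")
  call <- if (n6 > n4) "N6mA" else if (n4 > n6) "N4mC" else "inconclusive"
  rationale <- c(
    sprintf("%s=%s -> votes %s", votes$field, votes$value, votes$vote),
    sprintf("tally: N6mA %d vs N4mC %d -> %s", n6, n4, call)
  )
  list(call = call, votes = votes, rationale = rationale)
}
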