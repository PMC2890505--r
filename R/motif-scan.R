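# Motif scanning: pattern models, catalytic dyads, hydrophobic windows.

empty_hits <- function() {
  tibble(label = character(0), start = integer(0), end = integer(0),
         matched = character(0), score = numeric(0), variant = character(0))
}

#' Scan a protein with a motif model
#'
#' Reports every match, left to right, overlapping matches included.
#' Where several spacer-length parses reach the same (start, end), the
#' highest-scoring parse is kept. The score is the fraction of non-spacer
#' positions matched exactly (literal residue or any-residue) versus via a
#' conservation-group wildcard (group matches carry half weight); it is 1
#' when every non-spacer position matches a literal residue-set member.
#' The variant tag is the matched residue at the model's first
#' multi-residue set element (e.g. D/N/S for the \[DNS\]-P-P-Y motif IV).
#'
#' @param protein Protein sequence string.
#' @param model A compiled motif model ([compile_motif()]).
#' @return A tibble of hits: `label`, `start`, `end`, `matched`, `score`,
#'   `variant`, ordered by start then shorter matches first.
#' @examples
#' scan_motif("LLNPPYKK", compile_motif("[DNS]-P-P-Y", "IV"))
#' @export
scan_motif <- function(protein, model) {
  stopifnot(inherits(model, "ma_motif"))
  protein <- validate_protein(protein)
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  elements <- model$elements
  is_spacer <- vapply(elements, function(e) e$type == "spacer", logical(1))
  variant_elem <- Position(function(e) e$type == "set" && length(e$set) > 1L,
                           elements)
  # the score depends only on element types: set/any positions are exact
  # matches, group-wildcard positions are group matches (half weight)
  n_exact <- sum(vapply(elements[!is_spacer],
                        function(e) e$type != "group", logical(1)))
  n_group <- sum(!is_spacer) - n_exact
  score <- (n_exact + 0.5 * n_group) / (n_exact + n_group)
  # per non-spacer element: where does it match? (X matches nothing)
  match_vec <- lapply(elements, function(e) {
    if (e$type == "spacer") NULL else (ch %in% e$set) & ch != "X"
  })
  # enumerate spacer-length combinations (few in practice)
  spacer_idx <- which(is_spacer)
  combos <- if (length(spacer_idx) == 0L) {
    matrix(integer(0), nrow = 1L)
  } else {
    as.matrix(expand.grid(lapply(spacer_idx, function(i) {
      elements[[i]]$min:elements[[i]]$max
    })))
  }
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    lens <- vapply(seq_along(elements), function(i) {
      if (is_spacer[i]) combos[ci, match(i, spacer_idx)] else 1L
    }, integer(1))
    total <- sum(lens)
    if (total > n) next
    offs <- c(0L, cumsum(lens))[seq_along(elements)] # element offsets
    starts_max <- n - total + 1L
    ok <- rep(TRUE, starts_max)
    for (i in seq_along(elements)) {
      if (is_spacer[i]) next
      ok <- ok & match_vec[[i]][seq_len(starts_max) + offs[i]]
    }
    s <- which(ok)
    if (length(s) == 0L) next
    out[[length(out) + 1L]] <- tibble(
      start = s, end = s + total - 1L,
      variant = if (!is.na(variant_elem)) ch[s + offs[variant_elem]]
                else NA_character_
    )
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- dplyr::bind_rows(out)
  hits <- hits[!duplicated(hits[c("start", "end")]), , drop = FALSE]
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  tibble(
    label = model$label,
    start = hits$start, end = hits$end,
    matched = substring(protein, hits$start, hits$end),
    score = score, variant = hits$variant
  )
}

#' Scan for an endonuclease catalytic site (dyad - spacer - tail)
#'
#' Matches placements of a residue dyad, an unconstrained spacer whose length
#' lies within bounds, and a short tail, e.g. the PD-X(21)-EVK /
#' DD-X(21)-EVK arrangement, or the Mrr-like DD-X(20)-QIK. Patterns use the
#' [compile_motif()] element grammar without spacers.
#'
#' @param protein Protein sequence string.
#' @param dyad Dyad pattern (default `"[PD]-D"`).
#' @param spacer_min,spacer_max Spacer length bounds (default 21, 21).
#' @param tail Tail pattern (default `"E-V-K"`).
#' @return A tibble: `start`, `end`, `matched`, `spacer_len`, `dyad`,
#'   `tail`.
#' @examples
#' prot <- paste0("MA", "PD", strrep("G", 21), "EVK", "LL")
#' scan_catalytic(prot)
#' @export
scan_catalytic <- function(protein, dyad = "[PD]-D",
                           spacer_min = 21L, spacer_max = 21L,
                           tail = "E-V-K") {
  stopifnot(spacer_min >= 0L, spacer_min <= spacer_max)
  pat <- paste0(dyad, "-x(", spacer_min, ",", spacer_max, ")-", tail)
  model <- compile_motif(pat, label = "catalytic")
  n_fixed <- sum(vapply(model$elements,
                        function(e) e$type != "spacer", logical(1)))
  hits <- scan_motif(protein, model)
  if (nrow(hits) == 0L) {
    return(tibble(start = integer(0), end = integer(0), matched = character(0),
                  spacer_len = integer(0), dyad = character(0),
                  tail = character(0)))
  }
  n_tail <- length(compile_motif(tail)$elements)
  tibble(
    start = hits$start, end = hits$end, matched = hits$matched,
    spacer_len = (hits$end - hits$start + 1L) - n_fixed,
    dyad = substr(hits$matched, 1L, n_fixed - n_tail),
    tail = substring(hits$matched, nchar(hits$matched) - n_tail + 1L)
  )
}

#' Scan for hydrophobic blocks (motifs VII and X)
#'
#' Slides a window over the region and reports maximal intervals formed by
#' the union of all windows containing at least `min_hydrophobic` residues
#' from the hydrophobic set \{V,L,I,M,F,Y,W,A\}. The score is the hydrophobic
#' fraction of the reported interval.
#'
#' @param protein Protein sequence string.
#' @param window Window length (>= 1).
#' @param min_hydrophobic Minimum hydrophobic residues per window.
#' @param region Length-2 integer vector `c(start, end)` restricting the scan
#'   (default: whole protein). Must lie within the protein.
#' @param label Motif label attached to the hits.
#' @return A hit tibble as in [scan_motif()] (variant is `NA`).
#' @examples
#' scan_hydrophobic_block("KKVLIMFKK", window = 5, min_hydrophobic = 4)
#' @export
scan_hydrophobic_block <- function(protein, window = 5L, min_hydrophobic = 4L,
                                   region = NULL, label = NA_character_) {
  protein <- validate_protein(protein)
  n <- nchar(protein)
  stopifnot(window >= 1L, min_hydrophobic >= 0L)
  region <- region %||% c(1L, n)
  if (region[1] < 1L || region[2] > n || region[1] > region[2]) {
    stop("region [", region[1], ", ", region[2],
         "] outside protein of length ", n, call. = FALSE)
  }
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  hydro <- as.integer(ch %in% HYDROPHOBIC_AA)
  starts <- region[1]:(region[2] - window + 1L)
  if (region[2] - region[1] + 1L < window) return(empty_hits())
  counts <- vapply(starts, function(s) sum(hydro[s:(s + window - 1L)]),
                   integer(1))
  ok <- starts[counts >= min_hydrophobic]
  if (length(ok) == 0L) return(empty_hits())
  # union of qualifying windows -> maximal intervals
  grp <- cumsum(c(TRUE, diff(ok) > window))
  spans <- tibble(start = tapply(ok, grp, min),
                  end = tapply(ok, grp, max) + window - 1L)
  spans$start <- as.integer(spans$start); spans$end <- as.integer(spans$end)
  tibble(
    label = label,
    start = spans$start, end = spans$end,
    matched = substring(protein, spans$start, spans$end),
    score = vapply(seq_len(nrow(spans)), function(i) {
      mean(hydro[spans$start[i]:spans$end[i]])
    }, numeric(1)),
    variant = NA_character_
  ) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Scan a protein with a full motif configuration
#'
#' Runs every enabled motif of a configuration table over the protein and
#' binds the hits.
#'
#' @param protein Protein sequence string.
#' @param config Motif configuration tibble (default
#'   [default_motif_config()]).
#' @return A hit tibble: `label`, `start`, `end`, `matched`, `score`,
#'   `variant`.
#' @export
scan_motifs <- function(protein, config = default_motif_config()) {
  config <- validate_motif_config(config)
  protein <- validate_protein(protein)
  n <- nchar(protein)
  rows <- purrr::map(which(config$enabled), function(i) {
    if (config$kind[i] == "pattern") {
      scan_motif(protein, compile_motif(config$pattern[i], config$label[i]))
    } else {
      reg <- c(
        if (is.na(config$region_start[i])) 1L else config$region_start[i],
        if (is.na(config$region_end[i])) n else min(config$region_end[i], n)
      )
      if (reg[1] > n || reg[1] > reg[2]) return(empty_hits())
      scan_hydrophobic_block(protein, config$window[i], config$min_hydro[i],
                             region = reg, label = config$label[i])
    }
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$start, out$end), , drop = FALSE]
}
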