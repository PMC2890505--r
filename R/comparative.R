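# Pairwise identity/similarity with conservation-group semantics,
# Clustal-style consensus annotation, minimum-linkage unrooted trees and
# force-directed similarity layout.

#' Align two proteins and score identity / similarity
#'
#' Optimal pairwise alignment by dynamic programming
#' (Needleman-Wunsch / Smith-Waterman via Biostrings) under BLOSUM62 with
#' affine gaps. Identity is the percentage of aligned columns (counting only
#' columns where neither sequence is gapped) with identical residues;
#' similarity additionally counts columns whose residues fall in the same
#' conservation group ([conservation_groups()]). `X` is identical/similar to
#' nothing. Local mode with gap open 11 / extend 1 is the default used to
#' emulate database-search style comparisons; global mode suits controlled
#' tests.
#'
#' @param a,b Protein sequence strings.
#' @param mode `"local"` (default) or `"global"`.
#' @param gap_open,gap_ext Affine gap penalties (defaults 11, 1).
#' @param substitution Substitution matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param scheme Conservation scheme (default [conservation_groups()]).
#' @return A one-row tibble of class `ma_pairwise`: `aligned_a`,
#'   `aligned_b`, `identity_pct`, `similarity_pct`, `aligned_length`,
#'   `denominator`, `mode`.
#' @export
align_pair <- function(a, b, mode = c("local", "global"),
                       gap_open = 11, gap_ext = 1,
                       substitution = "BLOSUM62",
                       scheme = conservation_groups()) {
  mode <- match.arg(mode)
  a <- validate_protein(a); b <- validate_protein(b)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = mode, substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  stats <- alignment_stats(ga, gb, scheme)
  out <- tibble(
    aligned_a = ga, aligned_b = gb,
    identity_pct = stats$identity_pct,
    similarity_pct = stats$similarity_pct,
    aligned_length = nchar(ga),
    denominator = stats$denominator,
    mode = mode
  )
  class(out) <- c("ma_pairwise", class(out))
  out
}

# identity/similarity percentages over columns where neither row is gapped
alignment_stats <- function(ga, gb, scheme = conservation_groups()) {
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  keep <- ca != "-" & cb != "-"
  ca <- ca[keep]; cb <- cb[keep]
  denom <- length(ca)
  if (denom == 0L) {
    return(list(identity_pct = 0, similarity_pct = 0, denominator = 0L))
  }
  ident <- ca == cb & ca != "X"
  simil <- mapply(same_group, ca, cb, MoreArgs = list(scheme = scheme))
  list(
    identity_pct = 100 * sum(ident) / denom,
    similarity_pct = 100 * (sum(ident) + sum(simil)) / denom,
    denominator = denom
  )
}

#' Clustal-style consensus annotation line
#'
#' Per alignment column: `*` when all residues are identical (and no gap),
#' `:` when all residues fall within one conservation group, a space
#' otherwise (gaps or mixed-group columns).
#'
#' @param block A data frame with columns `id`, `seq` (equal-length gapped
#'   rows) or a character vector of gapped rows.
#' @param scheme Conservation scheme.
#' @return A single annotation string as long as the alignment.
#' @export
consensus_line <- function(block, scheme = conservation_groups()) {
  rows <- if (is.data.frame(block)) block$seq else block
  stopifnot(length(rows) >= 1L, length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  marks <- apply(mat, 2L, function(col) {
    if (any(col == "-")) return(" ")
    if (length(unique(col)) == 1L) return("*")
    if (any(col == "X")) return(" ")
    for (g in scheme) {
      if (all(col %in% g)) return(":")
    }
    " "
  })
  paste(marks, collapse = "")
}

#' Pairwise distance matrix from sequence identity
#'
#' `d(i, j) = 1 - identity_fraction(i, j)` with identity from [align_pair()]
#' (or computed column-wise from a precomputed alignment when
#' `aligned = TRUE`).
#'
#' @param seqs A data frame with columns `id`, `seq`.
#' @param mode Alignment mode passed to [align_pair()] (default
#'   `"global"`).
#' @param aligned If `TRUE`, `seqs$seq` are equal-length gapped rows of a
#'   precomputed alignment and no re-alignment is performed.
#' @param ... Further arguments to [align_pair()].
#' @return A symmetric numeric matrix with zero diagonal and `seqs$id`
#'   dimnames.
#' @export
distance_matrix <- function(seqs, mode = "global", aligned = FALSE, ...) {
  stopifnot(all(c("id", "seq") %in% names(seqs)), nrow(seqs) >= 2L)
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idf <- if (aligned) {
        alignment_stats(seqs$seq[i], seqs$seq[j])$identity_pct / 100
      } else {
        align_pair(seqs$seq[i], seqs$seq[j], mode = mode, ...)$identity_pct / 100
      }
      d[i, j] <- d[j, i] <- 1 - idf
    }
  }
  d
}

#' Single (minimum) linkage agglomerative clustering
#'
#' Classic single-linkage agglomeration with a deterministic tie-break: when
#' several pairs share the minimum distance, the pair whose (sorted) cluster
#' labels are lexicographically smallest merges first. A cluster inherits the
#' lexicographically smallest label of its members. Returns an `hclust`
#' object (so `stats::cutree()` works), with merge heights that are
#' non-decreasing by the single-linkage property.
#'
#' @param dm Symmetric distance matrix with labelled dimnames.
#' @return An object of class `hclust`.
#' @export
single_linkage <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 2L)
  labels <- rownames(dm)
  stopifnot(!is.null(labels))
  n <- nrow(dm)
  active <- seq_len(n)
  # cluster id: negative = singleton index, positive = merge row
  cl_id <- -seq_len(n)
  cl_name <- labels
  cl_members <- as.list(seq_len(n))
  d <- dm
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    # find min distance among active pairs; tie-break lexicographic
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        key <- sort(c(cl_name[i], cl_name[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(cl_id[i], cl_id[j]))
    height[step] <- best$d
    # single linkage update onto slot i
    for (k in active) {
      if (k != i && k != j) {
        d[i, k] <- d[k, i] <- min(d[i, k], d[j, k])
      }
    }
    cl_id[i] <- step
    cl_name[i] <- min(cl_name[i], cl_name[j])
    cl_members[[i]] <- c(cl_members[[i]], cl_members[[j]])
    active <- setdiff(active, j)
  }
  structure(list(
    merge = merge, height = height,
    order = leaf_order(merge, n), labels = labels,
    method = "single", call = match.call(),
    dist.method = "identity"
  ), class = "hclust")
}

# leaf ordering by recursive traversal of the merge matrix
leaf_order <- function(merge, n) {
  rec <- function(k) {
    if (k < 0L) return(-k)
    c(rec(merge[k, 1]), rec(merge[k, 2]))
  }
  rec(nrow(merge))
}

#' Minimum-linkage unrooted distance tree
#'
#' Single-linkage agglomeration ([single_linkage()]) serialised as an
#' unrooted `phylo` tree (the root is suppressed into a multifurcation).
#' Branch lengths follow midpoint semantics: a two-taxon matrix with
#' distance 0.4 yields two branches of 0.2.
#'
#' @param dm Symmetric distance matrix with labelled dimnames.
#' @return An `ape::phylo` object (unrooted for >= 3 taxa).
#' @export
minimum_linkage_tree <- function(dm) {
  hc <- single_linkage(dm)
  tr <- ape::as.phylo(hc) # ape halves merge heights: midpoint branch lengths
  if (length(tr$tip.label) >= 3L) tr <- ape::unroot(tr)
  tr
}

#' Force-directed layout of a similarity matrix
#'
#' Fruchterman-Reingold-style iterative layout in 2-D: every node pair
#' repels with force k^2/d, and attracts proportionally to its similarity
#' (k * s_ij * d); displacement per sweep is capped by a linearly cooling
#' temperature. Coordinates are reproducible for a fixed seed.
#'
#' @param sim Symmetric similarity matrix with values in \[0, 1\] and
#'   labelled dimnames.
#' @param iterations Number of sweeps (default 200).
#' @param seed RNG seed for the initial placement.
#' @param k Spring constant / ideal spacing (default 0.1, independent of the
#'   node count so that repulsion-only spread grows with the number of
#'   mutually repelling nodes instead of saturating the temperature cap).
#' @param t0 Initial temperature (default 0.1).
#' @return A tibble of class `ma_layout`: `label`, `x`, `y`; attributes
#'   `seed` and `iterations`.
#' @export
force_layout <- function(sim, iterations = 200L, seed = 1L, k = NULL,
                         t0 = 0.1) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), iterations >= 1L)
  if (any(sim < 0 | sim > 1)) stop("similarities must lie in [0, 1]",
                                   call. = FALSE)
  n <- nrow(sim)
  labels <- rownames(sim) %||% as.character(seq_len(n))
  set.seed(seed)
  pos <- matrix(stats::runif(2L * n, -0.5, 0.5), n, 2L)
  if (n == 1L) pos <- matrix(0, 1L, 2L)
  k <- k %||% 0.1
  if (n > 1L) {
    for (it in seq_len(iterations)) {
      temp <- t0 * (1 - (it - 1L) / iterations)
      disp <- matrix(0, n, 2L)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          delta <- pos[i, ] - pos[j, ]
          dist <- max(sqrt(sum(delta^2)), 1e-9)
          dir <- delta / dist
          f_rep <- k^2 / dist
          f_att <- k * sim[i, j] * dist
          f <- f_rep - f_att
          disp[i, ] <- disp[i, ] + dir * f
          disp[j, ] <- disp[j, ] - dir * f
        }
      }
      for (i in seq_len(n)) {
        dlen <- max(sqrt(sum(disp[i, ]^2)), 1e-9)
        pos[i, ] <- pos[i, ] + disp[i, ] / dlen * min(dlen, temp)
      }
    }
  }
  out <- tibble(label = labels, x = pos[, 1], y = pos[, 2])
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  class(out) <- c("ma_layout", class(out))
  out
}

#' Plot a force-directed similarity layout
#'
#' @param object An `ma_layout` tibble from [force_layout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ma_layout <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Force-directed similarity layout") +
    ggplot2::theme_minimal()
}

#' Write a distance matrix or layout to TSV
#'
#' @param x A matrix with dimnames, or a layout tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- as_tibble(x, rownames = "id")
  } else {
    df <- as_tibble(x)
  }
  readr::write_tsv(df, path)
  invisible(x)
}
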