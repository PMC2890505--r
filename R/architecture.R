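# Methyltransferase motif-architecture inference and group assignment.
#
# The AdoMet-binding cluster is motifs (Xa,)X-I-II-III, the catalytic cluster
# is motifs IV(-IVa)-V-VI-VII(-VIII); the position of the target-recognition
# domain (TRD) relative to these two clusters defines the alpha, beta and
# gamma groups. The proposed subgroup is gamma order with motif IV = DPPY
# plus auxiliary motifs IVa and Xa.

ADOMET_LABELS <- c("Xa", "X", "I", "II", "III")
CATALYTIC_LABELS <- c("IV", "IVa", "V", "VI", "VII", "VIII")

motif_cluster <- function(label) {
  dplyr::case_when(
    label %in% ADOMET_LABELS ~ "adomet",
    label %in% CATALYTIC_LABELS ~ "catalytic",
    TRUE ~ "other"
  )
}

#' Choose one best hit per motif label
#'
#' Selects at most one hit per label, maximising total score subject to:
#' (i) no two chosen hits overlap; (ii) within each cluster, chosen hits
#' appear in canonical left-to-right label order (Xa < X < I < II < III;
#' IV < IVa < V < VI < VII < VIII); (iii) each cluster's chosen hits are
#' contiguous — no hit of the other cluster falls between two hits of one
#' cluster; and (iv) a chosen hit must lie within `cluster_max_gap` residues
#' of its nearest same-cluster chosen hit (motif blocks of one functional
#' region are adjacent; a domain-sized hole cannot be internal to a
#' cluster). Ties in total score break toward the assignment with the most
#' compact clusters (smallest summed cluster extents), then deterministically
#' toward the leftmost assignment (labels in canonical order, candidates
#' left to right).
#'
#' @param hits A hit tibble from [scan_motifs()].
#' @param cluster_max_gap Maximum gap (aa) between neighbouring chosen hits
#'   of one cluster (default 40, matching the minimum TRD length).
#' @return The selected subset of `hits`, ordered by start.
#' @export
choose_hits <- function(hits, cluster_max_gap = 40L) {
  if (nrow(hits) == 0L) return(hits)
  hits <- dplyr::arrange(hits, .data$start, .data$end)
  labels <- intersect(c(ADOMET_LABELS, CATALYTIC_LABELS), unique(hits$label))
  labels <- c(labels, setdiff(unique(hits$label), labels))
  order_ref <- c(ADOMET_LABELS, CATALYTIC_LABELS)
  # plain-vector working copies (performance: the DFS is hot)
  h_start <- hits$start; h_end <- hits$end; h_score <- hits$score
  h_rank <- match(hits$label, order_ref) # NA for labels outside the scheme
  h_cl <- c("adomet", "catalytic")[
    (hits$label %in% CATALYTIC_LABELS) + 1L]
  h_cl[!hits$label %in% c(ADOMET_LABELS, CATALYTIC_LABELS)] <- "other"
  cand <- lapply(labels, function(l) {
    idx <- which(hits$label == l)
    idx[order(h_start[idx], -h_score[idx], h_end[idx])]
  })
  names(cand) <- labels
  max_scores <- vapply(cand, function(i) max(h_score[i]), numeric(1))
  tail_bound <- rev(cumsum(rev(max_scores)))

  best_score <- -Inf
  best_span <- Inf
  best_rows <- integer(0)
  n_lab <- length(labels)
  cluster_span <- function(chosen) {
    tot <- 0L
    for (cl in c("adomet", "catalytic")) {
      in_cl <- chosen[h_cl[chosen] == cl]
      if (length(in_cl) > 0L) {
        tot <- tot + max(h_end[in_cl]) - min(h_start[in_cl])
      }
    }
    tot
  }
  dfs <- function(li, chosen, score) {
    if (li <= n_lab && score + tail_bound[li] < best_score - 1e-9) return()
    if (li > n_lab) {
      if (score > best_score + 1e-9) {
        best_score <<- score; best_span <<- cluster_span(chosen)
        best_rows <<- chosen
      } else if (score > best_score - 1e-9) {
        sp <- cluster_span(chosen)
        if (sp < best_span) {
          best_span <<- sp
          best_rows <<- chosen
        }
      }
      return()
    }
    for (i in cand[[li]]) {
      if (selection_valid(chosen, i, h_start, h_end, h_rank, h_cl,
                          cluster_max_gap)) {
        dfs(li + 1L, c(chosen, i), score + h_score[i])
      }
    }
    dfs(li + 1L, chosen, score) # skip this label
  }
  dfs(1L, integer(0), 0)
  dplyr::arrange(hits[sort(best_rows), , drop = FALSE], .data$start)
}

# Is adding hit `i` to the chosen set valid under non-overlap, in-cluster
# label order, cluster contiguity and the nearest-neighbour gap cap?
# (vectorised over the chosen set)
selection_valid <- function(chosen, i, h_start, h_end, h_rank, h_cl,
                            cluster_max_gap) {
  if (length(chosen) == 0L) return(TRUE)
  s <- h_start[i]; e <- h_end[i]
  cs <- h_start[chosen]; ce <- h_end[chosen]
  if (any(s <= ce & e >= cs)) return(FALSE) # overlap
  cl <- h_cl[i]
  if (cl == "other") return(TRUE)
  ccl <- h_cl[chosen]
  same <- ccl == cl
  if (any(same)) {
    rk <- h_rank[i]; crk <- h_rank[chosen]
    if (any(same & crk < rk & cs > s) ||
        any(same & crk > rk & cs < s)) return(FALSE)
    # nearest same-cluster neighbour within the gap cap
    gaps <- pmax(cs[same] - e - 1L, s - ce[same] - 1L)
    if (min(gaps) > cluster_max_gap) return(FALSE)
    other <- ccl != cl & ccl != "other"
    if (any(other)) {
      lo <- min(cs[same], s); hi <- max(ce[same], e)
      if (any(other & cs > lo & ce < hi)) return(FALSE)
    }
  } else {
    other <- ccl != cl & ccl != "other"
    if (sum(other) >= 2L) {
      lo <- min(cs[other]); hi <- max(ce[other])
      if (s > lo && e < hi) return(FALSE)
    }
  }
  TRUE
}

#' Infer the target-recognition domain (TRD) span
#'
#' The TRD is the single longest maximal span free of chosen motif hits,
#' among the N-terminal span, spans between hits of *different* clusters,
#' and the C-terminal span; ties break toward the C-terminus. Spans shorter
#' than `trd_min` (TRDs are domains, not gaps) and architectures with fewer
#' than two chosen hits yield an absent TRD.
#'
#' @param chosen Chosen hit tibble ([choose_hits()]).
#' @param protein_length Protein length (aa).
#' @param trd_min Minimum span length to count as a TRD (default 40 aa).
#' @return Integer `c(start, end)`, or `NULL` when absent.
#' @export
infer_trd <- function(chosen, protein_length, trd_min = 40L) {
  if (nrow(chosen) < 2L) return(NULL)
  chosen <- dplyr::arrange(chosen, .data$start)
  spans <- list()
  if (chosen$start[1] > 1L) {
    spans[[length(spans) + 1L]] <- c(1L, chosen$start[1] - 1L)
  }
  for (i in seq_len(nrow(chosen) - 1L)) {
    if (motif_cluster(chosen$label[i]) != motif_cluster(chosen$label[i + 1L]) &&
        chosen$end[i] + 1L <= chosen$start[i + 1L] - 1L) {
      spans[[length(spans) + 1L]] <- c(chosen$end[i] + 1L,
                                       chosen$start[i + 1L] - 1L)
    }
  }
  if (chosen$end[nrow(chosen)] < protein_length) {
    spans[[length(spans) + 1L]] <- c(chosen$end[nrow(chosen)] + 1L,
                                     protein_length)
  }
  if (length(spans) == 0L) return(NULL)
  lens <- vapply(spans, function(s) s[2] - s[1] + 1L, integer(1))
  if (max(lens) < trd_min) return(NULL)
  # ties toward the C-terminus: last span among the longest
  spans[[max(which(lens == max(lens)))]]
}

#' Assign a methyltransferase to the alpha/beta/gamma group
#'
#' Classifies from chosen hits and the TRD span: alpha when the AdoMet
#' cluster precedes the TRD and the TRD precedes the catalytic cluster;
#' beta when the catalytic cluster precedes the TRD and the TRD precedes the
#' AdoMet cluster; gamma when the AdoMet cluster precedes the catalytic
#' cluster and the TRD is C-terminal. The subgroup flag is raised only for
#' gamma order with motif IV variant D (DPPY) and both auxiliary motifs IVa
#' and Xa present. Cluster evidence requirements: at least 2 of
#' \{X,I,II,III\} and motif IV plus at least 1 of \{V,VI,VII\}; anything
#' less is unclassified.
#'
#' @param chosen Chosen hit tibble.
#' @param trd TRD span (`c(start, end)` or `NULL`), from [infer_trd()].
#' @return A list: `group` (`"alpha"`, `"beta"`, `"gamma"` or
#'   `"unclassified"`), `subgroup` (logical), `evidence` (character vector
#'   of satisfied/failed criteria).
#' @export
assign_group <- function(chosen, trd) {
  ev <- character(0)
  note <- function(x) ev <<- c(ev, x)
  adomet <- chosen[chosen$label %in% c("X", "I", "II", "III"), , drop = FALSE]
  adomet_all <- chosen[chosen$label %in% ADOMET_LABELS, , drop = FALSE]
  catal <- chosen[chosen$label %in% CATALYTIC_LABELS, , drop = FALSE]
  unclassified <- function() {
    list(group = "unclassified", subgroup = FALSE, evidence = ev)
  }

  if (!("IV" %in% chosen$label)) {
    note("fail: no catalytic anchor (motif IV missing)")
    return(unclassified())
  }
  note("ok: catalytic anchor motif IV present")
  if (nrow(adomet) < 2L) {
    note(paste0("fail: AdoMet cluster too weak (", nrow(adomet),
                " of X/I/II/III found, need >=2)"))
    return(unclassified())
  }
  note(paste0("ok: AdoMet cluster has ", nrow(adomet), " of X/I/II/III"))
  n_support <- sum(c("V", "VI", "VII") %in% catal$label)
  if (n_support < 1L) {
    note("fail: catalytic cluster lacks support (need >=1 of V/VI/VII)")
    return(unclassified())
  }
  note(paste0("ok: catalytic cluster supported by ", n_support, " of V/VI/VII"))
  if (is.null(trd)) {
    note("fail: no TRD span")
    return(unclassified())
  }
  note(paste0("ok: TRD at ", trd[1], "..", trd[2]))

  a_rng <- c(min(adomet_all$start), max(adomet_all$end))
  c_rng <- c(min(catal$start), max(catal$end))
  group <-
    if (a_rng[2] < trd[1] && trd[2] < c_rng[1]) "alpha"
    else if (c_rng[2] < trd[1] && trd[2] < a_rng[1]) "beta"
    else if (a_rng[2] < c_rng[1] && trd[1] > c_rng[2]) "gamma"
    else "unclassified"
  note(paste0("order: AdoMet ", a_rng[1], "..", a_rng[2], ", catalytic ",
              c_rng[1], "..", c_rng[2], " -> ", group))

  subgroup <- FALSE
  if (group == "gamma") {
    iv_variant <- chosen$variant[chosen$label == "IV"][1]
    crit <- c(
      `motif IV variant is D (DPPY)` = identical(iv_variant, "D"),
      `motif IVa present` = "IVa" %in% chosen$label,
      `motif Xa present` = "Xa" %in% chosen$label
    )
    for (i in seq_along(crit)) {
      note(paste0(if (crit[i]) "ok: " else "fail: ", names(crit)[i]))
    }
    subgroup <- all(crit)
  }
  list(group = group, subgroup = subgroup, evidence = ev)
}

#' Classify the motif architecture of one protein
#'
#' Convenience wrapper: scan with a motif configuration, choose hits, infer
#' the TRD and assign the group.
#'
#' @param protein Protein sequence string.
#' @param config Motif configuration (default [default_motif_config()]).
#' @param trd_min Minimum TRD length (default 40 aa).
#' @param cluster_max_gap Passed to [choose_hits()].
#' @param id Sequence label carried through to output.
#' @return An object of class `ma_architecture`: list with `id`, `hits`
#'   (chosen hits tibble), `trd`, `group`, `subgroup`, `evidence`,
#'   `protein_length`, `motif_order` (string such as
#'   `"X-I-II-III-IV-V-VI-VII-TRD"`).
#' @export
classify_architecture <- function(protein, config = default_motif_config(),
                                  trd_min = 40L, cluster_max_gap = 40L,
                                  id = NA_character_) {
  protein <- validate_protein(protein)
  all_hits <- scan_motifs(protein, config)
  chosen <- choose_hits(all_hits, cluster_max_gap = cluster_max_gap)
  trd <- infer_trd(chosen, nchar(protein), trd_min = trd_min)
  call <- assign_group(chosen, trd)
  structure(list(
    id = id,
    hits = chosen,
    trd = trd,
    group = call$group,
    subgroup = call$subgroup,
    evidence = call$evidence,
    protein_length = nchar(protein),
    motif_order = motif_order_string(chosen, trd)
  ), class = "ma_architecture")
}

motif_order_string <- function(chosen, trd) {
  if (nrow(chosen) == 0L) return("")
  parts <- tibble(label = chosen$label, pos = chosen$start)
  if (!is.null(trd)) {
    parts <- dplyr::bind_rows(parts, tibble(label = "TRD", pos = trd[1]))
  }
  paste(parts$label[order(parts$pos)], collapse = "-")
}

#' Classify many methyltransferase sequences
#'
#' @param seqs A data frame with columns `id` and `seq`.
#' @param config,trd_min As in [classify_architecture()].
#' @return A tibble: `id`, `group`, `subgroup`, `motif_order`, `n_motifs`,
#'   `trd_start`, `trd_end`, `evidence` (collapsed with `"; "`).
#' @export
classify_mtases <- function(seqs, config = default_motif_config(),
                            trd_min = 40L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  purrr::map2(seqs$id, seqs$seq, function(id, s) {
    glance(classify_architecture(s, config, trd_min = trd_min, id = id))
  }) |>
    dplyr::bind_rows()
}

#' @export
print.ma_architecture <- function(x, ...) {
  cat("<methyltransferase architecture", if (!is.na(x$id)) paste0(" ", x$id),
      ">\n", sep = "")
  cat("  group:    ", x$group,
      if (x$subgroup) " (DPPY-in-gamma-order subgroup)", "\n", sep = "")
  cat("  order:    ", x$motif_order, "\n", sep = "")
  if (!is.null(x$trd)) {
    cat("  TRD:      ", x$trd[1], "..", x$trd[2], "\n", sep = "")
  }
  cat("  motifs:   ", nrow(x$hits), " chosen hits on ", x$protein_length,
      " aa\n", sep = "")
  invisible(x)
}

#' Tidy a classified architecture into its chosen hits
#'
#' @param x An `ma_architecture` object.
#' @param ... Unused.
#' @return The chosen-hit tibble with an `id` column prepended.
#' @export
tidy.ma_architecture <- function(x, ...) {
  dplyr::bind_cols(tibble(id = x$id), x$hits)
}

#' One-row summary of a classified architecture
#'
#' @param x An `ma_architecture` object.
#' @param ... Unused.
#' @return A one-row tibble: `id`, `group`, `subgroup`, `motif_order`,
#'   `n_motifs`, `trd_start`, `trd_end`, `evidence`.
#' @export
glance.ma_architecture <- function(x, ...) {
  tibble(
    id = x$id, group = x$group, subgroup = x$subgroup,
    motif_order = x$motif_order, n_motifs = nrow(x$hits),
    trd_start = if (is.null(x$trd)) NA_integer_ else x$trd[1],
    trd_end = if (is.null(x$trd)) NA_integer_ else x$trd[2],
    evidence = paste(x$evidence, collapse = "; ")
  )
}

#' Plot a motif architecture as blocks along the sequence
#'
#' @param object An `ma_architecture` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ma_architecture <- function(object, ...) {
  blocks <- dplyr::bind_rows(
    dplyr::transmute(object$hits, label = .data$label, start = .data$start,
                     end = .data$end, kind = "motif"),
    if (!is.null(object$trd)) {
      tibble(label = "TRD", start = object$trd[1], end = object$trd[2],
             kind = "TRD")
    }
  )
  ggplot2::ggplot(blocks) +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = object$protein_length,
                                       y = 0, yend = 0),
                          colour = "grey70", linewidth = 0.5) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.3, ymax = 0.3,
                                    fill = .data$kind)) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2, y = 0.55,
                                    label = .data$label), size = 3) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(x = "residue", y = NULL,
                  title = paste0(object$id %||% "", "  [", object$group,
                                 if (object$subgroup) ", subgroup", "]")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
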