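# Seeded synthetic-data generators with planted ground truth: motif
# architectures, sequence families, and R-M loci. Identical seeds and
# parameters give byte-identical output.

GROUP_ORDERS <- list(
  alpha    = list(before = c("X", "I", "II", "III"),
                  after = c("IV", "V", "VI", "VII")),
  beta     = list(before = c("IV", "V", "VI", "VII"),
                  after = c("X", "I", "II", "III")),
  gamma    = list(before = c("X", "I", "II", "III", "IV", "V", "VI", "VII"),
                  after = character(0)),
  subgroup = list(before = c("Xa", "X", "I", "II", "III", "IV", "IVa",
                             "V", "VI", "VII"),
                  after = character(0))
)

sample_background <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# Sample one concrete instance of a configured motif. Motif IV's first
# residue can be forced to control the D/N/S variant.
sample_motif_instance <- function(cfg_row, force_first = NULL) {
  if (cfg_row$kind == "hydrophobic") {
    return(paste(sample(HYDROPHOBIC_AA, cfg_row$window, replace = TRUE),
                 collapse = ""))
  }
  model <- compile_motif(cfg_row$pattern, cfg_row$label)
  chars <- character(0)
  first_fixed <- FALSE
  for (e in model$elements) {
    if (e$type == "spacer") {
      len <- if (e$min == e$max) e$min else sample(e$min:e$max, 1L)
      if (len > 0L) chars <- c(chars, sample(AA_LETTERS, len, replace = TRUE))
    } else {
      pick <- if (!first_fixed && !is.null(force_first) &&
                  e$type == "set" && length(e$set) > 1L) {
        first_fixed <- TRUE
        stopifnot(force_first %in% e$set)
        force_first
      } else if (length(e$set) == 1L) e$set else sample(e$set, 1L)
      chars <- c(chars, pick)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic methyltransferase with a planted motif architecture
#'
#' Plants concrete motif instances (sampled from the configured patterns) in
#' the canonical order of the requested group, separated by short gaps, with
#' a target-recognition domain (TRD) of at least `trd_min` residues at the
#' group's canonical position (central for alpha/beta, C-terminal for
#' gamma/subgroup). The background is uniform over the 20 residues.
#' Substitution noise is applied only outside planted motifs unless
#' `noise_in_motifs = TRUE`. Motif IV is planted as NPPY for gamma and DPPY
#' for alpha, beta and the subgroup; the subgroup additionally plants Xa and
#' IVa, whose patterns the configuration must supply (e.g.
#' [subgroup_motif_config()]).
#'
#' @param group `"alpha"`, `"beta"`, `"gamma"` or `"subgroup"`.
#' @param length Protein length (aa); an error names the required minimum if
#'   too short to hold all blocks plus the TRD.
#' @param noise Substitution fraction applied outside planted motifs.
#' @param seed RNG seed.
#' @param config Motif configuration (default [synthetic_motif_config()],
#'   which supplies concrete patterns for every planted block).
#' @param trd_min Minimum TRD length (default 40 aa).
#' @param noise_in_motifs Allow noise inside planted motifs (default FALSE).
#' @param id Sequence label.
#' @return A list: `protein` (tibble `id`, `seq`) and `truth` (list with
#'   `group`, `motifs` tibble of planted label/start/end/planted/variant,
#'   and `trd` span).
#' @export
gen_mtase <- function(group = c("gamma", "alpha", "beta", "subgroup"),
                      length = 320L, noise = 0, seed = 1L,
                      config = synthetic_motif_config(), trd_min = 40L,
                      noise_in_motifs = FALSE, id = NULL) {
  group <- match.arg(group)
  config <- validate_motif_config(config)
  set.seed(seed)
  ord <- GROUP_ORDERS[[group]]
  enabled <- config$label[config$enabled]
  # plant only configured motifs (III and VIII have no consensus pattern)
  ord$before <- ord$before[ord$before %in% enabled]
  ord$after <- ord$after[ord$after %in% enabled]
  labels <- c(ord$before, ord$after)
  need <- c("IV", if (group == "subgroup") c("Xa", "IVa"))
  if (!all(need %in% labels) ||
      sum(c("X", "I", "II", "III") %in% labels) < 2L ||
      sum(c("V", "VI", "VII") %in% labels) < 1L) {
    stop("motif config does not enable enough motifs to plant a ",
         "recoverable ", group, " architecture", call. = FALSE)
  }
  iv_variant <- if (group == "gamma") "N" else "D"
  instances <- purrr::map_chr(labels, function(l) {
    row <- config[config$label == l, ]
    sample_motif_instance(row, force_first = if (l == "IV") iv_variant)
  })
  names(instances) <- labels
  lead_gap <- sample(2:4, 1L)
  n_gaps <- (base::length(ord$before) - 1L) +
    max(base::length(ord$after) - 1L, 0L)
  gaps <- sample(4:12, n_gaps, replace = TRUE) # gaps between in-cluster motifs
  tail_gap <- if (base::length(ord$after) > 0L) sample(3:8, 1L) else 0L
  fixed <- lead_gap + sum(nchar(instances)) + sum(gaps) + tail_gap
  trd_len <- length - fixed
  if (trd_len < trd_min) {
    stop("length ", length, " too short: need at least ", fixed + trd_min,
         " aa to hold all planted blocks plus a ", trd_min, "-aa TRD",
         call. = FALSE)
  }
  # assemble: [lead] before-motifs(+gaps) [TRD] after-motifs(+gaps) [tail]
  seq_ch <- strsplit(sample_background(length), "", fixed = TRUE)[[1]]
  pos <- lead_gap + 1L
  truth <- list()
  place <- function(label) {
    inst <- instances[[label]]
    s <- pos; e <- pos + nchar(inst) - 1L
    seq_ch[s:e] <<- strsplit(inst, "", fixed = TRUE)[[1]]
    truth[[length(truth) + 1L]] <<- tibble(
      label = label, start = s, end = e, planted = inst,
      variant = if (label == "IV") iv_variant else NA_character_
    )
    pos <<- e + 1L
  }
  gi <- 1L
  for (i in seq_along(ord$before)) {
    place(ord$before[i])
    if (i < base::length(ord$before)) {
      pos <- pos + gaps[gi]; gi <- gi + 1L
    }
  }
  if (base::length(ord$after) > 0L) {
    trd <- c(pos, pos + trd_len - 1L) # central TRD directly after cluster
    pos <- pos + trd_len
    for (i in seq_along(ord$after)) {
      place(ord$after[i])
      if (i < base::length(ord$after)) {
        pos <- pos + gaps[gi]; gi <- gi + 1L
      }
    }
  } else {
    trd <- c(pos, length) # C-terminal TRD
  }
  truth_tbl <- dplyr::bind_rows(truth)
  # substitution noise
  if (noise > 0) {
    protected <- unlist(purrr::map2(truth_tbl$start, truth_tbl$end, seq))
    eligible <- if (noise_in_motifs) seq_len(length) else
      setdiff(seq_len(length), protected)
    n_sub <- round(noise * base::length(eligible))
    if (n_sub > 0L) {
      at <- sample(eligible, n_sub)
      seq_ch[at] <- vapply(seq_ch[at], function(r) {
        sample(setdiff(AA_LETTERS, r), 1L)
      }, character(1))
    }
  }
  id <- id %||% paste0("mtase_", group, "_seed", seed)
  list(
    protein = tibble(id = id, seq = paste(seq_ch, collapse = "")),
    truth = list(group = group, motifs = truth_tbl, trd = trd)
  )
}

# substitute n positions, biased to stay within conservation groups
mutate_protein <- function(seq, n_subs, p_within_group = 0.7,
                           scheme = conservation_groups()) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_subs == 0L) return(seq)
  at <- sample(seq_along(ch), min(n_subs, length(ch)))
  for (i in at) {
    r <- ch[i]
    grp <- NULL
    for (g in scheme) if (r %in% g) grp <- g
    ch[i] <- if (!is.null(grp) && length(grp) > 1L &&
                 stats::runif(1) < p_within_group) {
      sample(setdiff(grp, r), 1L)
    } else {
      sample(setdiff(AA_LETTERS, r), 1L)
    }
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic protein family along a recorded tree
#'
#' Duplicate-and-mutate: a random binary topology is drawn, the parent
#' sequence is placed at the root, and a fixed number of substitutions is
#' applied along every branch. Substitutions stay within the residue's
#' conservation group with probability `p_within_group` (so similarity decays
#' more slowly than identity). The generating topology is returned as truth.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param parent_length Root sequence length (aa).
#' @param subs_per_branch Substitutions applied on each branch.
#' @param seed RNG seed.
#' @param p_within_group Probability a substitution stays in-group.
#' @return A list: `seqs` (tibble `id`, `seq`) and `truth` (list with the
#'   generating `tree`, an `ape::phylo`).
#' @export
gen_family <- function(n_leaves = 6L, parent_length = 200L,
                       subs_per_branch = 8L, seed = 1L,
                       p_within_group = 0.7) {
  stopifnot(n_leaves >= 2L)
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL,
                     tip.label = paste0("t", seq_len(n_leaves)))
  tree <- stats::reorder(tree, "cladewise") # preorder: parent before child
  parent <- sample_background(parent_length)
  seqs <- character(n_leaves + tree$Nnode)
  seqs[n_leaves + 1L] <- parent # root
  for (k in seq_len(nrow(tree$edge))) {
    e <- tree$edge[k, ]
    seqs[e[2]] <- mutate_protein(seqs[e[1]], subs_per_branch, p_within_group)
  }
  list(
    seqs = tibble(id = tree$tip.label, seq = seqs[seq_len(n_leaves)]),
    truth = list(tree = tree)
  )
}

#' Generate a two-clade protein family
#'
#' A parent sequence is mutated into two clade ancestors, each of which is
#' mutated independently into its leaves. Truth records the planted
#' bipartition.
#'
#' @param n_per_clade Leaves per clade.
#' @param parent_length Parent sequence length (aa).
#' @param subs_ancestor Substitutions on each parent-to-ancestor branch.
#' @param subs_leaf Substitutions on each ancestor-to-leaf branch.
#' @param seed RNG seed.
#' @param p_within_group In-group substitution probability.
#' @return A list: `seqs` (tibble) and `truth` (list with `clades`, a named
#'   list of leaf-id vectors).
#' @export
gen_two_clade_family <- function(n_per_clade = 3L, parent_length = 200L,
                                 subs_ancestor = 30L, subs_leaf = 5L,
                                 seed = 1L, p_within_group = 0.7) {
  stopifnot(n_per_clade >= 1L)
  set.seed(seed)
  parent <- sample_background(parent_length)
  anc <- purrr::map_chr(1:2, function(i) {
    mutate_protein(parent, subs_ancestor, p_within_group)
  })
  leaves <- purrr::map(1:2, function(ci) {
    purrr::map_chr(seq_len(n_per_clade), function(li) {
      mutate_protein(anc[ci], subs_leaf, p_within_group)
    })
  })
  ids <- c(paste0("A", seq_len(n_per_clade)), paste0("B", seq_len(n_per_clade)))
  list(
    seqs = tibble(id = ids, seq = c(leaves[[1]], leaves[[2]])),
    truth = list(clades = list(A = ids[seq_len(n_per_clade)],
                               B = ids[n_per_clade + seq_len(n_per_clade)]))
  )
}

#' Generate a synthetic R-M locus with exact planted geometry
#'
#' Emits a DNA sequence carrying protein-coding-style genes (ATG, non-stop
#' codons, TAA; reverse-complemented for minus-strand genes) at exactly the
#' requested sizes, strands and intergenic gaps, plus optional planted
#' recognition-site contexts (e.g. `TCGCGA` or the Dam-overlap `TCGCGATC`).
#' Accidental occurrences of planted context strings arising from the random
#' background are scrubbed (one base changed) so that site positions in the
#' truth are exhaustive.
#'
#' @param genes A data frame with columns `name`, `role`, `length_bp`
#'   (divisible by 3), `strand`.
#' @param gaps Integer vector of intergenic gaps (length `nrow(genes) - 1`);
#'   negative gaps (overlapping genes) are an error.
#' @param flank Length-2 vector: bases before the first and after the last
#'   gene.
#' @param seed RNG seed.
#' @param gc GC fraction of the background (default 0.5; raise to emulate
#'   high-GC genomes).
#' @param plant_sites Optional tibble (`pos`, `context`) of contexts to
#'   write into the sequence at 1-based positions.
#' @param scrub Character vector of motifs to scrub outside planted
#'   positions (default `"TCGCGA"`).
#' @param id Sequence label.
#' @return A list: `locus` (tibble `id`, `seq`), `genes` (tibble `name`,
#'   `role`, `start`, `end`, `strand`) and `truth` (list with `geometry`
#'   = the gene tibble, `gaps`, and `sites` = planted site positions).
#' @export
gen_rm_locus <- function(genes, gaps, flank = c(60L, 60L), seed = 1L,
                         gc = 0.5, plant_sites = NULL, scrub = "TCGCGA",
                         id = "synthetic_locus") {
  stopifnot(all(c("name", "role", "length_bp", "strand") %in% names(genes)),
            length(gaps) == nrow(genes) - 1L)
  if (any(genes$length_bp %% 3 != 0)) {
    stop("gene lengths must be divisible by 3", call. = FALSE)
  }
  if (any(gaps < 0L)) stop("overlapping genes requested (negative gap)",
                           call. = FALSE)
  set.seed(seed)
  total <- flank[1] + sum(genes$length_bp) + sum(gaps) + flank[2]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_ch <- sample(names(p), total, replace = TRUE, prob = p)
  gene_tbl <- as_tibble(genes)
  gene_tbl$start <- NA_integer_; gene_tbl$end <- NA_integer_
  pos <- flank[1] + 1L
  for (i in seq_len(nrow(gene_tbl))) {
    len <- gene_tbl$length_bp[i]
    orf <- make_orf(len)
    if (gene_tbl$strand[i] == "-") orf <- reverse_complement(orf)
    gene_tbl$start[i] <- pos
    gene_tbl$end[i] <- pos + len - 1L
    seq_ch[pos:(pos + len - 1L)] <- strsplit(orf, "", fixed = TRUE)[[1]]
    pos <- pos + len + if (i < nrow(gene_tbl)) gaps[i] else 0L
  }
  dna <- paste(seq_ch, collapse = "")
  planted_pos <- integer(0)
  if (!is.null(plant_sites) && nrow(plant_sites) > 0L) {
    for (i in seq_len(nrow(plant_sites))) {
      s <- plant_sites$pos[i]; ctx <- validate_nuc(plant_sites$context[i])
      if (s < 1L || s + nchar(ctx) - 1L > total) {
        stop("planted context at ", s, " does not fit the locus",
             call. = FALSE)
      }
      substr(dna, s, s + nchar(ctx) - 1L) <- ctx
      planted_pos <- c(planted_pos, s)
    }
  }
  # scrub accidental occurrences of the scrub motifs outside planted spans
  for (motif in scrub) {
    repeat {
      bh <- find_binding_sites(motif, dna)
      hits <- bh$pos[bh$strand == "+"] # palindrome: plus-strand starts suffice
      hits <- hits[!vapply(hits, function(h) {
        any(vapply(seq_along(planted_pos), function(i) {
          ctx_len <- nchar(plant_sites$context[i])
          h >= planted_pos[i] && h + nchar(motif) - 1L <=
            planted_pos[i] + ctx_len - 1L
        }, logical(1)))
      }, logical(1))]
      if (length(hits) == 0L) break
      h <- hits[1]
      mid <- h + nchar(motif) %/% 2L
      cur <- substr(dna, mid, mid)
      substr(dna, mid, mid) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
  }
  list(
    locus = tibble(id = id, seq = dna),
    genes = gene_tbl[, c("name", "role", "start", "end", "strand")],
    truth = list(geometry = gene_tbl, gaps = gaps, sites = planted_pos)
  )
}

# ATG + random non-stop codons + TAA, length `len` (divisible by 3, >= 9)
make_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(codons, len / 3 - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Canonical NruI-like locus geometry
#'
#' Two genes transcribed divergently — the endonuclease gene (660 bp,
#' minus strand) and the methylase gene (804 bp, plus strand) — separated by
#' a 326-bp non-coding gap.
#'
#' @return A list with `genes` and `gaps` ready for [gen_rm_locus()].
#' @export
nrui_locus_geometry <- function() {
  list(
    genes = tibble(
      name = c("nruIR", "nruIM"), role = c("R", "M"),
      length_bp = c(660L, 804L), strand = c("-", "+")
    ),
    gaps = 326L
  )
}

#' Canonical Sbo13I-like locus geometry
#'
#' Three genes: controller and endonuclease in tandem on the plus strand,
#' methylase on the minus strand. Gene sizes other than orientation are not
#' published and are synthetic choices.
#'
#' @return A list with `genes` and `gaps` ready for [gen_rm_locus()].
#' @export
sbo13i_locus_geometry <- function() {
  list(
    genes = tibble(
      name = c("sbo13IC", "sbo13IR", "sbo13IM"), role = c("C", "R", "M"),
      length_bp = c(249L, 660L, 804L), strand = c("+", "+", "-")
    ),
    gaps = c(30L, 120L)
  )
}

#' Write a synthetic locus to FASTA + GFF-like TSV
#'
#' @param locus The list returned by [gen_rm_locus()].
#' @param dir Output directory (created if needed).
#' @param stem File stem (default the locus id).
#' @return Paths of the two written files, invisibly.
#' @export
write_locus <- function(locus, dir, stem = locus$locus$id[1]) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  tsv <- file.path(dir, paste0(stem, ".genes.tsv"))
  write_fasta(locus$locus, fa)
  readr::write_tsv(locus$genes, tsv)
  invisible(c(fa, tsv))
}
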