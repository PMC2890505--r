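test_that("generators are deterministic for fixed seeds and parameters", {
  a <- gen_mtase("subgroup", 320, 0.05, seed = 9)
  b <- gen_mtase("subgroup", 320, 0.05, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$protein$seq,
                         gen_mtase("subgroup", 320, 0.05, seed = 10)$protein$seq))
  f1 <- gen_family(5, 100, 6, seed = 4)
  f2 <- gen_family(5, 100, 6, seed = 4)
  expect_identical(f1$seqs, f2$seqs)
  geo <- nrui_locus_geometry()
  l1 <- gen_rm_locus(geo$genes, geo$gaps, seed = 2)
  l2 <- gen_rm_locus(geo$genes, geo$gaps, seed = 2)
  expect_identical(l1$locus$seq, l2$locus$seq)
})

test_that("planted motif coordinates slice back to matching instances", {
  cfg <- synthetic_motif_config()
  for (g in c("gamma", "alpha", "beta", "subgroup")) {
    res <- gen_mtase(g, 320, 0, seed = 23)
    tr <- res$truth$motifs
    for (i in seq_len(nrow(tr))) {
      slice <- substr(res$protein$seq, tr$start[i], tr$end[i])
      expect_identical(slice, tr$planted[i],
                       label = paste(g, "motif", tr$label[i]))
      # the slice matches the configured pattern (via the scanner itself)
      row <- cfg[cfg$label == tr$label[i], ]
      if (row$kind == "pattern") {
        h <- scan_motif(slice, compile_motif(row$pattern, row$label))
        expect_true(any(h$start == 1L & h$end == nchar(slice)),
                    label = paste(g, "pattern match", tr$label[i]))
      } else {
        expect_true(all(strsplit(slice, "")[[1]] %in%
                          c("V", "L", "I", "M", "F", "Y", "W", "A")))
      }
    }
    # motif IV variant as planted: NPPY for gamma, DPPY otherwise
    iv <- tr[tr$label == "IV", ]
    expect_identical(substr(iv$planted, 1, 1),
                     if (g == "gamma") "N" else "D")
    # TRD is hit-free in truth and at least 40 aa
    expect_gte(res$truth$trd[2] - res$truth$trd[1] + 1L, 40L)
  }
})

test_that("noise respects planted motifs by default", {
  clean <- gen_mtase("gamma", 320, 0, seed = 31)
  noisy <- gen_mtase("gamma", 320, 0.1, seed = 31)
  # same seed: same layout; motifs untouched by noise
  expect_identical(clean$truth$motifs[c("label", "start", "end")],
                   noisy$truth$motifs[c("label", "start", "end")])
  tr <- noisy$truth$motifs
  for (i in seq_len(nrow(tr))) {
    expect_identical(substr(noisy$protein$seq, tr$start[i], tr$end[i]),
                     tr$planted[i])
  }
  expect_false(identical(clean$protein$seq, noisy$protein$seq))
})

test_that("family generator produces the recorded topology semantics", {
  # zero substitutions: all leaves identical, all distances zero
  f0 <- gen_family(4, 80, 0, seed = 5)
  expect_identical(length(unique(f0$seqs$seq)), 1L)
  dm0 <- distance_matrix(f0$seqs)
  expect_true(all(dm0 == 0))
  expect_s3_class(gen_family(6, 50, 2, seed = 1)$truth$tree, "phylo")
  # siblings are more alike than cross-clade pairs, on average over seeds
  diffs <- vapply(1:20, function(s) {
    fam <- gen_two_clade_family(2, 120, 20, 4, seed = s)
    dm <- distance_matrix(fam$seqs)
    intra <- mean(c(dm["A1", "A2"], dm["B1", "B2"]))
    inter <- mean(dm[c("A1", "A2"), c("B1", "B2")])
    inter - intra
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("locus generator plants exact geometry and site truth tables", {
  geo <- nrui_locus_geometry()
  loc <- gen_rm_locus(geo$genes, geo$gaps, seed = 13,
                      plant_sites = tibble::tibble(pos = 780L,
                                                   context = "TCGCGATC"))
  layout <- locus_layout(loc$genes)
  expect_identical(layout$gap_bp, 326L)
  expect_identical(layout$orientation, "divergent")
  # gene lengths divisible by 3 and coordinates exact
  expect_identical(loc$genes$end - loc$genes$start + 1L,
                   geo$genes$length_bp)
  # planted site is the only recognition site (accidental ones scrubbed)
  expect_identical(find_sites(loc$locus$seq, nrui())$pos, 780L)
  # minus-strand gene starts with a reverse-complemented ORF
  r <- loc$genes[loc$genes$name == "nruIR", ]
  orf <- reverse_complement(substr(loc$locus$seq, r$start, r$end))
  expect_identical(substr(orf, 1, 3), "ATG")
  expect_identical(substring(orf, nchar(orf) - 2), "TAA")
  # plus-strand gene likewise
  m <- loc$genes[loc$genes$name == "nruIM", ]
  expect_identical(substr(loc$locus$seq, m$start, m$start + 2), "ATG")
  # cleavage truth table at the planted Dam-overlap context
  marks <- dam_marks(loc$locus$seq)
  expect_true(785L %in% marks)
  expect_false(any(cleave(loc$locus$seq, nrui(), marks)$start == 783L))
  expect_true(any(cleave(loc$locus$seq, sbo13i(), marks)$start == 783L))
})

test_that("locus generator rejects impossible geometries", {
  genes <- tibble::tibble(name = c("a", "b"), role = c("R", "M"),
                          length_bp = c(300L, 301L), strand = c("+", "+"))
  expect_error(gen_rm_locus(genes, 10L, seed = 1), "divisible by 3")
  genes$length_bp <- c(300L, 300L)
  expect_error(gen_rm_locus(genes, -5L, seed = 1), "overlap")
})

test_that("zero-gap tandem loci report tandem with gap 0", {
  genes <- tibble::tibble(name = c("a", "b"), role = c("R", "M"),
                          length_bp = c(300L, 300L), strand = c("+", "+"))
  loc <- gen_rm_locus(genes, 0L, seed = 3)
  layout <- locus_layout(loc$genes)
  expect_identical(layout$orientation, "tandem")
  expect_identical(layout$gap_bp, 0L)
})

test_that("loci round-trip through FASTA + gene-table files", {
  geo <- sbo13i_locus_geometry()
  loc <- gen_rm_locus(geo$genes, geo$gaps, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_locus(loc, dir)
  fa <- read_fasta(paths[1])
  expect_identical(fa$seq, loc$locus$seq)
  genes <- readr::read_tsv(paths[2], show_col_types = FALSE)
  expect_identical(as.integer(genes$start), loc$genes$start)
  expect_identical(genes$strand, loc$genes$strand)
  # three-gene layout: C/R tandem, R/M in opposite orientation
  layout <- locus_layout(loc$genes)
  expect_identical(layout$orientation[1], "tandem")
  expect_identical(layout$orientation[2], "convergent")
})
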