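test_that("ORF arithmetic converts gene sizes to protein lengths", {
  expect_identical(orf_protein_length(804), 267L)
  expect_identical(orf_protein_length(660), 219L)
  expect_identical(orf_protein_length(6), 1L)
  expect_error(orf_protein_length(805), "complete ORF")
  expect_error(orf_protein_length(3), "complete ORF")
  # orf_protein_length(3(n+1)) = n for all n >= 1
  n <- 1:200
  expect_identical(orf_protein_length(3 * (n + 1)), n)
})

test_that("locus layout reports orientation, gaps and overlaps", {
  g <- tibble::tibble(
    name = c("R", "M"), role = c("R", "M"),
    start = c(1L, 987L), end = c(660L, 1790L), strand = c("-", "+")
  )
  rep1 <- locus_layout(g)
  expect_identical(rep1$gap_bp, 326L)
  expect_identical(rep1$orientation, "divergent")
  expect_false(rep1$overlap)
  # adjacent same-strand genes, no gap: tandem
  g2 <- tibble::tibble(name = c("a", "b"), role = c("R", "M"),
                       start = c(1L, 301L), end = c(300L, 600L),
                       strand = c("+", "+"))
  rep2 <- locus_layout(g2)
  expect_identical(rep2$orientation, "tandem")
  expect_identical(rep2$gap_bp, 0L)
  # three-gene Sbo13I-like layout: C/R tandem, R/M opposite (convergent)
  g3 <- tibble::tibble(
    name = c("C", "R", "M"), role = c("C", "R", "M"),
    start = c(1L, 300L, 1100L), end = c(249L, 959L, 1903L),
    strand = c("+", "+", "-")
  )
  rep3 <- locus_layout(g3)
  expect_identical(rep3$orientation, c("tandem", "convergent"))
  # overlapping genes: gap 0 with overlap flag
  g4 <- tibble::tibble(name = c("a", "b"), role = c("R", "M"),
                       start = c(1L, 250L), end = c(300L, 600L),
                       strand = c("+", "+"))
  expect_true(locus_layout(g4)$overlap)
  expect_identical(locus_layout(g4)$gap_bp, 0L)
})

test_that("site finding and blunt cleavage are exact", {
  expect_identical(find_sites("TTCGCGAA", nrui())$pos, 2L)
  frags <- cleave("TTCGCGAA", nrui())
  expect_identical(frags$seq, c("TTCG", "CGAA"))
  expect_identical(overhang(nrui()), 0L)
  # no site: one fragment, the input
  expect_identical(cleave("AAAA", nrui())$seq, "AAAA")
})

test_that("cleavage conserves every base on linear inputs", {
  set.seed(141)
  for (rep in 1:10) {
    dna <- paste0(rand_dna(40), "TCGCGA", rand_dna(30), "TCGCGA",
                  rand_dna(20))
    frags <- cleave(dna, nrui())
    expect_identical(paste(frags$seq, collapse = ""), dna)
  }
})

test_that("palindromic sites mirror under reverse complement", {
  set.seed(151)
  for (rep in 1:5) {
    dna <- paste0(rand_dna(25), "TCGCGA", rand_dna(50), "TCGCGA",
                  rand_dna(10))
    L <- nchar(dna)
    fwd <- find_sites(dna, nrui())$pos
    rev <- find_sites(reverse_complement(dna), nrui())$pos
    expect_identical(sort(rev), sort(L - fwd - 6L + 2L))
  }
})

test_that("Dam methylation at the overlap blocks NruI but not Sbo13I", {
  dna <- paste0("GG", "TCGCGATC", "GG")
  marks <- dam_marks(dna)
  expect_identical(marks, 8L) # the adenine of the GATC overlap
  # methylated: NruI blocked (no cut), Sbo13I cleaves
  expect_identical(nrow(cleave(dna, nrui(), marks)), 1L)
  expect_identical(nrow(cleave(dna, sbo13i(), marks)), 2L)
  # unmethylated: both cleave
  expect_identical(nrow(cleave(dna, nrui())), 2L)
  expect_identical(nrow(cleave(dna, sbo13i())), 2L)
  # a site without the Dam context is cut by NruI even with marks elsewhere
  dna2 <- paste0("GG", "TCGCGAAA", "GGGATCGG")
  expect_identical(nrow(cleave(dna2, nrui(), dam_marks(dna2))), 2L)
})

test_that("inverse PCR products cross the ligation junction correctly", {
  set.seed(161)
  scrub <- function(s) gsub("TCGCGA", "TACGTA", s)
  left <- scrub(rand_dna(80)); mid <- scrub(rand_dna(10))
  spc <- scrub(rand_dna(20)); right <- scrub(rand_dna(80))
  fwd <- "ACGTACGTACGTACGT"
  rev <- "TTGCATGCATGCATGC"
  genome <- paste0(left, "TCGCGA", mid, reverse_complement(rev), spc, fwd,
                   right)
  amp <- simulate_inverse_pcr(genome, nrui(), fwd, rev)
  junction <- amp[amp$crosses_junction, ]
  expect_identical(nrow(junction), 1L)
  # string-surgery oracle: circularised downstream fragment re-read across
  # the junction
  frag2 <- substring(genome, 80 + 3 + 1)
  L <- nchar(frag2)
  a <- junction[1, ]
  oracle <- paste0(substring(frag2, a$start, L), substr(frag2, 1, a$end))
  expect_identical(a$seq, oracle)
  expect_identical(substr(a$seq, 1, nchar(fwd)), fwd)
  expect_identical(substring(a$seq, a$length - nchar(rev) + 1),
                   reverse_complement(rev))
})

test_that("inverse PCR with primers on different fragments yields nothing", {
  set.seed(171)
  scrub <- function(s) gsub("TCGCGA", "TACGTA", s)
  fwd <- "ACGTACGTACGTACGT"
  rev <- "TTGCATGCATGCATGC"
  genome <- paste0(scrub(rand_dna(50)), reverse_complement(rev),
                   scrub(rand_dna(20)), "TCGCGA", scrub(rand_dna(20)),
                   fwd, scrub(rand_dna(50)))
  amp <- simulate_inverse_pcr(genome, nrui(), fwd, rev)
  expect_identical(nrow(amp), 0L)
  # no recognition site at all: empty result, not an error
  expect_identical(nrow(simulate_inverse_pcr(scrub(rand_dna(100)), nrui(),
                                             fwd, rev)), 0L)
})

test_that("a primer binding twice reports every consistent product", {
  set.seed(181)
  scrub <- function(s) gsub("TCGCGA", "TACGTA", s)
  fwd <- "ACGTACGTACGTACGT"
  rev <- "TTGCATGCATGCATGC"
  genome <- paste0(scrub(rand_dna(40)), "TCGCGA",
                   scrub(rand_dna(10)), reverse_complement(rev),
                   scrub(rand_dna(15)), fwd,
                   scrub(rand_dna(15)), fwd, scrub(rand_dna(40)))
  amp <- simulate_inverse_pcr(genome, nrui(), fwd, rev)
  # two plus-strand placements of fwd against one rev site
  expect_identical(nrow(amp[amp$crosses_junction, ]), 2L)
})

test_that("the evidence vote reproduces the published methylation calls", {
  # NruI-like profile
  nru <- call_methylation_type(dotblot_n6ma = "pos",
                               dam_overlap_cleaved = "no")
  expect_identical(nru$call, "N6mA")
  expect_identical(nrow(nru$votes), 2L)
  # Sbo13I-like profile
  sbo <- call_methylation_type(dotblot_n4mc = "pos", mrr_restricted = "no",
                               dam_overlap_cleaved = "yes",
                               homology_hint = "N4mC")
  expect_identical(sbo$call, "N4mC")
  expect_identical(nrow(sbo$votes), 4L)
  expect_true(any(grepl("tally", sbo$rationale)))
  # one vote each way: inconclusive
  tie <- call_methylation_type(dotblot_n6ma = "pos", dotblot_n4mc = "pos")
  expect_identical(tie$call, "inconclusive")
  # Mrr restriction votes for adenine methylation
  expect_identical(call_methylation_type(mrr_restricted = "yes")$call, "N6mA")
  expect_error(call_methylation_type(), "untested")
})
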