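# Independent oracles and small generators used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Motif-pattern oracle: translate the pattern string to an anchored regex,
# independently of compile_motif, and test every substring.
pattern_to_regex <- function(pattern) {
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    if (grepl("^x\\(\\d+,\\d+\\)$", tok)) {
      m <- regmatches(tok, regexec("^x\\((\\d+),(\\d+)\\)$", tok))[[1]]
      sprintf("[A-Z]{%s,%s}", m[2], m[3]) # spacers tolerate X
    } else if (tok == "x") {
      "[ACDEFGHIKLMNPQRSTVWY]" # any residue, but never unknown X
    } else if (grepl("^\\[", tok) || grepl("^\\{", tok)) {
      paste0("[", substr(tok, 2, nchar(tok) - 1), "]")
    } else {
      tok
    }
  }, character(1))
  paste0("^", paste(parts, collapse = ""), "$")
}

brute_scan_spans <- function(protein, pattern, max_len = 16L) {
  rx <- pattern_to_regex(pattern)
  n <- nchar(protein)
  starts <- rep(seq_len(n), each = max_len)
  ends <- starts + rep(seq_len(max_len) - 1L, times = n)
  keep <- ends <= n
  starts <- starts[keep]; ends <- ends[keep]
  hit <- grepl(rx, substring(protein, starts, ends))
  cbind(starts[hit], ends[hit])
}

# Exhaustive hit-selection oracle: enumerate every subset, keep valid ones,
# and return the best (score, then cluster compactness) objective value.
ADOMET <- c("Xa", "X", "I", "II", "III")
CATALYTIC <- c("IV", "IVa", "V", "VI", "VII", "VIII")

subset_valid <- function(h, gap_cap = 40L) {
  if (nrow(h) == 0L) return(TRUE)
  if (anyDuplicated(h$label)) return(FALSE)
  h <- h[order(h$start), , drop = FALSE]
  if (nrow(h) > 1L) {
    if (any(h$start[-1] <= h$end[-nrow(h)])) return(FALSE) # overlap
  }
  ref <- c(ADOMET, CATALYTIC)
  cl <- ifelse(h$label %in% ADOMET, "a",
               ifelse(h$label %in% CATALYTIC, "c", "o"))
  for (k in c("a", "c")) {
    idx <- which(cl == k)
    if (length(idx) < 2L) next
    rk <- match(h$label[idx], ref)
    if (is.unsorted(rk)) return(FALSE) # in-cluster label order
    # nearest-neighbour gap cap
    for (i in idx) {
      gaps <- vapply(setdiff(idx, i), function(j) {
        max(h$start[j] - h$end[i] - 1L, h$start[i] - h$end[j] - 1L)
      }, numeric(1))
      if (min(gaps) > gap_cap) return(FALSE)
    }
    # contiguity: no other-cluster hit inside this cluster's span
    span <- range(c(h$start[idx], h$end[idx]))
    other <- which(cl != k & cl != "o")
    if (any(h$start[other] > span[1] & h$end[other] < span[2])) return(FALSE)
  }
  TRUE
}

subset_objective <- function(h) {
  span <- 0
  cl <- ifelse(h$label %in% ADOMET, "a",
               ifelse(h$label %in% CATALYTIC, "c", "o"))
  for (k in c("a", "c")) {
    idx <- which(cl == k)
    if (length(idx) > 0L) span <- span + max(h$end[idx]) - min(h$start[idx])
  }
  c(score = sum(h$score), span = span)
}

exhaustive_best <- function(hits, gap_cap = 40L) {
  n <- nrow(hits)
  best <- c(score = -Inf, span = Inf)
  for (mask in 0:(2^n - 1L)) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    h <- hits[keep, , drop = FALSE]
    if (!subset_valid(h, gap_cap)) next
    obj <- subset_objective(h)
    if (obj["score"] > best["score"] + 1e-9 ||
        (abs(obj["score"] - best["score"]) <= 1e-9 &&
         obj["span"] < best["span"])) {
      best <- obj
    }
  }
  best
}

# Single-linkage oracle: naive agglomeration returning sorted merge heights.
single_linkage_heights <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- min(dm[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Does an unrooted tree contain the bipartition separating `tips_a`?
has_bipartition <- function(tree, tips_a) {
  parts <- ape::prop.part(tree)
  labs <- tree$tip.label
  target <- sort(match(tips_a, labs))
  other <- sort(setdiff(seq_along(labs), target))
  for (p in parts) {
    if (identical(sort(p), target) || identical(sort(p), other)) return(TRUE)
  }
  # also check splits induced by internal edges via unrooted representation
  any(vapply(parts, function(p) identical(sort(p), target) ||
               identical(sort(p), other), logical(1)))
}
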