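# FASTA and aligned-FASTA I/O. Biostrings does the parsing; the package
# surface is a tibble with `id` and `seq` columns.

#' Read a (multi-)FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq` (uppercase).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss)))
  )
}

#' Write sequences from a tibble to a FASTA file
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `x`, invisibly (pipe-friendly).
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  lines <- unlist(purrr::map2(x$id, x$seq, function(id, s) {
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    c(paste0(">", id),
      if (nchar(s) > 0L) substring(s, starts, pmin(starts + width - 1L, nchar(s))) else "")
  }))
  writeLines(lines, path)
  invisible(x)
}

#' Read an aligned FASTA file as an alignment block
#'
#' All rows must have equal length; `-` is the only accepted gap character
#' (a `.` gap is rejected with an error rather than silently translated).
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id` and `seq`, plus attribute `aligned = TRUE`.
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path)
  validate_alignment(x)
}

#' Validate an alignment block
#'
#' @param x A data frame with columns `id` and `seq` (gapped, `-` only).
#' @return `x` with attribute `aligned = TRUE`, or an error.
#' @export
validate_alignment <- function(x) {
  stopifnot(all(c("id", "seq") %in% names(x)), nrow(x) >= 1L)
  if (any(grepl(".", x$seq, fixed = TRUE))) {
    stop("alignment uses '.' as a gap character; only '-' is accepted",
         call. = FALSE)
  }
  widths <- nchar(x$seq)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  attr(x, "aligned") <- TRUE
  x
}

#' Remove gaps from a gapped sequence
#'
#' @param seq Gapped sequence string.
#' @return The ungapped sequence.
#' @export
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)
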