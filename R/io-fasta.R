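#' Read and write protein FASTA
#'
#' `read_fasta()` parses a protein FASTA file into a tibble with one row per
#' record.  Sequences are uppercased and trailing `*` stop characters are
#' stripped; residues are indexed 1-based throughout the package.
#'
#' @param path path to a FASTA file.
#' @param aligned logical; when `FALSE` (default) gap characters (`-` or
#'   `.`) in any sequence are an error.  Use `aligned = TRUE` to read a
#'   pre-aligned block (see [read_alignment()]).
#' @return a tibble with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (remainder of the header) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo", "mkr"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(
      "duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("\\*+$", "", seqs)
  seqs <- gsub("\\*", "", seqs)
  if (!aligned && any(grepl("[-.]", seqs))) {
    bad <- ids[grepl("[-.]", seqs)]
    stop(
      "gap characters in unaligned FASTA (use read_alignment?): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(nchar(seqs) == 0)) {
    stop(
      "zero-length sequence: ",
      paste(ids[nchar(seqs) == 0], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(id = unname(ids), desc = unname(desc), sequence = unname(seqs))
}

#' @rdname read_fasta
#' @param proteins a tibble with columns `id`, `sequence` and optionally
#'   `desc`.
#' @param width line width for sequence wrapping.
#' @return `write_fasta()` returns `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) {
    stop("duplicate ids in FASTA output", call. = FALSE)
  }
  desc <- if ("desc" %in% names(proteins)) {
    proteins$desc
  } else {
    rep("", nrow(proteins))
  }
  header <- ifelse(
    is.na(desc) | desc == "",
    paste0(">", proteins$id),
    paste0(">", proteins$id, " ", desc)
  )
  wrap <- function(s) {
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    substring(s, starts, pmin(starts + width - 1, n))
  }
  lines <- purrr::map2(header, proteins$sequence, ~ c(.x, wrap(.y)))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a pre-aligned protein FASTA block
#'
#' Alignment itself (e.g. ClustalX/MAFFT) is outside this package; trees are
#' built from an alignment the user supplies.  All sequences must have equal
#' length; gaps are `-` (dots are normalized to `-`).
#'
#' @inheritParams read_fasta
#' @return a tibble `id`, `desc`, `sequence` whose sequences all have equal
#'   length and may contain `-` gaps.
#' @export
read_alignment <- function(path) {
  block <- read_fasta(path, aligned = TRUE)
  block$sequence <- gsub("\\.", "-", block$sequence)
  validate_alignment(block)
}

validate_alignment <- function(block) {
  stopifnot(all(c("id", "sequence") %in% names(block)))
  if (nrow(block) < 2) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  len <- unique(nchar(block$sequence))
  if (length(len) != 1) {
    stop("aligned sequences have unequal lengths", call. = FALSE)
  }
  if (len < 1) stop("alignment has zero columns", call. = FALSE)
  block
}
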