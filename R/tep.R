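#' Find the thioester motif of a TEP
#'
#' Thioester-containing proteins (TEPs, including alpha-2-macroglobulins)
#' carry a diagnostic `GCGEQ` thioester motif; a `DCGEQ` variant occurs in
#' divergent members.  When both occur, the canonical `GCGEQ` is
#' preferred; among equals the leftmost match wins.
#'
#' @param sequence protein sequence string.
#' @return `NULL` when absent, else a list with `position` (1-based start
#'   of the 5-mer) and `motif`.
#' @examples
#' find_thioester_motif("AAGCGEQAA")
#' @export
find_thioester_motif <- function(sequence) {
  g <- stringr::str_locate(sequence, "GCGEQ")[1, 1]
  d <- stringr::str_locate(sequence, "DCGEQ")[1, 1]
  if (!is.na(g)) {
    list(position = as.integer(g), motif = "GCGEQ")
  } else if (!is.na(d)) {
    list(position = as.integer(d), motif = "DCGEQ")
  } else {
    NULL
  }
}

#' Locate the catalytic histidine downstream of the thioester
#'
#' In functional A2Ms a His residue sits approximately 100 residues
#' downstream of the thioester motif and modulates thioester reactivity.
#' The search window is `thioester_pos + 100 +/- window`; among candidate
#' His residues the one closest to +100 wins (ties to the smaller
#' position).
#'
#' @param sequence protein sequence string.
#' @param thioester_pos 1-based position of the thioester motif start.
#' @param window half-width of the search window (default 20).
#' @return His position (integer) or `NULL` when no His in window.
#' @export
check_catalytic_his <- function(sequence, thioester_pos, window = 20) {
  lo <- thioester_pos + 100 - window
  hi <- min(thioester_pos + 100 + window, nchar(sequence))
  if (lo > nchar(sequence)) {
    return(NULL)
  }
  chars <- strsplit(substr(sequence, lo, hi), "")[[1]]
  cand <- which(chars == "H") + lo - 1L
  if (length(cand) == 0) {
    return(NULL)
  }
  dist <- abs(cand - (thioester_pos + 100))
  as.integer(cand[order(dist, cand)][1])
}

#' Find the A2M bait-region motif
#'
#' The bait region of A2Ms — the segment cleaved by the attacking protease
#' to spring the trap — conserves an `FPETW` motif in this lineage.
#'
#' @param sequence protein sequence string.
#' @return 1-based position of the first exact `FPETW` match, or `NULL`.
#' @export
find_bait_region <- function(sequence) {
  p <- stringr::str_locate(sequence, "FPETW")[1, 1]
  if (is.na(p)) NULL else as.integer(p)
}

#' Cysteine fraction of the C-terminal tail
#'
#' Some A2Ms carry an excessive cysteine-rich C-terminal extension; this
#' measures the Cys fraction of the last `tail_len` residues (the whole
#' sequence when shorter).
#'
#' @param sequence protein sequence string.
#' @param tail_len tail length considered (default 150).
#' @param threshold fraction at or above which the tail is flagged
#'   cysteine-rich (default 0.06).
#' @return a list with `fraction` and logical `cys_rich`.
#' @export
cterm_cys_fraction <- function(sequence, tail_len = 150, threshold = 0.06) {
  n <- nchar(sequence)
  tail <- substr(sequence, max(1L, n - tail_len + 1L), n)
  frac <- stringr::str_count(tail, "C") / nchar(tail)
  list(fraction = frac, cys_rich = frac >= threshold)
}

#' Annotate TEP features on one protein
#'
#' Collects the thioester motif, catalytic His, bait-region motif,
#' C-terminal cysteine fraction and signal-peptide heuristic into one
#' annotation row, then classifies it with [classify_tep()].
#'
#' @param sequence protein sequence string.
#' @param id sequence identifier carried into the output.
#' @param his_window passed to [check_catalytic_his()].
#' @param tail_len,cys_threshold passed to [cterm_cys_fraction()].
#' @return a one-row tibble: `gene_id`, `thioester_pos`, `thioester_motif`,
#'   `canonical_thioester`, `his_pos`, `bait_pos`, `cterm_cys`,
#'   `cys_rich`, `signal_peptide`, `tep_class`.
#' @export
annotate_tep <- function(sequence, id = NA_character_, his_window = 20,
                         tail_len = 150, cys_threshold = 0.06) {
  te <- find_thioester_motif(sequence)
  his <- if (is.null(te)) {
    NULL
  } else {
    check_catalytic_his(sequence, te$position, his_window)
  }
  bait <- find_bait_region(sequence)
  tail <- cterm_cys_fraction(sequence, tail_len, cys_threshold)
  ann <- tibble::tibble(
    gene_id = id,
    thioester_pos = if (is.null(te)) NA_integer_ else te$position,
    thioester_motif = if (is.null(te)) NA_character_ else te$motif,
    canonical_thioester = !is.null(te) && te$motif == "GCGEQ",
    his_pos = if (is.null(his)) NA_integer_ else his,
    bait_pos = if (is.null(bait)) NA_integer_ else bait,
    cterm_cys = tail$fraction,
    cys_rich = tail$cys_rich,
    signal_peptide = signal_peptide_heuristic(sequence)
  )
  ann$tep_class <- classify_tep(ann)
  ann
}

#' Classify a TEP annotation as A2M / iTEP / atypical
#'
#' Motif-level rule cascade: no thioester motif at all means the protein
#' is not a TEP; canonical `GCGEQ` plus catalytic His plus bait `FPETW`
#' is an A2M; canonical motif plus His without the bait is an insect TEP
#' (iTEP); a variant motif or a missing His marks the protein atypical.
#' The cascade is a motif-level surrogate for the phylogenetic placement
#' practitioners would ultimately use; [nj_tree()] on a reference panel
#' can refine the call.
#'
#' @param ann a one-row TEP annotation tibble (see [annotate_tep()]).
#' @return one of `"A2M"`, `"iTEP"`, `"atypical"`, `"not_tep"`.
#' @export
classify_tep <- function(ann) {
  if (is.na(ann$thioester_pos)) {
    return("not_tep")
  }
  has_his <- !is.na(ann$his_pos)
  if (ann$canonical_thioester && has_his) {
    if (!is.na(ann$bait_pos)) "A2M" else "iTEP"
  } else {
    "atypical"
  }
}
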