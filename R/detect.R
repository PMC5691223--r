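#' Scan a protein for a canonical-family cysteine framework
#'
#' Canonical SPI domains are recognized by the number and arrangement of
#' their framework cysteines.  The scanner walks the cysteine positions of
#' the sequence left to right and reports every non-overlapping chain of
#' `framework_size(family)` cysteines whose successive inter-cysteine gaps
#' (number of residues strictly between two cysteines) fall inside the
#' family's spacing windows.  When a window admits several next cysteines
#' the smaller gap is preferred (leftmost-compact match); within a family,
#' hits never overlap (greedy leftmost).  Hit coordinates pad the outer
#' cysteines by `flank` residues, clipped to the sequence.
#'
#' @param sequence a protein sequence string (no gaps).
#' @param family one of `canonical_families()`.
#' @param spacing a spacing tibble as returned by [default_spacing()].
#' @param flank residues of context added on each side of the outer
#'   framework cysteines (default 3).
#' @return a tibble of hits: `family`, `start`, `end` (1-based inclusive),
#'   `cys_positions` (list column of increasing integer vectors), `score`
#'   in (0, 1], higher for more compact matches.  Zero rows when nothing
#'   matches.
#' @examples
#' # a compact synthetic Kazal framework
#' seq <- paste0(
#'   strrep("A", 10), "CAAAC", "AAAAC", "AAAAC", "AAAAC", "AAAAAAC",
#'   strrep("A", 10)
#' )
#' scan_cysteine_framework(seq, "Kazal")
#' @export
scan_cysteine_framework <- function(sequence, family,
                                    spacing = default_spacing(),
                                    flank = 3) {
  if (!family %in% canonical_families()) {
    stop(
      "scan_cysteine_framework handles canonical families only, got: ",
      family,
      call. = FALSE
    )
  }
  windows <- validate_spacing(spacing, family)
  k <- framework_size(family)
  len <- nchar(sequence)
  cys <- stringr::str_locate_all(sequence, "C")[[1]][, 1]
  if (length(cys) < k) {
    return(empty_hits())
  }
  hits <- list()
  i <- 1L
  last_end <- 0L
  while (i <= length(cys) - k + 1L) {
    chain <- chain_from(cys, i, windows)
    if (is.null(chain)) {
      i <- i + 1L
      next
    }
    pos <- cys[chain]
    gaps <- diff(pos) - 1L
    slack <- (gaps - windows$min_gap) / (windows$max_gap - windows$min_gap + 1)
    # flank padding is clipped against the previous hit so that hits of
    # the same family never overlap
    hits[[length(hits) + 1L]] <- tibble::tibble(
      family = family,
      start = max(1L, last_end + 1L, pos[1L] - as.integer(flank)),
      end = min(len, pos[k] + as.integer(flank)),
      cys_positions = list(as.integer(pos)),
      score = 1 - mean(slack)
    )
    last_end <- min(len, pos[k] + as.integer(flank))
    i <- chain[k] + 1L
  }
  if (length(hits) == 0) empty_hits() else dplyr::bind_rows(hits)
}

# Greedy leftmost-compact chain starting at cysteine index `start_idx`.
chain_from <- function(cys, start_idx, windows) {
  chain <- start_idx
  cur <- start_idx
  for (w in seq_len(nrow(windows))) {
    gaps <- cys - cys[cur] - 1L
    ok <- which(gaps >= windows$min_gap[w] & gaps <= windows$max_gap[w])
    ok <- ok[ok > cur]
    if (length(ok) == 0) {
      return(NULL)
    }
    cur <- ok[1L]
    chain <- c(chain, cur)
  }
  chain
}

empty_hits <- function() {
  tibble::tibble(
    family = character(0),
    start = integer(0),
    end = integer(0),
    cys_positions = list(),
    score = numeric(0)
  )
}

#' Detect serpin domains by their hinge consensus
#'
#' A serpin domain is reported wherever the hinge consensus motif (the
#' small-residue P17..P9 pattern required for inhibitory serpins) occurs
#' with at least 200 residues upstream — i.e. in the C-terminal third of a
#' plausible 300-500 residue serpin domain, a typical mature serpin being
#' about 300-400 amino acids.  Motif occurrences closer than
#' `min_separation` residues collapse into one hit (best-scoring
#' occurrence); twin-domain serpins yield one hit per well-separated motif.
#'
#' @inheritParams scan_cysteine_framework
#' @param min_length minimum sequence length considered (default 300).
#' @param min_upstream residues required upstream of the hinge motif
#'   (default 200, two thirds of the minimal domain length).
#' @param min_separation minimum residue separation between motifs counted
#'   as distinct domains (default 250).
#' @return a hits tibble as in [scan_cysteine_framework()], with
#'   `family = "serpin"`, empty `cys_positions`, and `score` equal to the
#'   number of hinge positions (0-9) matching the consensus classes.
#' @export
detect_serpin_domain <- function(sequence, min_length = 300,
                                 min_upstream = 200, min_separation = 250) {
  len <- nchar(sequence)
  if (len < min_length) {
    return(empty_hits())
  }
  m <- stringr::str_locate_all(sequence, hinge_regex())[[1]]
  if (nrow(m) == 0) {
    return(empty_hits())
  }
  keep <- m[, 1] > min_upstream
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(empty_hits())
  }
  score <- vapply(seq_len(nrow(m)), function(i) {
    hinge_match_count(substr(sequence, m[i, 1], m[i, 2]))
  }, numeric(1))
  # cluster occurrences closer than min_separation; keep best per cluster
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  score <- score[ord]
  cluster <- cumsum(c(1, diff(m[, 1]) >= min_separation))
  out <- purrr::map_dfr(split(seq_len(nrow(m)), cluster), function(idx) {
    best <- idx[which.max(score[idx])]
    p <- m[best, 1]
    tibble::tibble(
      family = "serpin",
      start = max(1L, as.integer(p) - 260L),
      end = min(len, as.integer(m[best, 2]) + 50L),
      cys_positions = list(integer(0)),
      score = score[best]
    )
  })
  dplyr::arrange(out, .data$start)
}

# Count of the nine hinge positions (P17..P9) of a regex match that carry a
# consensus-preferred residue.  The variable-length P16 insertion is
# collapsed so the match is read as first char + last 8 chars.
hinge_match_count <- function(match_str) {
  n <- nchar(match_str)
  ninemer <- paste0(substr(match_str, 1, 1), substr(match_str, n - 7, n))
  9 * hinge_consensus_score(ninemer)$score
}

#' Detect an alpha-2-macroglobulin-like (TEP) protein
#'
#' Thioester-containing proteins are large multidomain proteins; the
#' detector reports a single whole-protein hit when the sequence is at
#' least `min_tep_length` residues long and carries a thioester motif
#' (`GCGEQ` or the `DCGEQ` variant, see [find_thioester_motif()]).
#'
#' @inheritParams scan_cysteine_framework
#' @param min_tep_length minimum protein length (default 1000).
#' @return a hits tibble with zero or one `A2M` row spanning the protein.
#' @export
detect_a2m_like <- function(sequence, min_tep_length = 1000) {
  len <- nchar(sequence)
  if (len < min_tep_length) {
    return(empty_hits())
  }
  te <- find_thioester_motif(sequence)
  if (is.null(te)) {
    return(empty_hits())
  }
  tibble::tibble(
    family = "A2M",
    start = 1L,
    end = as.integer(len),
    cys_positions = list(integer(0)),
    score = if (te$motif == "GCGEQ") 1 else 0.5
  )
}

#' Detect SPI domains across a whole proteome
#'
#' Maps all seven family detectors over a protein tibble and returns one
#' long hits table keyed by `gene_id`.
#'
#' A cysteine run satisfying a large framework (TIL, WAP) usually contains
#' sub-chains that also satisfy a smaller six-cysteine envelope, so raw
#' per-family scans overlap across families by construction.  With
#' `resolve_overlaps = TRUE` (default) overlapping canonical hits on the
#' same protein are arbitrated: the more specific pattern wins (larger
#' framework, then higher score, then leftmost), mirroring how domain
#' databases resolve nested pattern matches.  Serpin and A2M hits are not
#' arbitrated against canonical hits.
#'
#' @param proteins a tibble with columns `id` and `sequence` (see
#'   [read_fasta()]).
#' @param families which families to scan (default all seven).
#' @param resolve_overlaps arbitrate overlapping canonical hits of
#'   different families (default TRUE).
#' @inheritParams scan_cysteine_framework
#' @inheritParams detect_a2m_like
#' @return a tibble `gene_id`, `family`, `start`, `end`, `cys_positions`,
#'   `score`, ordered by gene then start.
#' @export
detect_spi_domains <- function(proteins, families = spi_families(),
                               spacing = default_spacing(), flank = 3,
                               min_tep_length = 1000,
                               resolve_overlaps = TRUE) {
  stop_if_unknown_family(families)
  per_protein <- function(id, sequence) {
    parts <- list()
    for (fam in intersect(families, canonical_families())) {
      parts[[fam]] <- scan_cysteine_framework(sequence, fam, spacing, flank)
    }
    if ("serpin" %in% families) {
      parts[["serpin"]] <- detect_serpin_domain(sequence)
    }
    if ("A2M" %in% families) {
      parts[["A2M"]] <- detect_a2m_like(sequence, min_tep_length)
    }
    out <- dplyr::bind_rows(parts)
    if (resolve_overlaps && nrow(out) > 0) {
      out <- resolve_canonical_overlaps(out)
    }
    if (nrow(out) > 0) out$gene_id <- id
    out
  }
  hits <- purrr::map2_dfr(proteins$id, proteins$sequence, per_protein)
  if (nrow(hits) == 0) {
    return(dplyr::mutate(empty_hits(), gene_id = character(0), .before = 1))
  }
  dplyr::arrange(
    dplyr::relocate(hits, "gene_id"),
    match(.data$gene_id, proteins$id), .data$start
  )
}

# Greedy arbitration of overlapping canonical hits of different families
# on one protein: larger framework first, then higher score, then
# leftmost; a hit is kept only if it overlaps no already-kept canonical
# hit.  Non-canonical (serpin, A2M) hits pass through untouched.
resolve_canonical_overlaps <- function(hits) {
  is_can <- hits$family %in% canonical_families()
  can <- hits[is_can, , drop = FALSE]
  if (nrow(can) <= 1) {
    return(hits)
  }
  ord <- order(
    -framework_size(can$family), -can$score, can$start
  )
  can <- can[ord, , drop = FALSE]
  keep <- logical(nrow(can))
  for (i in seq_len(nrow(can))) {
    kept <- which(keep)
    clash <- any(
      can$start[i] <= can$end[kept] & can$end[i] >= can$start[kept]
    )
    keep[i] <- !clash
  }
  dplyr::bind_rows(hits[!is_can, , drop = FALSE], can[keep, , drop = FALSE])
}

#' Classify a gene from its domain hits
#'
#' Mode-of-action category precedence: any A2M hit makes the gene an A2M
#' (with a warning flag if serpin hits coexist, a combination not seen in
#' nature); otherwise any serpin hit makes it a serpin; otherwise any
#' canonical-family hit makes it canonical; a gene with no hits is
#' category `"none"`.  The result is invariant to the order of the hits.
#'
#' @param hits a hits tibble for a single protein (as returned by the
#'   detectors; a `gene_id` column is carried through if present).
#' @return a one-row tibble: `gene_id` (`NA` if absent from input),
#'   `category`, `families` (list column, sorted), `domain_counts` (list
#'   column, named integer vector of hits per family),
#'   `serpin_a2m_conflict` flag.
#' @export
classify_gene <- function(hits) {
  gene_id <- if ("gene_id" %in% names(hits) && nrow(hits) > 0) {
    ids <- unique(hits$gene_id)
    if (length(ids) > 1) {
      stop("classify_gene expects hits from a single protein", call. = FALSE)
    }
    ids
  } else {
    NA_character_
  }
  fams <- sort(unique(hits$family))
  has <- function(f) any(hits$family %in% f)
  category <- if (has("A2M")) {
    "A2M"
  } else if (has("serpin")) {
    "serpin"
  } else if (has(canonical_families())) {
    "canonical"
  } else {
    "none"
  }
  counts <- if (nrow(hits) == 0) {
    integer(0)
  } else {
    tab <- table(hits$family)
    setNames(as.integer(tab), names(tab))[fams]
  }
  conflict <- has("A2M") && has("serpin")
  if (conflict) {
    warning(
      "gene ", gene_id, " has both serpin and A2M hits; classified as A2M",
      call. = FALSE
    )
  }
  tibble::tibble(
    gene_id = gene_id,
    category = category,
    families = list(fams),
    domain_counts = list(counts),
    serpin_a2m_conflict = conflict
  )
}
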