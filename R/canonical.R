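#' Family disulfide connectivity maps
#'
#' Canonical SPI families pair their framework cysteines in a fixed,
#' family-characteristic pattern: Kazal 1-5, 2-4, 3-6; Kunitz 1-6, 2-4,
#' 3-5; Pacifastin 1-4, 2-6, 3-5 (three disulfide pairs each); WAP 1-6,
#' 2-7, 3-5, 4-8 (four pairs); TIL 1-7, 2-6, 3-5, 4-10, 8-9 (five pairs).
#' Indices refer to the framework cysteines in N- to C-terminal order.
#'
#' @param family optional single canonical family; when given, only that
#'   family's pairs are returned.
#' @return a tibble `family`, `pair` (index), `cys_a`, `cys_b`.
#' @examples
#' disulfide_map("Kazal")
#' @export
disulfide_map <- function(family = NULL) {
  maps <- list(
    Kazal       = list(c(1, 5), c(2, 4), c(3, 6)),
    Kunitz_BPTI = list(c(1, 6), c(2, 4), c(3, 5)),
    Pacifastin  = list(c(1, 4), c(2, 6), c(3, 5)),
    WAP         = list(c(1, 6), c(2, 7), c(3, 5), c(4, 8)),
    TIL         = list(c(1, 7), c(2, 6), c(3, 5), c(4, 10), c(8, 9))
  )
  out <- purrr::imap_dfr(maps, function(pairs, fam) {
    tibble::tibble(
      family = fam,
      pair = seq_along(pairs),
      cys_a = purrr::map_int(pairs, ~ as.integer(.x[1])),
      cys_b = purrr::map_int(pairs, ~ as.integer(.x[2]))
    )
  })
  if (!is.null(family)) {
    stopifnot(length(family) == 1)
    if (!family %in% out$family) {
      stop("no disulfide map for family: ", family, call. = FALSE)
    }
    out <- dplyr::filter(out, .data$family == !!family)
  }
  out
}

#' Map framework disulfide pairs onto residue positions
#'
#' Translates the family's cysteine-index connectivity into actual residue
#' positions for one detected domain: three pairs for Kazal, Kunitz and
#' Pacifastin, four for WAP, five for TIL.
#'
#' @param hit a one-row hits tibble (or list) with fields `family` and
#'   `cys_positions` (increasing residue positions of the framework
#'   cysteines).
#' @return a tibble `pair`, `cys_a_index`, `cys_b_index`, `cys_a_pos`,
#'   `cys_b_pos`.
#' @examples
#' hit <- tibble::tibble(
#'   family = "Kazal",
#'   cys_positions = list(c(10L, 20L, 30L, 40L, 50L, 60L))
#' )
#' assign_disulfide_pairs(hit)
#' @export
assign_disulfide_pairs <- function(hit) {
  family <- hit$family[[1]]
  cys <- hit$cys_positions[[1]]
  k <- framework_size(family)
  if (length(cys) != k) {
    stop(
      "incomplete framework for ", family, ": expected ", k,
      " cysteines, found ", length(cys),
      call. = FALSE
    )
  }
  if (is.unsorted(cys, strictly = TRUE)) {
    stop("cys_positions must be strictly increasing", call. = FALSE)
  }
  dm <- disulfide_map(family)
  tibble::tibble(
    pair = dm$pair,
    cys_a_index = dm$cys_a,
    cys_b_index = dm$cys_b,
    cys_a_pos = cys[dm$cys_a],
    cys_b_pos = cys[dm$cys_b]
  )
}

#' Default P1 anchor offsets for canonical domains
#'
#' The P1 residue of a canonical inhibitor's binding loop sits at a fixed
#' offset from an anchor framework cysteine.  These defaults make the
#' pipeline deterministic; the synthetic generator plants P1 residues at
#' the same offsets, and calibration against curated alignments is a user
#' task when applying the scanner to real proteomes.
#'
#' @return a tibble `family`, `anchor_cys` (framework index), `offset`
#'   (residues downstream of the anchor cysteine).
#' @export
p1_anchors <- function() {
  tibble::tribble(
    ~family, ~anchor_cys, ~offset,
    "Kazal", 2L, 2L,
    "Kunitz_BPTI", 1L, 2L,
    "Pacifastin", 4L, 1L,
    "TIL", 5L, 2L,
    "WAP", 2L, 2L
  )
}

#' Call the P1 residue of a canonical domain
#'
#' Looks up the family's anchor framework cysteine and offset
#' ([p1_anchors()]) and reads the residue at that position.  Returns an
#' "unassigned" row (NA position/residue) when the offset leaves the
#' sequence.
#'
#' @inheritParams assign_disulfide_pairs
#' @param sequence the full protein sequence the hit was found on.
#' @param anchors anchor table, defaulting to [p1_anchors()].
#' @return a one-row tibble `p1_position`, `p1_residue` (NA when
#'   unassigned) and `specificity` (list column).
#' @export
call_domain_p1 <- function(hit, sequence, anchors = p1_anchors()) {
  family <- hit$family[[1]]
  a <- dplyr::filter(anchors, .data$family == !!family)
  if (nrow(a) != 1) {
    stop("no P1 anchor for family: ", family, call. = FALSE)
  }
  cys <- hit$cys_positions[[1]]
  if (length(cys) < a$anchor_cys) {
    stop("incomplete framework: anchor cysteine missing", call. = FALSE)
  }
  pos <- cys[a$anchor_cys] + a$offset
  if (pos < 1 || pos > nchar(sequence)) {
    return(tibble::tibble(
      p1_position = NA_integer_, p1_residue = NA_character_,
      specificity = list(character(0))
    ))
  }
  res <- substr(sequence, pos, pos)
  tibble::tibble(
    p1_position = as.integer(pos),
    p1_residue = res,
    specificity = list(classify_specificity(res))
  )
}

#' Aggregate per-domain specificities for a multi-domain gene
#'
#' Multi-domain canonical SPIs carry a variety of P1 residues, so the
#' gene-level inhibitory repertoire is the union of the per-domain calls;
#' a gene with six domains presenting Ile/Phe, Ala/Val and Arg/Lys P1
#' residues is predicted to inhibit all of trypsin, chymotrypsin and
#' elastase.
#'
#' @param p1_residues character vector of P1 residues (NAs ignored).
#' @return sorted character vector, subset of
#'   `c("chymotrypsin", "elastase", "trypsin")`.
#' @examples
#' aggregate_specificities(c("I", "F", "A", "V", "R", "K"))
#' @export
aggregate_specificities <- function(p1_residues) {
  p1_residues <- p1_residues[!is.na(p1_residues)]
  if (length(p1_residues) == 0) {
    return(character(0))
  }
  sort(unique(unlist(lapply(p1_residues, classify_specificity))))
}

#' Flag mixed-type inhibitor architectures
#'
#' Some SPI genes combine inhibitor domains with non-inhibitor accessory
#' domains (Reeler, Spond_N, TSP, EGF, Laminin G, ... as seen in the
#' Kunitz family).  Accessory domains are accepted as pre-computed
#' annotations, not detected.  A gene is mixed-type iff it has at least
#' one SPI domain hit and at least one accessory domain.
#'
#' @param hits hits tibble for one gene.
#' @param accessory optional tibble of accessory domains with columns
#'   `name`, `start`, `end`.
#' @return a list: `mixed_type` (logical), `accessory` (names, possibly
#'   empty), `overlap_warning` (TRUE when an accessory span overlaps an
#'   SPI hit span).
#' @export
flag_mixed_type <- function(hits, accessory = NULL) {
  has_spi <- nrow(hits) > 0
  if (is.null(accessory) || nrow(accessory) == 0) {
    return(list(
      mixed_type = FALSE, accessory = character(0), overlap_warning = FALSE
    ))
  }
  overlap <- FALSE
  if (has_spi) {
    for (i in seq_len(nrow(accessory))) {
      if (any(accessory$start[i] <= hits$end & accessory$end[i] >= hits$start)) {
        overlap <- TRUE
      }
    }
    if (overlap) {
      warning("accessory domain overlaps an SPI domain span", call. = FALSE)
    }
  }
  list(
    mixed_type = has_spi,
    accessory = accessory$name,
    overlap_warning = overlap
  )
}

#' Annotate canonical inhibitor genes end to end
#'
#' Detects canonical-family domains on each protein, assigns disulfide
#' connectivity and per-domain P1 calls, and aggregates gene-level
#' specificity sets.
#'
#' @param proteins tibble with `id`, `sequence`.
#' @param spacing spacing table (see [default_spacing()]).
#' @param accessory optional accessory-domain tibble with columns
#'   `gene_id`, `name`, `start`, `end`.
#' @return a list of two tibbles: `domains` (one row per detected domain
#'   with P1 call and disulfide pairs as a nested list column) and `genes`
#'   (one row per gene with `specificity_set` and `mixed_type` flag).
#' @export
annotate_canonical <- function(proteins, spacing = default_spacing(),
                               accessory = NULL) {
  hits <- detect_spi_domains(
    proteins,
    families = canonical_families(), spacing = spacing
  )
  domains <- if (nrow(hits) == 0) {
    dplyr::mutate(
      hits,
      p1_position = integer(0), p1_residue = character(0),
      specificity = list(), disulfides = list()
    )
  } else {
    purrr::map_dfr(seq_len(nrow(hits)), function(i) {
      hit <- hits[i, ]
      seqfull <- proteins$sequence[proteins$id == hit$gene_id]
      p1 <- call_domain_p1(hit, seqfull)
      dplyr::bind_cols(hit, p1) %>%
        dplyr::mutate(disulfides = list(assign_disulfide_pairs(hit)))
    })
  }
  genes <- domains %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      families = list(sort(unique(.data$family))),
      n_domains = dplyr::n(),
      specificity_set = list(aggregate_specificities(.data$p1_residue)),
      .groups = "drop"
    )
  if (nrow(genes) > 0) {
    genes$mixed_type <- purrr::map_lgl(genes$gene_id, function(g) {
      acc <- if (is.null(accessory)) {
        NULL
      } else {
        dplyr::filter(accessory, .data$gene_id == g)
      }
      flag_mixed_type(
        dplyr::filter(domains, .data$gene_id == g), acc
      )$mixed_type
    })
  }
  list(domains = domains, genes = genes)
}
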