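#' P1-residue inhibitory specificity rules
#'
#' The residue at the P1 position of the scissile bond determines which
#' protease class an inhibitor targets: Arg or Lys at P1 suggests
#' inhibition of trypsin-like proteases; Phe, Tyr, Leu or Ile suggests
#' chymotrypsin-like; Ala or Val suggests elastase-like.  Any other amino
#' acid yields no call (empty set).  The same rule applies to serpin RCLs
#' and to the binding loops of canonical inhibitors.
#'
#' @param p1_residue a single one-letter amino-acid code (the 20 standard
#'   letters or `X`).
#' @return a character vector that is a subset of
#'   `c("trypsin", "chymotrypsin", "elastase")` (possibly empty).
#' @examples
#' classify_specificity("R")
#' classify_specificity("L")
#' classify_specificity("G")
#' @export
classify_specificity <- function(p1_residue) {
  stopifnot(length(p1_residue) == 1)
  if (!p1_residue %in% c(AA20, "X")) {
    stop("not an amino-acid code: ", p1_residue, call. = FALSE)
  }
  if (p1_residue %in% c("R", "K")) {
    "trypsin"
  } else if (p1_residue %in% c("F", "Y", "L", "I")) {
    "chymotrypsin"
  } else if (p1_residue %in% c("A", "V")) {
    "elastase"
  } else {
    character(0)
  }
}

#' Hinge consensus score
#'
#' Fraction of the nine hinge positions (P17..P9) carrying a residue from
#' that position's consensus preference class.  The hinge stabilizes the
#' metastable native serpin fold; inhibitory serpins conserve small
#' residues here, so a low score flags a likely non-inhibitory serpin.
#'
#' @param hinge_seq a 9-residue string (P17..P9).
#' @param inhibitory_threshold score at or above which the hinge is flagged
#'   inhibitory-competent (default 6 of 9 positions).
#' @return a list with `score` in \[0, 1\] and logical `inhibitory`.
#' @examples
#' hinge_consensus_score("EEGTEAAAA")$score # exact consensus
#' @export
hinge_consensus_score <- function(hinge_seq, inhibitory_threshold = 6 / 9) {
  if (nchar(hinge_seq) != 9) {
    stop(
      "hinge must be exactly 9 residues (P17..P9), got ", nchar(hinge_seq),
      call. = FALSE
    )
  }
  chars <- strsplit(hinge_seq, "")[[1]]
  classes <- hinge_classes()
  score <- mean(purrr::map2_lgl(chars, classes, ~ .x %in% .y))
  list(score = score, inhibitory = score >= inhibitory_threshold)
}

#' Packaged serpin reference
#'
#' A synthetic reference serpin with fixture-annotated hinge start and P1
#' position, playing the role that structurally characterized inhibitory
#' serpins (e.g. Manduca sexta serpin-1K, human alpha-1 antitrypsin) play
#' when annotating a new serpin set by alignment.  The fixture's
#' annotations define coordinate truth for this package; they make no
#' claim about any real serpin's numbering.
#'
#' @return a list with `id`, `sequence`, `hinge_start`, `p1_position`.
#' @export
serpin_reference <- function() {
  fa <- read_fasta(system.file("extdata", "synthetic_serpin_reference.fasta",
    package = "spiscan", mustWork = TRUE
  ))
  ann <- readr::read_tsv(
    system.file("extdata", "synthetic_serpin_reference.tsv",
      package = "spiscan", mustWork = TRUE
    ),
    col_types = "cii"
  )
  stopifnot(ann$id == fa$id)
  list(
    id = fa$id,
    sequence = fa$sequence,
    hinge_start = ann$hinge_start,
    p1_position = ann$p1_position
  )
}

#' Locate the hinge and reactive center loop of a serpin by alignment
#'
#' Globally aligns the query serpin to an annotated reference
#' (BLOSUM62, gap open 10 / extend 1) and maps the reference hinge-start
#' and P1 columns through the alignment into query coordinates.  The RCL is
#' taken as P17..P1' (hinge start through one residue past P1).  A
#' reference position aligned to a query gap yields `NA` ("unresolved")
#' for that coordinate.  When fewer than `min_coverage` of the reference
#' RCL positions align to a positively scoring (BLOSUM62 > 0) query
#' residue the RCL is declared unmappable — the behaviour expected for
#' degenerate serpins missing the definitive hinge residues.
#'
#' @param sequence query protein sequence (length >= 200).
#' @param reference a reference list as from [serpin_reference()].
#' @param min_coverage minimum fraction of reference RCL positions with a
#'   positive-scoring aligned query residue (default 0.5).
#' @return a one-row tibble: `hinge_start`, `hinge_end`, `rcl_start`,
#'   `rcl_end`, `p1_position` (query coordinates, `NA` when unresolved).
#' @export
locate_rcl <- function(sequence, reference = serpin_reference(),
                       min_coverage = 0.5) {
  if (nchar(sequence) < 200) {
    stop("serpin query too short (< 200 residues)", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(sequence),
    subject = Biostrings::AAString(reference$sequence),
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1, type = "global"
  )
  q_aln <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  r_aln <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # ref position -> query position (NA when ref column is a query gap)
  map <- integer(nchar(reference$sequence))
  qpos <- 0L
  rpos <- 0L
  for (i in seq_along(q_aln)) {
    if (q_aln[i] != "-") qpos <- qpos + 1L
    if (r_aln[i] != "-") {
      rpos <- rpos + 1L
      map[rpos] <- if (q_aln[i] == "-") NA_integer_ else qpos
    }
  }
  h <- reference$hinge_start
  p1 <- reference$p1_position
  rcl_ref <- h:(p1 + 1L)
  b62 <- blosum62()
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  qry_chars <- strsplit(sequence, "")[[1]]
  positive <- vapply(rcl_ref, function(r) {
    q <- map[r]
    !is.na(q) && b62[ref_chars[r], qry_chars[q]] > 0
  }, logical(1))
  if (mean(positive) < min_coverage) {
    stop("RCL unmappable: reference RCL alignment coverage below ",
      min_coverage,
      call. = FALSE
    )
  }
  tibble::tibble(
    hinge_start = map[h],
    hinge_end = map[h + 8L],
    rcl_start = map[h],
    rcl_end = map[p1 + 1L],
    p1_position = map[p1]
  )
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Annotate serpin domains end to end
#'
#' For each protein, runs [detect_serpin_domain()] (unless hits are
#' supplied), aligns each detected domain to the reference with
#' [locate_rcl()], and reports hinge/RCL coordinates (in full-protein
#' coordinates), the P1/P1' residues, the hinge consensus score and the
#' P1-based specificity call.  Multi-domain serpins get sub-domain labels
#' `<gene>-1`, `<gene>-2`, ... in N- to C-terminal order, the convention
#' used for twin-domain serpins.
#'
#' @param proteins tibble with `id`, `sequence`.
#' @param reference a reference list as from [serpin_reference()].
#' @param hits optional precomputed hits tibble (`gene_id`, `start`, `end`).
#' @return a tibble with one row per serpin domain: `gene_id`, `domain`
#'   (sub-domain label), `hinge_start`..`p1_position` as in [locate_rcl()],
#'   `p1_residue`, `p1prime_residue`, `hinge_score`, `inhibitory`,
#'   `specificity` (list column), `rcl_unmappable` flag.
#' @export
annotate_serpins <- function(proteins, reference = serpin_reference(),
                             hits = NULL) {
  if (is.null(hits)) {
    hits <- detect_spi_domains(proteins, families = "serpin")
  }
  hits <- dplyr::filter(hits, .data$family == "serpin")
  purrr::map_dfr(proteins$id, function(gid) {
    seqfull <- proteins$sequence[proteins$id == gid]
    gh <- dplyr::arrange(
      dplyr::filter(hits, .data$gene_id == gid), .data$start
    )
    if (nrow(gh) == 0) {
      return(tibble::tibble())
    }
    purrr::map_dfr(seq_len(nrow(gh)), function(i) {
      label <- if (nrow(gh) > 1) paste0(gid, "-", i) else gid
      sub_seq <- substr(seqfull, gh$start[i], gh$end[i])
      loc <- tryCatch(
        locate_rcl(sub_seq, reference),
        error = function(e) NULL
      )
      if (is.null(loc)) {
        return(tibble::tibble(
          gene_id = gid, domain = label,
          hinge_start = NA_integer_, hinge_end = NA_integer_,
          rcl_start = NA_integer_, rcl_end = NA_integer_,
          p1_position = NA_integer_, p1_residue = NA_character_,
          p1prime_residue = NA_character_, hinge_score = NA_real_,
          inhibitory = NA, specificity = list(character(0)),
          rcl_unmappable = TRUE
        ))
      }
      offset <- gh$start[i] - 1L
      loc <- dplyr::mutate(
        loc,
        dplyr::across(dplyr::everything(), ~ .x + offset)
      )
      p1 <- loc$p1_position
      p1res <- if (is.na(p1)) NA_character_ else substr(seqfull, p1, p1)
      p1p <- if (is.na(p1)) NA_character_ else substr(seqfull, p1 + 1, p1 + 1)
      hseq <- if (is.na(loc$hinge_start) || is.na(loc$hinge_end) ||
        loc$hinge_end - loc$hinge_start != 8L) {
        NA_character_
      } else {
        substr(seqfull, loc$hinge_start, loc$hinge_end)
      }
      hsc <- if (is.na(hseq)) {
        list(score = NA_real_, inhibitory = NA)
      } else {
        hinge_consensus_score(hseq)
      }
      spec <- if (is.na(p1res)) character(0) else classify_specificity(p1res)
      dplyr::mutate(loc,
        gene_id = gid, domain = label, .before = 1
      ) %>%
        dplyr::mutate(
          p1_residue = p1res, p1prime_residue = p1p,
          hinge_score = hsc$score, inhibitory = hsc$inhibitory,
          specificity = list(spec), rcl_unmappable = FALSE
        )
    })
  })
}
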