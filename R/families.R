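#' SPI family vocabulary
#'
#' The seven serine protease inhibitor (SPI) domain families handled by the
#' pipeline, and how each family maps onto a mode-of-action category.
#' Serpins inhibit by covalent trapping after cleavage of their reactive
#' center loop; canonical inhibitors (Kazal, Pacifastin, TIL, Kunitz/BPTI,
#' WAP) are small disulfide-stabilized domains binding the protease
#' reversibly in substrate-like mode; alpha-2-macroglobulins (A2M) are large
#' thioester-containing protease traps.
#'
#' @return `spi_families()` returns a character vector of the seven family
#'   tokens.  `canonical_families()` returns the five canonical-inhibitor
#'   families.  `family_category()` maps family tokens to one of
#'   `"serpin"`, `"canonical"`, `"A2M"`.
#' @examples
#' spi_families()
#' family_category(c("Kazal", "serpin", "A2M"))
#' @export
spi_families <- function() {
  c("serpin", "Kazal", "Pacifastin", "TIL", "Kunitz_BPTI", "WAP", "A2M")
}

#' @rdname spi_families
#' @export
canonical_families <- function() {
  c("Kazal", "Pacifastin", "TIL", "Kunitz_BPTI", "WAP")
}

#' @rdname spi_families
#' @param family character vector of family tokens.
#' @export
family_category <- function(family) {
  stop_if_unknown_family(family)
  dplyr::case_when(
    family == "serpin" ~ "serpin",
    family == "A2M" ~ "A2M",
    TRUE ~ "canonical"
  )
}

stop_if_unknown_family <- function(family) {
  bad <- setdiff(unique(family), spi_families())
  if (length(bad) > 0) {
    stop("unknown SPI family: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(family)
}

#' Number of framework cysteines per canonical family
#'
#' Canonical SPI domains are cysteine-rich, with a family-characteristic
#' number and arrangement of disulfide-bonded cysteines: 6 in Kazal, Kunitz
#' and Pacifastin, 8 in WAP and 10 in TIL.
#'
#' @param family character vector of canonical family tokens.
#' @return integer vector of framework sizes.
#' @examples
#' framework_size(c("Kazal", "TIL"))
#' @export
framework_size <- function(family) {
  sizes <- c(
    Kazal = 6L, Kunitz_BPTI = 6L, Pacifastin = 6L, WAP = 8L, TIL = 10L
  )
  bad <- setdiff(unique(family), names(sizes))
  if (length(bad) > 0) {
    stop(
      "no cysteine framework defined for family: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  unname(sizes[family])
}

#' Default inter-cysteine spacing windows
#'
#' PROSITE-style spacing envelopes used by [scan_cysteine_framework()]:
#' for a family with k framework cysteines, k - 1 windows give the minimum
#' and maximum number of intervening residues allowed between successive
#' framework cysteines.  These envelopes are this package's own defaults
#' (deliberately generous); they are a calibration target when applied to
#' real proteomes and can be overridden per family.
#'
#' @param family optional single family token; when supplied only that
#'   family's window tibble is returned.
#' @return a tibble with columns `family`, `window` (1-based index),
#'   `min_gap`, `max_gap`; or the single-family subset.
#' @examples
#' default_spacing("Kazal")
#' @export
default_spacing <- function(family = NULL) {
  tabs <- list(
    Kazal       = list(c(1, 12), c(4, 12), c(1, 14), c(4, 16), c(6, 30)),
    Kunitz_BPTI = list(c(6, 10), c(12, 18), c(5, 9), c(10, 16), c(2, 6)),
    Pacifastin  = list(c(7, 12), c(4, 8), c(2, 6), c(6, 10), c(3, 7)),
    WAP         = list(
      c(4, 10), c(4, 8), c(4, 8), c(4, 10), c(4, 8), c(2, 6), c(2, 6)
    ),
    TIL         = list(
      c(4, 10), c(4, 10), c(3, 8), c(3, 10), c(4, 12), c(3, 8), c(3, 10),
      c(2, 8), c(3, 10)
    )
  )
  out <- purrr::imap_dfr(tabs, function(wins, fam) {
    tibble::tibble(
      family = fam,
      window = seq_along(wins),
      min_gap = purrr::map_dbl(wins, 1),
      max_gap = purrr::map_dbl(wins, 2)
    )
  })
  if (!is.null(family)) {
    stopifnot(length(family) == 1)
    if (!family %in% out$family) {
      stop("no spacing table for family: ", family, call. = FALSE)
    }
    out <- dplyr::filter(out, .data$family == !!family)
  }
  out
}

validate_spacing <- function(spacing, family) {
  sub <- dplyr::filter(spacing, .data$family == !!family)
  k <- framework_size(family)
  if (nrow(sub) != k - 1L) {
    stop(
      "spacing table for ", family, " must have ", k - 1L, " windows, found ",
      nrow(sub),
      call. = FALSE
    )
  }
  sub <- dplyr::arrange(sub, .data$window)
  if (any(sub$min_gap < 0) || any(sub$min_gap > sub$max_gap)) {
    stop("spacing windows must satisfy 0 <= min_gap <= max_gap", call. = FALSE)
  }
  sub
}

# Residues, in preference order, accepted at each of the nine hinge
# positions (P17..P9).  The first entry of each class is the consensus
# residue used when planting synthetic hinges.
hinge_classes <- function() {
  list(
    c("E", "D"),
    c("E", "D", "K", "R", "Q"),
    "G",
    c("T", "S"),
    c("E", "K", "R", "Q"),
    c("A", "G"),
    c("A", "G", "S"),
    c("A", "G", "S", "T"),
    c("A", "G", "S", "T", "V")
  )
}

# Regex form of the hinge consensus used for de-novo serpin detection.
# P16 is allowed to be a short insertion (.{0,2}) to tolerate the small
# indels seen between serpins in this region.
hinge_regex <- function() {
  "[ED].{0,2}G[TS][EKRQ][AG][AGS][AGST][AGSTV]"
}

AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V"
)
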