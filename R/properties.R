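# Average residue masses (Da) and water, Expasy-style constants.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Side-chain and terminal pKa values (Bjellqvist set as used by the
# Expasy pI tool family).
PKA <- list(
  pos = c(K = 10.0, R = 12.0, H = 5.98),
  neg = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  nterm = 7.5, cterm = 3.55
)

# Kyte-Doolittle hydropathy.
KD_HYDRO <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5, X = 0
)

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass; `X` (unknown)
#' residues contribute the mean residue mass.
#'
#' @param sequence protein sequence string (non-empty).
#' @return molecular weight in Da.
#' @examples
#' molecular_weight("G") # glycine residue + water, about 75.07 Da
#' @export
molecular_weight <- function(sequence) {
  if (nchar(sequence) == 0) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(names(RESIDUE_MASS), "X"))
  if (length(bad) > 0) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  masses <- ifelse(chars == "X", mean(RESIDUE_MASS), RESIDUE_MASS[chars])
  sum(masses) + WATER_MASS
}

#' Theoretical isoelectric point
#'
#' Bisection on the Henderson-Hasselbalch net charge over the two termini
#' and the D, E, C, Y, H, K, R side chains with a fixed published pKa
#' set, to a tolerance of 0.01 pH units.  Matches the spirit, not the
#' last digit, of the familiar web calculators.
#'
#' @param sequence protein sequence string (non-empty).
#' @param tol bisection tolerance in pH units.
#' @return pI in \[0, 14\].
#' @export
isoelectric_point <- function(sequence, tol = 0.01) {
  if (nchar(sequence) == 0) stop("empty sequence", call. = FALSE)
  counts <- table(strsplit(sequence, "")[[1]])
  cnt <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PKA$nterm)) +
      sum(vapply(
        names(PKA$pos),
        function(a) cnt(a) / (1 + 10^(ph - PKA$pos[[a]])), numeric(1)
      ))
    neg <- 1 / (1 + 10^(PKA$cterm - ph)) +
      sum(vapply(
        names(PKA$neg),
        function(a) cnt(a) / (1 + 10^(PKA$neg[[a]] - ph)), numeric(1)
      ))
    pos - neg
  }
  lo <- 0
  hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Signal-peptide heuristic
#'
#' An explicitly heuristic secretion-signal check (not a replacement for a
#' dedicated predictor): TRUE when the first 30 residues contain a
#' hydrophobic stretch of at least 8 residues with mean Kyte-Doolittle
#' hydropathy above 1.6, preceded by at least one Lys/Arg (the n-region
#' positive charge) or starting within the first 6 positions.  Sequences
#' shorter than 15 residues return FALSE.
#'
#' @param sequence protein sequence string.
#' @param min_hydropathy mean hydropathy threshold (default 1.6).
#' @return logical scalar.
#' @export
signal_peptide_heuristic <- function(sequence, min_hydropathy = 1.6) {
  len <- nchar(sequence)
  if (len < 15) {
    return(FALSE)
  }
  head_chars <- strsplit(substr(sequence, 1, min(30, len)), "")[[1]]
  h <- unname(KD_HYDRO[head_chars])
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < 8) {
    return(FALSE)
  }
  for (s in 1:(n - 7)) {
    if (mean(h[s:(s + 7)]) > min_hydropathy) {
      before <- head_chars[seq_len(s - 1)]
      if (s <= 6 || any(before %in% c("K", "R"))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Physicochemical property table for a proteome
#'
#' @param proteins tibble with `id`, `sequence`.
#' @return a tibble `gene_id`, `length`, `mw_da`, `pi`,
#'   `has_signal_peptide`.
#' @export
protein_properties <- function(proteins) {
  tibble::tibble(
    gene_id = proteins$id,
    length = nchar(proteins$sequence),
    mw_da = purrr::map_dbl(proteins$sequence, molecular_weight),
    pi = purrr::map_dbl(proteins$sequence, isoelectric_point),
    has_signal_peptide = purrr::map_lgl(
      proteins$sequence, signal_peptide_heuristic
    )
  )
}
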