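#' Find dibasic cleavage sites
#'
#' Pacifastin precursors are processed into smaller inhibitor peptides at
#' dibasic sites.  The liable fracture motifs are `RR`, `RK` and `KK`
#' (`KR` is deliberately not a site).  Occurrences may overlap (e.g.
#' `KKK` contains two `KK` sites).
#'
#' @param sequence protein sequence string.
#' @return a tibble `pos_a`, `pos_b` (the two residues, `pos_b = pos_a +
#'   1`) and `motif`, ordered left to right.
#' @examples
#' find_dibasic_sites("AARRGAKK")
#' @export
find_dibasic_sites <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) {
    return(tibble::tibble(
      pos_a = integer(0), pos_b = integer(0), motif = character(0)
    ))
  }
  duo <- paste0(chars[-n], chars[-1])
  idx <- which(duo %in% c("RR", "RK", "KK"))
  tibble::tibble(
    pos_a = as.integer(idx),
    pos_b = as.integer(idx + 1L),
    motif = duo[idx]
  )
}

#' Split a Pacifastin precursor at usable dibasic sites
#'
#' Cleavage is modelled C-terminal of the dibasic pair, leaving the pair
#' at the end of the upstream product (site prediction, not processing
#' chemistry — lengths are conserved).  A site falling inside or within
#' one residue of a domain span is suppressed so that no inhibitor domain
#' is ever bisected; overlapping usable sites are resolved greedily left
#' to right.  Products tile the precursor without gaps or overlap; each
#' lists the complete domains it contains and is flagged `domainless`
#' when it contains none.
#'
#' @param protein a one-row tibble (or list) with `id` and `sequence`.
#' @param sites dibasic sites from [find_dibasic_sites()]; computed when
#'   `NULL`.
#' @param domain_hits hits tibble for this protein (typically Pacifastin
#'   hits from [scan_cysteine_framework()]); may have zero rows.
#' @return a tibble `gene_id`, `product`, `start`, `end`, `n_domains`,
#'   `domainless`.
#' @export
split_precursor <- function(protein, sites = NULL, domain_hits = NULL) {
  sequence <- protein$sequence[[1]]
  gene_id <- protein$id[[1]]
  len <- nchar(sequence)
  if (is.null(sites)) sites <- find_dibasic_sites(sequence)
  if (is.null(domain_hits)) domain_hits <- empty_hits()
  if (nrow(domain_hits) > 0 &&
    (any(domain_hits$start < 1) || any(domain_hits$end > len))) {
    stop("domain hit coordinates outside the precursor", call. = FALSE)
  }
  usable <- sites
  if (nrow(domain_hits) > 0 && nrow(sites) > 0) {
    inside <- vapply(seq_len(nrow(sites)), function(i) {
      any(sites$pos_a[i] >= domain_hits$start - 1L &
        sites$pos_b[i] <= domain_hits$end + 1L)
    }, logical(1))
    usable <- sites[!inside, , drop = FALSE]
  }
  # greedy leftmost resolution of overlapping usable sites
  cuts <- integer(0)
  last_cut <- 0L
  for (i in seq_len(nrow(usable))) {
    if (usable$pos_a[i] > last_cut) {
      cuts <- c(cuts, usable$pos_b[i]) # cleave C-terminal of the pair
      last_cut <- usable$pos_b[i]
    }
  }
  cuts <- cuts[cuts < len] # a cut at the terminus yields no new product
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  n_dom <- vapply(seq_along(starts), function(i) {
    if (nrow(domain_hits) == 0) {
      return(0L)
    }
    sum(domain_hits$start >= starts[i] & domain_hits$end <= ends[i])
  }, integer(1))
  tibble::tibble(
    gene_id = gene_id,
    product = seq_along(starts),
    start = starts,
    end = ends,
    n_domains = n_dom,
    domainless = n_dom == 0L
  )
}
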