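#' Read a gene-by-family SPI inventory table
#'
#' The inventory is a tab-delimited table with columns `gene_id`, `family`,
#' `domain_count` and `category`; one row per (gene, family) pair, so a gene
#' carrying two domain families (e.g. a mixed Kunitz/WAP architecture)
#' appears on two rows.  Rows are validated against the category-from-family
#' rule: serpin family implies category `serpin`, A2M implies `A2M`, and the
#' five canonical families imply `canonical`.
#'
#' @param path path to the TSV file.
#' @return a tibble with the four validated columns (`domain_count` as
#'   integer).
#' @seealso [spi_inventory()] for the packaged *Pteromalus puparum*
#'   inventory, [count_summary()] for roll-up counts.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) {
    stop("inventory file not found: ", path, call. = FALSE)
  }
  inv <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      family = readr::col_character(),
      domain_count = readr::col_integer(),
      category = readr::col_character()
    )
  )
  need <- c("gene_id", "family", "domain_count", "category")
  missing <- setdiff(need, names(inv))
  if (length(missing) > 0) {
    stop(
      "inventory lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  stop_if_unknown_family(inv$family)
  if (any(is.na(inv$domain_count)) || any(inv$domain_count < 1)) {
    stop("domain_count must be a positive integer", call. = FALSE)
  }
  expected <- family_category(inv$family)
  bad <- inv$category != expected
  if (any(bad)) {
    stop(
      "category inconsistent with family for: ",
      paste(unique(inv$gene_id[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  dup <- duplicated(inv[, c("gene_id", "family")])
  if (any(dup)) {
    stop(
      "duplicated (gene_id, family) row(s): ",
      paste(unique(inv$gene_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  inv[need]
}

#' Packaged Pteromalus puparum SPI inventory
#'
#' The 57-gene SPI inventory of the pupal parasitoid wasp *Pteromalus
#' puparum* (gene ids `PpSPI1`..`PpSPI57`), shipped with the package as a
#' plain-text fixture.  `PpSPI54` carries both Kunitz/BPTI and WAP domains
#' and therefore occupies two rows (58 rows in total).
#'
#' @return a validated inventory tibble (see [read_inventory()]).
#' @examples
#' count_summary(spi_inventory())
#' @export
spi_inventory <- function() {
  read_inventory(
    system.file("extdata", "ppspi_inventory.tsv", package = "spiscan",
      mustWork = TRUE
    )
  )
}

#' Summarize an SPI inventory
#'
#' Pure table arithmetic over an inventory: total gene count, genes per
#' mode-of-action category, genes per domain family, the number of distinct
#' domain families present, and how many of those are canonical-inhibitor
#' families.  A gene with rows in two families counts once in
#' `total_genes` and per-category counts, and once per family in the family
#' counts.
#'
#' @param inventory an inventory tibble from [read_inventory()].
#' @return a list with elements `total_genes`, `by_category` (named integer
#'   vector over serpin/canonical/A2M), `by_family` (named integer vector),
#'   `distinct_domain_types` and `canonical_family_count`.
#' @export
count_summary <- function(inventory) {
  if (nrow(inventory) == 0) {
    return(list(
      total_genes = 0L,
      by_category = c(serpin = 0L, canonical = 0L, A2M = 0L),
      by_family = integer(0),
      distinct_domain_types = 0L,
      canonical_family_count = 0L
    ))
  }
  genes <- dplyr::distinct(inventory, .data$gene_id, .data$category)
  if (anyDuplicated(genes$gene_id)) {
    stop("a gene maps to more than one category", call. = FALSE)
  }
  by_cat <- c(serpin = 0L, canonical = 0L, A2M = 0L)
  tab <- table(genes$category)
  by_cat[names(tab)] <- as.integer(tab)
  fam_tab <- dplyr::distinct(inventory, .data$gene_id, .data$family) %>%
    dplyr::count(.data$family, name = "n_genes")
  by_family <- setNames(as.integer(fam_tab$n_genes), fam_tab$family)
  fams <- unique(inventory$family)
  list(
    total_genes = nrow(genes),
    by_category = by_cat,
    by_family = by_family,
    distinct_domain_types = length(fams),
    canonical_family_count = length(intersect(fams, canonical_families()))
  )
}
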