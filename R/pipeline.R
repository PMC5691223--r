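#' Write a gene annotation table
#'
#' One row per gene, deterministically ordered by `gene_id`, with list
#' columns flattened to `;`-separated text.  The header comment line
#' records that all coordinates are 1-based inclusive, so identical
#' inputs give byte-identical files.
#'
#' @param annotations a gene-level annotation tibble (see
#'   [run_pipeline()]); list columns `families`, `specificity_set` and
#'   character columns are flattened as-is.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  flatten <- function(x) {
    if (is.list(x)) {
      vapply(x, function(v) paste(v, collapse = ";"), character(1))
    } else {
      x
    }
  }
  out <- dplyr::mutate(
    annotations,
    dplyr::across(dplyr::everything(), flatten)
  )
  out <- dplyr::arrange(out, .data$gene_id)
  txt <- paste0(
    "# spiscan gene annotations; all coordinates 1-based inclusive\n",
    readr::format_tsv(out)
  )
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' Run the whole SPI annotation pipeline on a proteome
#'
#' Detects domains of all seven families, classifies each gene, annotates
#' serpin RCL/P1 and canonical P1/disulfides, classifies TEPs, computes
#' physicochemical properties, and rolls everything into one gene-level
#' table plus a summary.  Deterministic for a given input and
#' configuration.
#'
#' @param fasta path to a protein FASTA file, or a protein tibble from
#'   [read_fasta()].
#' @param out_tsv optional path; when given the annotation table is
#'   written there with [write_annotation_tsv()].
#' @param out_json optional path for the JSON summary.
#' @param spacing spacing table for the canonical scanner.
#' @param min_tep_length TEP length gate (default 1000).
#' @param reference serpin reference (see [serpin_reference()]).
#' @return (invisibly) a list: `genes` (annotation tibble), `hits` (all
#'   domain hits), `serpins`, `teps`, `properties`, `summary`.
#' @export
run_pipeline <- function(fasta, out_tsv = NULL, out_json = NULL,
                         spacing = default_spacing(), min_tep_length = 1000,
                         reference = serpin_reference()) {
  proteins <- if (is.character(fasta)) read_fasta(fasta) else fasta
  if (nrow(proteins) == 0) stop("empty proteome", call. = FALSE)
  hits <- detect_spi_domains(
    proteins,
    spacing = spacing, min_tep_length = min_tep_length
  )
  classes <- purrr::map_dfr(proteins$id, function(g) {
    cl <- classify_gene(dplyr::filter(hits, .data$gene_id == g))
    cl$gene_id <- g
    cl
  })
  serpins <- annotate_serpins(proteins, reference,
    hits = dplyr::filter(hits, .data$family == "serpin")
  )
  if (nrow(serpins) == 0) {
    serpins <- tibble::tibble(
      gene_id = character(0), p1_residue = character(0)
    )
  }
  tep_ids <- unique(hits$gene_id[hits$family == "A2M"])
  teps <- purrr::map_dfr(tep_ids, function(g) {
    annotate_tep(proteins$sequence[proteins$id == g], id = g)
  })
  canonical_p1 <- hits %>%
    dplyr::filter(.data$family %in% canonical_families()) %>%
    (function(h) {
      if (nrow(h) == 0) {
        return(tibble::tibble(
          gene_id = character(0), p1_residue = character(0)
        ))
      }
      purrr::map_dfr(seq_len(nrow(h)), function(i) {
        p1 <- call_domain_p1(
          h[i, ], proteins$sequence[proteins$id == h$gene_id[i]]
        )
        tibble::tibble(gene_id = h$gene_id[i], p1_residue = p1$p1_residue)
      })
    })()
  props <- protein_properties(proteins)
  genes <- classes %>%
    dplyr::mutate(
      n_domains = purrr::map_int(.data$domain_counts, ~ sum(.x)),
      specificity_set = purrr::map(.data$gene_id, function(g) {
        p1s <- c(
          canonical_p1$p1_residue[canonical_p1$gene_id == g],
          serpins$p1_residue[serpins$gene_id == g]
        )
        aggregate_specificities(p1s)
      }),
      domain_spans = purrr::map_chr(.data$gene_id, function(g) {
        hh <- dplyr::filter(hits, .data$gene_id == g)
        paste(sprintf("%s:%d-%d", hh$family, hh$start, hh$end),
          collapse = ";"
        )
      })
    ) %>%
    dplyr::select(
      "gene_id", "category", "families", "n_domains", "domain_spans",
      "specificity_set", "serpin_a2m_conflict"
    ) %>%
    dplyr::left_join(props, by = "gene_id")
  summary <- list(
    n_proteins = nrow(proteins),
    n_hits = nrow(hits),
    by_category = as.list(table(genes$category)),
    by_family = as.list(table(hits$family))
  )
  if (!is.null(out_tsv)) write_annotation_tsv(genes, out_tsv)
  if (!is.null(out_json)) {
    jsonlite::write_json(summary, out_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(
    genes = genes, hits = hits, serpins = serpins, teps = teps,
    properties = props, summary = summary
  ))
}
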