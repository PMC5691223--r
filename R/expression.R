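#' Read a gene-by-sample FPKM matrix
#'
#' Tab-delimited, header row, first column `gene`, remaining columns one
#' per sample (non-negative FPKM values).
#'
#' @param path TSV path.
#' @return a tibble with `gene` plus one numeric column per sample.
#' @export
read_fpkm <- function(path) {
  mat <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ))
  validate_fpkm(mat)
}

validate_fpkm <- function(mat) {
  if (!"gene" %in% names(mat)) {
    stop("FPKM table needs a 'gene' column", call. = FALSE)
  }
  samples <- setdiff(names(mat), "gene")
  if (length(samples) == 0) stop("FPKM table has no samples", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  vals <- as.matrix(mat[samples])
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("FPKM values must be non-negative and complete", call. = FALSE)
  }
  mat
}

#' Log2 expression profile
#'
#' Elementwise `log2(FPKM + pseudocount)` over all sample columns; row and
#' column order preserved.  The pseudocount (default 1) handles the zeros
#' routine in tissue-restricted genes.
#'
#' @param mat FPKM tibble (see [read_fpkm()]).
#' @param pseudocount positive offset added before the log (default 1).
#' @return a tibble of the same shape with transformed sample columns.
#' @export
log2_profile <- function(mat, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  mat <- validate_fpkm(mat)
  samples <- setdiff(names(mat), "gene")
  dplyr::mutate(
    mat,
    dplyr::across(dplyr::all_of(samples), ~ log2(.x + pseudocount))
  )
}

#' Flag putative pseudogenes
#'
#' A gene whose FPKM never exceeds 1 in any sample is flagged as a
#' putative pseudogene; expression profiling is conventionally restricted
#' to genes with FPKM greater than 1 somewhere.
#'
#' @param mat FPKM tibble.
#' @param gene optional gene id; when omitted all genes are returned.
#' @return a logical scalar for one gene, or a tibble `gene`,
#'   `pseudogene` for all.
#' @export
flag_pseudogene <- function(mat, gene = NULL) {
  mat <- validate_fpkm(mat)
  samples <- setdiff(names(mat), "gene")
  flags <- apply(as.matrix(mat[samples]), 1, max) <= 1
  if (!is.null(gene)) {
    if (!gene %in% mat$gene) stop("gene not in matrix: ", gene, call. = FALSE)
    return(unname(flags[mat$gene == gene]))
  }
  tibble::tibble(gene = mat$gene, pseudogene = unname(flags))
}

#' Venom-gland enrichment test for one gene
#'
#' A deterministic stand-in for a count-based differential test on a
#' two-library comparison without replicates: FPKM values are scaled to
#' pseudo-counts (`round(fpkm * library_scale)`) and an exact one-sided
#' binomial test asks whether the venom-gland share of the combined
#' pseudo-counts exceeds one half.  The engine is declared and swappable;
#' the scientific content of the venom-specificity call lies in the
#' three-part threshold applied afterwards (see [call_venom_specific()]).
#'
#' @param fpkm_vg,fpkm_carcass FPKM in venom gland and carcass.
#' @param library_scale pseudo-count multiplier (default 10).
#' @return raw one-sided p-value in (0, 1]; exactly 1 when both FPKM are
#'   zero (no evidence).
#' @export
venom_specificity_test <- function(fpkm_vg, fpkm_carcass, library_scale = 10) {
  stopifnot(library_scale > 0, fpkm_vg >= 0, fpkm_carcass >= 0)
  k <- round(fpkm_vg * library_scale)
  n <- round((fpkm_vg + fpkm_carcass) * library_scale)
  if (n == 0) {
    return(1.0)
  }
  stats::binom.test(k, n, p = 0.5, alternative = "greater")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' order-preserving with respect to the input and clipped to 1.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) {
    return(numeric(0))
  }
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call venom-gland-specific genes
#'
#' For every gene in the matrix: the log2 venom-gland/carcass ratio (with
#' pseudocount 1 on both FPKM values), the raw enrichment p-value from
#' [venom_specificity_test()], BH adjustment across all genes in the
#' matrix, and the three-part threshold — adjusted p below `alpha`
#' (default 0.001), log2 ratio above `min_log2_ratio` (default 1, i.e. at
#' least twofold), and venom-gland FPKM above `min_fpkm_vg` (default 10).
#' A gene passes only when all three gates hold.
#'
#' @param mat FPKM tibble.
#' @param vg_sample,carcass_sample column names of the venom-gland and
#'   carcass samples.
#' @param alpha adjusted-p threshold (strict `<`).
#' @param min_log2_ratio log2 ratio threshold (strict `>`).
#' @param min_fpkm_vg venom-gland FPKM threshold (strict `>`).
#' @param library_scale passed to [venom_specificity_test()].
#' @return a `venom_calls` tibble: `gene`, `fpkm_vg`, `fpkm_carcass`,
#'   `log2_ratio`, `p_raw`, `p_adj`, `pass`; thresholds stored as
#'   attributes.  Supports [tidy()], [glance()] and [autoplot()].
#' @export
call_venom_specific <- function(mat, vg_sample, carcass_sample,
                                alpha = 0.001, min_log2_ratio = 1,
                                min_fpkm_vg = 10, library_scale = 10) {
  mat <- validate_fpkm(mat)
  for (s in c(vg_sample, carcass_sample)) {
    if (!s %in% names(mat)) stop("sample not in matrix: ", s, call. = FALSE)
  }
  vg <- mat[[vg_sample]]
  ca <- mat[[carcass_sample]]
  p_raw <- purrr::map2_dbl(vg, ca, venom_specificity_test,
    library_scale = library_scale
  )
  out <- tibble::tibble(
    gene = mat$gene,
    fpkm_vg = vg,
    fpkm_carcass = ca,
    log2_ratio = log2((vg + 1) / (ca + 1)),
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw)
  )
  out$pass <- out$p_adj < alpha &
    out$log2_ratio > min_log2_ratio &
    out$fpkm_vg > min_fpkm_vg
  structure(
    out,
    class = c("venom_calls", class(out)),
    thresholds = list(
      alpha = alpha, min_log2_ratio = min_log2_ratio,
      min_fpkm_vg = min_fpkm_vg, library_scale = library_scale
    ),
    vg_sample = vg_sample,
    carcass_sample = carcass_sample
  )
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical/biological replicates are averaged per (gene, sample) before
#' any differencing; then per sample `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - dCt_calibrator` and `fold = 2^-ddCt`, so the calibrator
#' sample has fold 1 by construction and a target Ct one cycle lower
#' than the calibrator (reference unchanged) gives fold 2.
#'
#' @param ct a Ct tibble with columns `gene`, `sample`, `replicate`, `ct`
#'   (reference-gene measurements are rows with `gene == ref_gene`).
#' @param target_gene,ref_gene gene ids of the target and the reference
#'   (housekeeping) gene.
#' @param calibrator_sample sample against which ddCt is computed.
#' @return a tibble `sample`, `dct`, `ddct`, `fold`.
#' @export
ddct <- function(ct, target_gene, ref_gene, calibrator_sample) {
  need <- c("gene", "sample", "replicate", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing) > 0) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  means <- ct %>%
    dplyr::filter(.data$gene %in% c(target_gene, ref_gene)) %>%
    dplyr::group_by(.data$gene, .data$sample) %>%
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  for (g in c(target_gene, ref_gene)) {
    if (!g %in% names(means) || any(is.na(means[[g]]))) {
      stop("missing Ct for gene ", g, " in some sample", call. = FALSE)
    }
  }
  if (!calibrator_sample %in% means$sample) {
    stop("calibrator sample not in Ct table: ", calibrator_sample,
      call. = FALSE
    )
  }
  dct <- means[[target_gene]] - means[[ref_gene]]
  dct_cal <- dct[means$sample == calibrator_sample]
  tibble::tibble(
    sample = means$sample,
    dct = dct,
    ddct = dct - dct_cal,
    fold = 2^(-(dct - dct_cal))
  )
}
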