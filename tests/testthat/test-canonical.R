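mk_hit <- function(family, cys) {
  tibble::tibble(
    family = family, start = min(cys) - 3L, end = max(cys) + 3L,
    cys_positions = list(as.integer(cys)), score = 1
  )
}

test_that("disulfide maps carry the printed connectivity and pair counts", {
  expected_pairs <- c(
    Kazal = 3L, Kunitz_BPTI = 3L, Pacifastin = 3L, WAP = 4L, TIL = 5L
  )
  for (fam in names(expected_pairs)) {
    dm <- disulfide_map(fam)
    expect_equal(nrow(dm), expected_pairs[[fam]])
    # the pairs partition the framework: each cysteine in exactly one pair
    expect_setequal(
      c(dm$cys_a, dm$cys_b), seq_len(framework_size(fam))
    )
  }
  # printed combinations
  expect_equal(
    purrr::map2_chr(
      disulfide_map("Kazal")$cys_a, disulfide_map("Kazal")$cys_b,
      ~ paste0(.x, "-", .y)
    ),
    c("1-5", "2-4", "3-6")
  )
  expect_equal(
    purrr::map2_chr(
      disulfide_map("Kunitz_BPTI")$cys_a, disulfide_map("Kunitz_BPTI")$cys_b,
      ~ paste0(.x, "-", .y)
    ),
    c("1-6", "2-4", "3-5")
  )
  expect_equal(
    purrr::map2_chr(
      disulfide_map("Pacifastin")$cys_a, disulfide_map("Pacifastin")$cys_b,
      ~ paste0(.x, "-", .y)
    ),
    c("1-4", "2-6", "3-5")
  )
})

test_that("assign_disulfide_pairs maps framework indices to residues", {
  pairs <- assign_disulfide_pairs(mk_hit("Kazal", c(10, 20, 30, 40, 50, 60)))
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$cys_a_pos, c(10, 20, 30))
  expect_equal(pairs$cys_b_pos, c(50, 40, 60))

  til <- assign_disulfide_pairs(mk_hit("TIL", seq(10, 100, by = 10)))
  expect_equal(nrow(til), 5)
  expect_true(any(til$cys_a_index == 4 & til$cys_b_index == 10))
  expect_true(any(til$cys_a_index == 8 & til$cys_b_index == 9))

  wap <- assign_disulfide_pairs(mk_hit("WAP", seq(5, 40, by = 5)))
  expect_equal(nrow(wap), 4)

  expect_error(
    assign_disulfide_pairs(mk_hit("Kazal", c(10, 20, 30, 40, 50))),
    "incomplete framework.*6.*5"
  )
})

test_that("P1 calls use the family anchor offset", {
  # Kazal anchor is Cys2, offset +2
  cys <- c(10L, 20L, 30L, 40L, 50L, 60L)
  seqlen <- 70
  seq <- strrep("A", seqlen)
  substr(seq, 22, 22) <- "R"
  p1 <- call_domain_p1(mk_hit("Kazal", cys), seq)
  expect_equal(p1$p1_position, 22L)
  expect_equal(p1$p1_residue, "R")
  expect_equal(p1$specificity[[1]], "trypsin")

  # offset beyond the sequence end -> unassigned
  short <- strrep("A", 21)
  p1s <- call_domain_p1(mk_hit("Kazal", cys), short)
  expect_true(is.na(p1s$p1_position))
  expect_length(p1s$specificity[[1]], 0)
})

test_that("planted P1 residues are recovered through the whole chain", {
  sim <- generate_proteome(
    seed = 17, n_decoys = 0,
    canonical_arch = list(Kazal = c(1L, 2L), TIL = 1L, WAP = 1L,
      Pacifastin = 1L, Kunitz_BPTI = 1L),
    n_serpin_single = 0, n_serpin_twin = 0, tep_classes = character(0)
  )
  ann <- annotate_canonical(sim$proteins)
  expect_equal(nrow(ann$domains), nrow(sim$truth))
  joined <- dplyr::inner_join(
    ann$domains, sim$truth,
    by = c("gene_id", "family"), suffix = c("", "_truth"),
    relationship = "many-to-many"
  ) %>%
    dplyr::filter(.data$p1_position == .data$p1_position_truth)
  expect_equal(nrow(joined), nrow(sim$truth))
  expect_equal(joined$p1_residue, joined$p1_residue_truth)
})

test_that("specificity aggregation is a union and is monotone", {
  expect_setequal(
    aggregate_specificities(c("I", "F", "A", "V", "R", "K")),
    c("trypsin", "chymotrypsin", "elastase")
  )
  expect_setequal(
    aggregate_specificities(c("F", "R")), c("chymotrypsin", "trypsin")
  )
  expect_length(aggregate_specificities(character(0)), 0)
  expect_length(aggregate_specificities(c(NA_character_)), 0)

  set.seed(12)
  for (i in 1:25) {
    base <- sample(c(AA20, NA), sample(0:6, 1), replace = TRUE)
    extra <- sample(AA20, 1)
    s0 <- aggregate_specificities(base)
    s1 <- aggregate_specificities(c(base, extra))
    expect_true(all(s0 %in% s1))
  }
})

test_that("mixed-type flagging needs both an SPI and an accessory domain", {
  kunitz <- mk_hit("Kunitz_BPTI", c(100, 107, 120, 126, 137, 140))
  acc <- tibble::tibble(
    name = c("TSP", "TSP", "TSP", "TSP", "Reeler", "Spond_N"),
    start = c(200L, 250L, 300L, 350L, 10L, 50L),
    end = c(240L, 290L, 340L, 390L, 45L, 90L)
  )
  res <- flag_mixed_type(kunitz, acc)
  expect_true(res$mixed_type)
  expect_length(res$accessory, 6)
  expect_false(res$overlap_warning)

  expect_false(flag_mixed_type(mk_hit("Kazal", c(1:5 * 6, 40)))$mixed_type)
  expect_false(flag_mixed_type(kunitz[0, ], acc)$mixed_type)

  overlapping <- tibble::tibble(name = "TSP", start = 90L, end = 130L)
  expect_warning(res2 <- flag_mixed_type(kunitz, overlapping), "overlap")
  expect_true(res2$mixed_type)
  expect_true(res2$overlap_warning)
})
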