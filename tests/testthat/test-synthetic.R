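test_that("generators are deterministic given the seed", {
  a <- generate_proteome(
    seed = 3, n_decoys = 5,
    canonical_arch = list(Kazal = c(1L, 2L)),
    n_serpin_single = 1, n_serpin_twin = 0, tep_classes = "iTEP"
  )
  b <- generate_proteome(
    seed = 3, n_decoys = 5,
    canonical_arch = list(Kazal = c(1L, 2L)),
    n_serpin_single = 1, n_serpin_twin = 0, tep_classes = "iTEP"
  )
  expect_identical(a, b)
  c_ <- generate_proteome(
    seed = 4, n_decoys = 5,
    canonical_arch = list(Kazal = c(1L, 2L)),
    n_serpin_single = 1, n_serpin_twin = 0, tep_classes = "iTEP"
  )
  expect_false(identical(a$proteins$sequence, c_$proteins$sequence))

  expect_identical(
    generate_pacifastin_precursors(seed = 9),
    generate_pacifastin_precursors(seed = 9)
  )
  expect_identical(generate_expression(seed = 9), generate_expression(seed = 9))
  expect_identical(generate_ct(seed = 9), generate_ct(seed = 9))
})

test_that("proteome truth bookkeeping matches the requested architecture", {
  sim <- generate_proteome(
    seed = 8, n_decoys = 0,
    canonical_arch = list(Kazal = c(rep(1L, 5), 11L)),
    n_serpin_single = 0, n_serpin_twin = 0, tep_classes = character(0)
  )
  kaz <- sim$truth[sim$truth$family == "Kazal", ]
  expect_equal(nrow(kaz), 16) # 5 singles + one 11-domain tandem
  expect_equal(length(unique(kaz$gene_id)), 6)
  expect_equal(max(table(kaz$gene_id)), 11)
  # truth coordinates are consistent with the recorded cysteines
  for (i in seq_len(nrow(kaz))) {
    seqfull <- sim$proteins$sequence[sim$proteins$id == kaz$gene_id[i]]
    cys <- kaz$cys_positions[[i]]
    expect_equal(
      unique(strsplit(
        paste(substring(seqfull, cys, cys), collapse = ""), ""
      )[[1]]),
      "C"
    )
    expect_equal(
      substr(seqfull, kaz$p1_position[i], kaz$p1_position[i]),
      kaz$p1_residue[i]
    )
  }
})

test_that("decoys alone yield no hits at all", {
  sim <- generate_proteome(
    seed = 21, n_decoys = 60,
    canonical_arch = list(Kazal = integer(0)),
    n_serpin_single = 0, n_serpin_twin = 0, tep_classes = character(0)
  )
  expect_equal(nrow(sim$truth), 0)
  hits <- detect_spi_domains(sim$proteins)
  expect_equal(nrow(hits), 0)
})

test_that("pacifastin generator validates motifs and tiles products", {
  expect_error(
    generate_pacifastin_precursors(seed = 1, motifs = c("KR")),
    "not a dibasic"
  )
  pac <- generate_pacifastin_precursors(seed = 2, k_domains = c(1L, 3L))
  for (g in unique(pac$truth$gene_id)) {
    tr <- pac$truth[pac$truth$gene_id == g, ]
    len <- nchar(pac$proteins$sequence[pac$proteins$id == g])
    expect_equal(sum(tr$end - tr$start + 1), len)
  }
})

test_that("expression generator plants the advertised design", {
  ex <- generate_expression(seed = 4, n_genes = 100)
  expect_equal(nrow(ex$fpkm), 100)
  expect_equal(nrow(ex$truth), 100)
  expect_equal(sum(ex$truth$role == "venom"), 8)
  expect_equal(sum(ex$truth$role == "pseudogene"), 5)
  venom <- ex$fpkm[ex$fpkm$gene %in%
    ex$truth$gene[ex$truth$role == "venom"], ]
  expect_true(all(venom$venom_gland >= 20))
  expect_true(all(
    (venom$venom_gland + 1) / (venom$carcass + 1) >= 4
  ))
  pseudo <- ex$fpkm[ex$fpkm$gene %in%
    ex$truth$gene[ex$truth$role == "pseudogene"], ]
  expect_true(all(as.matrix(pseudo[-1]) <= 1))
  expect_error(generate_expression(seed = 1, n_genes = 10), "too small")
})

test_that("noisy Ct recovery stays within the calibrated tolerance", {
  sim <- generate_ct(seed = 6, n_genes = 40, noise_sd = 0.1)
  ok <- purrr::map_lgl(unique(sim$truth$gene), function(g) {
    f <- ddct(sim$ct, g, sim$ref_gene, sim$calibrator)
    tr <- sim$truth[sim$truth$gene == g, ]
    rel <- abs(f$fold[match(tr$sample, f$sample)] - tr$fold) / tr$fold
    all(rel <= 0.25)
  })
  expect_gte(mean(ok), 0.9)
})
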