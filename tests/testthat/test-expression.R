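toy_mat <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3"),
    VG = c(0, 7, 1023),
    Carcass = c(0, 7, 1023)
  )
}

test_that("log2 profiling transforms elementwise with a pseudocount", {
  prof <- log2_profile(toy_mat(), pseudocount = 1)
  expect_equal(prof$VG, c(0, 3, 10))
  expect_equal(prof$gene, toy_mat()$gene)
  bad <- toy_mat()
  bad$VG[1] <- -1
  expect_error(log2_profile(bad), "non-negative")
  expect_error(log2_profile(toy_mat(), pseudocount = 0))
})

test_that("pseudogene flag is max FPKM <= 1 over all samples", {
  mat <- tibble::tibble(
    gene = c("dead", "alive", "edge"),
    s1 = c(0, 0, 1), s2 = c(0, 50, 1)
  )
  flags <- flag_pseudogene(mat)
  expect_equal(flags$pseudogene, c(TRUE, FALSE, TRUE))
  expect_true(flag_pseudogene(mat, "dead"))
  expect_false(flag_pseudogene(mat, "alive"))
  expect_error(flag_pseudogene(mat, "nope"), "not in matrix")
})

test_that("the binomial enrichment stand-in behaves as declared", {
  expect_gte(venom_specificity_test(5, 5), 0.5)
  expect_equal(venom_specificity_test(0, 0), 1.0)
  # independent check against the exact binomial tail
  p <- venom_specificity_test(100, 10, library_scale = 10)
  expect_equal(p, sum(stats::dbinom(1000:1100, 1100, 0.5)), tolerance = 1e-12)
  expect_error(venom_specificity_test(-1, 0))
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:100) {
    p <- stats::runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p))
    # step-up is non-decreasing on the sorted scale
    expect_true(!is.unsorted(bh_adjust(sort(p))))
  }
})

test_that("the three venom gates are each enforced", {
  mat <- tibble::tibble(
    gene = c("pass", "lowvg", "lowratio"),
    VG = c(100, 9, 15),
    Carcass = c(5, 0.1, 10)
  )
  calls <- call_venom_specific(mat, "VG", "Carcass")
  expect_equal(calls$gene[calls$pass], "pass")
  expect_false(calls$pass[calls$gene == "lowvg"]) # FPKM_VG > 10 gate
  expect_false(calls$pass[calls$gene == "lowratio"]) # log2 ratio gate
  expect_equal(
    calls$log2_ratio,
    log2((mat$VG + 1) / (mat$Carcass + 1))
  )
  expect_error(call_venom_specific(mat, "VG", "nope"), "sample")

  g <- glance(calls)
  expect_equal(g$n_pass, 1L)
  expect_s3_class(autoplot(calls), "ggplot")
})

test_that("planted venom-specific genes are called exactly", {
  ex <- generate_expression(seed = 19)
  calls <- call_venom_specific(ex$fpkm, "venom_gland", "carcass")
  expect_setequal(
    calls$gene[calls$pass],
    ex$truth$gene[ex$truth$role == "venom"]
  )
  # pseudogenes flagged by the profile filter
  flags <- flag_pseudogene(ex$fpkm)
  expect_true(all(
    flags$pseudogene[flags$gene %in%
      ex$truth$gene[ex$truth$role == "pseudogene"]]
  ))
})

test_that("2^-ddCt recovers fold changes", {
  # all Cts equal -> fold 1 everywhere
  flat <- tidyr::expand_grid(
    gene = c("t", "ref"), sample = c("s1", "s2"), replicate = 1:3
  )
  flat$ct <- 20
  f <- ddct(flat, "t", "ref", "s1")
  expect_equal(f$fold, c(1, 1))

  # target one cycle lower in treatment -> fold 2
  ct <- flat
  ct$ct[ct$gene == "t" & ct$sample == "s2"] <- 19
  expect_equal(ddct(ct, "t", "ref", "s1")$fold[2], 2)

  # ddCt of +2 -> fold 0.25
  ct2 <- flat
  ct2$ct[ct2$gene == "t" & ct2$sample == "s2"] <- 22
  expect_equal(ddct(ct2, "t", "ref", "s1")$fold[2], 0.25)

  # shifting every Ct by a constant leaves folds unchanged
  shifted <- ct2
  shifted$ct <- shifted$ct + 3.7
  expect_equal(ddct(shifted, "t", "ref", "s1")$fold,
    ddct(ct2, "t", "ref", "s1")$fold)

  expect_error(ddct(flat[flat$gene == "t", ], "t", "ref", "s1"), "ref")
})

test_that("noiseless Ct tables give exact fold recovery", {
  sim <- generate_ct(seed = 23, noise_sd = 0)
  for (g in unique(sim$truth$gene)) {
    f <- ddct(sim$ct, g, sim$ref_gene, sim$calibrator)
    tr <- sim$truth[sim$truth$gene == g, ]
    expect_equal(
      f$fold[match(tr$sample, f$sample)], tr$fold,
      tolerance = 1e-10
    )
  }
})
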