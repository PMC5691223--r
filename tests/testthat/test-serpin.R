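test_that("P1 specificity rules cover exactly eight residues", {
  expect_equal(classify_specificity("R"), "trypsin")
  expect_equal(classify_specificity("K"), "trypsin")
  expect_equal(classify_specificity("L"), "chymotrypsin")
  for (aa in c("F", "Y", "I")) {
    expect_equal(classify_specificity(aa), "chymotrypsin")
  }
  expect_equal(classify_specificity("A"), "elastase")
  expect_equal(classify_specificity("V"), "elastase")
  expect_error(classify_specificity("Z"), "amino-acid")

  # the three rule sets partition disjointly and nothing else is covered
  called <- character(0)
  for (aa in c(
    "G", "P", "S", "T", "C", "M", "N", "Q", "D", "E", "H", "W", "X"
  )) {
    expect_length(classify_specificity(aa), 0)
  }
  for (aa in c("R", "K", "F", "Y", "L", "I", "A", "V")) {
    spec <- classify_specificity(aa)
    expect_length(spec, 1)
    called <- c(called, aa)
  }
  expect_length(called, 8)
})

test_that("hinge consensus scoring counts matching positions", {
  expect_equal(hinge_consensus_score("EEGTEAAAA")$score, 1.0)
  expect_true(hinge_consensus_score("EEGTEAAAA")$inhibitory)
  expect_equal(hinge_consensus_score("WWWWWWWWW")$score, 0.0)
  expect_false(hinge_consensus_score("WWWWWWWWW")$inhibitory)
  # three mismatches -> 6/9
  expect_equal(hinge_consensus_score("WWGTEAAAW")$score, 6 / 9,
    tolerance = 1e-12
  )
  expect_true(hinge_consensus_score("WWGTEAAAW")$inhibitory)
  expect_error(hinge_consensus_score("EEGTE"), "9 residues")
})

test_that("locate_rcl maps reference annotations through the alignment", {
  ref <- serpin_reference()
  self <- locate_rcl(ref$sequence, ref)
  expect_equal(self$hinge_start, ref$hinge_start)
  expect_equal(self$hinge_end, ref$hinge_start + 8L)
  expect_equal(self$p1_position, ref$p1_position)
  expect_equal(self$rcl_end, ref$p1_position + 1L)

  # deleting 10 residues upstream of the hinge shifts everything by -10
  del <- paste0(
    substr(ref$sequence, 1, 99), substr(ref$sequence, 110, nchar(ref$sequence))
  )
  shifted <- locate_rcl(del, ref)
  expect_equal(shifted$p1_position, ref$p1_position - 10L)
  expect_equal(shifted$hinge_start, ref$hinge_start - 10L)

  expect_error(locate_rcl(strrep("G", 380), ref), "RCL unmappable")
  expect_error(locate_rcl(strrep("G", 100), ref), "too short")
})

test_that("planted serpin P1 positions are recovered exactly", {
  sim <- generate_proteome(
    seed = 31, n_decoys = 0, canonical_arch = list(Kazal = integer(0)),
    n_serpin_single = 3, n_serpin_twin = 1, tep_classes = character(0)
  )
  ann <- annotate_serpins(sim$proteins)
  truth <- sim$truth[sim$truth$family == "serpin", ]
  expect_equal(nrow(ann), nrow(truth))
  ann <- dplyr::arrange(ann, .data$gene_id, .data$hinge_start)
  truth <- dplyr::arrange(truth, .data$gene_id, .data$start)
  # hinge planted at truth start; P1 sixteen residues downstream
  expect_equal(ann$hinge_start, truth$start)
  expect_equal(ann$p1_position, truth$start + 16L)
  expect_equal(ann$p1_residue, truth$p1_residue)
  # reported residue always equals the sequence character at the position
  for (i in seq_len(nrow(ann))) {
    seqfull <- sim$proteins$sequence[sim$proteins$id == ann$gene_id[i]]
    expect_equal(
      substr(seqfull, ann$p1_position[i], ann$p1_position[i]),
      ann$p1_residue[i]
    )
  }
  # twin-domain serpin gets -1/-2 sub-domain labels
  twin <- ann[grepl("twin", ann$gene_id), ]
  expect_equal(nrow(twin), 2)
  expect_match(twin$domain[1], "-1$")
  expect_match(twin$domain[2], "-2$")
})
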