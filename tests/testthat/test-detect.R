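make_kazal <- function(gaps = c(3, 4, 4, 4, 6)) {
  paste0(
    "C", paste(vapply(gaps, function(g) {
      paste0(strrep("A", g), "C")
    }, character(1)), collapse = "")
  )
}

test_that("the framework scanner finds planted domains and nothing else", {
  dom <- make_kazal()
  seq <- paste0(strrep("L", 49), dom, strrep("L", 40))
  hits <- scan_cysteine_framework(seq, "Kazal")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 50 - 3)
  expect_equal(hits$end, 49 + nchar(dom) + 3)
  expect_equal(hits$cys_positions[[1]][1], 50L)
  expect_length(hits$cys_positions[[1]], 6)

  expect_equal(nrow(scan_cysteine_framework(strrep("A", 100), "Kazal")), 0)
  expect_error(scan_cysteine_framework(seq, "serpin"), "canonical")

  # two tandem domains separated by a linker too long to bridge
  two <- paste0(
    strrep("L", 20), dom, strrep("L", 35), make_kazal(c(5, 5, 3, 6, 8)),
    strrep("L", 20)
  )
  hits2 <- scan_cysteine_framework(two, "Kazal")
  expect_equal(nrow(hits2), 2)
  expect_true(hits2$end[1] < hits2$start[2]) # in order, non-overlapping
})

test_that("hits stay within bounds and never overlap within a family", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(80:300, 1)
    seq <- paste(
      sample(c("A", "C", "G", "S", "T"), n,
        replace = TRUE, prob = c(0.4, 0.15, 0.15, 0.15, 0.15)
      ),
      collapse = ""
    )
    for (fam in canonical_families()) {
      h <- scan_cysteine_framework(seq, fam)
      if (nrow(h) == 0) next
      expect_true(all(h$start >= 1 & h$end <= nchar(seq)))
      expect_true(all(purrr::map_lgl(
        h$cys_positions, ~ !is.unsorted(.x, strictly = TRUE)
      )))
      if (nrow(h) > 1) {
        expect_true(all(h$start[-1] > h$end[-nrow(h)]))
      }
    }
  }
})

test_that("serpin detection needs an in-context hinge motif", {
  hinge <- "EEGTEAAAA"
  seq1 <- paste0(strrep("L", 320), hinge, strrep("L", 40))
  h1 <- detect_serpin_domain(seq1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$score, 9)

  # same motif too close to the N-terminus does not qualify
  expect_equal(nrow(detect_serpin_domain(
    paste0(strrep("L", 100), hinge, strrep("L", 260))
  )), 0)
  expect_equal(nrow(detect_serpin_domain(strrep("A", 400))), 0)

  # twin-domain: two motifs 380 residues apart give two hits
  twin <- paste0(
    strrep("L", 320), hinge, strrep("L", 371), hinge, strrep("L", 40)
  )
  expect_equal(nrow(detect_serpin_domain(twin)), 2)
  # closer motifs collapse into one hit
  near <- paste0(
    strrep("L", 320), hinge, strrep("L", 100), hinge, strrep("L", 40)
  )
  expect_equal(nrow(detect_serpin_domain(near)), 1)
})

test_that("A2M detection gates on length and thioester motif", {
  long_tep <- paste0(strrep("L", 600), "GCGEQ", strrep("L", 800))
  h <- detect_a2m_like(long_tep)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1L, nchar(long_tep)))

  short <- paste0(strrep("L", 100), "GCGEQ", strrep("L", 100))
  expect_equal(nrow(detect_a2m_like(short)), 0)
  expect_equal(nrow(detect_a2m_like(strrep("L", 1400))), 0)
})

test_that("gene classification follows category precedence", {
  serpin_hit <- tibble::tibble(
    family = "serpin", start = 1L, end = 300L,
    cys_positions = list(integer(0)), score = 9
  )
  kazal_hits <- purrr::map_dfr(1:11, ~ tibble::tibble(
    family = "Kazal", start = .x * 50L, end = .x * 50L + 30L,
    cys_positions = list(integer(0)), score = 1
  ))
  a2m_hit <- tibble::tibble(
    family = "A2M", start = 1L, end = 1400L,
    cys_positions = list(integer(0)), score = 1
  )
  expect_equal(classify_gene(serpin_hit)$category, "serpin")
  ck <- classify_gene(kazal_hits)
  expect_equal(ck$category, "canonical")
  expect_equal(ck$domain_counts[[1]][["Kazal"]], 11L)
  expect_equal(classify_gene(kazal_hits[0, ])$category, "none")
  expect_warning(
    both <- classify_gene(dplyr::bind_rows(serpin_hit, a2m_hit)),
    "A2M"
  )
  expect_equal(both$category, "A2M")
  expect_true(both$serpin_a2m_conflict)

  # permutation invariance
  mixed <- dplyr::bind_rows(kazal_hits, serpin_hit)
  shuffled <- mixed[sample(nrow(mixed)), ]
  expect_equal(
    classify_gene(mixed)[c("category", "families", "domain_counts")],
    classify_gene(shuffled)[c("category", "families", "domain_counts")]
  )
})

test_that("cross-family arbitration keeps the more specific framework", {
  sim <- generate_proteome(
    seed = 5, n_decoys = 0,
    canonical_arch = list(TIL = c(1L, 1L)),
    n_serpin_single = 0, n_serpin_twin = 0, tep_classes = character(0)
  )
  hits <- detect_spi_domains(sim$proteins)
  expect_setequal(unique(hits$family), "TIL")
  # without arbitration the TIL cysteine runs also satisfy smaller
  # six-cysteine envelopes
  raw <- detect_spi_domains(sim$proteins, resolve_overlaps = FALSE)
  expect_gt(nrow(raw), nrow(hits))
})
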