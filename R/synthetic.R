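# Ground-truthed synthetic data generators.
#
# Every generator is deterministic given its seed and returns both the
# data and a truth table in the same coordinate schema the detectors
# emit, so recovery metrics reduce to a join.  Domains are sampled
# strictly inside the detection spacing windows: detection tests then
# measure the pipeline, not window mis-specification.  Backgrounds of
# planted genes carry no cysteines (and no stray hinge motifs), and each
# planted domain is rejection-sampled against the other canonical
# families, so the planted truth is unambiguous; decoys are
# rejection-sampled to contain no framework-compatible cysteine run at
# all.

sample_bg <- function(n, exclude = "C", cys_freq = 0) {
  alphabet <- setdiff(AA20, exclude)
  if (cys_freq > 0 && "C" %in% exclude) {
    alphabet <- c(alphabet, "C")
    w <- c(rep((1 - cys_freq) / (length(alphabet) - 1), length(alphabet) - 1),
      cys_freq)
    return(paste(sample(alphabet, n, replace = TRUE, prob = w), collapse = ""))
  }
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

P1_CHOICES <- c("R", "K", "F", "Y", "L", "I", "A", "V")

# One canonical domain sampled inside the family windows; gap residues are
# cysteine-free, the P1 residue is planted at the family anchor offset.
sim_domain <- function(family, spacing = default_spacing(), max_tries = 200) {
  windows <- validate_spacing(spacing, family)
  anchors <- p1_anchors()
  a <- anchors[anchors$family == family, ]
  others <- setdiff(canonical_families(), family)
  for (try in seq_len(max_tries)) {
    gaps <- as.integer(round(stats::runif(
      nrow(windows), windows$min_gap, windows$max_gap
    )))
    gaps <- pmin(pmax(gaps, windows$min_gap), windows$max_gap)
    pieces <- character(0)
    cys_rel <- integer(0)
    pos <- 0L
    for (w in seq_along(gaps)) {
      pieces <- c(pieces, "C", sample_bg(gaps[w]))
      cys_rel <- c(cys_rel, pos + 1L)
      pos <- pos + 1L + gaps[w]
    }
    pieces <- c(pieces, "C")
    cys_rel <- c(cys_rel, pos + 1L)
    seq <- paste(pieces, collapse = "")
    p1_rel <- cys_rel[a$anchor_cys] + a$offset
    p1_res <- sample(P1_CHOICES, 1)
    substr(seq, p1_rel, p1_rel) <- p1_res
    # Same-size families (6-cysteine Kazal/Kunitz/Pacifastin) can rarely
    # draw gap vectors inside each other's envelopes; those draws are
    # rejected because overlap arbitration cannot break the tie.  Larger
    # frameworks legitimately contain smaller sub-chains; the scanner's
    # cross-family arbitration resolves those, so they are not rejected.
    peers <- others[framework_size(others) == framework_size(family)]
    padded <- paste0(sample_bg(5), seq, sample_bg(5))
    cross <- any(vapply(peers, function(f) {
      nrow(scan_cysteine_framework(padded, f, spacing)) > 0
    }, logical(1)))
    if (!cross) {
      return(list(
        sequence = seq, cys_rel = cys_rel, p1_rel = p1_rel, p1_res = p1_res
      ))
    }
  }
  stop("could not sample an unambiguous ", family, " domain", call. = FALSE)
}

# Hinge 9-mer drawn from the consensus preference classes (always matches
# the detection motif).
sim_hinge <- function() {
  paste(vapply(hinge_classes(), function(cl) sample(cl, 1), character(1)),
    collapse = ""
  )
}

#' Generate a synthetic proteome with planted SPI domains
#'
#' Builds a proteome of cysteine-poor decoys plus genes carrying planted
#' SPI domains: canonical-family genes with single or tandem frameworks
#' sampled inside the spacing windows (P1 residues planted at the family
#' anchor offsets), serpins with planted hinge motifs (including a
#' twin-domain serpin), and one TEP per configured class.  The truth
#' table records every planted domain with its coordinates, cysteine
#' positions and planted P1.
#'
#' @param seed integer seed (full determinism).
#' @param n_decoys number of decoy proteins (default 200).
#' @param canonical_arch named list: family -> integer vector of domains
#'   per gene.  The default plants 12 domains over 9 genes per family
#'   (seven singles, one 2-tandem, one 3-tandem), 60 canonical domains in
#'   all.
#' @param n_serpin_single,n_serpin_twin serpin gene counts (default 5 + 1).
#' @param tep_classes TEP classes to plant (default one of each).
#' @param spacing spacing table shared with the detector.
#' @param decoy_cys_freq cysteine frequency of the decoy model (<= 0.02).
#' @return a list: `proteins` (tibble `id`, `desc`, `sequence`) and
#'   `truth` (tibble `gene_id`, `category`, `family`, `domain_index`,
#'   `start`, `end`, `cys_positions`, `p1_position`, `p1_residue`,
#'   `tep_class`).
#' @export
generate_proteome <- function(seed = 1, n_decoys = 200,
                              canonical_arch = NULL,
                              n_serpin_single = 5, n_serpin_twin = 1,
                              tep_classes = c("A2M", "iTEP", "atypical"),
                              spacing = default_spacing(),
                              decoy_cys_freq = 0.02) {
  if (decoy_cys_freq > 0.02) {
    stop("decoy cysteine frequency capped at 0.02", call. = FALSE)
  }
  if (is.null(canonical_arch)) {
    canonical_arch <- setNames(
      rep(list(c(rep(1L, 7), 2L, 3L)), 5), canonical_families()
    )
  }
  set.seed(seed)
  proteins <- list()
  truth <- list()
  add_protein <- function(id, sequence, desc = "") {
    proteins[[length(proteins) + 1L]] <<- tibble::tibble(
      id = id, desc = desc, sequence = sequence
    )
  }
  add_truth <- function(...) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(...)
  }

  # canonical genes: flank + domains joined by >= 31-residue cys-free
  # linkers; rebuilt if the random background happens to contain a
  # qualifying serpin hinge motif (which would poison the gene category)
  for (family in names(canonical_arch)) {
    stop_if_unknown_family(family)
    counts <- canonical_arch[[family]]
    for (g in seq_along(counts)) {
      gid <- sprintf("SYN_%s_%02d", family, g)
      n_dom <- counts[g]
      repeat {
        seq <- sample_bg(sample(15:30, 1))
        gene_truth <- list()
        for (d in seq_len(n_dom)) {
          dom <- sim_domain(family, spacing)
          offset <- nchar(seq)
          gene_truth[[d]] <- tibble::tibble(
            gene_id = gid, category = "canonical", family = family,
            domain_index = d,
            start = offset + 1L, end = offset + nchar(dom$sequence),
            cys_positions = list(dom$cys_rel + offset),
            p1_position = dom$p1_rel + offset, p1_residue = dom$p1_res,
            tep_class = NA_character_
          )
          seq <- paste0(seq, dom$sequence)
          if (d < n_dom) seq <- paste0(seq, sample_bg(sample(31:45, 1)))
        }
        seq <- paste0(seq, sample_bg(sample(15:30, 1)))
        if (nrow(detect_serpin_domain(seq)) == 0) break
      }
      truth <- c(truth, gene_truth)
      add_protein(gid, seq, paste0("synthetic ", family, " x", n_dom))
    }
  }

  # serpins: diverged copies of the packaged reference (substitutions
  # only, no indels) with a fresh consensus hinge and a planted P1, so
  # alignment-based RCL location has genuine homology to work with
  ref <- serpin_reference()
  ref_len <- nchar(ref$sequence)
  plant_serpin <- function(gid, n_domains, divergence = 0.15) {
    h <- ref$hinge_start
    one_domain <- function() {
      chars <- strsplit(ref$sequence, "")[[1]]
      protected <- h:(h + 17L) # hinge .. P1' stay under generator control
      mut <- which(stats::runif(ref_len) < divergence)
      mut <- setdiff(mut, protected)
      chars[mut] <- sample(setdiff(AA20, "C"), length(mut), replace = TRUE)
      seq <- paste(chars, collapse = "")
      substr(seq, h, h + 8L) <- sim_hinge()
      p1 <- sample(P1_CHOICES, 1)
      substr(seq, h + 16L, h + 16L) <- p1
      list(sequence = seq, p1 = p1)
    }
    repeat {
      doms <- replicate(n_domains, one_domain(), simplify = FALSE)
      seq <- paste(vapply(doms, `[[`, character(1), "sequence"),
        collapse = ""
      )
      hinge_abs <- h + (seq_len(n_domains) - 1L) * ref_len
      m <- gregexpr(hinge_regex(), seq, perl = TRUE)[[1]]
      m <- m[m > 0]
      if (length(m) == n_domains && all(m == hinge_abs)) break
    }
    for (i in seq_len(n_domains)) {
      add_truth(
        gene_id = gid, category = "serpin", family = "serpin",
        domain_index = i, start = hinge_abs[i], end = hinge_abs[i] + 8L,
        cys_positions = list(integer(0)),
        p1_position = hinge_abs[i] + 16L,
        p1_residue = doms[[i]]$p1,
        tep_class = NA_character_
      )
    }
    add_protein(gid, seq, "synthetic serpin")
  }
  for (g in seq_len(n_serpin_single)) {
    plant_serpin(sprintf("SYN_serpin_%02d", g), 1L)
  }
  for (g in seq_len(n_serpin_twin)) {
    plant_serpin(sprintf("SYN_serpin_twin_%02d", g), 2L)
  }

  # TEPs, one per class
  for (i in seq_along(tep_classes)) {
    cls <- tep_classes[i]
    gid <- sprintf("SYN_TEP_%s", cls)
    tep <- sim_tep(cls)
    add_truth(
      gene_id = gid, category = "A2M", family = "A2M",
      domain_index = 1L, start = 1L, end = nchar(tep),
      cys_positions = list(integer(0)),
      p1_position = NA_integer_, p1_residue = NA_character_,
      tep_class = cls
    )
    add_protein(gid, tep, paste0("synthetic TEP (", cls, ")"))
  }

  # decoys: no framework-compatible cysteine run, no qualifying hinge motif
  for (g in seq_len(n_decoys)) {
    gid <- sprintf("DECOY_%03d", g)
    repeat {
      seq <- sample_bg(sample(150:500, 1),
        exclude = "C", cys_freq = decoy_cys_freq
      )
      clean <- all(vapply(canonical_families(), function(f) {
        nrow(scan_cysteine_framework(seq, f, spacing)) == 0
      }, logical(1))) && nrow(detect_serpin_domain(seq)) == 0
      if (clean) break
    }
    add_protein(gid, seq, "decoy")
  }

  list(
    proteins = dplyr::bind_rows(proteins),
    truth = dplyr::bind_rows(truth)
  )
}

# One TEP-like sequence following the class feature grammar.  Backgrounds
# exclude C, H and W so the planted motif, catalytic His and bait region
# are the only occurrences.
sim_tep <- function(class = c("A2M", "iTEP", "atypical"), length = 1400,
                    min_tep_length = 1000) {
  class <- match.arg(class)
  if (length < min_tep_length) {
    stop("TEP length below min_tep_length", call. = FALSE)
  }
  bg <- function(n) sample_bg(n, exclude = c("C", "H", "W"))
  signal <- "MKWLLLLLLLLLLASA"
  te_pos <- 600L
  motif <- if (class == "atypical") "DCGEQ" else "GCGEQ"
  his_res <- if (class == "atypical") "D" else "H"
  repeat {
    seq <- paste0(signal, bg(length - nchar(signal)))
    substr(seq, te_pos, te_pos + 4L) <- motif
    substr(seq, te_pos + 100L, te_pos + 100L) <- his_res
    if (class == "A2M") {
      substr(seq, 900L, 904L) <- "FPETW"
      tail_start <- length - 150L + 1L
      for (b in c(0L, 34L, 68L)) {
        substr(seq, tail_start + b, tail_start + b + 2L) <- "CCC"
      }
    }
    # background must not fake a serpin hinge or a canonical framework
    clean <- nrow(detect_serpin_domain(seq)) == 0 &&
      all(vapply(canonical_families(), function(f) {
        nrow(scan_cysteine_framework(seq, f)) == 0
      }, logical(1)))
    if (clean) {
      return(seq)
    }
  }
}

#' Generate Pacifastin precursors with dibasic linkers
#'
#' Each precursor is a signal-peptide-like N-terminus followed by `k`
#' Pacifastin domains joined by linkers that each contain exactly one
#' dibasic site (motif drawn from RR/RK/KK), so cleavage prediction
#' should recover exactly `k` products with one intact domain each.
#' Backgrounds exclude C, R and K outside the planted features.
#'
#' @param seed integer seed.
#' @param k_domains integer vector: domains per precursor (one precursor
#'   per entry; default `c(1, 2, 3, 5)`).
#' @param motifs dibasic motifs to sample from; must be a subset of
#'   RR/RK/KK (`KR` is not a cleavage motif and is rejected).
#' @param spacing spacing table shared with the detector.
#' @return list: `proteins` tibble and `truth` tibble (`gene_id`,
#'   `product`, `start`, `end`, `n_domains`).
#' @export
generate_pacifastin_precursors <- function(seed = 1,
                                           k_domains = c(1L, 2L, 3L, 5L),
                                           motifs = c("RR", "RK", "KK"),
                                           spacing = default_spacing()) {
  bad <- setdiff(motifs, c("RR", "RK", "KK"))
  if (length(bad) > 0) {
    stop(
      "not a dibasic cleavage motif: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  set.seed(seed)
  bg <- function(n) sample_bg(n, exclude = c("C", "R", "K"))
  proteins <- list()
  truth <- list()
  for (p in seq_along(k_domains)) {
    k <- k_domains[p]
    gid <- sprintf("SYN_PacPre_%02d", p)
    seq <- paste0("MKWLLLLLLLLLLASA", bg(10))
    dom_spans <- matrix(0L, nrow = k, ncol = 2)
    cut_pos <- integer(0)
    for (d in seq_len(k)) {
      dom <- sim_domain("Pacifastin", spacing)
      offset <- nchar(seq)
      dom_spans[d, ] <- c(offset + 1L, offset + nchar(dom$sequence))
      seq <- paste0(seq, dom$sequence)
      if (d < k) {
        site <- sample(motifs, 1)
        pre <- bg(15)
        post <- bg(18)
        cut_pos <- c(cut_pos, nchar(seq) + 15L + 2L)
        seq <- paste0(seq, pre, site, post)
      }
    }
    seq <- paste0(seq, bg(10))
    starts <- c(1L, cut_pos + 1L)
    ends <- c(cut_pos, nchar(seq))
    truth[[p]] <- tibble::tibble(
      gene_id = gid, product = seq_len(k),
      start = starts, end = ends, n_domains = 1L
    )
    proteins[[p]] <- tibble::tibble(
      id = gid, desc = paste0("synthetic Pacifastin precursor x", k),
      sequence = seq
    )
  }
  list(
    proteins = dplyr::bind_rows(proteins),
    truth = dplyr::bind_rows(truth)
  )
}

#' Generate TEP sequences by class grammar
#'
#' One sequence per requested class: A2M (GCGEQ thioester, catalytic His
#' about 100 residues downstream, FPETW bait, cysteine-rich C-terminal
#' tail), iTEP (GCGEQ + His, no bait), atypical (DCGEQ variant with Asp
#' in place of the catalytic His).
#'
#' @param seed integer seed.
#' @param classes character vector of classes to generate.
#' @param length sequence length (>= `min_tep_length`).
#' @param min_tep_length minimum length (errors below it).
#' @return list: `proteins` tibble, `truth` tibble (`gene_id`,
#'   `tep_class`).
#' @export
generate_tep_sequences <- function(seed = 1,
                                   classes = c("A2M", "iTEP", "atypical"),
                                   length = 1400, min_tep_length = 1000) {
  set.seed(seed)
  proteins <- purrr::imap_dfr(classes, function(cls, i) {
    tibble::tibble(
      id = sprintf("SYN_TEP_%02d_%s", i, cls),
      desc = paste0("synthetic TEP (", cls, ")"),
      sequence = sim_tep(cls, length, min_tep_length)
    )
  })
  truth <- tibble::tibble(gene_id = proteins$id, tep_class = classes)
  list(proteins = proteins, truth = truth)
}

#' Generate an FPKM matrix with planted venom-specific genes
#'
#' Emulates a stage/tissue expression panel (nine samples including
#' venom gland and carcass).  Planted venom-specific genes satisfy all
#' three venom gates with margin (venom-gland FPKM at least 20 and at
#' least a fourfold pseudocounted ratio); near-miss genes are planted per
#' gate; putative pseudogenes stay at or below FPKM 1 everywhere;
#' background genes share a per-gene baseline with small log-normal
#' sample noise.  Under the exact binomial enrichment stand-in, any gene
#' passing both the FPKM and ratio gates necessarily has a tiny p-value,
#' so the "p-gate" near-miss is constructed with carcass expression close
#' to venom-gland expression and therefore also fails the ratio gate
#' (recorded as such in the truth table).
#'
#' @param seed integer seed.
#' @param n_genes total genes (default 100).
#' @param n_venom planted venom-specific genes (default 8).
#' @param n_near_per_gate near-miss genes per gate (default 3).
#' @param n_pseudo putative pseudogenes (default 5).
#' @return list: `fpkm` tibble (`gene` + 9 sample columns), `truth`
#'   tibble (`gene`, `role`), where `role` is one of `venom`,
#'   `near_miss_vg`, `near_miss_ratio`, `near_miss_p`, `pseudogene`,
#'   `background`.
#' @export
generate_expression <- function(seed = 1, n_genes = 100, n_venom = 8,
                                n_near_per_gate = 3, n_pseudo = 5) {
  samples <- c(
    "embryo", "larva", "pupa_female", "pupa_male", "adult_female",
    "adult_male", "ovary", "venom_gland", "carcass"
  )
  n_special <- n_venom + 3 * n_near_per_gate + n_pseudo
  if (n_genes < n_special) {
    stop("n_genes too small for the planted design", call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  truth <- list()
  emit <- function(gene, role, values) {
    rows[[length(rows) + 1L]] <<- tibble::as_tibble_row(
      c(list(gene = gene), as.list(setNames(values, samples)))
    )
    truth[[length(truth) + 1L]] <<- tibble::tibble(gene = gene, role = role)
  }
  base_profile <- function(level) {
    pmax(level * 2^stats::rnorm(length(samples), 0, 0.15), 0)
  }
  for (i in seq_len(n_venom)) {
    vg <- stats::runif(1, 30, 300)
    ca <- max((vg + 1) / stats::runif(1, 4, 8) - 1, 0)
    v <- base_profile(ca + 0.5)
    v[samples == "venom_gland"] <- vg
    v[samples == "carcass"] <- ca
    emit(sprintf("VEN%02d", i), "venom", v)
  }
  for (i in seq_len(n_near_per_gate)) {
    vg <- stats::runif(1, 5, 9.5) # fails FPKM_VG > 10 only
    v <- base_profile(0.3)
    v[samples == "venom_gland"] <- vg
    v[samples == "carcass"] <- 0.1
    emit(sprintf("NMV%02d", i), "near_miss_vg", v)
  }
  for (i in seq_len(n_near_per_gate)) {
    vg <- stats::runif(1, 30, 60) # fails the log2 ratio gate only
    ca <- (vg + 1) / stats::runif(1, 1.2, 1.9) - 1
    v <- base_profile(ca)
    v[samples == "venom_gland"] <- vg
    v[samples == "carcass"] <- ca
    emit(sprintf("NMR%02d", i), "near_miss_ratio", v)
  }
  for (i in seq_len(n_near_per_gate)) {
    vg <- stats::runif(1, 11, 15) # carcass ~ venom: p (and ratio) fail
    ca <- vg * 2^stats::rnorm(1, 0, 0.05)
    v <- base_profile(vg)
    v[samples == "venom_gland"] <- vg
    v[samples == "carcass"] <- ca
    emit(sprintf("NMP%02d", i), "near_miss_p", v)
  }
  for (i in seq_len(n_pseudo)) {
    emit(
      sprintf("PSG%02d", i), "pseudogene",
      stats::runif(length(samples), 0, 0.8)
    )
  }
  n_bg <- n_genes - n_special
  for (i in seq_len(n_bg)) {
    emit(
      sprintf("BGD%02d", i), "background",
      base_profile(10^stats::rnorm(1, 1.5, 1))
    )
  }
  fpkm <- dplyr::bind_rows(rows)
  list(fpkm = fpkm, truth = dplyr::bind_rows(truth))
}

#' Generate qPCR Ct tables with known fold changes
#'
#' Per gene and sample, `Ct = baseline - log2(true fold) + noise`, with a
#' constant-baseline reference gene measured with the same replicate
#' noise; the calibrator sample has true fold 1 by construction (three
#' biological replicates by default).
#'
#' @param seed integer seed.
#' @param n_genes number of target genes (default 8).
#' @param samples sample names; the first is the calibrator.
#' @param n_reps replicates per (gene, sample) (default 3).
#' @param noise_sd replicate Ct noise SD (default 0.1).
#' @param ref_gene reference gene id (default "ref18S").
#' @param log2_fold_range true log2 folds are drawn uniformly from this
#'   range for non-calibrator samples (default `c(-3, 3)`).
#' @return list: `ct` tibble (`gene`, `sample`, `replicate`, `ct`),
#'   `truth` tibble (`gene`, `sample`, `fold`), `calibrator`, `ref_gene`.
#' @export
generate_ct <- function(seed = 1, n_genes = 8,
                        samples = c("gut", "fat_body", "ovary", "venom",
                          "carcass"),
                        n_reps = 3, noise_sd = 0.1, ref_gene = "ref18S",
                        log2_fold_range = c(-3, 3)) {
  stopifnot(n_reps >= 1, length(samples) >= 2)
  set.seed(seed)
  calibrator <- samples[1]
  ct_rows <- list()
  truth_rows <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("TGT%02d", g)
    baseline <- stats::runif(1, 18, 28)
    lf <- c(0, stats::runif(
      length(samples) - 1, log2_fold_range[1], log2_fold_range[2]
    ))
    truth_rows[[g]] <- tibble::tibble(
      gene = gene, sample = samples, fold = 2^lf
    )
    for (s in seq_along(samples)) {
      ct_rows[[length(ct_rows) + 1L]] <- tibble::tibble(
        gene = gene, sample = samples[s], replicate = seq_len(n_reps),
        ct = baseline - lf[s] + stats::rnorm(n_reps, 0, noise_sd)
      )
    }
  }
  for (s in samples) {
    ct_rows[[length(ct_rows) + 1L]] <- tibble::tibble(
      gene = ref_gene, sample = s, replicate = seq_len(n_reps),
      ct = 15 + stats::rnorm(n_reps, 0, noise_sd)
    )
  }
  list(
    ct = dplyr::bind_rows(ct_rows),
    truth = dplyr::bind_rows(truth_rows),
    calibrator = calibrator,
    ref_gene = ref_gene
  )
}
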