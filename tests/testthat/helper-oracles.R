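# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Brute-force Benjamini-Hochberg step-up straight from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted scale.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- pmin(1, m * ranked / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Random unrooted binary tree with branch lengths in [0.1, 1]; the
# additive matrix comes from ape's independent path-length machinery.
random_additive_case <- function(n) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# Exhaustive least-squares oracle for 4 taxa: evaluate all three unrooted
# topologies, fit the five branch lengths by ordinary least squares, and
# return the topology with the smallest residual as a split string.
ls_best_quartet <- function(dm) {
  labs <- rownames(dm)
  stopifnot(length(labs) == 4)
  d <- c(
    dm[1, 2], dm[1, 3], dm[1, 4], dm[2, 3], dm[2, 4], dm[3, 4]
  )
  # pairings: which two taxa sit together (with taxon 1 fixed on one side)
  pairings <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))
  best <- NULL
  best_rss <- Inf
  pair_index <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "")
    switch(key,
      "12" = 1, "13" = 2, "14" = 3, "23" = 4, "24" = 5, "34" = 6
    )
  }
  for (p in pairings) {
    a <- 1
    b <- p[1]
    c_ <- p[2]
    e <- p[3]
    # columns: ta, tb, tc, te, internal
    rows <- list(
      c(a, b, 0), c(a, c_, 1), c(a, e, 1), c(b, c_, 1), c(b, e, 1),
      c(c_, e, 0)
    )
    x <- matrix(0, 6, 5)
    y <- numeric(6)
    leaf_col <- c(1, 2, 3, 4)
    names(leaf_col) <- c(a, b, c_, e)
    for (r in seq_along(rows)) {
      i <- rows[[r]][1]
      j <- rows[[r]][2]
      x[r, leaf_col[as.character(i)]] <- 1
      x[r, leaf_col[as.character(j)]] <- 1
      x[r, 5] <- rows[[r]][3]
      y[r] <- d[pair_index(i, j)]
    }
    fit <- stats::lm.fit(x, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c(labs[c_], labs[e]) # the side away from the first row taxon
    }
  }
  # same canonical side convention as tree_bipartitions()
  anchor <- sort(labs)[1]
  if (anchor %in% best) best <- setdiff(labs, best)
  paste(sort(best), collapse = "|")
}

# Truth-vs-hits matching: a planted domain is recovered when a hit of the
# same family on the same gene covers its span (up to the scanner flank).
recovered <- function(hits, truth_row, flank = 3) {
  h <- hits[
    hits$gene_id == truth_row$gene_id & hits$family == truth_row$family &
      hits$start <= truth_row$start + flank &
      hits$end >= truth_row$end - flank, ,
    drop = FALSE
  ]
  nrow(h) >= 1
}

# Per-family precision/recall of detected hits against a generator truth
# table.
recovery_metrics <- function(hits, truth) {
  fams <- unique(truth$family)
  purrr::map_dfr(fams, function(fam) {
    tr <- truth[truth$family == fam, , drop = FALSE]
    hh <- hits[hits$family == fam, , drop = FALSE]
    rec <- vapply(
      seq_len(nrow(tr)), function(i) recovered(hits, tr[i, ]), logical(1)
    )
    # a hit is a true positive when it covers some planted domain of its
    # family on its gene
    tp <- vapply(seq_len(nrow(hh)), function(i) {
      any(
        tr$gene_id == hh$gene_id[i] &
          tr$start >= hh$start[i] - 3 & tr$end <= hh$end[i] + 3
      )
    }, logical(1))
    tibble::tibble(
      family = fam,
      n_planted = nrow(tr),
      n_hits = nrow(hh),
      recall = mean(rec),
      precision = if (nrow(hh) == 0) NA_real_ else mean(tp)
    )
  })
}
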