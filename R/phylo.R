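#' Pairwise p-distances from an aligned block
#'
#' Proportion of mismatching residues over compared columns for every
#' sequence pair.  Under `pairwise_deletion` (default, the convention used
#' for protein distance matrices here) a column is compared for a pair
#' when neither sequence has a gap there; under `complete_deletion` only
#' columns with no gap in any sequence are used for all pairs.
#'
#' @param block an aligned tibble (`id`, `sequence`, equal lengths; gaps
#'   `-`), e.g. from [read_alignment()].
#' @param gap_mode `"pairwise_deletion"` or `"complete_deletion"`.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance <- function(block,
                       gap_mode = c("pairwise_deletion", "complete_deletion")) {
  gap_mode <- match.arg(gap_mode)
  block <- validate_alignment(block)
  ids <- block$id
  mat <- do.call(rbind, strsplit(block$sequence, ""))
  rownames(mat) <- ids
  if (gap_mode == "complete_deletion") {
    keep <- colSums(mat == "-") == 0
    if (!any(keep)) {
      stop("no gap-free columns under complete deletion", call. = FALSE)
    }
    mat <- mat[, keep, drop = FALSE]
  }
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop(
          "no comparable columns between ", ids[i], " and ", ids[j],
          call. = FALSE
        )
      }
      d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and two-point
#' branch-length formulas; the last three lineages are resolved by the
#' three-point formulas, giving the usual unrooted tree with a basal
#' trifurcation.  Ties in Q are broken by the lowest (i, j) index pair,
#' and negative branch-length estimates are clamped to zero (the deficit
#' is recorded in attribute `"clamped"`), so the construction is fully
#' deterministic.
#'
#' @param dm symmetric distance matrix with taxon dimnames (see
#'   [p_distance()]).
#' @return an [ape::read.tree()]-style `phylo` object.
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (is.null(rownames(dm))) {
    stop("distance matrix needs taxon labels", call. = FALSE)
  }
  labels <- rownames(dm)
  clamped <- 0
  bl <- function(x) {
    if (x < 0) {
      clamped <<- clamped + abs(x)
      x <- 0
    }
    sprintf("%.12g", x)
  }
  nodes <- labels # newick fragment per active node
  d <- dm
  while (length(nodes) > 3) {
    r <- length(nodes)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    # lowest (i, j) with i < j on ties
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]
    j <- best[1, 2]
    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    new_frag <- paste0("(", nodes[i], ":", bl(bi), ",", nodes[j], ":", bl(bj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], new_frag)
  }
  # resolve the final three lineages by the three-point formulas
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0(
    "(", nodes[1], ":", bl(b1), ",", nodes[2], ":", bl(b2), ",",
    nodes[3], ":", bl(b3), ");"
  )
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One row per internal edge: the set of tip labels on the far side of the
#' edge from the anchor taxon (the alphabetically first label), encoded as
#' a sorted, `|`-joined string so splits compare across trees regardless
#' of rotation or taxon order.
#'
#' @param tree a `phylo` object.
#' @return a tibble `node` (the ape node id below the edge) and `split`.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  rows <- purrr::map_dfr(internal, function(node) {
    tips <- tips_below(tree, node)
    if (length(tips) < 2 || length(tips) > n - 2) {
      return(tibble::tibble())
    }
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    tibble::tibble(node = node, split = paste(sort(side), collapse = "|"))
  })
  rows
}

tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    tips <- c(tips, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  tree$tip.label[tips]
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the distance matrix and NJ tree per replicate, and reports for each
#' internal edge of the full-data tree the percentage of replicates whose
#' tree contains the same bipartition.  A replicate in which some pair
#' has no comparable columns is discarded (a warning reports the count).
#' Supports are attached as integer `node.label`s on the full-data tree.
#'
#' @inheritParams p_distance
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; the resampling is reproducible given the
#'   seed and invariant to taxon order.
#' @return the full-data `phylo` tree with integer percentage supports in
#'   `node.label` (empty string on the basal node) and attribute
#'   `"discarded_reps"`.
#' @export
bootstrap_support <- function(block, n_reps = 1000, seed = 1,
                              gap_mode = "pairwise_deletion") {
  stopifnot(n_reps >= 1)
  block <- validate_alignment(block)
  block <- dplyr::arrange(block, .data$id) # taxon-order invariance
  full <- nj_tree(p_distance(block, gap_mode))
  bip <- tree_bipartitions(full)
  counts <- setNames(rep(0L, nrow(bip)), bip$split)
  ncol_aln <- nchar(block$sequence[1])
  chars <- do.call(rbind, strsplit(block$sequence, ""))
  discarded <- 0L
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_block <- tibble::tibble(
      id = block$id,
      sequence = apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    )
    rep_tree <- tryCatch(
      nj_tree(p_distance(rep_block, gap_mode)),
      error = function(e) NULL
    )
    if (is.null(rep_tree)) {
      discarded <- discarded + 1L
      next
    }
    rep_splits <- tree_bipartitions(rep_tree)$split
    hit <- names(counts) %in% rep_splits
    counts[hit] <- counts[hit] + 1L
  }
  if (discarded > 0) {
    warning(discarded, " bootstrap replicate(s) discarded", call. = FALSE)
  }
  valid <- n_reps - discarded
  support <- if (valid > 0) round(100 * counts / valid) else counts * NA
  n <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[bip$node - n] <- as.character(as.integer(support))
  full$node.label <- labs
  attr(full, "discarded_reps") <- discarded
  full
}

#' Test a clade hypothesis on an unrooted tree
#'
#' TRUE iff some edge of the tree bipartitions the taxa exactly into
#' `taxa` versus the rest (singletons and the full taxon set are trivially
#' monophyletic).
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  taxa <- unique(taxa)
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad) > 0) {
    stop("taxa not in tree: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(tree$tip.label)
  if (length(taxa) %in% c(1L, n)) {
    return(TRUE)
  }
  anchor <- sort(tree$tip.label)[1]
  side <- if (anchor %in% taxa) setdiff(tree$tip.label, taxa) else taxa
  key <- paste(sort(side), collapse = "|")
  key %in% tree_bipartitions(tree)$split
}

#' Write and read newick trees
#'
#' `write_newick()` serializes a `phylo` tree with branch lengths to six
#' decimals and any integer bootstrap supports as internal-node labels;
#' labels containing newick metacharacters are single-quoted.
#' `read_newick()` parses the same dialect back.
#'
#' @param tree a `phylo` object (optionally with `node.label` supports).
#' @param path output / input file path.
#' @return `write_newick()` the path invisibly; `read_newick()` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  n <- length(tree$tip.label)
  edge_len <- function(node) {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0 || is.null(tree$edge.length)) {
      return("")
    }
    sprintf(":%.6f", tree$edge.length[e])
  }
  quote_label <- function(lab) {
    if (grepl("[ ,():;'\\[\\]]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  node_str <- function(node) {
    if (node <= n) {
      return(paste0(quote_label(tree$tip.label[node]), edge_len(node)))
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - n] else ""
    paste0(
      "(", paste(vapply(kids, node_str, character(1)), collapse = ","), ")",
      lab, edge_len(node)
    )
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  writeLines(paste0(node_str(root), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
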