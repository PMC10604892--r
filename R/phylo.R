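# Distance-based phylogenetics: p-distances on a protein alignment,
# Saitou-Nei neighbor joining with a deterministic tie-break, column
# bootstrap, and nearest-anchor clade assignment. Trees are ape `phylo`
# objects; Newick I/O goes through ape.

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    stopifnot(!is.null(rownames(alignment)))
    return(alignment)
  }
  alignment <- as_protein_tbl(alignment)
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) != 1) {
    abort("Sequences are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, strsplit(toupper(alignment$sequence), ""))
  rownames(m) <- alignment$id
  m
}

#' Pairwise p-distance matrix from a protein alignment
#'
#' `d(i, j)` is the mismatch proportion over the alignment columns passing
#' the gap-deletion rule: `complete` drops every column containing a gap
#' in any sequence; `pairwise` drops, per pair, the columns gapped in
#' either sequence; `partial` keeps columns whose non-gap coverage is at
#' least `partial_coverage` and compares each pair over the kept columns
#' where both have residues.
#'
#' @param alignment Tibble of aligned records (`id`, `sequence`), a named
#'   character vector, or a character matrix with row names.
#' @param deletion_mode `"complete"`, `"pairwise"` or `"partial"`.
#' @param partial_coverage Minimum non-gap column coverage for
#'   `"partial"` (default 0.95).
#' @param model `"p"` for raw p-distance or `"poisson"` for the
#'   Poisson-corrected distance `-ln(1 - p)`.
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
p_distance_matrix <- function(alignment,
                              deletion_mode = c("complete", "pairwise",
                                                "partial"),
                              partial_coverage = 0.95,
                              model = c("p", "poisson")) {
  deletion_mode <- match.arg(deletion_mode)
  model <- match.arg(model)
  m <- as_alignment_matrix(alignment)
  gap <- m == "-" | m == "."
  keep <- switch(deletion_mode,
    complete = !apply(gap, 2, any),
    pairwise = rep(TRUE, ncol(m)),
    partial = colMeans(!gap) >= partial_coverage
  )
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cols <- keep & !gap[i, ] & !gap[j, ]
      if (!any(cols)) {
        abort(paste0("No comparable sites between ", rownames(m)[i],
                     " and ", rownames(m)[j]))
      }
      p <- mean(m[i, cols] != m[j, cols])
      if (model == "poisson") {
        if (p >= 1) abort("Poisson correction undefined at p = 1")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing the
#' Q-criterion, with a deterministic tie-break (the lexicographically
#' lowest active-node index pair). Negative branch-length estimates are
#' clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object (ape) with branch lengths.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) abort("Neighbor joining requires at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12 || any(d < 0)) {
    abort("Distance matrix must be symmetric and non-negative")
  }
  labels <- quote_newick(rownames(d))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  active <- d
  while (nrow(active) > 3) {
    m <- nrow(active)
    r <- rowSums(active)
    q <- (m - 2) * active - outer(r, r, `+`)
    diag(q) <- Inf
    # lexicographically lowest (i, j), i < j, among Q-minima
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- clamp(active[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(active[i, j] - (active[i, j] / 2 +
                                  (r[i] - r[j]) / (2 * (m - 2))))
    new_label <- sprintf("(%s:%.12g,%s:%.12g)", labels[i], vi,
                         labels[j], vj)
    du <- (active[i, ] + active[j, ] - active[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    nxt <- rbind(cbind(active[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    labels <- c(labels[keep], new_label)
    dimnames(nxt) <- list(NULL, NULL)
    active <- nxt
  }
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  l1 <- clamp((d12 + d13 - d23) / 2)
  l2 <- clamp((d12 + d23 - d13) / 2)
  l3 <- clamp((d13 + d23 - d12) / 2)
  if (clamped) warn("Negative NJ branch length(s) clamped to 0")
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 labels[1], l1, labels[2], l2, labels[3], l3)
  ape::read.tree(text = nwk)
}

quote_newick <- function(x) {
  bad <- grepl("[,:;()\\s]", x, perl = TRUE)
  x[bad] <- paste0("'", x[bad], "'")
  x
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds the tree per replicate, and
#' attaches to each internal edge the percentage of replicates containing
#' its bipartition (stored in `node.label`).
#'
#' @inheritParams p_distance_matrix
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @param ... Passed on to [p_distance_matrix()].
#' @return A `phylo` object whose internal `node.label`s are integer
#'   supports in \[0, 100\] (the basal node has no support).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L,
                              ...) {
  stopifnot(n_replicates >= 1)
  m <- as_alignment_matrix(alignment)
  full <- nj_tree(p_distance_matrix(m, ...))
  boots <- with_seed_local(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample(ncol(m), ncol(m), replace = TRUE)
      # replicate matrices are rarely additive; clamping there is routine
      suppressWarnings(
        nj_tree(p_distance_matrix(m[, cols, drop = FALSE], ...)))
    })
  })
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates)
  support[1] <- NA  # basal (trifurcating) node: trivial bipartition
  full$node.label <- support
  full
}

#' Assign family members to clades via reference anchors
#'
#' Each non-anchor tip is labeled with the clade of its nearest anchor by
#' tree path length; exact ties between anchors of different clades leave
#' the member `unassigned` with a warning.
#'
#' @param tree A `phylo` object.
#' @param anchors Tibble (`anchor_id`, `clade`) or a named character
#'   vector `clade` named by anchor id; at least one anchor per clade must
#'   be present in the tree.
#' @return Tibble `member_id`, `clade`.
#' @export
assign_clades <- function(tree, anchors) {
  if (is.character(anchors)) {
    anchors <- tibble(anchor_id = names(anchors), clade = unname(anchors))
  }
  stopifnot(all(c("anchor_id", "clade") %in% names(anchors)))
  if (nrow(anchors) == 0) abort("No anchors supplied")
  missing <- setdiff(anchors$anchor_id, tree$tip.label)
  if (length(missing)) {
    abort(paste0("Anchors absent from tree: ",
                 paste(missing, collapse = ", ")))
  }
  pd <- ape::cophenetic.phylo(tree)
  members <- setdiff(tree$tip.label, anchors$anchor_id)
  out <- purrr::map_dfr(members, function(mid) {
    dists <- pd[mid, anchors$anchor_id]
    best <- min(dists)
    hit <- unique(anchors$clade[dists <= best + 1e-12])
    if (length(hit) > 1) {
      warn(paste0("Tie between clades for ", mid, "; left unassigned"))
      hit <- "unassigned"
    }
    tibble(member_id = mid, clade = hit)
  })
  out
}
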