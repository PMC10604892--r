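test_that("p-distances follow the deletion rules", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"],
               0.25)
  # gap column excluded under complete deletion: compared over 3 columns
  expect_equal(p_distance_matrix(c(a = "AA-A", b = "AATA"),
                                 deletion_mode = "complete")["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "CA-A", b = "AATA"),
                                 deletion_mode = "complete")["a", "b"],
               1 / 3)
  # pairwise deletion uses the pair's own comparable sites
  m <- c(a = "AA-A", b = "AATA", c = "----")
  expect_error(p_distance_matrix(m, deletion_mode = "pairwise"),
               "No comparable sites")
  expect_error(p_distance_matrix(c(a = "AAA", b = "AAAA")), "aligned")
})

test_that("partial deletion keeps columns by coverage", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AA-A", d = "AAAA")
  # column 3 has 75% coverage: dropped at 0.95, kept at 0.5
  d95 <- p_distance_matrix(aln, deletion_mode = "partial",
                           partial_coverage = 0.95)
  expect_equal(d95["a", "b"], 1 / 3)
  d50 <- p_distance_matrix(aln, deletion_mode = "partial",
                           partial_coverage = 0.5)
  expect_equal(d50["a", "b"], 1 / 4)
})

test_that("NJ recovers the generating quartet and 3-taxon closed form", {
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d, tolerance = 1e-12)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(same_topology(tr, want))

  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  pd3 <- ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(pd3, d3, tolerance = 1e-12)
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ is consistent on additive matrices (exhaustive oracle)", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    gen <- random_additive_matrix(n)
    tr <- nj_tree(gen$d)
    labels <- rownames(gen$d)
    # path lengths reproduce the additive matrix
    expect_equal(ape::cophenetic.phylo(tr)[labels, labels], gen$d,
                 tolerance = 1e-9)
    # topology equals the exhaustive least-squares oracle's choice
    best <- oracle_best_topology(gen$d)
    expect_true(same_topology(tr, best))
    expect_true(same_topology(tr, gen$tree))
  }
})

test_that("NJ output is invariant to taxon input order", {
  set.seed(32)
  gen <- random_additive_matrix(6)
  labels <- rownames(gen$d)
  perm <- sample(labels)
  t1 <- nj_tree(gen$d)
  t2 <- nj_tree(gen$d[perm, perm])
  expect_true(same_topology(t1, t2))
  expect_equal(ape::cophenetic.phylo(t2)[labels, labels],
               ape::cophenetic.phylo(t1)[labels, labels],
               tolerance = 1e-9)
})

test_that("NJ agrees with ape's reference implementation", {
  set.seed(33)
  for (i in 1:5) {
    gen <- random_additive_matrix(sample(5:8, 1))
    labels <- rownames(gen$d)
    ours <- nj_tree(gen$d)
    theirs <- ape::nj(stats::as.dist(gen$d))
    expect_true(same_topology(ours, theirs))
    expect_equal(ape::cophenetic.phylo(ours)[labels, labels],
                 ape::cophenetic.phylo(theirs)[labels, labels],
                 tolerance = 1e-8)
  }
})

# two well-separated clades: within-clade mutations differ per taxon,
# between-clade positions differ at half the alignment
two_clade_alignment <- function() {
  base1 <- strrep("A", 40)
  base2 <- paste0(strrep("A", 20), strrep("W", 20))
  mutate_at <- function(s, pos, ch) {
    substr(s, pos, pos) <- ch
    s
  }
  c(a1 = mutate_at(base1, 1, "C"), a2 = mutate_at(base1, 2, "D"),
    a3 = mutate_at(base1, 3, "E"),
    b1 = mutate_at(base2, 4, "F"), b2 = mutate_at(base2, 5, "G"),
    b3 = mutate_at(base2, 6, "H"))
}

test_that("bootstrap supports are reproducible percentages in [0, 100]", {
  aln <- two_clade_alignment()
  t1 <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  t2 <- bootstrap_support(aln, n_replicates = 100, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- as.numeric(t1$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the clade-separating edge is strongly supported
  expect_gte(max(sup), 95)

  one <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  s1 <- as.numeric(one$node.label)
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("clade assignment follows the nearest anchor by path length", {
  aln <- two_clade_alignment()
  tree <- nj_tree(p_distance_matrix(aln))
  anchors <- tibble::tibble(anchor_id = c("a1", "b1"),
                            clade = c("C1-1Q-A", "C1-2Q"))
  cl <- assign_clades(tree, anchors)
  expect_equal(cl$clade[cl$member_id %in% c("a2", "a3")],
               rep("C1-1Q-A", 2))
  expect_equal(cl$clade[cl$member_id %in% c("b2", "b3")],
               rep("C1-2Q", 2))
  expect_error(
    assign_clades(tree, tibble::tibble(anchor_id = "zz", clade = "C1-2Q")),
    "absent")
})

test_that("five-clade simulation is assigned perfectly with two anchors each", {
  set.seed(34)
  clades <- c("C1-1Q-A", "C1-1Q-B", "C1-2Q", "C1-QM-A", "C1-QM-B")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  L <- 60
  seqs <- character(0)
  truth <- character(0)
  for (ci in seq_along(clades)) {
    # clade backbone: distinct residues in a clade-specific block
    backbone <- rep("A", L)
    backbone[((ci - 1) * 12 + 1):(ci * 12)] <- sample(aa[-1], 12,
                                                      replace = TRUE)
    for (k in 1:4) {
      s <- backbone
      pos <- sample(setdiff(seq_len(L), ((ci - 1) * 12 + 1):(ci * 12)), 2)
      s[pos] <- vapply(s[pos], function(x) sample(setdiff(aa, x), 1), "")
      nm <- paste0("c", ci, "_", k)
      seqs[nm] <- paste(s, collapse = "")
      truth[nm] <- clades[ci]
    }
  }
  tree <- nj_tree(p_distance_matrix(seqs))
  anchor_ids <- paste0("c", rep(1:5, each = 2), "_", rep(1:2, 5))
  anchors <- tibble::tibble(anchor_id = anchor_ids,
                            clade = truth[anchor_ids])
  cl <- assign_clades(tree, anchors)
  expect_equal(cl$clade, unname(truth[cl$member_id]))
})
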