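mk_expr <- function() {
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"),
    s1 = c(10L, 0L), s2 = c(20L, 5L))
  samples <- tibble::tibble(sample_id = c("s1", "s2"),
                            tissue = c("root", "root"),
                            condition = c("control", "salt"))
  lens <- tibble::tibble(gene_id = c("g1", "g2"),
                         length = c(1000L, 500L))
  expression_matrix(counts, samples, lens,
                    library_sizes = c(s1 = 1e6, s2 = 2e6))
}

test_that("FPKM follows its formula and scale invariances", {
  fp <- fpkm(mk_expr())
  # 10 counts, 1 kb gene, 1e6 library -> FPKM 10
  expect_equal(fp$s1[fp$gene_id == "g1"], 10)
  expect_equal(fp$s1[fp$gene_id == "g2"], 0)
  expect_equal(fp$s2[fp$gene_id == "g2"], 5 * 1e9 / (2e6 * 500))
  # doubling counts and library size jointly leaves FPKM unchanged
  x <- mk_expr()
  x2 <- expression_matrix(
    dplyr::mutate(x$counts, s1 = s1 * 2L, s2 = s2 * 2L),
    x$samples, x$gene_lengths,
    library_sizes = x$library_sizes * 2)
  expect_equal(fpkm(x2), fp)
  # linearity in counts at fixed library size and length
  x3 <- expression_matrix(
    dplyr::mutate(x$counts, s1 = s1 * 3L, s2 = s2 * 3L),
    x$samples, x$gene_lengths, library_sizes = x$library_sizes)
  fp3 <- fpkm(x3)
  expect_equal(fp3$s1, fp$s1 * 3)
  expect_error(expression_matrix(x$counts, x$samples, x$gene_lengths,
                                 library_sizes = c(s1 = 0, s2 = 1)),
               "> 0")
})

test_that("log transform is elementwise log2(x + 1)", {
  fp <- tibble::tibble(gene_id = "g", a = 0, b = 1, c = 7)
  lg <- log_fpkm(fp)
  expect_equal(unlist(lg[, c("a", "b", "c")], use.names = FALSE),
               c(0, 1, 3))
})

test_that("tissue-specificity calls follow the expressed-threshold rule", {
  counts <- tibble::tibble(
    gene_id = c("root_gene", "silent_gene", "both_gene"),
    leaf_r1 = c(0L, 0L, 40L), leaf_r2 = c(1L, 0L, 44L),
    root_r1 = c(50L, 0L, 60L), root_r2 = c(70L, 0L, 62L))
  samples <- tibble::tibble(
    sample_id = c("leaf_r1", "leaf_r2", "root_r1", "root_r2"),
    tissue = c("leaf", "leaf", "root", "root"),
    condition = "control")
  lens <- tibble::tibble(gene_id = counts$gene_id, length = 1000L)
  ex <- expression_matrix(counts, samples, lens,
                          library_sizes = setNames(rep(1e6, 4),
                                                   samples$sample_id))
  sp <- call_specificity(fpkm(ex), samples)
  expect_equal(sp$specificity,
               c("root_only", "neither", "both"))
  expect_error(call_specificity(fpkm(ex), samples[1:2, ]), "root")
})

test_that("response calls apply the pseudo-count fold-change rule", {
  fp <- tibble::tibble(gene_id = c("up", "flat"),
                       t1 = c(30, 10), t2 = c(30, 10),
                       c1 = c(10, 10), c2 = c(10, 10))
  r <- call_response(fp, treated = c("t1", "t2"),
                     control = c("c1", "c2"), contrast = "demo")
  expect_equal(r$log2fc[r$gene_id == "up"], log2(31 / 11))
  expect_equal(r$call[r$gene_id == "up"], "up")
  expect_equal(r$log2fc[r$gene_id == "flat"], 0)
  expect_equal(r$call[r$gene_id == "flat"], "unchanged")
  # mirrored contrast negates the fold change and mirrors calls
  rr <- call_response(fp, treated = c("c1", "c2"),
                      control = c("t1", "t2"))
  expect_equal(rr$log2fc, -r$log2fc)
  expect_equal(rr$call[r$call == "up"], "down")
  expect_error(call_response(fp, character(0), c("c1")), "Empty")
})

test_that("planted expression classes are recovered at default thresholds", {
  recovered <- vapply(c(1, 2, 3), function(seed) {
    mc <- make_counts(sim_config(seed = seed))
    fp <- fpkm(mc$expr)
    s <- mc$expr$samples
    sp <- call_specificity(fp, s)
    spec_ok <- sp$specificity == mc$truth$specificity

    calls_ok <- rep(TRUE, nrow(mc$truth))
    for (tis in c("leaf", "root")) {
      tr <- s$sample_id[s$condition == "salt" & s$timepoint == 72 &
                          s$tissue == tis]
      ct <- s$sample_id[s$condition == "control" & s$tissue == tis]
      r <- call_response(fp, tr, ct)
      # salt truth applies where the gene is expressed in that tissue
      exp_here <- mc$truth$specificity %in%
        c("both", paste0(tis, "_only"))
      calls_ok <- calls_ok &
        (!exp_here | r$call == mc$truth$salt_call)
    }
    tv <- s$sample_id[!is.na(s$condition) & s$condition == "virus"]
    tm <- s$sample_id[!is.na(s$condition) & s$condition == "mock"]
    rv <- call_response(fp, tv, tm)
    exp_root <- mc$truth$specificity %in% c("both", "root_only")
    calls_ok <- calls_ok & (!exp_root | rv$call == mc$truth$virus_call)
    mean(spec_ok & calls_ok)
  }, numeric(1))
  expect_gte(mean(recovered), 0.95)
})
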