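test_that("generators are byte-deterministic for a fixed config", {
  cfg <- sim_config(seed = 7, n_members_per_group = c("1i" = 3, "2i" = 2),
                    n_background_proteins = 5)
  a <- make_proteome(cfg)
  b <- make_proteome(cfg)
  expect_identical(a, b)

  gcfg <- sim_config(seed = 11, n_genes = 5)
  expect_identical(make_genome_with_genes(gcfg),
                   make_genome_with_genes(gcfg))
  path1 <- withr::local_tempfile(fileext = ".gff3")
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(make_genome_with_genes(gcfg)$models, path1)
  write_gff3(make_genome_with_genes(gcfg)$models, path2)
  expect_identical(readLines(path1), readLines(path2))

  expect_identical(make_counts(sim_config(seed = 3)),
                   make_counts(sim_config(seed = 3)))
  # different seeds give different data
  expect_false(identical(make_proteome(sim_config(seed = 1))$proteins,
                         make_proteome(sim_config(seed = 2))$proteins))
})

test_that("proteome bookkeeping matches the configured design", {
  sim <- make_proteome(sim_config(
    seed = 7, n_members_per_group = c("1i" = 3, "2i" = 2),
    n_background_proteins = 5))
  expect_equal(nrow(sim$proteins), 10)
  truth_q <- sim$truth[sim$truth$feature == "zf_domain" &
                         sim$truth$zf_class == "Q", ]
  expect_equal(nrow(truth_q), 3 * 1 + 2 * 2)
  # an explicit too-short member length is a config error
  expect_error(
    make_proteome(sim_config(seed = 1, member_length = 30)),
    "too short")
})

test_that("generator RNG use does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_proteome(sim_config(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("evolved CDS pairs carry exactly the requested changes", {
  p0 <- evolve_cds_pair(50, 0, 0, seed = 1)
  expect_identical(p0$cds_a, p0$cds_b)

  p <- evolve_cds_pair(100, 5, 0, seed = 2)
  expect_identical(translate_cds(p$cds_a), translate_cds(p$cds_b))
  hamming <- sum(strsplit(p$cds_a, "")[[1]] != strsplit(p$cds_b, "")[[1]])
  expect_equal(hamming, 5)

  # independent codon-table recount of the planted changes
  for (seed in 1:5) {
    pp <- evolve_cds_pair(80, 6, 9, seed = seed)
    ca <- substring(pp$cds_a, seq(1, 240, 3), seq(3, 240, 3))
    cb <- substring(pp$cds_b, seq(1, 240, 3), seq(3, 240, 3))
    changed <- which(ca != cb)
    expect_equal(length(changed), 15)  # one substitution per codon
    syn <- vapply(changed, function(i) {
      oracle_translate(ca[i]) == oracle_translate(cb[i])
    }, logical(1))
    expect_equal(sum(syn), 6)
    expect_equal(sum(!syn), 9)
    expect_false(any(vapply(cb, oracle_is_stop, logical(1))))
  }
  expect_error(evolve_cds_pair(3, 2, 2, seed = 1), "more substitutions")
})

test_that("synthetic genome layout matches its truth table", {
  g <- make_genome_with_genes(sim_config(seed = 5, n_genes = 7))
  expect_gte(length(unique(g$models$chromosome)), 2)
  expect_setequal(unique(g$models$strand), c("+", "-"))
  expect_true(any(g$gene_truth$clipped))
  expect_equal(chromosome_distribution(g$models),
               dplyr::count(g$gene_truth, chromosome) |>
                 (\(d) d[qzfp:::natural_chrom_order(d$chromosome), ])())
  # exon structure variety for intron counting
  ic <- intron_counts(g$models)
  expect_setequal(ic$n_introns[match(g$gene_truth$gene_id, ic$gene_id)],
                  g$gene_truth$n_exons - 1L)
})

test_that("planted silent genes are all-zero and null fold changes stay flat", {
  mc <- make_counts(sim_config(seed = 6))
  cmat <- as.matrix(mc$expr$counts[, -1])
  silent <- mc$truth$gene_id[mc$truth$class == "silent"]
  expect_true(all(cmat[match(silent, mc$expr$counts$gene_id), ] == 0))

  flat <- make_counts(sim_config(seed = 6, expression_design =
                                   list(fold_change = 1)))
  fp <- fpkm(flat$expr)
  s <- flat$expr$samples
  tr <- s$sample_id[s$condition == "salt" & s$timepoint == 72 &
                      s$tissue == "root"]
  ct <- s$sample_id[s$condition == "control" & s$tissue == "root"]
  resp <- call_response(fp, tr, ct)
  expressed <- flat$truth$specificity %in% c("both", "root_only")
  # a null fold change stays near zero up to sampling error
  expect_lt(abs(mean(resp$log2fc[expressed])), 0.3)
  expect_lt(median(abs(resp$log2fc[expressed])), 0.5)
})
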