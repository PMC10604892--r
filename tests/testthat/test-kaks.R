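test_that("identical sequences give zero differences and rates", {
  cds <- "ATGGCTAAGGCTTGG"
  r <- nei_gojobori(cds, cds)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$S + r$N, nchar(cds))
  expect_equal(r$selection_class, "undefined")  # Ks = 0
})

test_that("purely synonymous evolution yields Nd = 0 and Ka = 0 exactly", {
  p <- evolve_cds_pair(120, 8, 0, seed = 5)
  r <- nei_gojobori(p$cds_a, p$cds_b)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
})

test_that("NG86 is symmetric and conserves sites on random codon pairs", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    a <- random_cds(n)
    p <- evolve_cds_pair(n, sample(0:2, 1), sample(0:3, 1),
                         seed = sample.int(1e6, 1))
    r_ab <- nei_gojobori(p$cds_a, p$cds_b)
    r_ba <- nei_gojobori(p$cds_b, p$cds_a)
    for (f in c("S", "N", "Sd", "Nd", "Ks", "Ka")) {
      expect_identical(r_ab[[f]], r_ba[[f]])
    }
    expect_equal(r_ab$S + r_ab$N, 3 * n, tolerance = 1e-9)
  }
})

test_that("NG86 equals the brute-force pathway oracle on small instances", {
  set.seed(22)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    a <- random_cds(n)
    # mutate heavily (up to 3 positions per codon) to exercise pathways
    b_cod <- substring(a, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
    for (k in sample(n, sample(n, 1))) {
      repeat {
        cand <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                      collapse = "")
        if (oracle_translate(cand) != "*") break
      }
      b_cod[k] <- cand
    }
    b <- paste(b_cod, collapse = "")
    got <- nei_gojobori(a, b)
    want <- oracle_nei_gojobori(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-12)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-12)
  }
})

test_that("selection classes follow the ratio thresholds", {
  expect_equal(classify_selection(ratio = 0.1419), "purifying")
  expect_equal(classify_selection(ratio = 1), "neutral")
  expect_equal(classify_selection(ratio = 1 + 1e-12), "neutral")
  expect_equal(classify_selection(ratio = 2.3), "positive")
  expect_equal(classify_selection(ratio = NA_real_, Ks = 0), "undefined")
  p <- evolve_cds_pair(200, 20, 4, seed = 9)
  expect_equal(nei_gojobori(p$cds_a, p$cds_b)$selection_class, "purifying")
})

test_that("saturated proportions flag the correction undefined", {
  # alanine codons vs glycine codons: every nonsynonymous site differs
  a <- strrep("GCA", 12)
  b <- strrep("CGT", 12)
  r <- nei_gojobori(a, b)
  expect_equal(r$selection_class, "undefined")
  expect_true(is.na(r$Ka) || is.na(r$Ks))
})

test_that("codon alignment projection threads gaps and validates", {
  # gap-free identical proteins: codon alignment is the CDS pair
  pr <- "MKV"
  ca <- "ATGAAAGTT"
  cb <- "ATGAAGGTA"
  out <- project_codon_alignment(pr, pr, ca, cb)
  expect_equal(out$cds_a, ca)
  expect_equal(out$cds_b, cb)

  # one aligned gap column: output shorter by 3 nt
  out2 <- project_codon_alignment("MK-V", "MKAV", "ATGAAAGTT",
                                  "ATGAAGGCTGTA")
  expect_equal(nchar(out2$cds_a), 9)
  expect_equal(nchar(out2$cds_b), 9)
  expect_equal(out2$cds_a, "ATGAAAGTT")
  expect_equal(out2$cds_b, "ATGAAGGTA")

  expect_error(project_codon_alignment("MKV", "MKV", "ATGTAAGTT",
                                       "ATGAAAGTT"), "stop")
  expect_error(project_codon_alignment("MQV", "MKV", "ATGAAAGTT",
                                       "ATGAAAGTT"), "discordant")
})

test_that("the estimator recovers a planted dN/dS of 0.2 at 300 codons", {
  ratios <- vapply(1:50, function(seed) {
    # cds_a depends only on the seed, so the site counts used to pick the
    # planted substitution numbers describe the very sequence evolved
    base <- evolve_cds_pair(300, 0, 0, seed = 2000 + seed)$cds_a
    r0 <- nei_gojobori(base, base)
    n_syn <- round(0.15 * r0$S)
    n_nonsyn <- round(0.2 * 0.15 * r0$N)
    p <- evolve_cds_pair(300, n_syn, n_nonsyn, seed = 2000 + seed)
    r <- nei_gojobori(p$cds_a, p$cds_b)
    r$ratio
  }, numeric(1))
  expect_gte(median(ratios), 0.15)
  expect_lte(median(ratios), 0.25)
})
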