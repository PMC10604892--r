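mk_models <- function(df) {
  df$exons <- lapply(seq_len(nrow(df)), function(i)
    tibble::tibble(start = df$start[i], end = df$end[i]))
  df$cds <- df$exons
  tibble::as_tibble(df)
}

test_that("positional renaming sorts naturally and appends unplaced last", {
  models <- mk_models(data.frame(
    gene_id = c("gX", "gY", "gZ", "gW"),
    chromosome = c("chr10", "chr2", "chr2", "chr1"),
    strand = "+",
    start = c(5L, 100L, 50L, 7L), end = c(30L, 130L, 80L, 20L)))
  nm <- rename_by_position(c("gX", "gY", "gZ", "gW", "gU"), models,
                           prefix = "ZFP")
  # chr1 < chr2 < chr10 (natural order), start ascending, unplaced last
  expect_equal(nm$member_id, c("gW", "gZ", "gY", "gX", "gU"))
  expect_equal(nm$name, paste0("ZFP", 1:5))
  expect_true(is.na(nm$chromosome[5]))
  expect_error(rename_by_position(c("a", "a"), models), "Duplicate")
  expect_equal(nrow(rename_by_position(character(0), models)), 0)
})

test_that("chromosome distribution tallies placed and unplaced members", {
  models <- mk_models(data.frame(
    gene_id = paste0("g", 1:4),
    chromosome = c("chrA", "chrA", "chrA", "chrB"),
    strand = "+", start = c(1L, 50L, 90L, 5L), end = c(10L, 60L, 99L, 9L)))
  d <- chromosome_distribution(models)
  expect_equal(d$n[d$chromosome == "chrA"], 3L)
  expect_equal(d$n[d$chromosome == "chrB"], 1L)
  d2 <- chromosome_distribution(models[0, ], member_ids = c("u1", "u2"))
  expect_equal(d2, tibble::tibble(chromosome = "unplaced", n = 2L))
})

test_that("intron count is the exon count minus one", {
  m5 <- tibble::tibble(
    gene_id = "g5", chromosome = "c", strand = "+", start = 1L,
    end = 500L,
    exons = list(tibble::tibble(start = c(1L, 101L, 201L, 301L, 401L),
                                end = c(50L, 150L, 250L, 350L, 450L))),
    cds = list(tibble::tibble(start = 1L, end = 50L)))
  expect_equal(intron_counts(m5)$n_introns, 4L)
  m1 <- mk_models(data.frame(gene_id = "g1", chromosome = "c",
                             strand = "+", start = 1L, end = 9L))
  expect_equal(intron_counts(m1)$n_introns, 0L)
  m0 <- m1
  m0$exons[[1]] <- m0$exons[[1]][0, ]
  expect_error(intron_counts(m0), "no exons")
})

test_that("promoter extraction is strand-aware, clipped, and CDS-free", {
  # chromosome: 20 bp; plus gene CDS at 11..16, minus gene CDS at 3..8
  genome <- c(chr = "ACGTACGTACGGTTCCAGGT")
  plus <- mk_models(data.frame(gene_id = "p", chromosome = "chr",
                               strand = "+", start = 11L, end = 16L))
  pr <- extract_promoters(genome, plus, length = 4)
  expect_equal(pr$sequence, "GTAC")          # bases 7..10
  expect_equal(c(pr$start, pr$end), c(7, 10))
  expect_false(pr$clipped)
  # last promoter base abuts the start codon
  expect_equal(pr$end + 1L, 11L)

  minus <- mk_models(data.frame(gene_id = "m", chromosome = "chr",
                                strand = "-", start = 3L, end = 8L))
  mr <- extract_promoters(genome, minus, length = 5)
  # genomic 9..13 is "ACGGT"; promoter-oriented = revcomp = "ACCGT"
  expect_equal(mr$sequence, "ACCGT")
  expect_equal(c(mr$start, mr$end), c(9, 13))

  clip <- mk_models(data.frame(gene_id = "c", chromosome = "chr",
                               strand = "+", start = 4L, end = 9L))
  cr <- extract_promoters(genome, clip, length = 10)
  expect_equal(cr$length, 3L)
  expect_true(cr$clipped)
  expect_error(extract_promoters(genome, mk_models(data.frame(
    gene_id = "x", chromosome = "nope", strand = "+", start = 1L,
    end = 3L))), "missing")
})

test_that("IUPAC consensus scanning reports offsets, strands and overlaps", {
  prom <- tibble::tibble(gene_id = "g", sequence = "AATGACGTT")
  tab <- tibble::tibble(element_name = "TGACG-motif", consensus = "TGACG",
                        category = "hormone")
  hits <- scan_cis_elements(prom, tab, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 3L)  # third base, 1-based

  # degenerate code R matches A and G
  tabR <- tibble::tibble(element_name = "RG", consensus = "RG",
                         category = "other")
  hitsR <- scan_cis_elements(tibble::tibble(gene_id = "g",
                                            sequence = "AGGG"),
                             tabR, both_strands = FALSE)
  expect_equal(hitsR$offset, c(1L, 2L, 3L))

  # reverse-strand match reported with forward-coordinate offset
  rc_tab <- tibble::tibble(element_name = "E", consensus = "CCGGA",
                           category = "other")
  rc_hits <- scan_cis_elements(tibble::tibble(gene_id = "g",
                                              sequence = "TTCCGGTT"),
                               rc_tab)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$offset, 2L)

  bad <- tibble::tibble(element_name = "bad", consensus = "ACZT",
                        category = "other")
  expect_error(scan_cis_elements(prom, bad), "bad")
})

test_that("planted cis elements are recovered perfectly from the genome", {
  for (seed in c(5, 17)) {
    g <- make_genome_with_genes(sim_config(seed = seed, n_genes = 9))
    prom <- extract_promoters(g$genome, g$models, length = 2000)
    hits <- scan_cis_elements(prom)
    truth <- g$element_truth
    key <- function(d) paste(d$gene_id, d$element_name, d$offset,
                             d$strand, sep = "/")
    expect_setequal(key(hits), key(truth))
    # per-category counts match exactly, minus-strand genes included
    s <- summarize_categories(hits)
    expect_equal(
      s$categories,
      dplyr::count(truth, category) |> dplyr::rename(n = n))
    minus_genes <- g$gene_truth$gene_id[g$gene_truth$strand == "-"]
    expect_true(length(minus_genes) > 0)
    clipped_genes <- g$gene_truth$gene_id[g$gene_truth$clipped]
    expect_true(all(clipped_genes %in% hits$gene_id))
  }
})

test_that("strand symmetry: minus-strand planting mirrors plus-strand", {
  g <- make_genome_with_genes(sim_config(seed = 23, n_genes = 8))
  prom <- extract_promoters(g$genome, g$models, length = 2000)
  hits <- scan_cis_elements(prom)
  truth <- g$element_truth
  for (strand in c("+", "-")) {
    ids <- g$gene_truth$gene_id[g$gene_truth$strand == strand]
    got <- hits[hits$gene_id %in% ids, ]
    want <- truth[truth$gene_id %in% ids, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$gene_id, got$offset),
                    paste(want$gene_id, want$offset))
  }
})

test_that("category summaries tally hits and flag element-rich genes", {
  hits <- tibble::tibble(
    gene_id = c(rep("g1", 11), rep("g2", 3)),
    element_name = "e", category = c(rep("hormone", 8),
                                     rep("development", 6)),
    offset = 1L, end = 5L, strand = "+", match = "X")
  s <- summarize_categories(hits)
  expect_equal(s$categories$n[s$categories$category == "hormone"], 8L)
  expect_equal(s$categories$n[s$categories$category == "development"], 6L)
  expect_true(s$genes$flagged[s$genes$gene_id == "g1"])
  expect_false(s$genes$flagged[s$genes$gene_id == "g2"])
  e <- summarize_categories(hits[0, ])
  expect_equal(nrow(e$categories), 0)
})
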