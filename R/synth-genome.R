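# Synthetic genome generator: chromosomes carrying strand-alternating
# genes whose promoter windows contain planted cis elements at recorded
# promoter-relative offsets.
#
# Promoter background is drawn over {A, C} only. Every element of the
# default dictionary contains at least one G or T, so the only substrings
# of a promoter matching any element (on either strand) are the planted
# realizations; the generator additionally verifies this at build time
# with Biostrings and re-draws the window on the (theoretical) collision.

rc_dna <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

realize_iupac <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(IUPAC_NT[[ch]], "")[[1]]
    sample(opts, 1)
  }, character(1)), collapse = "")
}

random_ac <- function(n) {
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_element_matches <- function(seq, consensus) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(consensus), subj,
                                  fixed = FALSE)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(consensus)), subj,
    fixed = FALSE)
  length(fwd) + length(rev)
}

# Build one promoter window of length p with the configured elements
# planted at non-overlapping offsets. Returns the promoter-oriented
# sequence plus a truth tibble of offsets/strands.
build_promoter <- function(gene_id, p, elements) {
  lens <- nchar(elements$consensus)
  total <- sum(elements$copies * (lens + 12))
  if (total > p) {
    abort(paste0("Promoter of length ", p,
                 " too short for the requested planted elements"))
  }
  for (attempt in 1:20) {
    bg <- strsplit(random_ac(p), "")[[1]]
    placed <- list()
    occupied <- integer(0)
    ok <- TRUE
    for (i in seq_len(nrow(elements))) {
      for (k in seq_len(elements$copies[i])) {
        len <- lens[i]
        for (try2 in 1:200) {
          off <- sample(p - len + 1L, 1)
          span <- seq(off - 6L, off + len + 5L)  # keep >=6 bp clearance
          if (!any(span %in% occupied)) break
          off <- NA_integer_
        }
        if (is.na(off)) { ok <- FALSE; break }
        occupied <- c(occupied, seq(off, off + len - 1L))
        strand <- sample(c("+", "-"), 1)
        realized <- realize_iupac(elements$consensus[i])
        inserted <- if (strand == "+") realized else rc_dna(realized)
        bg[seq(off, off + len - 1L)] <- strsplit(inserted, "")[[1]]
        placed[[length(placed) + 1L]] <- tibble(
          gene_id = gene_id, element_name = elements$element_name[i],
          category = elements$category[i], offset = off,
          end = off + len - 1L, strand = strand, match = realized
        )
      }
      if (!ok) break
    }
    if (!ok) next
    seq <- paste(bg, collapse = "")
    truth <- dplyr::bind_rows(placed)
    # verify planted-only matches on both strands
    counts_ok <- all(vapply(seq_len(nrow(elements)), function(i) {
      count_element_matches(seq, elements$consensus[i]) ==
        sum(truth$element_name == elements$element_name[i])
    }, logical(1)))
    if (counts_ok) return(list(seq = seq, truth = truth))
  }
  abort("Could not build a collision-free promoter window in 20 attempts")
}

#' Generate a synthetic genome with gene models and planted promoters
#'
#' Places `n_genes` genes on three chromosomes (named `chr1`, `chr2`,
#' `chr10` to exercise natural-order sorting), alternating strands. Each
#' gene's promoter window carries the configured planted cis elements at
#' recorded promoter-relative offsets and strands; the first gene sits
#' closer than one promoter length to its chromosome edge so the clipping
#' path is exercised. A few genes are multi-exonic (two of them with 2 and
#' 5 exons) so intron counting has variety.
#'
#' @param config A [sim_config()]; `planted_elements` defaults to one copy
#'   of each [default_cis_elements()] row.
#' @return A list: `genome` (tibble `id`, `sequence`), `models`
#'   (gene-model tibble as from [read_gff3()]), `gene_truth` and
#'   `element_truth` tibbles.
#' @export
make_genome_with_genes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed + 1L, make_genome_impl(config))
}

make_genome_impl <- function(config) {
  elements <- config$planted_elements %||%
    dplyr::mutate(default_cis_elements(), copies = 1L)
  validate_cis_table(elements)
  if (!"copies" %in% names(elements)) elements$copies <- 1L
  chroms <- c("chr1", "chr2", "chr10")
  n <- config$n_genes
  if (n < 1) abort("n_genes must be >= 1")
  chrom_of <- chroms[(seq_len(n) - 1L) %% length(chroms) + 1L]
  strand_of <- c("+", "-")[(seq_len(n) - 1L) %% 2L + 1L]

  seqs <- setNames(rep("", length(chroms)), chroms)
  cursors <- setNames(rep(0L, length(chroms)), chroms)
  models <- list()
  gene_truth <- list()
  element_truth <- list()

  for (i in seq_len(n)) {
    chrom <- chrom_of[i]
    strand <- strand_of[i]
    # first gene is deliberately close to the chromosome edge: its
    # promoter window is clipped to what fits
    edge_gene <- i == 1L
    p <- if (edge_gene) min(500L, config$promoter_length) else
      config$promoter_length
    clipped <- p < config$promoter_length
    # the edge gene's promoter starts exactly at base 1 of chr1, so an
    # extraction at the full configured length is truncated to p bases
    gap <- if (edge_gene) 0L else 40L
    n_exons <- if (i == 4L) 2L else if (i == 6L) 5L else 1L
    cds_len <- 300L
    intron_len <- 80L
    body_len <- cds_len + (n_exons - 1L) * intron_len

    prom <- build_promoter(sprintf("G%03d", i), p, elements)
    body <- random_dna(body_len)

    start0 <- cursors[chrom] + gap  # 0-based start of the gene block
    if (strand == "+") {
      block <- paste0(prom$seq, body)
      cds_start <- start0 + p + 1L
      cds_end <- start0 + p + body_len
      prom_start <- start0 + 1L
      prom_end <- start0 + p
    } else {
      block <- paste0(body, rc_dna(prom$seq))
      cds_start <- start0 + 1L
      cds_end <- start0 + body_len
      prom_start <- cds_end + 1L
      prom_end <- cds_end + p
    }
    seqs[chrom] <- paste0(seqs[chrom], strrep("A", gap), block)
    cursors[chrom] <- cursors[chrom] + gap + nchar(block)

    # coding-only exon structure: exons coincide with CDS pieces
    piece <- cds_len %/% n_exons
    piece_lens <- c(rep(piece, n_exons - 1L),
                    cds_len - piece * (n_exons - 1L))
    starts <- cds_start + cumsum(c(0L, head(piece_lens, -1) + intron_len))
    ints <- tibble(start = as.integer(starts),
                   end = as.integer(starts + piece_lens - 1L))
    gid <- sprintf("G%03d", i)
    models[[i]] <- tibble(
      gene_id = gid, chromosome = chrom, strand = strand,
      start = as.integer(cds_start), end = as.integer(cds_end),
      exons = list(ints), cds = list(ints)
    )
    gene_truth[[i]] <- tibble(
      gene_id = gid, chromosome = chrom, strand = strand,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      n_exons = n_exons,
      promoter_start = as.integer(prom_start),
      promoter_end = as.integer(prom_end),
      promoter_length = p, clipped = clipped
    )
    element_truth[[i]] <- prom$truth |> dplyr::mutate(gene_id = gid)
  }
  # pad chromosome tails so no gene abuts the right edge except by design
  for (ch in chroms) seqs[ch] <- paste0(seqs[ch], strrep("A", 50L))
  gene_truth <- dplyr::bind_rows(gene_truth)
  # genomic CDS end must not overflow (minus-strand promoters extend right)
  stopifnot(all(gene_truth$promoter_end <= nchar(seqs[gene_truth$chromosome])))
  list(
    genome = tibble(id = chroms, description = "synthetic chromosome",
                    sequence = unname(seqs[chroms])),
    models = dplyr::bind_rows(models),
    gene_truth = gene_truth,
    element_truth = dplyr::bind_rows(element_truth)
  )
}
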