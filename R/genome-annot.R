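# Genomic placement and promoter analysis: positional renaming,
# per-chromosome counts, intron counts, strand-aware promoter extraction
# anchored on the start codon (first CDS base), and IUPAC cis-element
# scanning of promoter windows.

# natural chromosome order: "chr2" before "chr10"; non-numeric names last
natural_chrom_order <- function(chroms) {
  prefix <- gsub("[0-9]+$", "", chroms)
  num <- suppressWarnings(as.numeric(stringr::str_extract(chroms, "[0-9]+$")))
  order(prefix, num, chroms, na.last = TRUE)
}

#' Rename family members by chromosomal position
#'
#' Members placed on chromosomes are sorted by chromosome (natural order,
#' so `chr2` precedes `chr10`) and ascending start position and numbered
#' `<prefix>1`, `<prefix>2`, ...; members without a gene model come last,
#' in input order. The result is a bijection onto `<prefix>1..N`.
#'
#' @param member_ids Character vector of member gene/protein ids.
#' @param models Gene-model tibble (as from [read_gff3()]); members absent
#'   from it are treated as unplaced.
#' @param prefix Name prefix (default `"ZFP"`).
#' @return Tibble `member_id`, `name`, `chromosome`, `start` with one row
#'   per member, in naming order.
#' @export
rename_by_position <- function(member_ids, models, prefix = "ZFP") {
  if (anyDuplicated(member_ids)) abort("Duplicate member ids")
  placed <- models[models$gene_id %in% member_ids, ]
  chrom_rank <- seq_along(unique(placed$chromosome))
  lv <- unique(placed$chromosome)[natural_chrom_order(unique(placed$chromosome))]
  placed <- placed[order(match(placed$chromosome, lv), placed$start), ]
  unplaced <- setdiff(member_ids, placed$gene_id)
  ordered <- c(placed$gene_id, unplaced)
  tibble(
    member_id = ordered,
    name = paste0(prefix, seq_along(ordered)),
    chromosome = c(placed$chromosome, rep(NA_character_,
                                          length(unplaced))),
    start = c(placed$start, rep(NA_integer_, length(unplaced)))
  )
}

#' Per-chromosome member counts
#'
#' @param models Gene-model tibble.
#' @param member_ids Optional member ids; ids without a model are tallied
#'   under `"unplaced"`. Defaults to all modeled genes.
#' @return Tibble `chromosome`, `n`, in natural chromosome order with
#'   `"unplaced"` last.
#' @export
chromosome_distribution <- function(models, member_ids = NULL) {
  member_ids <- member_ids %||% models$gene_id
  placed <- models[models$gene_id %in% member_ids, ]
  chroms <- c(placed$chromosome,
              rep("unplaced", length(setdiff(member_ids, placed$gene_id))))
  if (length(chroms) == 0) {
    return(tibble(chromosome = character(), n = integer()))
  }
  out <- dplyr::count(tibble(chromosome = chroms), .data$chromosome)
  real <- out[out$chromosome != "unplaced", ]
  real <- real[natural_chrom_order(real$chromosome), ]
  dplyr::bind_rows(real, out[out$chromosome == "unplaced", ])
}

#' Intron counts per gene model
#'
#' The intron count of a gene is its exon count minus one.
#'
#' @param models Gene-model tibble.
#' @return Tibble `gene_id`, `n_exons`, `n_introns`.
#' @export
intron_counts <- function(models) {
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    nex <- nrow(models$exons[[i]])
    if (nex == 0) {
      abort(paste0("Gene ", models$gene_id[i], " has no exons"))
    }
    tibble(gene_id = models$gene_id[i], n_exons = nex,
           n_introns = nex - 1L)
  })
}

#' Extract strand-aware promoter windows upstream of start codons
#'
#' For a plus-strand gene the promoter is the `length` bases immediately
#' 5' of the first CDS base; for a minus-strand gene, the reverse
#' complement of the `length` bases immediately 3' of the last CDS base.
#' The returned sequence always reads 5' to 3' toward the start codon.
#' Windows are clipped at chromosome boundaries and flagged; they never
#' overlap the CDS.
#'
#' @param genome Tibble of nucleotide records (`id`, `sequence`) or a
#'   named character vector of chromosome sequences.
#' @param models Gene-model tibble.
#' @param length Promoter length in bp (default 2000).
#' @return Tibble `gene_id`, `chromosome`, `strand`, `start`, `end`
#'   (genomic, 1-based inclusive), `length`, `clipped`, `sequence`.
#' @export
extract_promoters <- function(genome, models, length = 2000L) {
  if (is.data.frame(genome)) {
    genome <- setNames(genome$sequence, genome$id)
  }
  purrr::map_dfr(seq_len(nrow(models)), function(i) {
    g <- models[i, ]
    if (!g$chromosome %in% names(genome)) {
      abort(paste0("Chromosome ", g$chromosome, " missing from genome"))
    }
    chrom_seq <- genome[[g$chromosome]]
    chrom_len <- nchar(chrom_seq)
    cds <- g$cds[[1]]
    if (nrow(cds) == 0) abort(paste0("Gene ", g$gene_id, " has no CDS"))
    if (g$strand == "+") {
      anchor <- min(cds$start)           # first base of the start codon
      from <- max(1L, anchor - length)
      to <- anchor - 1L
      seq <- substr(chrom_seq, from, to)
    } else {
      anchor <- max(cds$end)
      from <- anchor + 1L
      to <- min(chrom_len, anchor + length)
      seq <- rc_dna(substr(chrom_seq, from, to))
    }
    if (to < from) {
      seq <- ""
      from <- NA_integer_; to <- NA_integer_
    }
    w <- nchar(seq)
    requested <- length
    tibble(gene_id = g$gene_id, chromosome = g$chromosome,
           strand = g$strand, start = from, end = to,
           length = w, clipped = w < requested, sequence = seq)
  })
}

#' Scan promoter windows for cis elements
#'
#' Reports every match of each element's IUPAC consensus in each promoter
#' sequence, on the forward strand and (by default) the reverse
#' complement. Offsets are promoter-relative (1-based, in the
#' promoter-oriented sequence). Overlapping hits are all reported.
#'
#' @param promoters Tibble from [extract_promoters()] (needs `gene_id`,
#'   `sequence`).
#' @param table Cis-element table (`element_name`, `consensus`,
#'   `category`), e.g. [default_cis_elements()].
#' @param both_strands Also scan the reverse complement (default `TRUE`).
#' @return Tibble `gene_id`, `element_name`, `category`, `offset`, `end`,
#'   `strand`, `match`.
#' @export
scan_cis_elements <- function(promoters, table = default_cis_elements(),
                              both_strands = TRUE) {
  validate_cis_table(table)
  empty <- tibble(gene_id = character(), element_name = character(),
                  category = character(), offset = integer(),
                  end = integer(), strand = character(),
                  match = character())
  out <- purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
    seq <- promoters$sequence[i]
    if (!nzchar(seq)) return(NULL)
    subj <- Biostrings::DNAString(seq)
    purrr::map_dfr(seq_len(nrow(table)), function(k) {
      pat <- Biostrings::DNAString(toupper(table$consensus[k]))
      hit_rows <- function(ranges, strand) {
        if (length(ranges) == 0) return(NULL)
        st <- Biostrings::start(ranges)
        en <- Biostrings::end(ranges)
        tibble(gene_id = promoters$gene_id[i],
               element_name = table$element_name[k],
               category = table$category[k],
               offset = as.integer(st), end = as.integer(en),
               strand = strand,
               match = substring(seq, st, en))
      }
      fwd <- hit_rows(Biostrings::matchPattern(pat, subj, fixed = FALSE),
                      "+")
      rev <- if (both_strands) {
        hit_rows(Biostrings::matchPattern(
          Biostrings::reverseComplement(pat), subj, fixed = FALSE), "-")
      } else NULL
      dplyr::bind_rows(fwd, rev)
    })
  })
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$gene_id,
                                                .data$offset)
}

#' Summarize cis-element hits by category and by gene
#'
#' @param hits Tibble from [scan_cis_elements()].
#' @param flag_threshold Genes with at least this many elements are
#'   flagged (default 10).
#' @return List with `categories` (tibble `category`, `n`) and `genes`
#'   (tibble `gene_id`, `n_elements`, `flagged`).
#' @export
summarize_categories <- function(hits, flag_threshold = 10L) {
  if (nrow(hits) == 0) {
    return(list(categories = tibble(category = character(), n = integer()),
                genes = tibble(gene_id = character(),
                               n_elements = integer(),
                               flagged = logical())))
  }
  list(
    categories = dplyr::count(hits, .data$category),
    genes = hits |>
      dplyr::count(.data$gene_id, name = "n_elements") |>
      dplyr::mutate(flagged = .data$n_elements >= flag_threshold)
  )
}
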