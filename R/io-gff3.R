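#' Read GFF3 gene models into a tibble
#'
#' Parses a GFF3 file (gene/mRNA/exon/CDS features linked through `Parent`
#' attributes) and assembles one row per gene. Coordinates are kept 1-based
#' inclusive as stored in GFF3. Exon and CDS intervals are returned sorted
#' by start position; CDS features whose `Parent` chain does not resolve to
#' a gene raise an error naming the orphan.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chromosome`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, and list-columns `exons` and `cds`, each
#'   entry a tibble of `start`/`end` intervals.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "source", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")
  ))
  if (nrow(gff) == 0) {
    return(tibble(gene_id = character(), chromosome = character(),
                  strand = character(), start = integer(), end = integer(),
                  exons = list(), cds = list()))
  }
  bad <- which(gff$end < gff$start)
  if (length(bad)) {
    abort(paste0("GFF3 parse error: feature with end < start (",
                 gff$type[bad[1]], " ", gff$seqid[bad[1]], ":",
                 gff$start[bad[1]], "-", gff$end[bad[1]], ")"))
  }
  gff$Parent <- vapply(gff$Parent,
                       function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                       character(1))
  genes <- gff[gff$type == "gene", ]
  if (anyDuplicated(genes$ID)) {
    abort("GFF3 parse error: duplicate gene IDs")
  }
  # Parent chain: exon/CDS -> mRNA -> gene (or directly gene-parented)
  mrna <- gff[gff$type == "mRNA", ]
  mrna_to_gene <- setNames(mrna$Parent, mrna$ID)
  resolve_gene <- function(parent, what) {
    if (is.na(parent)) {
      abort(paste0("GFF3 parse error: ", what, " feature without Parent"))
    }
    if (parent %in% genes$ID) return(parent)
    g <- unname(mrna_to_gene[parent])
    if (length(g) != 1 || is.na(g) || !(g %in% genes$ID)) {
      abort(paste0("GFF3 parse error: orphan ", what,
                   " with unresolvable Parent '", parent, "'"))
    }
    g
  }
  parts <- gff[gff$type %in% c("exon", "CDS"), ]
  parts$gene <- vapply(seq_len(nrow(parts)), function(i) {
    resolve_gene(parts$Parent[i], parts$type[i])
  }, character(1))

  interval_tbl <- function(sub) {
    sub <- sub[order(sub$start), ]
    tbl <- tibble(start = as.integer(sub$start), end = as.integer(sub$end))
    if (nrow(tbl) > 1 && any(tbl$start[-1] <= tbl$end[-nrow(tbl)])) {
      abort("GFF3 parse error: overlapping intervals within one gene")
    }
    tbl
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    ex <- interval_tbl(parts[parts$type == "exon" & parts$gene == gid, ])
    cd <- interval_tbl(parts[parts$type == "CDS" & parts$gene == gid, ])
    tibble(
      gene_id = gid,
      chromosome = as.character(genes$seqid[i]),
      strand = as.character(genes$strand[i]),
      start = as.integer(genes$start[i]),
      end = as.integer(genes$end[i]),
      exons = list(ex),
      cds = list(cd)
    )
  })
  dplyr::bind_rows(out)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()]: emits gene, mRNA, exon and CDS features with
#' `Parent` attributes so that reading the file back reproduces the input
#' tibble.
#'
#' @param models Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    writeLines(fmt(g$chromosome, "qzfp", "gene", g$start, g$end, g$strand,
                   paste0("ID=", gid)), con)
    writeLines(fmt(g$chromosome, "qzfp", "mRNA", g$start, g$end, g$strand,
                   paste0("ID=", mid, ";Parent=", gid)), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      writeLines(fmt(g$chromosome, "qzfp", "exon", ex$start[j], ex$end[j],
                     g$strand, paste0("Parent=", mid)), con)
    }
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      writeLines(fmt(g$chromosome, "qzfp", "CDS", cd$start[j], cd$end[j],
                     g$strand, paste0("Parent=", mid)), con)
    }
  }
  invisible(path)
}
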