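# Expression profiling: FPKM normalisation, log2(FPKM + 1) transform,
# tissue-specificity calls and fold-change-based stress-response calls.
# The container keeps counts, sample metadata, gene lengths and library
# sizes together; all derived outputs are plain tibbles.

#' Build an expression matrix container
#'
#' @param counts Tibble with a `gene_id` column and one non-negative
#'   integer column per sample.
#' @param samples Tibble of sample metadata: `sample_id` plus any of
#'   `tissue`, `condition`, `timepoint`, `replicate`.
#' @param gene_lengths Tibble `gene_id`, `length` (bp, > 0).
#' @param library_sizes Optional named vector of total mapped counts per
#'   sample; defaults to the column sums.
#' @return An object of class `qzfp_expr`.
#' @export
expression_matrix <- function(counts, samples, gene_lengths,
                              library_sizes = NULL) {
  stopifnot("gene_id" %in% names(counts),
            all(c("sample_id") %in% names(samples)),
            all(c("gene_id", "length") %in% names(gene_lengths)))
  sample_ids <- setdiff(names(counts), "gene_id")
  if (!setequal(sample_ids, samples$sample_id)) {
    abort("counts columns and samples$sample_id disagree")
  }
  if (!setequal(counts$gene_id, gene_lengths$gene_id)) {
    abort("counts genes and gene_lengths genes disagree")
  }
  if (any(gene_lengths$length <= 0)) abort("gene lengths must be > 0")
  cmat <- as.matrix(counts[, sample_ids])
  if (any(cmat < 0)) abort("counts must be non-negative")
  colsums <- colSums(cmat)
  if (is.null(library_sizes)) {
    library_sizes <- colsums
  } else {
    library_sizes <- library_sizes[sample_ids]
    if (any(is.na(library_sizes))) abort("library_sizes missing a sample")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be > 0")
  structure(list(counts = counts, samples = as_tibble(samples),
                 gene_lengths = as_tibble(gene_lengths),
                 library_sizes = library_sizes), class = "qzfp_expr")
}

#' @export
print.qzfp_expr <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$counts), nrow(x$samples)))
  invisible(x)
}

#' FPKM normalisation
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (library_size[s] * gene_length[g])`
#' — fragments per kilobase of exon per million mapped reads.
#'
#' @param x A `qzfp_expr` from [expression_matrix()].
#' @return Tibble `gene_id` plus one FPKM column per sample.
#' @export
fpkm <- function(x) {
  stopifnot(inherits(x, "qzfp_expr"))
  sample_ids <- x$samples$sample_id
  len <- setNames(x$gene_lengths$length, x$gene_lengths$gene_id)
  out <- x$counts
  lg <- unname(len[out$gene_id])
  for (s in sample_ids) {
    out[[s]] <- unname(out[[s]]) * 1e9 / (x$library_sizes[[s]] * lg)
  }
  out
}

#' log2(FPKM + 1) transform
#'
#' @param fpkm_tbl Tibble from [fpkm()] (or any tibble whose non-`gene_id`
#'   columns are non-negative).
#' @return Tibble of the same shape with `log2(x + 1)` values.
#' @export
log_fpkm <- function(fpkm_tbl) {
  out <- fpkm_tbl
  for (s in setdiff(names(out), "gene_id")) {
    out[[s]] <- log2(out[[s]] + 1)
  }
  out
}

mean_over_samples <- function(fpkm_tbl, sample_ids) {
  if (length(sample_ids) == 0) abort("Empty sample group")
  rowMeans(as.matrix(fpkm_tbl[, sample_ids, drop = FALSE]))
}

#' Tissue-specificity calls from control-condition FPKM
#'
#' A gene is "expressed" in a tissue when its mean control FPKM over
#' replicates exceeds `expressed_threshold`; the two per-tissue flags then
#' map to `root_only`, `leaf_only`, `both` or `neither`.
#'
#' @param fpkm_tbl Tibble from [fpkm()].
#' @param samples Sample metadata with `sample_id`, `tissue`, `condition`.
#' @param expressed_threshold FPKM threshold for "expressed" (default 1).
#' @param control Condition label of the baseline samples.
#' @return Tibble `gene_id`, `mean_leaf`, `mean_root`, `specificity`.
#' @export
call_specificity <- function(fpkm_tbl, samples, expressed_threshold = 1,
                             control = "control") {
  ctrl <- samples[samples$condition == control, ]
  for (tis in c("leaf", "root")) {
    if (!any(ctrl$tissue == tis)) {
      abort(paste0("No control samples for tissue '", tis, "'"))
    }
  }
  mleaf <- mean_over_samples(fpkm_tbl,
                             ctrl$sample_id[ctrl$tissue == "leaf"])
  mroot <- mean_over_samples(fpkm_tbl,
                             ctrl$sample_id[ctrl$tissue == "root"])
  leaf_on <- mleaf > expressed_threshold
  root_on <- mroot > expressed_threshold
  tibble(
    gene_id = fpkm_tbl$gene_id,
    mean_leaf = mleaf, mean_root = mroot,
    specificity = dplyr::case_when(
      leaf_on & root_on ~ "both",
      root_on ~ "root_only",
      leaf_on ~ "leaf_only",
      .default = "neither"
    )
  )
}

#' Stress-response calls from a fold-change rule
#'
#' `log2fc = log2((mean_treated + pseudo) / (mean_control + pseudo))`;
#' a gene is called `up` when `log2fc >= lfc_threshold`, `down` when
#' `log2fc <= -lfc_threshold`, otherwise `unchanged`. This documented
#' rule replaces dispersion-modeled differential testing.
#'
#' @param fpkm_tbl Tibble from [fpkm()].
#' @param treated,control Character vectors of sample ids for the two
#'   groups (both non-empty).
#' @param contrast Label stored in the output.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param pseudo Pseudo-count added to both means (default 1).
#' @return Tibble `gene_id`, `contrast`, `mean_treated`, `mean_control`,
#'   `log2fc`, `call`.
#' @export
call_response <- function(fpkm_tbl, treated, control,
                          contrast = "treated_vs_control",
                          lfc_threshold = 1, pseudo = 1) {
  mt <- mean_over_samples(fpkm_tbl, treated)
  mc <- mean_over_samples(fpkm_tbl, control)
  lfc <- log2((mt + pseudo) / (mc + pseudo))
  tibble(
    gene_id = fpkm_tbl$gene_id, contrast = contrast,
    mean_treated = mt, mean_control = mc, log2fc = lfc,
    call = dplyr::case_when(
      lfc >= lfc_threshold ~ "up",
      lfc <= -lfc_threshold ~ "down",
      .default = "unchanged"
    )
  )
}
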