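# Count-matrix generator emulating the study's RNA-seq design: leaf and
# root tissue, a salt time course (0/12/24/48/72 h, the 0 h samples are
# the controls), a virus-infected vs mock contrast in root, three
# biological replicates throughout, negative-binomial noise.

#' Generate a synthetic expression count matrix with planted effects
#'
#' Genes are planted in classes (`n_genes_per_class` of each):
#' `both` (expressed in leaf and root), `root_only`, `leaf_only`,
#' `silent` (all-zero counts), `salt_up` / `salt_down` (fold change
#' applied in both tissues at every salt timepoint > 0 h), and
#' `virus_up` / `virus_down` (fold change in infected vs mock root).
#' Counts are negative binomial with the configured baseline mean and
#' dispersion; planted fold changes use `fold_change`.
#'
#' @param config A [sim_config()]; see its `expression_design` argument.
#' @return List with `expr` (a [expression_matrix()] object) and `truth`
#'   (tibble `gene_id`, `class`, `specificity`, `salt_call`,
#'   `virus_call`).
#' @export
make_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed + 2L, make_counts_impl(config))
}

make_counts_impl <- function(config) {
  des <- config$expression_design
  classes <- c("both", "root_only", "leaf_only", "silent",
               "salt_up", "salt_down", "virus_up", "virus_down")
  gene_class <- rep(classes, each = des$n_genes_per_class)
  n_genes <- length(gene_class)
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))

  samples <- dplyr::bind_rows(
    tidyr::expand_grid(tissue = des$tissues,
                       timepoint = des$timepoints,
                       replicate = seq_len(des$replicates)) |>
      dplyr::mutate(condition = ifelse(.data$timepoint == 0,
                                       "control", "salt")),
    tidyr::expand_grid(tissue = "root", condition = c("mock", "virus"),
                       replicate = seq_len(des$replicates)) |>
      dplyr::mutate(timepoint = NA_integer_)
  ) |>
    dplyr::mutate(sample_id = paste0(
      .data$tissue, "_", .data$condition,
      ifelse(is.na(.data$timepoint), "", paste0("_", .data$timepoint, "h")),
      "_r", .data$replicate
    )) |>
    dplyr::select("sample_id", "tissue", "condition", "timepoint",
                  "replicate")

  base <- des$baseline_mean
  fc <- des$fold_change
  mu_for <- function(class, tissue, condition) {
    mu <- base
    if (class == "silent") return(0)
    if (class == "root_only" && tissue == "leaf") return(0)
    if (class == "leaf_only" && tissue == "root") return(0)
    if (class == "salt_up" && condition == "salt") mu <- mu * fc
    if (class == "salt_down" && condition == "salt") mu <- mu / fc
    if (class == "virus_up" && condition == "virus") mu <- mu * fc
    if (class == "virus_down" && condition == "virus") mu <- mu / fc
    mu
  }
  cmat <- matrix(0L, nrow = n_genes, ncol = nrow(samples),
                 dimnames = list(gene_ids, samples$sample_id))
  for (g in seq_len(n_genes)) {
    for (s in seq_len(nrow(samples))) {
      mu <- mu_for(gene_class[g], samples$tissue[s], samples$condition[s])
      cmat[g, s] <- if (mu == 0) 0L else
        rnbinom(1, mu = mu, size = 1 / des$dispersion)
    }
  }
  counts <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                             as_tibble(as.data.frame(cmat)))
  gene_lengths <- tibble(gene_id = gene_ids, length = des$gene_length)
  # fixed library size keeps planted FPKM fold changes exact in
  # expectation (column sums would absorb part of the planted effect)
  libs <- setNames(rep(1e6, nrow(samples)), samples$sample_id)
  truth <- tibble(
    gene_id = gene_ids, class = gene_class,
    specificity = dplyr::case_when(
      gene_class == "silent" ~ "neither",
      gene_class == "root_only" ~ "root_only",
      gene_class == "leaf_only" ~ "leaf_only",
      .default = "both"
    ),
    salt_call = dplyr::case_when(
      gene_class == "salt_up" ~ "up",
      gene_class == "salt_down" ~ "down",
      .default = "unchanged"
    ),
    virus_call = dplyr::case_when(
      gene_class == "virus_up" ~ "up",
      gene_class == "virus_down" ~ "down",
      .default = "unchanged"
    )
  )
  list(expr = expression_matrix(counts, samples, gene_lengths,
                                library_sizes = libs),
       truth = truth)
}
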