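# Seeded synthetic-data generators. All generators restore the caller's
# RNG state and are byte-deterministic for a fixed config.

# Residues usable as member "linker" background: excludes C/F/H (scaffold
# letters), L/D (EAR letters), E (L-box letter), so planted features are
# provably the only pattern matches in a member sequence.
LINKER_AA <- c("A", "G", "I", "K", "M", "N", "P", "Q", "R", "S",
               "T", "V", "W", "Y")

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generators
#'
#' The defaults emulate the structure of the study system: a 35-member
#' family split 22/6/6/1 across the 1i-4i domain-count groups, an EAR motif
#' in roughly nine of ten members, 2000-bp promoters, and an RNA-seq design
#' with two tissues (leaf, root), a salt time course (0/12/24/48/72 h), a
#' virus-infected vs mock contrast and three biological replicates, with
#' negative-binomial count noise.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param n_members_per_group Named counts for groups `1i`-`4i`.
#' @param n_background_proteins Number of non-family background proteins.
#' @param ear_fraction Fraction of family members carrying one planted EAR
#'   motif.
#' @param member_length Optional total protein length for members; `NULL`
#'   sizes each protein automatically. Too-short lengths are a config
#'   error.
#' @param promoter_length Promoter window length in bp.
#' @param planted_elements Tibble (`element_name`, `category`, `copies`)
#'   of cis elements to plant per promoter; defaults to one copy of each
#'   default dictionary entry.
#' @param n_genes Number of synthetic genes for the genome generator.
#' @param expression_design List: `tissues`, `timepoints`, `replicates`,
#'   `baseline_mean` (counts), `fold_change`, `dispersion`,
#'   `gene_length` (bp), `n_genes_per_class`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_members_per_group = c("1i" = 22L, "2i" = 6L,
                                               "3i" = 6L, "4i" = 1L),
                       n_background_proteins = 20L,
                       ear_fraction = 0.9,
                       member_length = NULL,
                       promoter_length = 2000L,
                       planted_elements = NULL,
                       n_genes = 12L,
                       expression_design = list()) {
  stopifnot(all(n_members_per_group >= 0), n_background_proteins >= 0,
            ear_fraction >= 0, ear_fraction <= 1, promoter_length > 0,
            n_genes >= 0)
  groups <- c("1i", "2i", "3i", "4i")
  counts <- setNames(rep(0L, 4), groups)
  counts[names(n_members_per_group)] <- as.integer(n_members_per_group)
  design <- utils::modifyList(list(
    tissues = c("leaf", "root"),
    timepoints = c(0L, 12L, 24L, 48L, 72L),
    replicates = 3L,
    baseline_mean = 100,
    fold_change = 4,
    dispersion = 0.1,
    gene_length = 1000L,
    n_genes_per_class = 5L
  ), expression_design)
  structure(list(
    seed = as.integer(seed),
    n_members_per_group = counts,
    n_background_proteins = as.integer(n_background_proteins),
    ear_fraction = ear_fraction,
    member_length = member_length,
    promoter_length = as.integer(promoter_length),
    planted_elements = planted_elements,
    n_genes = as.integer(n_genes),
    expression_design = design
  ), class = "sim_config")
}

sample_linker <- function(n) {
  paste(sample(LINKER_AA, n, replace = TRUE), collapse = "")
}
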