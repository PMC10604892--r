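# End-to-end orchestration: scan -> classify -> physchem -> motifs ->
# rename -> promoters -> phylo -> kaks -> expression -> family report.
# Stages run in dependency order and are individually optional: a stage
# runs when its inputs are configured. Inputs may be file paths (read
# with the package's readers) or in-memory objects of the same shape.

#' Pipeline configuration
#'
#' Every input is optional except the proteome; a stage is skipped when
#' its inputs are absent. Inputs may be file paths (FASTA/GFF3/TSV) or
#' the corresponding in-memory tibbles.
#'
#' @param proteome Protein FASTA path or records tibble (required).
#' @param genome Nucleotide FASTA path or tibble (promoter stage).
#' @param gff GFF3 path or gene-model tibble (placement/promoter stages).
#' @param alignment Aligned FASTA path or tibble (phylogeny stage).
#' @param anchors Anchor TSV path (`anchor_id`, `clade`) or tibble.
#' @param elements Cis-element TSV path or tibble; defaults to
#'   [default_cis_elements()] when the promoter stage runs.
#' @param cds CDS FASTA path or tibble (Ka/Ks stage).
#' @param pairs Gene-pair TSV path or tibble (`id_a`, `id_b`).
#' @param counts,samples,gene_lengths Expression inputs: counts TSV
#'   (`gene_id` + samples), sample metadata TSV, gene-length TSV.
#' @param contrasts Named list of `list(treated = , control = )` sample-id
#'   vectors for [call_response()].
#' @param pattern_config A [zf_pattern_config()].
#' @param prefix Positional-renaming prefix.
#' @param promoter_length Promoter window length (bp).
#' @param expressed_threshold,lfc_threshold,pseudo Expression thresholds.
#' @param bootstrap Bootstrap replicates for the phylogeny stage (0 for a
#'   plain NJ tree).
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `qzfp_pipeline_config`.
#' @export
pipeline_config <- function(proteome, genome = NULL, gff = NULL,
                            alignment = NULL, anchors = NULL,
                            elements = NULL, cds = NULL, pairs = NULL,
                            counts = NULL, samples = NULL,
                            gene_lengths = NULL, contrasts = NULL,
                            pattern_config = zf_pattern_config(),
                            prefix = "ZFP", promoter_length = 2000L,
                            expressed_threshold = 1, lfc_threshold = 1,
                            pseudo = 1, bootstrap = 0L, seed = 1L) {
  cfg <- list(proteome = proteome, genome = genome, gff = gff,
              alignment = alignment, anchors = anchors,
              elements = elements, cds = cds, pairs = pairs,
              counts = counts, samples = samples,
              gene_lengths = gene_lengths, contrasts = contrasts,
              pattern_config = pattern_config, prefix = prefix,
              promoter_length = as.integer(promoter_length),
              expressed_threshold = expressed_threshold,
              lfc_threshold = lfc_threshold, pseudo = pseudo,
              bootstrap = as.integer(bootstrap), seed = as.integer(seed))
  for (nm in c("proteome", "genome", "gff", "alignment", "anchors",
               "elements", "cds", "pairs", "counts", "samples",
               "gene_lengths")) {
    x <- cfg[[nm]]
    if (is.character(x) && length(x) == 1 && !file.exists(x)) {
      abort(paste0("Configured ", nm, " file does not exist: ", x))
    }
  }
  structure(cfg, class = "qzfp_pipeline_config")
}

load_input <- function(x, loader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) loader(x) else x
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full family-analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @return An object of class `qzfp_report`: a list of stage outputs
#'   (`members`, `domains`, `motifs`, `physchem`, `naming`,
#'   `chromosomes`, `introns`, `promoters`, `cis_hits`, `cis_summary`,
#'   `tree`, `clades`, `kaks`, `specificity`, `responses`) plus a
#'   `summary` list of family-level tallies. Use [generics::tidy()] for
#'   the per-member table and [generics::glance()] for the one-row
#'   summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qzfp_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  proteome <- stage("read_proteome",
                    load_input(config$proteome, read_fasta))
  if (is.null(proteome)) abort("A proteome input is required")

  members <- stage("scan", identify_qtype_members(proteome,
                                                  config$pattern_config))
  member_prot <- proteome[proteome$id %in% members$protein_id, ]
  domains <- stage("scan", scan_zf_domains(member_prot,
                                           config$pattern_config))
  phys <- stage("physchem", physchem_profile(member_prot))
  motifs <- stage("motifs", find_protein_motifs(member_prot))

  models <- stage("read_gff", load_input(config$gff, read_gff3))
  naming <- chrom_dist <- introns <- NULL
  if (!is.null(models)) {
    naming <- stage("rename", rename_by_position(members$protein_id,
                                                 models, config$prefix))
    chrom_dist <- stage("rename", chromosome_distribution(
      models, members$protein_id))
    introns <- stage("rename", intron_counts(
      models[models$gene_id %in% members$protein_id, ]))
  }

  genome <- stage("read_genome", load_input(config$genome, read_fasta))
  promoters <- cis_hits <- cis_summary <- NULL
  if (!is.null(genome) && !is.null(models)) {
    promoters <- stage("promoters", extract_promoters(
      genome, models, length = config$promoter_length))
    element_tbl <- load_input(config$elements, read_tsv_quiet) %||%
      default_cis_elements()
    cis_hits <- stage("promoters", scan_cis_elements(promoters,
                                                     element_tbl))
    cis_summary <- stage("promoters", summarize_categories(cis_hits))
  }

  alignment <- stage("read_alignment",
                     load_input(config$alignment, read_fasta))
  tree <- clades <- NULL
  if (!is.null(alignment)) {
    tree <- stage("phylo", if (config$bootstrap > 0) {
      bootstrap_support(alignment, n_replicates = config$bootstrap,
                        seed = config$seed)
    } else {
      nj_tree(p_distance_matrix(alignment))
    })
    anchors <- load_input(config$anchors, read_tsv_quiet)
    if (!is.null(anchors)) {
      clades <- stage("phylo", assign_clades(tree, anchors))
    }
  }

  kaks_tbl <- NULL
  cds <- load_input(config$cds, read_fasta)
  pairs <- load_input(config$pairs, read_tsv_quiet)
  if (!is.null(cds) && !is.null(pairs)) {
    kaks_tbl <- stage("kaks", purrr::map_dfr(seq_len(nrow(pairs)),
      function(i) {
        ca <- cds$sequence[cds$id == pairs$id_a[i]]
        cb <- cds$sequence[cds$id == pairs$id_b[i]]
        if (length(ca) != 1 || length(cb) != 1) {
          abort(paste0("CDS missing for pair ", pairs$id_a[i], "/",
                       pairs$id_b[i]))
        }
        res <- nei_gojobori(ca, cb)
        dplyr::mutate(tidy(res), id_a = pairs$id_a[i],
                      id_b = pairs$id_b[i], .before = 1)
      }))
  }

  specificity <- responses <- NULL
  counts <- load_input(config$counts, read_tsv_quiet)
  if (!is.null(counts)) {
    samples <- load_input(config$samples, read_tsv_quiet)
    lengths <- load_input(config$gene_lengths, read_tsv_quiet)
    if (is.null(samples) || is.null(lengths)) {
      abort("Expression stage needs counts, samples and gene_lengths")
    }
    ex <- stage("expression", expression_matrix(counts, samples, lengths))
    fp <- stage("expression", fpkm(ex))
    specificity <- stage("expression", call_specificity(
      fp, ex$samples, expressed_threshold = config$expressed_threshold))
    if (!is.null(config$contrasts)) {
      responses <- stage("expression", purrr::imap_dfr(
        config$contrasts, function(ct, nm) {
          call_response(fp, treated = ct$treated, control = ct$control,
                        contrast = nm,
                        lfc_threshold = config$lfc_threshold,
                        pseudo = config$pseudo)
        }))
    }
  }

  member_tbl <- members |>
    dplyr::select("protein_id", "group", "n_q", "n_m", "n_domains") |>
    dplyr::left_join(phys, by = c(protein_id = "id"))
  if (!is.null(naming)) {
    member_tbl <- dplyr::left_join(member_tbl, naming,
                                   by = c(protein_id = "member_id"))
  }
  ear_ids <- unique(motifs$protein_id[startsWith(motifs$kind, "EAR")])
  summary <- list(
    n_members = nrow(members),
    group_counts = dplyr::count(members, .data$group),
    mw_by_group = purrr::map_dfr(unique(members$group), function(g) {
      ids <- members$protein_id[members$group == g]
      x <- phys$mw[phys$id %in% ids]
      tibble(group = g, mean_mw = floor(mean(x)), min_mw = min(x),
             max_mw = max(x), n = length(x))
    }),
    chromosome_distribution = chrom_dist,
    n_with_ear = length(ear_ids),
    n_with_lxlxl = length(unique(
      motifs$protein_id[motifs$kind == "EAR_LxLxL"])),
    n_with_dlnp = length(unique(
      motifs$protein_id[motifs$kind == "EAR_DLNP"]))
  )
  structure(list(
    members = member_tbl, domains = domains, motifs = motifs,
    physchem = phys, naming = naming, chromosomes = chrom_dist,
    introns = introns, promoters = promoters, cis_hits = cis_hits,
    cis_summary = cis_summary, tree = tree, clades = clades,
    kaks = kaks_tbl, specificity = specificity, responses = responses,
    summary = summary
  ), class = "qzfp_report")
}

#' @export
print.qzfp_report <- function(x, ...) {
  cat("Q-type ZFP family report\n")
  cat("  members:", x$summary$n_members, "\n")
  gc <- x$summary$group_counts
  cat("  groups: ", paste(gc$group, gc$n, sep = "=", collapse = ", "),
      "\n")
  cat("  with EAR motif:", x$summary$n_with_ear, "\n")
  stages <- c("naming", "promoters", "tree", "kaks", "specificity")
  on <- stages[!vapply(x[stages], is.null, logical(1))]
  if (length(on)) cat("  stages run:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Compare a family report (or member table) against the packaged
#' reference table
#'
#' Per-member, per-field comparison with tolerances: molecular weight
#' 0.5 Da, pI 0.05, all other fields exact. An empty result is a pass.
#'
#' @param report A `qzfp_report`, or a tibble with columns `gene_name`,
#'   `aa_length`, `mw`, `pi`, `instability`, `gravy`, `group`.
#' @param fixture Reference table from [load_table1()].
#' @param tolerances Named numeric tolerances per field.
#' @return Tibble of discrepancies: `gene_name`, `field`, `expected`,
#'   `actual`, `delta`.
#' @export
validate_against_table1 <- function(report, fixture = load_table1(),
                                    tolerances = c(mw = 0.5, pi = 0.05)) {
  tbl <- if (inherits(report, "qzfp_report")) {
    dplyr::transmute(report$members,
                     gene_name = .data$name, aa_length = .data$length,
                     mw = .data$mw, pi = .data$pi,
                     instability = .data$instability, gravy = .data$gravy,
                     group = .data$group)
  } else {
    as_tibble(report)
  }
  fields <- intersect(c("aa_length", "mw", "pi", "instability", "gravy",
                        "group"), names(tbl))
  out <- list()
  for (gn in fixture$gene_name) {
    exp_row <- fixture[fixture$gene_name == gn, ]
    act_row <- tbl[tbl$gene_name == gn, ]
    if (nrow(act_row) != 1) {
      out[[length(out) + 1L]] <- tibble(
        gene_name = gn, field = "(row)", expected = "present",
        actual = paste0(nrow(act_row), " rows"), delta = NA_real_)
      next
    }
    for (f in fields) {
      e <- exp_row[[f]]; a <- act_row[[f]]
      tol <- unname(tolerances[f])
      if (is.na(tol)) tol <- 0  # fields without a tolerance: exact
      bad <- if (is.numeric(e)) {
        abs(a - e) > tol
      } else {
        !identical(as.character(a), as.character(e))
      }
      if (isTRUE(bad)) {
        out[[length(out) + 1L]] <- tibble(
          gene_name = gn, field = f, expected = as.character(e),
          actual = as.character(a),
          delta = if (is.numeric(e)) as.numeric(a) - as.numeric(e)
            else NA_real_)
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(gene_name = character(), field = character(),
           expected = character(), actual = character(),
           delta = double())
}
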