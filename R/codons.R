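# Codon-level utilities shared by the CDS evolver and the Ka/Ks
# estimator. Standard genetic code via Biostrings::GENETIC_CODE.

GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_TBL), STOP_CODONS)
NT <- c("A", "C", "G", "T")

translate_codon <- function(codon) unname(GENETIC_CODE_TBL[codon])

split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("CDS length not divisible by 3")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Translate a coding sequence
#'
#' @param cds Gapless coding sequence (length divisible by 3).
#' @param allow_terminal_stop Tolerate a single trailing stop codon.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, allow_terminal_stop = TRUE) {
  codons <- split_codons(cds)
  aa <- translate_codon(codons)
  if (any(is.na(aa))) abort("CDS contains a non-ACGT codon")
  if (allow_terminal_stop && length(aa) > 1 && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  if (any(aa == "*")) {
    abort(paste0("CDS contains an internal stop codon at codon ",
                 which(aa == "*")[1]))
  }
  paste(aa, collapse = "")
}

# All single-nucleotide neighbors of a codon, with their class.
codon_neighbors <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- list()
  for (pos in 1:3) {
    for (nt in setdiff(NT, chars[pos])) {
      alt <- chars
      alt[pos] <- nt
      alt_codon <- paste(alt, collapse = "")
      out[[length(out) + 1L]] <- list(
        pos = pos, codon = alt_codon,
        stop = alt_codon %in% STOP_CODONS,
        synonymous = identical(translate_codon(alt_codon),
                               translate_codon(codon))
      )
    }
  }
  out
}

#' Evolve a coding-sequence pair with exact substitution counts
#'
#' Generates a random stop-free CDS of `n_codons` codons and a partner
#' differing by exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous
#' single-nucleotide substitutions, at most one substitution per codon and
#' never creating a stop codon. This gives unambiguous ground truth for
#' substitution-counting estimators.
#'
#' @param n_codons Number of codons.
#' @param n_syn,n_nonsyn Requested substitution counts.
#' @param seed Integer seed.
#' @return List with `cds_a`, `cds_b` (strings) and `truth` (tibble
#'   `codon`, `pos_in_codon`, `from`, `to`, `synonymous`).
#' @examples
#' p <- evolve_cds_pair(100, n_syn = 5, n_nonsyn = 0, seed = 1)
#' identical(translate_cds(p$cds_a), translate_cds(p$cds_b))
#' @export
evolve_cds_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L) {
  stopifnot(n_codons >= 1, n_syn >= 0, n_nonsyn >= 0)
  if (n_syn + n_nonsyn > n_codons) {
    abort("Requested more substitutions than codons (one change per codon)")
  }
  with_seed_local(seed, {
    codons_a <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    neighbors <- lapply(codons_a, codon_neighbors)
    has_syn <- vapply(neighbors, function(nb)
      any(vapply(nb, function(x) x$synonymous && !x$stop, logical(1))),
      logical(1))
    has_nonsyn <- vapply(neighbors, function(nb)
      any(vapply(nb, function(x) !x$synonymous && !x$stop, logical(1))),
      logical(1))
    syn_pool <- which(has_syn)
    if (length(syn_pool) < n_syn) {
      abort("Infeasible: not enough codons with a synonymous neighbor")
    }
    syn_sites <- if (n_syn > 0) sort(sample(syn_pool, n_syn)) else integer(0)
    nonsyn_pool <- setdiff(which(has_nonsyn), syn_sites)
    if (length(nonsyn_pool) < n_nonsyn) {
      abort("Infeasible: not enough codons with a nonsynonymous neighbor")
    }
    nonsyn_sites <- if (n_nonsyn > 0) sort(sample(nonsyn_pool, n_nonsyn))
      else integer(0)
    codons_b <- codons_a
    truth <- list()
    apply_change <- function(site, want_syn) {
      nb <- neighbors[[site]]
      ok <- Filter(function(x) x$synonymous == want_syn && !x$stop, nb)
      pick <- ok[[sample(length(ok), 1)]]
      codons_b[site] <<- pick$codon
      truth[[length(truth) + 1L]] <<- tibble(
        codon = site, pos_in_codon = pick$pos,
        from = codons_a[site], to = pick$codon, synonymous = want_syn
      )
    }
    for (s in syn_sites) apply_change(s, TRUE)
    for (s in nonsyn_sites) apply_change(s, FALSE)
    truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
      tibble(codon = integer(), pos_in_codon = integer(),
             from = character(), to = character(), synonymous = logical())
    list(cds_a = paste(codons_a, collapse = ""),
         cds_b = paste(codons_b, collapse = ""),
         truth = truth_tbl)
  })
}
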