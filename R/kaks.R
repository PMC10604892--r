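# Nei-Gojobori (NG86) Ka/Ks estimation on codon alignments.
#
# Site counting: for each codon position, the synonymous-site fraction is
# the share of synonymous changes among the single-nucleotide changes that
# do not create a stop codon; each position contributes exactly one site
# split between S and N, so S + N equals the nucleotide length. Site
# counts are averaged over the two sequences. Difference counting: codons
# differing at k positions are resolved over all k! minimal mutational
# pathways; pathways passing through a stop codon are excluded (if every
# pathway is blocked, all are used). Proportions are corrected with the
# Jukes-Cantor formula K = -(3/4) ln(1 - 4p/3).

ng_env <- new.env(parent = emptyenv())

# per-codon synonymous site count (sum over 3 positions of syn fraction)
ng_syn_sites <- function(codon) {
  if (is.null(ng_env$sites)) {
    ng_env$sites <- vapply(SENSE_CODONS, function(cd) {
      nb <- codon_neighbors(cd)
      s <- 0
      for (pos in 1:3) {
        at <- Filter(function(x) x$pos == pos && !x$stop, nb)
        if (length(at) == 0) next  # position contributes a full N site
        s <- s + sum(vapply(at, function(x) x$synonymous, logical(1))) /
          length(at)
      }
      s
    }, numeric(1))
  }
  ng_env$sites[codon]
}

# pathway-averaged (syn, nonsyn) difference counts for one codon pair
ng_codon_differences <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  perms <- list(
    list(1L), list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )[[k]]
  walk <- function(order) {
    cur <- a
    syn <- 0; nonsyn <- 0
    for (step in order) {
      nxt <- cur
      pos <- diff_pos[step]
      nxt[pos] <- b[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (to %in% STOP_CODONS) return(NULL)
      if (identical(translate_codon(from), translate_codon(to))) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- lapply(perms, walk)
  valid <- Filter(Negate(is.null), paths)
  if (length(valid) == 0) {
    # all minimal pathways pass through a stop: fall back to all pathways
    valid <- lapply(perms, function(order) {
      cur <- a; syn <- 0; nonsyn <- 0
      for (step in order) {
        nxt <- cur
        pos <- diff_pos[step]
        nxt[pos] <- b[pos]
        same <- identical(translate_codon(paste(cur, collapse = "")),
                          translate_codon(paste(nxt, collapse = "")))
        if (isTRUE(same)) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  Reduce(`+`, valid) / length(valid)
}

jukes_cantor <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

validate_codon_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE)) {
    abort("Codon alignment must be gapless")
  }
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("Codon alignment sequences differ in length")
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS)) {
    abort("Codon alignment contains an internal stop codon")
  }
  list(a = ca, b = cb)
}

#' Nei-Gojobori Ka/Ks estimation for a codon-aligned sequence pair
#'
#' @param cds_a,cds_b Gapless, same-length coding sequences (no internal
#'   stops), e.g. from [project_codon_alignment()] or
#'   [evolve_cds_pair()].
#' @return An object of class `qzfp_kaks`: a list with fractional site
#'   counts `S`, `N` (summing to the nucleotide length), pathway-averaged
#'   difference counts `Sd`, `Nd`, proportions `ps`, `pn`, Jukes-Cantor
#'   corrected rates `Ks`, `Ka`, their `ratio` (NA when `Ks` is 0 or a
#'   proportion is >= 3/4, flagged `undefined`), and `selection_class`.
#'   Use [generics::tidy()] for a one-row tibble.
#' @examples
#' p <- evolve_cds_pair(100, n_syn = 6, n_nonsyn = 3, seed = 2)
#' nei_gojobori(p$cds_a, p$cds_b)
#' @export
nei_gojobori <- function(cds_a, cds_b) {
  pair <- validate_codon_pair(cds_a, cds_b)
  S <- (sum(ng_syn_sites(pair$a)) + sum(ng_syn_sites(pair$b))) / 2
  len <- 3 * length(pair$a)
  N <- len - S
  diffs <- vapply(seq_along(pair$a), function(i) {
    ng_codon_differences(pair$a[i], pair$b[i])
  }, numeric(2))
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  ps <- Sd / S
  pn <- Nd / N
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  undefined <- is.na(Ks) || is.na(Ka)
  ratio <- if (!undefined && Ks > 0) Ka / Ks else NA_real_
  out <- structure(list(
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    Ks = Ks, Ka = Ka, ratio = ratio,
    selection_class = if (undefined) "undefined" else
      classify_selection(ratio = ratio, Ks = Ks)
  ), class = "qzfp_kaks")
  out
}

#' Selection-class interpretation of a Ka/Ks ratio
#'
#' Ratios above 1 indicate positive selection, below 1 purifying
#' selection, and ratios within `tolerance` of 1 neutral evolution; a zero
#' synonymous rate leaves the ratio undefined.
#'
#' @param result A `qzfp_kaks` object (alternative to `ratio`/`Ks`).
#' @param ratio,Ks Ka/Ks ratio and synonymous rate, if no `result` given.
#' @param tolerance Half-width of the neutrality band around 1.
#' @return `"positive"`, `"neutral"`, `"purifying"` or `"undefined"`.
#' @examples
#' classify_selection(ratio = 0.1419, Ks = 0.2)
#' @export
classify_selection <- function(result = NULL, ratio = NULL, Ks = NULL,
                               tolerance = 1e-9) {
  if (!is.null(result)) {
    ratio <- result$ratio
    Ks <- result$Ks
  }
  if (!is.null(Ks) && (is.na(Ks) || Ks == 0)) return("undefined")
  if (is.null(ratio) || is.na(ratio)) return("undefined")
  if (abs(ratio - 1) <= tolerance) return("neutral")
  if (ratio > 1) "positive" else "purifying"
}

#' @export
print.qzfp_kaks <- function(x, ...) {
  cat("Nei-Gojobori Ka/Ks estimate\n")
  cat(sprintf("  sites:       S = %.3f, N = %.3f\n", x$S, x$N))
  cat(sprintf("  differences: Sd = %.3f, Nd = %.3f\n", x$Sd, x$Nd))
  cat(sprintf("  rates:       Ks = %s, Ka = %s\n",
              format(x$Ks, digits = 5), format(x$Ka, digits = 5)))
  cat(sprintf("  Ka/Ks = %s (%s)\n",
              format(x$ratio, digits = 5), x$selection_class))
  invisible(x)
}

#' Thread a protein alignment back onto its coding sequences
#'
#' Expands each aligned protein column to its codon and drops columns
#' where either sequence has a gap, producing the gapless codon alignment
#' NG86 expects. Each CDS must translate exactly to its ungapped aligned
#' protein.
#'
#' @param protein_a,protein_b Aligned amino-acid strings (with `-` gaps).
#' @param cds_a,cds_b Coding sequences (a trailing stop codon is
#'   tolerated).
#' @return List with gapless `cds_a` and `cds_b` of equal length.
#' @export
project_codon_alignment <- function(protein_a, protein_b, cds_a, cds_b) {
  thread_one <- function(prot, cds, label) {
    aa_aln <- strsplit(toupper(prot), "")[[1]]
    aa_cds <- strsplit(translate_cds(cds), "")[[1]]
    codons <- split_codons(toupper(cds))[seq_along(aa_cds)]
    ungapped <- aa_aln[aa_aln != "-"]
    if (length(ungapped) != length(aa_cds) ||
        any(ungapped != aa_cds)) {
      bad <- which(ungapped != aa_cds)[1] %||% (length(aa_cds) + 1L)
      abort(paste0("CDS ", label, " does not translate to its aligned ",
                   "protein (first discordant codon: ", bad, ")"))
    }
    out <- rep(NA_character_, length(aa_aln))
    out[aa_aln != "-"] <- codons
    out
  }
  ca <- thread_one(protein_a, cds_a, "a")
  cb <- thread_one(protein_b, cds_b, "b")
  if (length(ca) != length(cb)) {
    abort("Aligned proteins differ in length")
  }
  keep <- !is.na(ca) & !is.na(cb)
  list(cds_a = paste(ca[keep], collapse = ""),
       cds_b = paste(cb[keep], collapse = ""))
}
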