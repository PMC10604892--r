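# Sequence-derived protein descriptors: molecular weight, theoretical pI,
# instability index, GRAVY. Conventions follow the ExPASy ProtParam scale:
# average residue masses, Bjellqvist pKa set, Guruprasad dipeptide weights,
# Kyte-Doolittle hydropathy. 'X' residues are excluded from sums (and from
# dipeptide pairs), counted in length, and tallied via attr(x, "n_x").

split_residues <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(res), c(AA_ALPHABET, "X"))
  if (length(bad)) {
    abort(paste0("Sequence contains non-amino-acid characters: ",
                 paste(bad, collapse = ", ")))
  }
  res
}

#' Protein molecular weight (average isotopic)
#'
#' Sum of average residue masses plus one water mass (18.0153 Da). `X`
#' residues are skipped in the sum; their count is attached as attribute
#' `n_x`.
#'
#' @param sequence Amino-acid sequence string.
#' @return Molecular weight in Da.
#' @examples
#' molecular_weight("G")  # 75.0672
#' @export
molecular_weight <- function(sequence) {
  res <- split_residues(sequence)
  if (length(res) == 0) abort("Empty sequence")
  known <- res[res != "X"]
  out <- sum(AA_AVG_MASS[known]) + WATER_MASS
  attr(out, "n_x") <- sum(res == "X")
  out
}

# Net charge of a peptide at a given pH under Henderson-Hasselbalch with
# the packaged Bjellqvist pKa set. Strictly decreasing in pH.
net_charge <- function(residues, ph) {
  counts <- table(factor(residues, levels = AA_ALPHABET))
  pos <- c(Nterm = 1, counts[c("K", "R", "H")])
  names(pos) <- names(PKA_POSITIVE)
  neg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(neg) <- names(PKA_NEGATIVE)
  sum(pos / (1 + 10^(ph - PKA_POSITIVE))) -
    sum(neg / (1 + 10^(PKA_NEGATIVE - ph)))
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge (Henderson-Hasselbalch sum over the termini
#' and the D, E, C, Y, H, K, R side chains, Bjellqvist pKa set) is zero,
#' found by bisection on \[0, 14\] to a tolerance of 1e-4 pH units.
#'
#' @param sequence Amino-acid sequence string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence) {
  res <- split_residues(sequence)
  if (length(res) == 0) abort("Empty sequence")
  res <- res[res != "X"]
  lo <- 0; hi <- 14
  # net charge is strictly monotone decreasing in pH: root is unique
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge(res, mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  (lo + hi) / 2
}

#' Instability index (Guruprasad dipeptide-weight statistic)
#'
#' `(10 / L) * sum(DIWV(x_i, x_{i+1}))` over all consecutive dipeptides,
#' using the published dipeptide instability weight values. Values above 40
#' are conventionally reported "unstable". Dipeptides containing `X` are
#' skipped; `L` counts all residues.
#'
#' @param sequence Amino-acid sequence string of length >= 2.
#' @return Dimensionless instability index.
#' @export
instability_index <- function(sequence) {
  res <- split_residues(sequence)
  if (length(res) < 2) abort("Instability index requires length >= 2")
  a <- res[-length(res)]
  b <- res[-1]
  keep <- a != "X" & b != "X"
  out <- 10 / length(res) * sum(DIWV[cbind(a[keep], b[keep])])
  attr(out, "n_x") <- sum(res == "X")
  out
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues
#' (`X` excluded from both numerator and denominator).
#'
#' @param sequence Amino-acid sequence string.
#' @return GRAVY value in \[-4.5, 4.5\].
#' @export
gravy <- function(sequence) {
  res <- split_residues(sequence)
  if (length(res) == 0) abort("Empty sequence")
  known <- res[res != "X"]
  if (length(known) == 0) abort("Sequence contains only 'X' residues")
  out <- mean(AA_KYTE_DOOLITTLE[known])
  attr(out, "n_x") <- sum(res == "X")
  out
}

#' Physicochemical profile for a set of proteins
#'
#' Computes length, molecular weight, theoretical pI, instability index
#' (with the conventional stable/unstable class at 40) and GRAVY for each
#' record.
#'
#' @param proteins Tibble of protein records (`id`, `sequence`), as from
#'   [read_fasta()].
#' @return A tibble with one row per protein: `id`, `length`, `mw`, `pi`,
#'   `instability`, `stability_class`, `gravy`, `n_x`.
#' @export
physchem_profile <- function(proteins) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    ii <- instability_index(s)
    tibble(
      id = proteins$id[i],
      length = nchar(s),
      mw = as.numeric(molecular_weight(s)),
      pi = isoelectric_point(s),
      instability = as.numeric(ii),
      stability_class = ifelse(ii > INSTABILITY_UNSTABLE_THRESHOLD,
                               "unstable", "stable"),
      gravy = as.numeric(gravy(s)),
      n_x = stringr::str_count(s, "X")
    )
  })
}

#' Group-wise summary of a reference-table field
#'
#' Mean, minimum, maximum and count of a numeric column of the packaged
#' family table, over one domain-count group or over all members. Means of
#' Da-scale fields (`mw`) are truncated (floored) to integer, matching how
#' family-level average weights are conventionally reported.
#'
#' @param fixture Reference table, as from [load_table1()].
#' @param field Column name, e.g. `"mw"`, `"pi"`, `"gravy"`.
#' @param group `"1i"`, `"2i"`, `"3i"`, `"4i"` or `"all"`.
#' @return A one-row tibble: `field`, `group`, `mean`, `min`, `max`, `n`.
#' @examples
#' group_summary_stats(load_table1(), "mw", "2i")
#' @export
group_summary_stats <- function(fixture, field, group = "all") {
  if (!field %in% names(fixture)) {
    abort(paste0("Unknown field: ", field))
  }
  rows <- if (identical(group, "all")) fixture else
    fixture[fixture$group == group, ]
  if (nrow(rows) == 0) abort(paste0("No rows in group ", group))
  x <- rows[[field]]
  m <- mean(x)
  if (identical(field, "mw")) m <- floor(m)
  tibble(field = field, group = group, mean = m,
         min = min(x), max = max(x), n = length(x))
}
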