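# Auxiliary motif annotation: EAR transcriptional-repression motifs
# (LxLxL and DLNx(1-2)P variants) and the L-box protein-interaction motif
# (core EXEXXAXCLXXL). 'x' positions match any residue, including L/D/P
# themselves. All occurrences are reported, overlapping ones included.

# All match start positions of a regex, overlapping occurrences included.
overlapping_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

motif_hits_one <- function(id, seq) {
  pats <- list(
    EAR_LxLxL = list(re = "L.L.L", len = 5L),
    # the two spacer widths are enumerated separately so that both report
    # when a substring supports them at the same start
    EAR_DLNP1 = list(re = "DLN.P", len = 5L, kind = "EAR_DLNP"),
    EAR_DLNP2 = list(re = "DLN..P", len = 6L, kind = "EAR_DLNP"),
    LBOX = list(re = "E.E..A.CL..L", len = 12L)
  )
  purrr::map_dfr(names(pats), function(nm) {
    p <- pats[[nm]]
    st <- overlapping_starts(seq, p$re)
    if (length(st) == 0) return(NULL)
    tibble(protein_id = id, kind = p$kind %||% nm,
           start = st, end = st + p$len - 1L,
           match = substring(seq, st, st + p$len - 1L))
  })
}

#' Find EAR repression motifs (LxLxL and DLNx(1-2)P variants)
#'
#' @param proteins Tibble of protein records (`id`, `sequence`) or a named
#'   character vector of sequences.
#' @return Tibble of hits: `protein_id`, `kind` (`"EAR_LxLxL"` or
#'   `"EAR_DLNP"`), `start`, `end` (1-based inclusive), `match`,
#'   `terminal_class` (N-terminal / C-terminal / internal under the
#'   default one-third terminal-fraction rule).
#' @examples
#' find_ear_motifs(c(p = "AALQLGLAA"))
#' @export
find_ear_motifs <- function(proteins) {
  find_protein_motifs(proteins, kinds = c("EAR_LxLxL", "EAR_DLNP"))
}

#' Find L-box motifs (core EXEXXAXCLXXL)
#'
#' @inheritParams find_ear_motifs
#' @return Tibble of hits with the same columns as [find_ear_motifs()],
#'   `kind` fixed to `"LBOX"`.
#' @export
find_lbox <- function(proteins) {
  find_protein_motifs(proteins, kinds = "LBOX")
}

#' Find EAR and L-box motifs in one pass
#'
#' @inheritParams find_ear_motifs
#' @param kinds Motif kinds to report.
#' @param terminal_fraction Fraction of the protein length treated as the
#'   N-/C-terminal region when classifying hit positions.
#' @return Tibble of hits (see [find_ear_motifs()]).
#' @export
find_protein_motifs <- function(proteins,
                                kinds = c("EAR_LxLxL", "EAR_DLNP", "LBOX"),
                                terminal_fraction = 1 / 3) {
  proteins <- as_protein_tbl(proteins)
  hits <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    motif_hits_one(proteins$id[i], toupper(proteins$sequence[i]))
  })
  empty <- tibble(protein_id = character(), kind = character(),
                  start = integer(), end = integer(), match = character(),
                  terminal_class = character())
  if (nrow(hits) == 0) return(empty)
  hits <- dplyr::filter(hits, .data$kind %in% kinds)
  if (nrow(hits) == 0) return(empty)
  lens <- setNames(nchar(proteins$sequence), proteins$id)
  annotate_terminal_class(hits, lens[hits$protein_id],
                          terminal_fraction = terminal_fraction)
}

#' Classify motif hits as N-terminal, C-terminal or internal
#'
#' A hit in a length-`L` protein is C-terminal when it starts in the last
#' `terminal_fraction` of the sequence (start - 1 >= (1 - f) * L in
#' zero-based terms), N-terminal when it ends within the first fraction
#' (end <= f * L), otherwise internal.
#'
#' @param hits Tibble of motif hits with `start` and `end` (1-based
#'   inclusive).
#' @param protein_length Protein length(s), recycled along `hits`.
#' @param terminal_fraction Terminal-region fraction `f` (default 1/3).
#' @return `hits` with a `terminal_class` column added (or replaced).
#' @export
annotate_terminal_class <- function(hits, protein_length,
                                    terminal_fraction = 1 / 3) {
  L <- as.numeric(protein_length)
  if (any(hits$start < 1 | hits$end > L)) {
    abort("Motif hit out of protein bounds")
  }
  f <- terminal_fraction
  dplyr::mutate(
    hits,
    terminal_class = dplyr::case_when(
      (.data$start - 1) >= (1 - f) * L ~ "C-terminal",
      .data$end <= f * L ~ "N-terminal",
      .default = "internal"
    )
  )
}
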