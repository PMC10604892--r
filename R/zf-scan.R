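# Degenerate scanning for the plant Q-type C2H2 zinc-finger scaffold
#
#   C X(a) C X3 F X3 <hexapeptide> X(b) H     a in 2-4, b in 3-5
#
# where the central hexapeptide is the invariant QALGGH (Q-type) or one of
# a configured set of modified variants (M-type). Matches are reported
# left-to-right, non-overlapping; at a given start the shortest spacer
# expansion (smallest a, then smallest b) is preferred, which makes the
# scan deterministic and oracle-checkable.

#' Scanner configuration for the zinc-finger scaffold
#'
#' @param cys_spacer Integer range (length 2) of allowed residues between
#'   the two Cys. The family definition allows 2-4; the stricter screen
#'   used for the 35-member family can be reproduced with `c(2, 2)`.
#' @param his_spacer Integer range of allowed residues between the
#'   hexapeptide's His and the closing His.
#' @param m_types Hexapeptides accepted as M-type (modified QALGGH)
#'   fingers.
#' @param relaxed_m If `TRUE`, any hexapeptide ending in `"LGGH"` (other
#'   than QALGGH itself) is accepted as M-type, superseding `m_types`.
#' @return A list of class `zf_pattern_config`.
#' @export
zf_pattern_config <- function(cys_spacer = c(2L, 4L),
                              his_spacer = c(3L, 5L),
                              m_types = MTYPE_HEXAPEPTIDES,
                              relaxed_m = FALSE) {
  stopifnot(length(cys_spacer) == 2, cys_spacer[1] <= cys_spacer[2],
            cys_spacer[1] >= 0, length(his_spacer) == 2,
            his_spacer[1] <= his_spacer[2], his_spacer[1] >= 0)
  structure(list(cys_spacer = as.integer(cys_spacer),
                 his_spacer = as.integer(his_spacer),
                 m_types = toupper(m_types),
                 relaxed_m = isTRUE(relaxed_m)),
            class = "zf_pattern_config")
}

hexapeptide_class <- function(hex, config) {
  if (hex == QTYPE_HEXAPEPTIDE) return("Q")
  if (config$relaxed_m) {
    if (endsWith(hex, "LGGH")) return("M") else return(NA_character_)
  }
  if (hex %in% config$m_types) return("M")
  NA_character_
}

# Scan one sequence; returns a data frame of hits with 1-based inclusive
# coordinates. Greedy leftmost-first, shortest spacers on ties; the cursor
# jumps past each accepted match so hits never share a residue.
scan_one_sequence <- function(seq, config) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  hits <- list()
  s <- 1L
  min_len <- 16L + config$cys_spacer[1] + config$his_spacer[1]
  while (s <= L - min_len + 1L) {
    found <- NULL
    if (res[s] == "C") {
      for (a in config$cys_spacer[1]:config$cys_spacer[2]) {
        c2 <- s + 1L + a
        f <- c2 + 4L
        h1 <- f + 4L
        if (h1 + 5L > L) break
        if (res[c2] != "C" || res[f] != "F") next
        hex <- paste(res[h1:(h1 + 5L)], collapse = "")
        cls <- hexapeptide_class(hex, config)
        if (is.na(cls)) next
        for (b in config$his_spacer[1]:config$his_spacer[2]) {
          hpos <- h1 + 6L + b
          if (hpos > L) break
          if (res[hpos] == "H") {
            found <- list(start = s, end = hpos, cys_cys_spacer = a,
                          his_his_spacer = b, hexapeptide = hex,
                          zf_class = cls)
            break
          }
        }
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) {
      s <- s + 1L
    } else {
      hits[[length(hits) + 1L]] <- found
      s <- found$end + 1L
    }
  }
  dplyr::bind_rows(hits)
}

#' Scan proteins for Q-type and M-type zinc-finger domains
#'
#' @param proteins Tibble of protein records (`id`, `sequence`), as from
#'   [read_fasta()], or a (optionally named) character vector of sequences.
#' @param config A [zf_pattern_config()].
#' @return Tibble of domain hits: `protein_id`, `start`, `end` (1-based
#'   inclusive), `cys_cys_spacer`, `his_his_spacer`, `hexapeptide`,
#'   `zf_class` (`"Q"` or `"M"`). No match yields zero rows.
#' @examples
#' scan_zf_domains(c(p1 = "CAACSGSFKRSQALGGHRRAH"))
#' @export
scan_zf_domains <- function(proteins, config = zf_pattern_config()) {
  proteins <- as_protein_tbl(proteins)
  empty <- tibble(protein_id = character(), start = integer(),
                  end = integer(), cys_cys_spacer = integer(),
                  his_his_spacer = integer(), hexapeptide = character(),
                  zf_class = character())
  if (nrow(proteins) == 0) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    h <- scan_one_sequence(toupper(proteins$sequence[i]), config)
    if (nrow(h) == 0) return(NULL)
    dplyr::mutate(h, protein_id = proteins$id[i], .before = 1)
  })
  if (nrow(out) == 0) empty else out
}

#' Classify a protein's domain complement into the 1i-4i groups
#'
#' Groups encode the total zinc-finger domain count (1 domain -> `"1i"`,
#' ... 4 -> `"4i"`); family membership requires at least one Q-type
#' (QALGGH) finger, so zero domains or an M-only complement yields
#' `"none"`. More than four domains is recorded as `"other"` and flagged
#' with a warning rather than silently dropped.
#'
#' @param domains Tibble of domain hits for one protein, as returned by
#'   [scan_zf_domains()].
#' @return Group label: `"1i"`, `"2i"`, `"3i"`, `"4i"`, `"other"` or
#'   `"none"`.
#' @export
classify_group <- function(domains) {
  n <- nrow(domains)
  if (n == 0 || sum(domains$zf_class == "Q") == 0) return("none")
  if (n > 4) {
    warn(paste0("Protein with ", n,
                " zinc-finger domains recorded as group 'other'"))
    return("other")
  }
  paste0(n, "i")
}

#' Identify Q-type family members in a proteome
#'
#' Scans every protein and keeps those with at least one Q-type finger,
#' classifying each into its domain-count group.
#'
#' @inheritParams scan_zf_domains
#' @return Tibble ordered by `protein_id`: `protein_id`, `group`, `n_q`,
#'   `n_m`, `n_domains`, and a `domains` list-column of per-protein hit
#'   tibbles.
#' @export
identify_qtype_members <- function(proteins, config = zf_pattern_config()) {
  proteins <- as_protein_tbl(proteins)
  hits <- scan_zf_domains(proteins, config)
  if (nrow(hits) == 0) {
    return(tibble(protein_id = character(), group = character(),
                  n_q = integer(), n_m = integer(), n_domains = integer(),
                  domains = list()))
  }
  out <- hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(d, key) {
      tibble(group = classify_group(d),
             n_q = sum(d$zf_class == "Q"),
             n_m = sum(d$zf_class == "M"),
             n_domains = nrow(d),
             domains = list(d))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$group != "none") |>
    dplyr::arrange(.data$protein_id)
  out
}

# Accept a records tibble or a character vector of sequences.
as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("seq", seq_along(proteins))
    return(tibble(id = ids, sequence = unname(proteins)))
  }
  stopifnot(is.data.frame(proteins),
            all(c("id", "sequence") %in% names(proteins)))
  as_tibble(proteins)
}
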