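# Proteome generator with planted zinc-finger domains and EAR/L-box
# motifs, plus a machine-readable truth table for recovery testing.
#
# Construction guarantees: member linker residues avoid the letters C, F,
# H, L, D, E, so the only substrings matching the scaffold grammar, the
# EAR patterns or the L-box pattern are the planted ones (each planted
# feature contributes its pattern letters exactly once, and features are
# separated by linker runs longer than any pattern). Background proteins
# are uniform over the 20-letter alphabet and rejection-sampled with a
# regex check (independent of the loop-based scanner) until they contain
# no scaffold, EAR or L-box match.

build_zf_domain <- function(zf_class, config) {
  a <- sample(seq(config$cys_spacer_range[1], config$cys_spacer_range[2]), 1)
  b <- sample(seq(config$his_spacer_range[1], config$his_spacer_range[2]), 1)
  hex <- if (zf_class == "Q") QTYPE_HEXAPEPTIDE else
    sample(MTYPE_HEXAPEPTIDES, 1)
  seq <- paste0("C", sample_linker(a), "C", sample_linker(3), "F",
                sample_linker(3), hex, sample_linker(b), "H")
  list(seq = seq, hexapeptide = hex, zf_class = zf_class,
       cys_cys_spacer = a, his_his_spacer = b)
}

build_ear <- function() {
  kind <- sample(c("EAR_LxLxL", "EAR_DLNP"), 1)
  seq <- if (kind == "EAR_LxLxL") {
    paste0("L", sample_linker(1), "L", sample_linker(1), "L")
  } else {
    paste0("DLN", sample_linker(sample(1:2, 1)), "P")
  }
  list(seq = seq, kind = kind)
}

build_lbox <- function() {
  paste0("E", sample_linker(1), "E", sample_linker(2), "A",
         sample_linker(1), "CL", sample_linker(2), "L")
}

scaffold_regex <- function(cys_spacer = c(2, 4), his_spacer = c(3, 5),
                           hexapeptides = c(QTYPE_HEXAPEPTIDE,
                                            MTYPE_HEXAPEPTIDES)) {
  sprintf("C.{%d,%d}C.{3}F.{3}(%s).{%d,%d}H",
          cys_spacer[1], cys_spacer[2],
          paste(hexapeptides, collapse = "|"),
          his_spacer[1], his_spacer[2])
}

#' Generate a synthetic proteome with planted domains and motifs
#'
#' Each family member carries its group's domain complement (1i: one Q
#' finger; 2i: two Q; 3i: two Q + one M; 4i: two Q + two M), an EAR motif
#' in an `ear_fraction` share of members (placed in the C-terminal third),
#' and an L-box in every multi-finger member. Background proteins contain
#' no scaffold, EAR or L-box match by rejection sampling.
#'
#' @param config A [sim_config()].
#' @return A list with `proteins` (tibble `id`, `description`, `sequence`)
#'   and `truth` (tibble `protein_id`, `group`, `feature`, `start`, `end`,
#'   `hexapeptide`, `zf_class` — coordinates 1-based inclusive).
#' @examples
#' sim <- make_proteome(sim_config(seed = 7,
#'   n_members_per_group = c("1i" = 3, "2i" = 2),
#'   n_background_proteins = 5))
#' nrow(sim$proteins)
#' @export
make_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed, make_proteome_impl(config))
}

group_domain_classes <- list(
  "1i" = "Q", "2i" = c("Q", "Q"), "3i" = c("Q", "Q", "M"),
  "4i" = c("Q", "Q", "M", "M")
)

make_proteome_impl <- function(config) {
  pat_cfg <- list(cys_spacer_range = c(2L, 4L), his_spacer_range = c(3L, 5L))
  groups <- rep(names(config$n_members_per_group),
                times = config$n_members_per_group)
  n_mem <- length(groups)
  ear_members <- if (n_mem > 0) {
    sort(sample(n_mem, round(config$ear_fraction * n_mem)))
  } else integer(0)

  proteins <- list()
  truth <- list()
  for (i in seq_len(n_mem)) {
    id <- sprintf("SYN%03d", i)
    classes <- group_domain_classes[[groups[i]]]
    segs <- character(0)
    feats <- list()
    pos <- 0L
    add_linker <- function(n) {
      segs[[length(segs) + 1L]] <<- sample_linker(n)
      pos <<- pos + n
    }
    add_feature <- function(seq, feature, hex = NA_character_,
                            cls = NA_character_) {
      segs[[length(segs) + 1L]] <<- seq
      feats[[length(feats) + 1L]] <<- tibble(
        protein_id = id, group = groups[i], feature = feature,
        start = pos + 1L, end = pos + nchar(seq),
        hexapeptide = hex, zf_class = cls
      )
      pos <<- pos + nchar(seq)
    }
    add_linker(sample(10:25, 1))
    for (cls in classes) {
      dom <- build_zf_domain(cls, pat_cfg)
      add_feature(dom$seq, "zf_domain", dom$hexapeptide, dom$zf_class)
      add_linker(sample(8:20, 1))
    }
    if (length(classes) >= 2) {
      add_feature(build_lbox(), "LBOX")
      add_linker(sample(8:20, 1))
    }
    if (i %in% ear_members) {
      ear <- build_ear()
      add_feature(ear$seq, ear$kind)
      add_linker(sample(5:12, 1))
    }
    seq <- paste(unlist(segs), collapse = "")
    if (!is.null(config$member_length)) {
      if (nchar(seq) > config$member_length) {
        abort(paste0("member_length ", config$member_length,
                     " too short for the requested features of ", id,
                     " (needs >= ", nchar(seq), ")"))
      }
      seq <- paste0(seq, sample_linker(config$member_length - nchar(seq)))
    }
    proteins[[length(proteins) + 1L]] <- tibble(
      id = id, description = paste0("synthetic family member group ",
                                    groups[i]),
      sequence = seq
    )
    truth <- c(truth, feats)
  }

  # background: uniform 20-aa, rejection-sampled against all patterns
  reject_re <- paste0("(", scaffold_regex(), ")|(L.L.L)|(DLN.{1,2}P)",
                      "|(E.E..A.CL..L)")
  for (i in seq_len(config$n_background_proteins)) {
    repeat {
      seq <- paste(sample(AA_ALPHABET, sample(150:350, 1), replace = TRUE),
                   collapse = "")
      if (!grepl(reject_re, seq, perl = TRUE)) break
    }
    proteins[[length(proteins) + 1L]] <- tibble(
      id = sprintf("BG%03d", i), description = "synthetic background",
      sequence = seq
    )
  }

  truth_tbl <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(protein_id = character(), group = character(),
           feature = character(), start = integer(), end = integer(),
           hexapeptide = character(), zf_class = character())
  prot_tbl <- if (length(proteins)) dplyr::bind_rows(proteins) else
    tibble(id = character(), description = character(),
           sequence = character())
  list(proteins = prot_tbl, truth = truth_tbl)
}
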