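TABLE1_MD5 <- "5feebe6a787425eae4b9c10d356bc48c"

#' Load the packaged reference table of the 35 sugar beet family members
#'
#' Returns the published per-member table for the Q-type C2H2 ZFP family of
#' sugar beet (*Beta vulgaris*): gene name, locus id, protein length, ORF
#' length, molecular weight (Da), theoretical pI, instability index, GRAVY,
#' genomic coordinates and domain-count group (1i-4i). The packaged file is
#' checksum-verified and its structural invariants (35 rows, ORF bp equal
#' to three times the amino-acid length, groups within 1i-4i) are enforced
#' at load time.
#'
#' @return A tibble with 35 rows and columns `gene_name`, `locus_id`,
#'   `aa_length`, `orf_bp`, `mw`, `pi`, `instability`, `gravy`, `start`,
#'   `end`, `group`.
#' @examples
#' tb <- load_table1()
#' dplyr::count(tb, group)
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_bvzfp.tsv", package = "qzfp",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != TABLE1_MD5) {
    abort("Packaged reference table failed its integrity checksum")
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          gene_name = "c", locus_id = "c", aa_length = "i",
                          orf_bp = "i", mw = "d", pi = "d", instability = "d",
                          gravy = "d", start = "d", end = "d", group = "c"
                        ))
  if (nrow(tb) != 35) abort("Reference table must have exactly 35 rows")
  if (!all(tb$orf_bp == 3L * tb$aa_length)) {
    abort("Reference table violates orf_bp == 3 * aa_length")
  }
  if (!all(tb$group %in% c("1i", "2i", "3i", "4i"))) {
    abort("Reference table contains an unknown group label")
  }
  tb
}
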