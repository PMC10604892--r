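#' Default cis-element dictionary
#'
#' A small curated table of promoter cis-acting elements with IUPAC
#' consensi and functional categories (hormone, abiotic stress, biotic
#' stress, development, other). The consensi are curated defaults chosen
#' for this package — element names follow common plant-promoter usage,
#' but the table is fully overridable and is a required input whenever a
#' specific dictionary matters. Every default consensus contains at least
#' one G or T, which the synthetic-genome generator exploits to guarantee
#' planted-only matches against its A/C promoter background.
#'
#' @return Tibble with columns `element_name`, `consensus`, `category`.
#' @export
default_cis_elements <- function() {
  tibble::tribble(
    ~element_name,  ~consensus,   ~category,
    "ABRE",         "ACGTG",      "hormone",
    "TGACG-motif",  "TGACG",      "hormone",
    "TGA-element",  "AACGAC",     "hormone",
    "TATC-box",     "TATCCCA",    "hormone",
    "TCA-element",  "CCATCTTTTT", "hormone",
    "LTR",          "CCGAAA",     "abiotic_stress",
    "MBS",          "CAACTG",     "abiotic_stress",
    "W-box",        "TTGACC",     "biotic_stress",
    "CAT-box",      "GCCACT",     "development",
    "O2-site",      "GATGACATGG", "other"
  )
}

validate_cis_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("element_name", "consensus", "category") %in% names(table)))
  if (anyDuplicated(table$element_name)) {
    abort("Cis-element table has duplicate element names")
  }
  for (i in seq_len(nrow(table))) {
    chars <- unique(strsplit(toupper(table$consensus[i]), "")[[1]])
    bad <- setdiff(chars, names(IUPAC_NT))
    if (length(bad)) {
      abort(paste0("Element '", table$element_name[i],
                   "' has invalid IUPAC code(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(table)
}
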