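#' Read a FASTA file into a tibble of sequence records
#'
#' Parses protein or nucleotide FASTA. Sequences are uppercased and all
#' whitespace is stripped; a record wrapped over several lines becomes one
#' concatenated sequence. The first whitespace-delimited token of each
#' header is the record id, the remainder its description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, one row
#'   per record, in file order. An empty file yields a zero-row tibble.
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MKV", "QALGGH"), faa)
#' read_fasta(faa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  # Validation pass: report malformed headers / empty sequences by line.
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) {
    return(tibble(id = character(), description = character(),
                  sequence = character()))
  }
  if (!startsWith(trimws(lines[meaningful[1]]), ">")) {
    abort(paste0("Malformed FASTA: line ", meaningful[1],
                 " is not a header (expected '>')"))
  }
  header_lines <- meaningful[startsWith(trimws(lines[meaningful]), ">")]
  next_line <- c(header_lines[-1], length(lines) + 1L)
  for (k in seq_along(header_lines)) {
    body <- lines[seq2(header_lines[k] + 1L, next_line[k] - 1L)]
    if (!any(nzchar(gsub("\\s", "", body)))) {
      abort(paste0("Malformed FASTA: record at line ", header_lines[k],
                   " has an empty sequence"))
    }
    if (!nzchar(sub("^>", "", trimws(lines[header_lines[k]])))) {
      abort(paste0("Malformed FASTA: empty header at line ", header_lines[k]))
    }
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    abort(paste0("Duplicate record ids in ", path, ": ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  tibble(
    id = id,
    description = description,
    sequence = unname(toupper(gsub("\\s", "", as.character(set))))
  )
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`, as produced by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# seq_len-style helper that returns integer(0) when from > to
seq2 <- function(from, to) {
  if (from > to) integer(0) else seq.int(from, to)
}
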