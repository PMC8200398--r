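#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a tibble of protein
#' records. Sequences are upcased before validation and must contain only
#' the 20 canonical one-letter amino-acid codes: ambiguity letters (B, J,
#' O, U, X, Z), gaps and whitespace are rejected, so that downstream
#' cleavage semantics are never ambiguous.
#'
#' The record id is the first whitespace-delimited token after `>`;
#' anything after it becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, one row
#'   per record, in file order.
#' @export
#' @examples
#' lectin <- read_fasta(tp_file("lectin_6tt9.fasta"))
#' nchar(lectin$sequence)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "tp_missing_input")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort("no records in FASTA input", class = "tp_validation")
  }
  headers <- str_trim(names(set))
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(
    grepl("\\s", headers),
    str_trim(sub("^\\S+\\s+", "", headers)),
    ""
  )
  sequence <- toupper(as.character(set))
  check_protein_alphabet(sequence, ids = id)
  tibble(id = id, description = description, sequence = unname(sequence))
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces
#' `x` exactly. Records are validated before writing.
#'
#' @param records A data frame with columns `id`, `description`, `sequence`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    abort("no records to write", class = "tp_validation")
  }
  if (!all(c("id", "sequence") %in% names(records))) {
    abort("records must have 'id' and 'sequence' columns", class = "tp_validation")
  }
  check_protein_alphabet(records$sequence, ids = records$id)
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' The bundled tepary-bean lectin record
#'
#' Reads the packaged sequence of the recombinant *Phaseolus acutifolius*
#' seed lectin construct (PDB entry 6TT9; 255 residues including the
#' leading EAEA propeptide remnant and a C-terminal His tag). This is the
#' substrate the default analysis pipeline digests.
#'
#' @return A one-row tibble as returned by [read_fasta()].
#' @export
#' @examples
#' lectin_record()
lectin_record <- function() {
  read_fasta(tp_file("lectin_6tt9.fasta"))
}
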