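# Sequence sets are plain tibbles: one row per sequence, columns
# id / description / accession / residues.  Every front-line function in the
# package takes such a tibble first, so calls chain with the pipe.

#' Construct a sequence set
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of IUPAC DNA strings (case-insensitive;
#'   stored uppercase, RNA `U` mapped to `T`).
#' @param description Optional free-text descriptions.
#' @param accession Optional NCBI accessions.
#' @return A tibble with columns `id`, `description`, `accession`, `residues`.
#' @examples
#' sequence_set(c("a", "b"), c("ACGT", "ggcc"))
#' @export
sequence_set <- function(id, residues, description = "", accession = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    abort("sequence ids must be unique within a set", class = "ardra_data_error")
  }
  residues <- normalize_residues(as.character(residues), id = id)
  tibble(
    id = id,
    description = rep_len(as.character(description), length(id)),
    accession = rep_len(as.character(accession), length(id)),
    residues = residues
  )
}

# Coerce user input (tibble, data frame, named/unnamed character vector) to a
# validated sequence-set tibble.
as_sequence_set <- function(x, arg = "seqs") {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(sequence_set(ids, x))
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "residues") %in% names(x))) {
      abort(sprintf("`%s` needs columns 'id' and 'residues'", arg),
            class = "ardra_data_error")
    }
    desc <- if ("description" %in% names(x)) x$description else ""
    acc <- if ("accession" %in% names(x)) x$accession else NA_character_
    if (nrow(x) == 0L) {
      return(tibble(id = character(), description = character(),
                    accession = character(), residues = character()))
    }
    return(sequence_set(x$id, x$residues, desc, acc))
  }
  abort(sprintf("`%s` must be a data frame or character vector", arg),
        class = "ardra_data_error")
}

#' Read a FASTA file
#'
#' One row per record; the header token before the first whitespace becomes
#' the `id`, the remainder the `description`.  Residues are normalized to
#' uppercase DNA (`U` mapped to `T`); any non-IUPAC character is an error
#' naming the record and position.  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A sequence-set tibble (see [sequence_set()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ardra_data_error")
  }
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("no records in FASTA file: ", path),
                              class = "ardra_data_error")
  )
  if (length(recs) == 0L) {
    abort(paste0("no records in FASTA file: ", path), class = "ardra_data_error")
  }
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  sequence_set(ids, as.character(recs), description = desc)
}

#' Write a sequence set to FASTA
#'
#' @param seqs A sequence-set tibble (or named character vector).
#' @param path Output path.
#' @param width Positive line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_sequence_set(seqs)
  if (nrow(seqs) == 0L) {
    abort("cannot write an empty sequence set", class = "ardra_data_error")
  }
  stopifnot(is.numeric(width), width >= 1)
  x <- Biostrings::DNAStringSet(seqs$residues)
  names(x) <- ifelse(nzchar(seqs$description) & !is.na(seqs$description),
                     paste(seqs$id, seqs$description), seqs$id)
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Fetch nucleotide records from NCBI by accession (network helper)
#'
#' Thin, separately-invoked convenience around NCBI EFetch that writes a
#' standard FASTA file to disk; every core operation in the package takes
#' files or in-memory sets only and never touches the network.
#'
#' @param accessions Character vector of NCBI nucleotide accessions.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
fetch_ncbi_fasta <- function(accessions, path) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=fasta&retmode=text&id=",
    paste(accessions, collapse = ",")
  )
  utils::download.file(url, path, quiet = TRUE, mode = "wb")
  invisible(path)
}
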