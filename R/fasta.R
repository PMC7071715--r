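#' Read protein records from a FASTA file
#'
#' Sequences are uppercased and a single trailing stop character (`*`) is
#' stripped. The first whitespace-delimited token of each header is the
#' record id; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `sequence`, `description`, one row
#'   per record in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (any(grepl("[-.]", seqs))) {
    stop("gap characters found in FASTA sequences; use read_seed_alignment() for alignments")
  }
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records A data.frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
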