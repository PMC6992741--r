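# Readers and writers for the interchange formats: the long-format tool
# output table, interaction tables, FASTA sequences and metric reports.

#' Read the long-format tool output table
#'
#' The interchange format is a TSV with header
#' `mirna_id, target_id, tool, field, value` — one row per (pair, tool,
#' field). The long format means a new tool or field needs no schema
#' change. Tool names are validated against [supported_tools()].
#'
#' @param path TSV file path. Lines starting with `#` are comments.
#' @return Data.frame with the five character columns.
#' @export
read_tool_table <- function(path) {
  need <- c("mirna_id", "target_id", "tool", "field", "value")
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  bad <- which(!is.na(nf) & nf != 5)
  if (length(bad) > 0)
    stop("malformed tool-table row at line ", bad[1], " of ", path,
         ": expected 5 tab-separated fields, found ", nf[bad[1]])
  tt <- utils::read.delim(path, colClasses = "character",
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (!identical(names(tt), need))
    stop("tool table must have header: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tt$tool), supported_tools())
  if (length(unknown) > 0)
    stop("unknown tool(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(supported_tools(), collapse = ", "))
  tt
}

#' @rdname read_tool_table
#' @param tool_table Data.frame in the interchange layout.
#' @param header Optional comment lines written with a leading `# `.
#' @export
write_tool_table <- function(tool_table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(tool_table[, c("mirna_id", "target_id", "tool",
                                    "field", "value")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labelled interaction table
#'
#' TSV with columns `mirna_id, target_id, label, energy_kcal_mol` (energy
#' optional on read).
#'
#' @param path File path.
#' @return Data.frame with `mirna_id`, `target_id`, `label` and, when
#'   present, `energy`.
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", quote = "",
                         stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "target_id") %in% names(d)))
    stop("interaction table needs mirna_id and target_id columns")
  if ("energy_kcal_mol" %in% names(d)) {
    d$energy <- as.numeric(d$energy_kcal_mol)
    d$energy_kcal_mol <- NULL
  }
  d
}

#' @rdname read_interactions
#' @param interactions Data.frame with `mirna_id`, `target_id` and
#'   optionally `label`, `energy`.
#' @param header Optional comment lines.
#' @export
write_interactions <- function(interactions, path, header = NULL) {
  out <- interactions
  if ("energy" %in% names(out)) {
    out$energy_kcal_mol <- out$energy
    out$energy <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' IDs are the first whitespace-delimited token of each header; sequences
#' are uppercased with T mapped to U, so DNA-alphabet files are accepted
#' transparently.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- chartr("T", "U", toupper(as.character(set)))
  if (any(nchar(seqs) == 0)) stop("empty FASTA record: ",
                                  ids[nchar(seqs) == 0][1])
  stats::setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
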