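# File interfaces. Tab-separated everywhere (ids may contain commas in the
# wild); FASTA via Biostrings; '#' comment lines and blank lines are skipped
# in all TSV inputs.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, col_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", blank.lines.skip = TRUE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(col_names, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  df
}

#' Read domain sequences from a FASTA file
#'
#' Headers are parsed up to the first whitespace as the domain id; wrapped
#' and unwrapped sequence lines, LF and CRLF line endings are all accepted.
#' Lowercase residues are uppercased. Duplicate ids and empty records are
#' errors.
#'
#' @param path FASTA file
#' @return named list of [domain_sequence()] objects, in file order
#' @export
read_fasta_domains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop(path, ": record with empty header")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(path, ": duplicate domain id '", dup[1L], "'")
  seqs <- toupper(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop(path, ": empty record '", ids[empty[1L]], "'")
  stats::setNames(Map(domain_sequence, ids, unname(seqs)), ids)
}

#' Write domain sequences as FASTA (60-column wrapped)
#' @param sequences named list of `domain_sequence` objects
#' @param path output file
#' @export
write_fasta_domains <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sequences) {
    writeLines(paste0(">", s$domain_id), con)
    sq <- s$sequence
    starts <- seq(1L, nchar(sq), by = 60L)
    writeLines(substring(sq, starts, pmin(starts + 59L, nchar(sq))), con)
  }
  invisible(path)
}

#' Read a pair table (2 or 3 tab-separated columns)
#'
#' Columns: `id_a`, `id_b`, optional `label` in {0, 1}. A bad label value is
#' an error naming its (data) line number.
#'
#' @param path TSV file
#' @return data frame with `id_a`, `id_b` (+ `label` when present)
#' @export
read_pair_table <- function(path) {
  df <- .read_tsv(path, c("id_a", "id_b"))
  if ("label" %in% names(df)) {
    bad <- which(!df$label %in% c(0L, 1L))
    if (length(bad))
      stop(path, ": bad label '", df$label[bad[1L]], "' at data row ",
           bad[1L], " (must be 0 or 1)")
    df$label <- as.integer(df$label)
  }
  df
}

#' Read a protein architecture table
#'
#' Columns: `protein_id`, `domain_ids` (comma-separated, ordered).
#'
#' @param path TSV file
#' @return named list of [protein_record()] objects
#' @export
read_architecture_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "domain_ids"))
  if (anyDuplicated(df$protein_id))
    stop(path, ": duplicate protein id")
  recs <- Map(function(p, d)
    protein_record(p, strsplit(d, ",", fixed = TRUE)[[1L]]),
    df$protein_id, df$domain_ids)
  stats::setNames(recs, df$protein_id)
}

#' Read a per-domain location annotation table
#'
#' Columns: `domain_id`, `location` (one of the ten categories of
#' [location_codes()], case-insensitive). The encoded `location_code` column
#' is added.
#'
#' @param path TSV file
#' @return data frame with `domain_id`, `location`, `location_code`
#' @export
read_location_table <- function(path) {
  df <- .read_tsv(path, c("domain_id", "location"))
  df$location_code <- encode_location(df$location)
  df
}

#' Read a domain-pair interaction-score table
#'
#' Columns: `id_a`, `id_b`, `lambda` (> 0). Builds a [score_table()]; see
#' there for the background-score rule.
#'
#' @param path TSV file
#' @param ... passed to [score_table()] (`background_score`,
#'   `interaction_cutoff`)
#' @return a `score_table`
#' @export
read_score_table <- function(path, ...) {
  df <- .read_tsv(path, c("id_a", "id_b", "lambda"))
  df$lambda <- as.numeric(df$lambda)
  score_table(df, ...)
}

#' Write a score table back to TSV
#'
#' A comment header records `s_max` and the background score after loading.
#' @param table a `score_table`
#' @param path output file
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# s_max=%.6g background_score=%.6g", table$s_max,
                     table$background_score), con)
  key <- strsplit(names(table$lambda), "\r", fixed = TRUE)
  df <- data.frame(id_a = vapply(key, `[`, character(1L), 1L),
                   id_b = vapply(key, `[`, character(1L), 2L),
                   lambda = sprintf("%.6g", unname(table$lambda)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
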