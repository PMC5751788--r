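#' Read a nucleotide FASTA file
#'
#' Parses a multi-record FASTA file into a record table. Residues are
#' uppercased; line breaks inside sequences are removed; record order is
#' preserved. The header is split at the first whitespace into an `id`
#' (never empty) and a free-text `desc` (possibly empty).
#'
#' @param path Path to a FASTA file. Must exist, be non-empty, and start
#'   with a `>` header.
#' @return A `data.frame` with character columns `id`, `desc`, `seq`, one
#'   row per record, in file order.
#' @details Errors are classed so they can be told apart programmatically:
#'   `dualseg_error_missing_file`, `dualseg_error_empty_fasta`,
#'   `dualseg_error_leading_garbage` (content before the first `>`), and
#'   `dualseg_error_empty_sequence` (a header with no residues).
#' @seealso [write_fasta()], [split_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    dseg_stop(sprintf("FASTA file not found: %s", path),
              "dualseg_error_missing_file")
  if (file.size(path) == 0)
    dseg_stop(sprintf("FASTA file is empty: %s", path),
              "dualseg_error_empty_fasta")
  first <- readChar(path, 1L, useBytes = TRUE)
  if (!identical(first, ">"))
    dseg_stop(sprintf("content before first '>' header in %s", path),
              "dualseg_error_leading_garbage")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0)
    dseg_stop(sprintf("no records in %s", path), "dualseg_error_empty_fasta")
  if (any(Biostrings::width(set) == 0)) {
    bad <- names(set)[Biostrings::width(set) == 0][1]
    dseg_stop(sprintf("record with empty sequence in %s: '%s'", path, bad),
              "dualseg_error_empty_sequence")
  }
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  data.frame(id = id, desc = desc,
             seq = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

fasta_check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "desc", "seq") %in% names(records)))
    dseg_stop("records must be a data.frame with columns id, desc, seq",
              "dualseg_error_bad_records")
  if (nrow(records) == 0)
    dseg_stop("record set is empty", "dualseg_error_no_records")
  if (any(records$id == "" | grepl("\\s", records$id)))
    dseg_stop("record ids must be non-empty and whitespace-free",
              "dualseg_error_bad_records")
  if (any(nchar(records$seq) == 0))
    dseg_stop("records must have non-empty sequences",
              "dualseg_error_empty_sequence")
  invisible(records)
}

#' Write records to a FASTA file
#'
#' Writes standard FASTA: header `>id desc` (no trailing space when the
#' description is empty), sequence wrapped at 60 columns.
#'
#' @param records Record `data.frame` as returned by [read_fasta()].
#' @param path Output file path.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(records, path) {
  fasta_check_records(records)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(records$desc == "", records$id,
                       paste(records$id, records$desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(nrow(records))
}

# Serialized FASTA byte length of each record (header + wrapped sequence,
# one byte per newline). This is the size used for greedy chunk packing so
# that chunk files on disk respect the byte budget exactly.
record_bytes <- function(records) {
  header <- 1L + nchar(records$id, type = "bytes") +
    ifelse(records$desc == "", 0L, 1L + nchar(records$desc, type = "bytes")) + 1L
  len <- nchar(records$seq, type = "bytes")
  header + len + ceiling(len / 60)
}

#' Split a FASTA file into record-preserving chunks of bounded size
#'
#' Records are appended in source order to the current chunk; a record
#' whose serialized FASTA size would push the chunk past `max_chunk_bytes`
#' starts a new chunk. A single record larger than `max_chunk_bytes`
#' occupies a chunk alone. Chunk files are named `<prefix>_1` ...
#' `<prefix>_M` (1-based, no gaps), mirroring array-job chunk naming.
#'
#' @param path Source FASTA file.
#' @param max_chunk_bytes Maximum chunk file size in bytes (>= 1).
#' @param out_dir Output directory (created if needed).
#' @param prefix Chunk file name prefix token.
#' @return A `split_manifest` object: list with `source_path`,
#'   `chunk_count`, `chunk_paths`, `chunk_record_counts`, `chunk_bytes`,
#'   `max_chunk_bytes`. A plain-text sidecar `<prefix>.manifest` is also
#'   written next to the chunks (one line per chunk: index, path, record
#'   count, byte size) so verification can run without re-reading chunks.
#' @export
split_fasta <- function(path, max_chunk_bytes, out_dir, prefix) {
  stopifnot(length(max_chunk_bytes) == 1, max_chunk_bytes >= 1)
  records <- read_fasta(path)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    dseg_stop(sprintf("cannot create output directory %s", out_dir),
              "dualseg_error_unwritable")
  sizes <- record_bytes(records)
  chunk_of <- integer(nrow(records))
  cur_chunk <- 1L; cur_bytes <- 0
  for (i in seq_len(nrow(records))) {
    if (cur_bytes > 0 && cur_bytes + sizes[i] > max_chunk_bytes) {
      cur_chunk <- cur_chunk + 1L
      cur_bytes <- 0
    }
    chunk_of[i] <- cur_chunk
    cur_bytes <- cur_bytes + sizes[i]
  }
  m <- cur_chunk
  paths <- file.path(out_dir, paste0(prefix, "_", seq_len(m)))
  counts <- integer(m); bytes <- numeric(m)
  for (k in seq_len(m)) {
    sel <- chunk_of == k
    write_fasta(records[sel, , drop = FALSE], paths[k])
    counts[k] <- sum(sel)
    bytes[k] <- sum(sizes[sel])
  }
  manifest <- structure(
    list(source_path = path, chunk_count = m, chunk_paths = paths,
         chunk_record_counts = counts, chunk_bytes = bytes,
         max_chunk_bytes = max_chunk_bytes, prefix = prefix),
    class = "split_manifest")
  sidecar <- file.path(out_dir, paste0(prefix, ".manifest"))
  writeLines(sprintf("%d\t%s\t%d\t%d", seq_len(m), paths, counts,
                     as.integer(bytes)), sidecar)
  manifest
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("FASTA split manifest: %s\n  %d chunk(s), max %d bytes each, %d record(s) total\n",
              x$source_path, x$chunk_count, x$max_chunk_bytes,
              sum(x$chunk_record_counts)))
  invisible(x)
}

#' Database statistics of a FASTA file
#'
#' Counts records and residues. `num_sequences` is the effective number
#' of sequences of the database (the quantity each fragment search needs
#' in order to compute E-values against the full database);
#' `total_length` is the raw residue count summed over all records.
#'
#' @param path FASTA file path.
#' @return A `db_stats` object: list with `num_sequences` and
#'   `total_length`.
#' @export
compute_db_stats <- function(path) {
  records <- read_fasta(path)
  db_stats(nrow(records), sum(nchar(records$seq)))
}

db_stats <- function(num_sequences, total_length) {
  stopifnot(num_sequences >= 1, total_length >= num_sequences)
  structure(list(num_sequences = as.numeric(num_sequences),
                 total_length = as.numeric(total_length)),
            class = "db_stats")
}

#' @export
print.db_stats <- function(x, ...) {
  cat(sprintf("Effective number of sequences in the database is %s; total residue count is %s.\n",
              format(x$num_sequences, big.mark = ","),
              format(x$total_length, big.mark = ",")))
  invisible(x)
}
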