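#' Read sequences from FASTA or FASTQ
#'
#' All sequences are normalized to the RNA alphabet internally (T -> U):
#' catalogs are RNA but sequencers emit DNA, so one representation is
#' enforced at the boundary. Identifiers are kept verbatim (the full
#' header line up to the first whitespace is the id; the remainder is
#' dropped, matching common FASTA usage).
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   missing (`.fq`/`.fastq` -> FASTQ).
#' @param as_rna Convert T to U on read (default `TRUE`).
#' @return Named character vector of sequences, in file order.
#' @export
read_sequences <- function(path, format = NULL, as_rna = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("malformed ", toupper(format), " in ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(utils::head(ids[bad], 3), collapse = ", "), call. = FALSE)
  if (as_rna) seqs <- chartr("T", "U", seqs)
  stats::setNames(seqs, ids)
}

#' Write collapsed tags as FASTA
#'
#' One record per unique sequence, header `tag<N>_x<COUNT>` (the
#' fastx-collapser dialect), so the file round-trips through
#' [read_sequences()] + [parse_count_header()].
#'
#' @param sequences Character vector of unique sequences.
#' @param counts Positive integer counts, one per sequence.
#' @param path Output path.
#' @param ids Optional identifier stems; default `tag1..tagN`.
#' @return Invisibly, the written headers.
#' @export
write_collapsed_fasta <- function(sequences, counts, path, ids = NULL) {
  stopifnot(length(sequences) == length(counts))
  if (length(counts) && (any(counts <= 0) || any(counts != round(counts))))
    stop("counts must be positive integers", call. = FALSE)
  if (is.null(ids)) ids <- paste0("tag", seq_along(sequences))
  headers <- sprintf("%s_x%d", ids, as.integer(counts))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(sequences))
    writeLines(paste0(">", headers, "\n", sequences), con, sep = "\n")
  invisible(headers)
}

#' Parse a collapsed-FASTA count header
#'
#' @param header Header text in the `<id>_x<COUNT>` dialect.
#' @return A list with `id` and integer `count` (vectorized: a data.frame
#'   when more than one header is given).
#' @export
parse_count_header <- function(header) {
  m <- regmatches(header, regexec("^(.*)_x([0-9]+)$", header))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("header(s) lack the '_x<COUNT>' suffix: ",
         paste(utils::head(header[bad], 3), collapse = ", "), call. = FALSE)
  ids <- vapply(m, `[`, "", 2L)
  counts <- as.integer(vapply(m, `[`, "", 3L))
  if (length(header) == 1L) return(list(id = ids, count = counts))
  data.frame(id = ids, count = counts, stringsAsFactors = FALSE)
}

#' Write a report table as TSV
#'
#' UTF-8, header row, tab-separated, `"."` for missing values.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (gene_id, term_id), multiple rows per gene allowed.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene_id`, `term_id`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop("annotation table needs two columns (gene_id, term_id)",
         call. = FALSE)
  names(df)[1:2] <- c("gene_id", "term_id")
  df[, 1:2]
}

# RNA complement (vectorized over a character vector of sequences)
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

# Reverse each sequence in a character vector
reverse_seq <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), "", USE.NAMES = FALSE)
}

#' Reverse complement in the RNA alphabet
#' @param x Character vector of RNA sequences.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) reverse_seq(rna_complement(x))

# Write a plain FASTA (id -> sequence), as DNA or RNA letters
write_fasta <- function(sequences, path, as_dna = FALSE) {
  seqs <- if (as_dna) chartr("U", "T", sequences) else sequences
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  invisible(path)
}

# Write reads as 4-line FASTQ with uniform dummy qualities (DNA letters)
write_fastq <- function(sequences, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(sequences))
  seqs <- chartr("U", "T", sequences)
  quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}
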