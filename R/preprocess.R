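## Raw-read preprocessing: adapter trimming, length/junk filtering,
## contaminant annotation, tag collapsing, and the per-library accounting
## table (raw reads -> valid reads cascade).

CONTAMINANT_CLASSES <- c("rfam:rRNA", "rfam:tRNA", "rfam:snoRNA",
                         "rfam:snRNA", "rfam:other", "mRNA", "repeat")

#' Trim the 3' adapter from reads
#'
#' The insert is the prefix before the leftmost adapter occurrence: a full
#' adapter match anywhere, or a read-terminal partial match of at least
#' `min_overlap` adapter-prefix bases. Reads with no qualifying match are
#' rejected (`NA`), mirroring the removal of reads lacking the 3' adapter.
#'
#' @param reads Character vector of read sequences (RNA alphabet).
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum terminal partial-match length.
#' @return Character vector of inserts; `NA` where the read is rejected.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  if (!nzchar(adapter)) stop("adapter must be nonempty", call. = FALSE)
  adapter <- chartr("T", "U", toupper(adapter))
  out <- rep(NA_character_, length(reads))
  pos <- regexpr(adapter, reads, fixed = TRUE)
  full <- pos > 0L
  out[full] <- substr(reads[full], 1L, pos[full] - 1L)
  todo <- which(!full)
  alen <- nchar(adapter)
  if (length(todo) && alen > min_overlap) {
    for (k in seq(alen - 1L, min_overlap)) {
      if (!length(todo)) break
      hit <- endsWith(reads[todo], substr(adapter, 1L, k))
      idx <- todo[hit]
      out[idx] <- substr(reads[idx], 1L, nchar(reads[idx]) - k)
      todo <- todo[!hit]
    }
  }
  out
}

#' Length and junk filtering of trimmed inserts
#'
#' An insert is removed as `length` when shorter than `min_len` or longer
#' than `max_len`; an in-range insert is removed as `junk` when it
#' contains an N or consists of >= `homopolymer_frac` of a single
#' nucleotide. Anything else is kept.
#'
#' @param inserts Character vector of post-trim inserts.
#' @param cfg A `run_config`.
#' @return Character vector in `{"kept", "removed:length", "removed:junk"}`.
#' @export
quality_filter <- function(inserts, cfg = run_config()) {
  len <- nchar(inserts)
  out <- rep("kept", length(inserts))
  out[len < cfg$min_len | len > cfg$max_len] <- "removed:length"
  inr <- out == "kept"
  if (any(inr)) {
    x <- inserts[inr]
    junk <- grepl("N", x, fixed = TRUE)
    maxbase <- pmax(nchar(x) - nchar(gsub("A", "", x, fixed = TRUE)),
                    nchar(x) - nchar(gsub("C", "", x, fixed = TRUE)),
                    nchar(x) - nchar(gsub("G", "", x, fixed = TRUE)),
                    nchar(x) - nchar(gsub("U", "", x, fixed = TRUE)))
    junk <- junk | (maxbase / nchar(x) >= cfg$homopolymer_frac)
    out[inr][junk] <- "removed:junk"
  }
  out
}

#' Annotate tags against contaminant reference sets
#'
#' A tag matches a class when it is an exact substring of any reference
#' sequence of that class. A single label is assigned by fixed precedence
#' rRNA > tRNA > snoRNA > snRNA > other Rfam > mRNA > repeat > valid, so
#' the class counts partition the tags.
#'
#' @param sequences Character vector of unique tag sequences (RNA).
#' @param references Named list of reference sequence vectors; recognized
#'   names: `rRNA`, `tRNA`, `snoRNA`, `snRNA`, `other`, `mRNA`, `repeat`.
#' @return Character vector of annotations (`"valid"` when nothing hits).
#' @export
annotate_contaminants <- function(sequences, references) {
  ann <- rep("valid", length(sequences))
  if (!length(sequences)) return(ann)
  key <- c(rRNA = "rfam:rRNA", tRNA = "rfam:tRNA", snoRNA = "rfam:snoRNA",
           snRNA = "rfam:snRNA", other = "rfam:other", mRNA = "mRNA",
           "repeat" = "repeat")
  present <- names(key)[vapply(names(key), function(cls)
    !is.null(references[[cls]]) && length(references[[cls]]) > 0, TRUE)]
  if (!length(present)) return(ann)
  subjects <- lapply(present, function(cls)
    Biostrings::DNAStringSet(chartr("U", "T", unname(references[[cls]]))))
  names(subjects) <- present
  ok <- which(!grepl("[^ACGU]", sequences))
  dna <- chartr("U", "T", sequences)
  widths <- nchar(dna)
  for (w in unique(widths[ok])) {
    idx <- ok[widths[ok] == w]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(dna[idx]))
    open <- rep(TRUE, length(idx))
    for (cls in present) {
      if (!any(open)) break
      hits <- rowSums(Biostrings::vcountPDict(pd, subjects[[cls]])) > 0L
      take <- open & hits
      ann[idx[take]] <- key[[cls]]
      open <- open & !hits
    }
  }
  ann
}

#' Collapse inserts into unique tags with per-library counts
#'
#' @param library Character vector of library names, parallel to `insert`.
#' @param insert Character vector of kept insert sequences.
#' @param libraries Optional library-name ordering for the count columns.
#' @return Data frame with `sequence` and one integer count column per
#'   library; the count columns sum to the number of inserts.
#' @export
collapse_tags <- function(library, insert, libraries = NULL) {
  if (is.null(libraries)) libraries <- unique(library)
  if (!length(insert)) {
    out <- data.frame(sequence = character(0), stringsAsFactors = FALSE)
    for (lib in libraries) out[[lib]] <- integer(0)
    return(out)
  }
  tab <- table(factor(insert), factor(library, levels = libraries))
  out <- data.frame(sequence = rownames(tab), stringsAsFactors = FALSE)
  for (lib in libraries) out[[lib]] <- as.integer(tab[, lib])
  rownames(out) <- NULL
  out
}

#' Per-library accounting summary
#'
#' Assembles the raw-to-valid filter cascade table for one library. The
#' Rfam total is recomputed as the sum of its five classes, and every
#' percentage is recomputed from the counts: total percentages against the
#' raw read count and unique percentages against the unique raw count,
#' both to two decimals.
#'
#' @param total_counts Named numeric vector of read totals with entries
#'   `raw`, `adapter_length`, `junk`, `rRNA`, `tRNA`, `snoRNA`, `snRNA`,
#'   `other`, `mRNA`, `repeat`, `valid`.
#' @param unique_counts Same names, unique-sequence counts.
#' @return Data frame (one row per category, including the derived
#'   `rfam_total` row) with columns `category`, `count`, `pct_total`,
#'   `unique_count`, `pct_unique`.
#' @export
library_summary <- function(total_counts, unique_counts) {
  need <- c("raw", "adapter_length", "junk", "rRNA", "tRNA", "snoRNA",
            "snRNA", "other", "mRNA", "repeat", "valid")
  miss <- setdiff(need, names(total_counts))
  if (length(miss))
    stop("missing counts: ", paste(miss, collapse = ", "), call. = FALSE)
  if (total_counts[["raw"]] <= 0) stop("raw total must be > 0", call. = FALSE)
  if (total_counts[["valid"]] > total_counts[["raw"]])
    stop("valid reads exceed raw reads", call. = FALSE)
  rfam_cls <- c("rRNA", "tRNA", "snoRNA", "snRNA", "other")
  tc <- c(total_counts[need],
          rfam_total = sum(total_counts[rfam_cls]))
  uc <- c(unique_counts[need],
          rfam_total = sum(unique_counts[rfam_cls]))
  order_rows <- c("raw", "adapter_length", "junk", "rfam_total", "mRNA",
                  "repeat", rfam_cls, "valid")
  data.frame(
    category = order_rows,
    count = as.numeric(tc[order_rows]),
    pct_total = round(100 * as.numeric(tc[order_rows]) / tc[["raw"]], 2),
    unique_count = as.numeric(uc[order_rows]),
    pct_unique = round(100 * as.numeric(uc[order_rows]) / uc[["raw"]], 2),
    stringsAsFactors = FALSE)
}

#' Length distribution of valid tags
#'
#' @param sequences Tag sequences.
#' @param counts Read counts per tag (summed over libraries or one
#'   library's column).
#' @param min_len,max_len Length range of the table.
#' @return Data frame with `length`, `total_count`, `unique_count`,
#'   `total_frac`, `unique_frac`; each fraction column sums to 1.
#' @export
length_distribution <- function(sequences, counts, min_len = 19L,
                                max_len = 24L) {
  if (!length(sequences)) stop("no tags supplied", call. = FALSE)
  len <- nchar(sequences)
  lv <- min_len:max_len
  total <- vapply(lv, function(l) sum(counts[len == l]), 0)
  uniq <- vapply(lv, function(l) sum(len == l), 0L)
  data.frame(length = lv, total_count = total, unique_count = uniq,
             total_frac = total / sum(total),
             unique_frac = uniq / sum(uniq))
}

#' Preprocess raw libraries into annotated collapsed tags
#'
#' Runs the full cascade for each library (trim, length/junk filter,
#' collapse, contaminant annotation) and assembles the per-library
#' accounting summaries.
#'
#' @param libs A `library_spec()` data frame.
#' @param adapter 3' adapter sequence.
#' @param references Contaminant reference list (see
#'   [annotate_contaminants()]).
#' @param cfg A `run_config`.
#' @return List with `tags` (collapsed tag data frame with `annotation`),
#'   `summaries` (named list of [library_summary()] tables), and
#'   `valid_totals` (named vector of per-library valid read totals).
#' @export
preprocess_libraries <- function(libs, adapter, references,
                                 cfg = run_config()) {
  all_lib <- character(0)
  all_insert <- character(0)
  tall <- list()
  uniq_tally <- list()
  for (r in seq_len(nrow(libs))) {
    lib <- libs$name[r]
    reads <- read_sequences(libs$reads_path[r])
    inserts <- trim_adapter(reads, adapter, cfg$min_overlap)
    status <- rep("removed:adapter", length(reads))
    has <- !is.na(inserts)
    status[has] <- quality_filter(inserts[has], cfg)
    kept <- status == "kept"
    # adapter-failures and length-failures share the Table-1 filter row
    adapter_length <- status %in% c("removed:adapter", "removed:length")
    key <- ifelse(has, inserts, reads)
    tall[[lib]] <- c(
      raw = length(reads),
      adapter_length = sum(adapter_length),
      junk = sum(status == "removed:junk"))
    uniq_tally[[lib]] <- c(
      raw = length(unique(reads)),
      adapter_length = length(unique(key[adapter_length])),
      junk = length(unique(key[status == "removed:junk"])))
    all_lib <- c(all_lib, rep(lib, sum(kept)))
    all_insert <- c(all_insert, inserts[kept])
  }
  tags <- collapse_tags(all_lib, all_insert, libraries = libs$name)
  tags$annotation <- annotate_contaminants(tags$sequence, references)
  cls_counts <- function(ann, lib) {
    sel <- tags$annotation == ann
    c(total = sum(tags[[lib]][sel]), unique = sum(tags[[lib]][sel] > 0L))
  }
  summaries <- list()
  valid_totals <- stats::setNames(numeric(nrow(libs)), libs$name)
  for (lib in libs$name) {
    cls <- vapply(CONTAMINANT_CLASSES, cls_counts, numeric(2), lib = lib)
    val <- cls_counts("valid", lib)
    tc <- c(tall[[lib]],
            rRNA = cls["total", "rfam:rRNA"], tRNA = cls["total", "rfam:tRNA"],
            snoRNA = cls["total", "rfam:snoRNA"],
            snRNA = cls["total", "rfam:snRNA"],
            other = cls["total", "rfam:other"], mRNA = cls["total", "mRNA"],
            "repeat" = cls["total", "repeat"], valid = val[["total"]])
    uc <- c(uniq_tally[[lib]],
            rRNA = cls["unique", "rfam:rRNA"],
            tRNA = cls["unique", "rfam:tRNA"],
            snoRNA = cls["unique", "rfam:snoRNA"],
            snRNA = cls["unique", "rfam:snRNA"],
            other = cls["unique", "rfam:other"], mRNA = cls["unique", "mRNA"],
            "repeat" = cls["unique", "repeat"], valid = val[["unique"]])
    summaries[[lib]] <- library_summary(tc, uc)
    valid_totals[lib] <- val[["total"]]
  }
  list(tags = tags, summaries = summaries, valid_totals = valid_totals)
}
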