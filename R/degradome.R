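## Degradome (PARE) analysis: exact mapping of degradome tag 5' ends onto
## transcripts, target plots, the penalty-scored miRNA:target duplex scan,
## cleavage-site validation at miRNA position `cleavage_pos`, and category
## 0-4 classification.

.base_int <- function(x) match(strsplit(x, "", fixed = TRUE)[[1]],
                               c("A", "C", "G", "U"))

# pair class matrix indexed [mirna base, aligned target base]:
# 0 = Watson-Crick, 0.5 = G:U wobble, 1 = mismatch
.pair_penalty <- local({
  m <- matrix(1, 4, 4)
  m[1, 4] <- m[4, 1] <- m[2, 3] <- m[3, 2] <- 0
  m[3, 4] <- m[4, 3] <- 0.5
  m
})

#' Score a miRNA:target duplex
#'
#' The target window is supplied 3'->5' relative to the miRNA, i.e. base i
#' of the window faces base i of the miRNA. Per position: Watson-Crick 0,
#' G:U wobble 0.5, mismatch 1; any penalty is doubled at miRNA positions
#' 2-13 inclusive (counted from the 5' end). The score is the sum.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param window Target window aligned position-by-position (3'->5'
#'   relative to the miRNA), same length.
#' @return List of class `duplex_alignment`: `mirna`, `window`, `pairing`
#'   (per-position `"WC"`/`"GU"`/`"mismatch"`), `score`.
#' @examples
#' score_duplex("ACGU", "UGCA")$score  # perfect complement: 0
#' @export
score_duplex <- function(mirna, window) {
  if (nchar(mirna) != nchar(window))
    stop("miRNA and window lengths differ", call. = FALSE)
  mi <- .base_int(mirna); wi <- .base_int(window)
  if (anyNA(mi) || anyNA(wi))
    stop("sequences must be over {A,C,G,U}", call. = FALSE)
  pen <- .pair_penalty[cbind(mi, wi)]
  pos <- seq_along(pen)
  mult <- ifelse(pos >= 2L & pos <= 13L, 2, 1)
  pairing <- c("WC", "GU", "mismatch")[match(pen, c(0, 0.5, 1))]
  structure(list(mirna = mirna, window = window, pairing = pairing,
                 score = sum(pen * mult)),
            class = "duplex_alignment")
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Every equal-length sense-strand window is scored against the miRNA
#' (ungapped, antiparallel) and windows with penalty score at most
#' `score_cap` are returned. The predicted cleavage site is the transcript
#' base paired to miRNA position `cleavage_pos` (default 10, the canonical
#' slicing register).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence (RNA), at least as long as the
#'   miRNA.
#' @param cfg A `run_config` (uses `score_cap`, `cleavage_pos`).
#' @return Data frame with `window_start` (transcript position of the
#'   window's 5' end), `site` (predicted cleavage position), `score`.
#' @export
find_target_sites <- function(mirna, transcript, cfg = run_config()) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  if (n < L) stop("transcript shorter than miRNA", call. = FALSE)
  mi <- .base_int(mirna)
  ti <- .base_int(transcript)
  nw <- n - L + 1L
  pos <- seq_len(L)
  mult <- ifelse(pos >= 2L & pos <= 13L, 2, 1)
  scores <- numeric(nw)
  starts <- seq_len(nw)
  for (i in pos) {
    # miRNA position i faces transcript position s + L - i
    scores <- scores + .pair_penalty[mi[i], ti[starts + L - i]] * mult[i]
  }
  sel <- which(scores <= cfg$score_cap)
  data.frame(window_start = sel, site = sel + L - cfg$cleavage_pos,
             score = scores[sel])
}

#' Map degradome tags onto transcripts
#'
#' Each tag contributes its count at the 1-based transcript position of
#' its 5' end for every exact-match locus; multi-mapping tags count at
#' every locus.
#'
#' @param sequences Unique degradome tag sequences (>= 15 nt).
#' @param counts Tag counts.
#' @param transcripts Named character vector of transcript sequences.
#' @return Named list of per-transcript integer count vectors (length =
#'   transcript length), plus attributes `n_mapped` / `n_unique_mapped`
#'   (read and tag totals that hit at least one locus).
#' @export
map_degradome_tags <- function(sequences, counts, transcripts) {
  stopifnot(length(sequences) == length(counts))
  if (any(nchar(sequences) < 15L))
    stop("degradome tags must be >= 15 nt", call. = FALSE)
  out <- lapply(transcripts, function(tx) integer(nchar(tx)))
  mapped <- logical(length(sequences))
  if (length(sequences)) {
    dna_tags <- chartr("U", "T", sequences)
    widths <- nchar(dna_tags)
    subjects <- lapply(transcripts, function(tx)
      Biostrings::DNAString(chartr("U", "T", tx)))
    for (w in unique(widths)) {
      idx <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(dna_tags[idx]))
      for (t in seq_along(subjects)) {
        m <- Biostrings::matchPDict(pd, subjects[[t]])
        st <- Biostrings::startIndex(m)
        for (k in seq_along(idx)) {
          s <- st[[k]]
          if (is.null(s) || !length(s)) next
          mapped[idx[k]] <- TRUE
          out[[t]][s] <- out[[t]][s] + counts[idx[k]]
        }
      }
    }
  }
  attr(out, "n_mapped") <- sum(counts[mapped])
  attr(out, "n_unique_mapped") <- sum(mapped)
  out
}

#' Build a target plot from a position count vector
#'
#' @param count_vector Per-position degradome 5'-end counts for one
#'   transcript.
#' @return List of class `tplot`: `position_counts` (data frame of covered
#'   positions), `max_count`, `n_at_max`, `median_count` (median over
#'   positions with at least one read; `NA` when empty).
#' @export
build_tplot <- function(count_vector) {
  covered <- which(count_vector > 0L)
  if (!length(covered)) {
    return(structure(list(position_counts = data.frame(position = integer(0),
                                                       count = integer(0)),
                          max_count = 0L, n_at_max = 0L,
                          median_count = NA_real_),
                     class = "tplot"))
  }
  counts <- count_vector[covered]
  mx <- max(counts)
  structure(list(position_counts = data.frame(position = covered,
                                              count = as.integer(counts)),
                 max_count = as.integer(mx),
                 n_at_max = sum(counts == mx),
                 median_count = stats::median(as.numeric(counts))),
            class = "tplot")
}

#' Classify a cleavage site into category 0-4
#'
#' Evaluated in order: category 4 when the site has a single raw read;
#' else 0 when the site carries the transcript maximum and that maximum is
#' attained at exactly one position; else 1 when the site carries the
#' maximum attained at more than one position; else 2 when the count lies
#' strictly between the median and the maximum; else 3 (at or below the
#' median). The median is taken over covered positions only.
#'
#' @param site_count Raw degradome count at the site (>= 1).
#' @param tplot A [build_tplot()] result containing the site.
#' @return Integer category in 0:4.
#' @export
classify_category <- function(site_count, tplot) {
  if (site_count < 1L || tplot$max_count < 1L ||
      site_count > tplot$max_count ||
      !site_count %in% tplot$position_counts$count)
    stop("site count absent from the target plot", call. = FALSE)
  if (site_count == 1L) return(4L)
  if (site_count == tplot$max_count)
    return(if (tplot$n_at_max == 1L) 0L else 1L)
  if (site_count > tplot$median_count) return(2L)
  3L
}

#' Validate and classify cleavage events for one library
#'
#' For every called miRNA and transcript, candidate sites from
#' [find_target_sites()] with at least one degradome read at the predicted
#' position become cleavage events, classified into categories 0-4
#' against the transcript's target plot.
#'
#' @param mirnas Named character vector (id -> mature sequence) of miRNAs
#'   to scan.
#' @param transcripts Named character vector of transcript sequences.
#' @param profiles [map_degradome_tags()] output for this library.
#' @param library Library label recorded on each event.
#' @param cfg A `run_config`.
#' @return Data frame of events: `mirna_id`, `mirna_seq`, `transcript_id`,
#'   `site`, `site_count`, `score`, `category`, `library`.
#' @export
validate_cleavage_events <- function(mirnas, transcripts, profiles, library,
                                     cfg = run_config()) {
  rows <- list()
  tplots <- lapply(profiles, build_tplot)
  for (mid in names(mirnas)) {
    mseq <- mirnas[[mid]]
    for (tid in names(transcripts)) {
      if (nchar(transcripts[[tid]]) < nchar(mseq)) next
      sites <- find_target_sites(mseq, transcripts[[tid]], cfg)
      if (!nrow(sites)) next
      prof <- profiles[[tid]]
      for (r in seq_len(nrow(sites))) {
        pos <- sites$site[r]
        if (pos < 1L || pos > length(prof) || prof[pos] < 1L) next
        cat <- classify_category(prof[pos], tplots[[tid]])
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, mirna_seq = mseq, transcript_id = tid,
          site = pos, site_count = prof[pos], score = sites$score[r],
          category = cat, library = library, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), mirna_seq = character(0),
                      transcript_id = character(0), site = integer(0),
                      site_count = integer(0), score = numeric(0),
                      category = integer(0), library = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compile per-library target tables and the cross-library union
#'
#' A target sequence is counted once per (miRNA, transcript, site) within
#' a library; the per-category counts therefore sum to each library's
#' target-sequence total.
#'
#' @param events Event data frame from [validate_cleavage_events()]
#'   (possibly several libraries concatenated).
#' @return List with `table` (deduplicated event rows), `summary` (per
#'   library: counts for categories 0-4 and `total`), and `union_count`
#'   (distinct (miRNA, transcript, site) across all libraries).
#' @export
compile_target_report <- function(events) {
  key <- paste(events$mirna_id, events$transcript_id, events$site,
               events$library, sep = "\r")
  tab <- events[!duplicated(key), , drop = FALSE]
  libs <- unique(tab$library)
  summ <- lapply(libs, function(lib) {
    e <- tab[tab$library == lib, , drop = FALSE]
    counts <- vapply(0:4, function(k) sum(e$category == k), 0L)
    data.frame(library = lib, category_0 = counts[1], category_1 = counts[2],
               category_2 = counts[3], category_3 = counts[4],
               category_4 = counts[5], total = nrow(e),
               stringsAsFactors = FALSE)
  })
  union_key <- unique(paste(tab$mirna_id, tab$transcript_id, tab$site,
                            sep = "\r"))
  list(table = tab, summary = do.call(rbind, summ),
       union_count = length(union_key))
}

#' Degradome library mapping summary
#'
#' Mirrors the degradome accounting table: raw and unique raw reads,
#' cDNA-mapped totals with percentages of raw, and covered cDNAs as a
#' percentage of input cDNAs (two decimals).
#'
#' @param raw_reads,unique_raw Total and unique raw degradome reads.
#' @param mapped,unique_mapped cDNA-mapped totals.
#' @param input_cdnas,covered_cdnas Transcriptome size and number of
#'   transcripts with at least one mapped tag.
#' @return One-row data frame with counts and `pct_mapped`,
#'   `pct_unique_mapped`, `pct_covered`.
#' @export
degradome_summary <- function(raw_reads, unique_raw, mapped, unique_mapped,
                              input_cdnas, covered_cdnas) {
  if (raw_reads <= 0 || unique_raw <= 0 || input_cdnas <= 0)
    stop("totals must be positive", call. = FALSE)
  data.frame(raw_reads = raw_reads, unique_raw = unique_raw,
             mapped = mapped, unique_mapped = unique_mapped,
             input_cdnas = input_cdnas, covered_cdnas = covered_cdnas,
             pct_mapped = round(100 * mapped / raw_reads, 2),
             pct_unique_mapped = round(100 * unique_mapped / unique_raw, 2),
             pct_covered = round(100 * covered_cdnas / input_cdnas, 2))
}
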