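## Conserved / novel miRNA classification: Hamming mapping of valid tags
## against a miRBase-style catalog within precursor hairpin arms
## (conserved), opposite-arm mapping (novel candidates), MFEI and copy
## number gates, and family assignment.

# Hamming distance between equal-length character splits
.hamming <- function(a, b) sum(a != b)

# Best equal-length-window match of `tag` inside `subject`.
# Returns list(dist, start) for the minimal Hamming distance (leftmost on
# ties); dist = Inf when the subject is shorter than the tag.
best_window_match <- function(tag, subject) {
  lt <- nchar(tag); ls <- nchar(subject)
  if (ls < lt) return(list(dist = Inf, start = NA_integer_))
  tv <- strsplit(tag, "", fixed = TRUE)[[1]]
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  best <- Inf; at <- NA_integer_
  for (s in 1:(ls - lt + 1L)) {
    d <- sum(tv != sv[s:(s + lt - 1L)])
    if (d < best) { best <- d; at <- s; if (d == 0L) break }
  }
  list(dist = best, start = at)
}

#' Map a tag against a catalog of mature sequences
#'
#' Compares the full tag against every equal-length window of each catalog
#' mature sequence (Hamming distance, no indels) and returns all entries
#' at the minimal distance when that distance is within `max_mismatch`.
#'
#' @param tag Tag sequence (RNA).
#' @param catalog Named character vector of catalog mature sequences.
#' @param max_mismatch Maximum allowed mismatches.
#' @return Data frame with `name`, `mismatches`, `start` (window offset in
#'   the catalog sequence); zero rows when nothing is close enough.
#' @export
map_with_mismatches <- function(tag, catalog, max_mismatch = 1L) {
  if (!length(catalog)) stop("catalog is empty", call. = FALSE)
  hits <- lapply(catalog, best_window_match, tag = tag)
  d <- vapply(hits, `[[`, 0, "dist")
  dmin <- min(d)
  if (dmin > max_mismatch)
    return(data.frame(name = character(0), mismatches = integer(0),
                      start = integer(0), stringsAsFactors = FALSE))
  sel <- which(d == dmin)
  data.frame(name = names(catalog)[sel],
             mismatches = as.integer(dmin),
             start = vapply(hits[sel], `[[`, 0L, "start"),
             stringsAsFactors = FALSE)
}

#' Build a catalog index from mature and hairpin sequences
#'
#' Locates each mature sequence inside a hairpin (exact substring, first
#' hairpin hit), folds each used hairpin once, and pre-validates the
#' mature-in-arm stem-loop criteria (without the MFEI rule, the looser
#' conserved-miRNA criterion). Matures found in no hairpin are dropped
#' with a warning.
#'
#' @param mature Named character vector of mature sequences.
#' @param hairpins Named character vector of precursor sequences.
#' @param cfg A `run_config`.
#' @return List with `entries` (data frame: `name`, `sequence`,
#'   `precursor_id`, `start`, `end`, `arm`, `valid`) and `precursors`
#'   (named list of `hairpin_record`s).
#' @export
build_catalog <- function(mature, hairpins, cfg = run_config()) {
  records <- lapply(hairpins, hairpin_record)
  rows <- vector("list", length(mature))
  for (i in seq_along(mature)) {
    seqi <- mature[[i]]
    hit <- NA_character_; st <- NA_integer_
    for (h in names(hairpins)) {
      p <- regexpr(seqi, hairpins[[h]], fixed = TRUE)
      if (p > 0L) { hit <- h; st <- as.integer(p); break }
    }
    if (is.na(hit)) next
    span <- c(st, st + nchar(seqi) - 1L)
    v <- validate_hairpin(records[[hit]], span, cfg, novel_mode = FALSE)
    rows[[i]] <- data.frame(
      name = names(mature)[i], sequence = seqi, precursor_id = hit,
      start = span[1], end = span[2],
      arm = if (is.na(v$arm)) NA_character_ else v$arm,
      valid = v$valid, stringsAsFactors = FALSE)
  }
  found <- !vapply(rows, is.null, TRUE)
  if (any(!found))
    warning(sum(!found), " mature sequence(s) not located in any hairpin")
  list(entries = do.call(rbind, rows[found]), precursors = records)
}

#' Classify a tag as a conserved miRNA
#'
#' A tag is conserved when it maps (at most `max_mismatch` mismatches) to
#' a catalog mature sequence that itself lies within an arm of a valid
#' stem-loop precursor. Among equally good matches the first catalog entry
#' is reported.
#'
#' @param tag Tag sequence.
#' @param catalog A [build_catalog()] result.
#' @param cfg A `run_config`.
#' @return A one-row data frame (`status = "conserved"`, `matched_known`,
#'   `precursor_id`, `arm`, `mismatches`) or `NULL`.
#' @export
classify_conserved <- function(tag, catalog, cfg = run_config()) {
  ent <- catalog$entries
  if (is.null(ent) || !nrow(ent)) return(NULL)
  seqs <- stats::setNames(ent$sequence, ent$name)
  m <- map_with_mismatches(tag, seqs, cfg$max_mismatch)
  if (!nrow(m)) return(NULL)
  m <- merge(m, ent, by = "name", sort = FALSE)
  m <- m[m$valid, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  data.frame(status = "conserved", matched_known = m$name[1],
             precursor_id = m$precursor_id[1], arm = m$arm[1],
             mismatches = m$mismatches[1], stringsAsFactors = FALSE)
}

#' Detect a novel (opposite-arm) miRNA candidate
#'
#' A tag mapping (at most `max_mismatch` mismatches) entirely within the
#' arm opposite the annotated mature arm of a known stem-loop precursor is
#' a novel 5p- or 3p-derived candidate.
#'
#' @param tag Tag sequence.
#' @param catalog A [build_catalog()] result (provides the annotated arm
#'   per precursor).
#' @param cfg A `run_config`.
#' @return A one-row data frame (`status = "novel_candidate"`,
#'   `precursor_id`, `arm`, `mismatches`, `start`, `end`) or `NULL`.
#' @export
detect_novel_candidates <- function(tag, catalog, cfg = run_config()) {
  ent <- catalog$entries
  if (is.null(ent) || !nrow(ent)) return(NULL)
  ann <- unique(ent[ent$valid & !is.na(ent$arm),
                    c("precursor_id", "arm")])
  # only precursors with exactly one annotated mature arm qualify
  n_arms <- table(ann$precursor_id)
  ann <- ann[ann$precursor_id %in% names(n_arms)[n_arms == 1L], ,
             drop = FALSE]
  best <- NULL
  for (r in seq_len(nrow(ann))) {
    pid <- ann$precursor_id[r]
    rec <- catalog$precursors[[pid]]
    if (!rec$is_stem_loop) next
    opp <- if (ann$arm[r] == "5p") "3p" else "5p"
    ivl <- if (opp == "5p") rec$arm5p else rec$arm3p
    armseq <- substr(rec$fold$sequence, ivl[1], ivl[2])
    m <- best_window_match(tag, armseq)
    if (m$dist > cfg$max_mismatch) next
    st <- ivl[1] + m$start - 1L
    cand <- data.frame(status = "novel_candidate", precursor_id = pid,
                       arm = opp, mismatches = as.integer(m$dist),
                       start = st, end = st + nchar(tag) - 1L,
                       stringsAsFactors = FALSE)
    if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
    if (best$mismatches == 0L) break
  }
  best
}

#' Apply the novel-miRNA acceptance thresholds
#'
#' A candidate is accepted when its precursor's MFEI is at least
#' `mfei_min` (both boundaries inclusive) and its normalized abundance
#' reaches `min_copy` TPM in at least one library.
#'
#' @param candidate A [detect_novel_candidates()] row.
#' @param record The candidate precursor's `hairpin_record`.
#' @param tpm Numeric vector of per-library normalized abundances.
#' @param cfg A `run_config`.
#' @return List with `accepted` (logical) and `reasons` (subset of
#'   `c("mfei", "abundance")`, empty when accepted).
#' @export
apply_novel_thresholds <- function(candidate, record, tpm,
                                   cfg = run_config()) {
  reasons <- character(0)
  if (is.na(record$mfei) || record$mfei < cfg$mfei_min)
    reasons <- c(reasons, "mfei")
  if (max(tpm) < cfg$min_copy)
    reasons <- c(reasons, "abundance")
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Assign conserved miRNAs to families
#'
#' The family is the `miR<number>` token extracted from the matched
#' catalog name (case-insensitive; species prefixes, letter suffixes and
#' arm labels are stripped). Names without the token stay unassigned.
#'
#' @param names Character vector of catalog miRNA names.
#' @return Data frame with `name` and `family` (`NA` when unassigned).
#' @examples
#' assign_families(c("spi-miR156d-5p", "spi-miR8007a", "PC-70-5p"))
#' @export
assign_families <- function(names) {
  m <- regmatches(names, regexpr("miR-?([0-9]+)", names, ignore.case = TRUE))
  fam <- rep(NA_character_, length(names))
  has <- regexpr("miR-?([0-9]+)", names, ignore.case = TRUE) > 0L
  fam[has] <- paste0("miR", gsub("[^0-9]", "", m))
  data.frame(name = names, family = fam, stringsAsFactors = FALSE)
}

#' Discover conserved and novel miRNAs among valid tags
#'
#' Applies conserved-first classification to every valid tag: catalog
#' mapping within hairpin arms, then opposite-arm novel detection with the
#' MFEI and copy-number thresholds. Expression is attributed to the mature
#' sequence, so catalog names sharing a sequence share the abundance.
#'
#' @param tags Collapsed tag data frame (from [preprocess_libraries()]):
#'   `sequence`, one count column per library, `annotation`.
#' @param catalog A [build_catalog()] result.
#' @param valid_totals Named per-library valid read totals (TPM
#'   denominators).
#' @param cfg A `run_config`.
#' @return Data frame of calls: `sequence`, `status`, `precursor_id`,
#'   `arm`, `matched_known`, `mismatches`, and one `tpm_<lib>` column per
#'   library.
#' @export
discover_mirnas <- function(tags, catalog, valid_totals,
                            cfg = run_config()) {
  libs <- names(valid_totals)
  valid <- tags[tags$annotation == "valid", , drop = FALSE]
  calls <- list()
  for (r in seq_len(nrow(valid))) {
    tag <- valid$sequence[r]
    if (nchar(tag) < cfg$min_len || nchar(tag) > cfg$max_len) next
    counts <- as.numeric(valid[r, libs])
    tpm <- 1e6 * counts / valid_totals
    cons <- classify_conserved(tag, catalog, cfg)
    call <- NULL
    if (!is.null(cons)) {
      call <- cbind(data.frame(sequence = tag, stringsAsFactors = FALSE),
                    cons)
    } else {
      cand <- detect_novel_candidates(tag, catalog, cfg)
      if (!is.null(cand)) {
        rec <- catalog$precursors[[cand$precursor_id]]
        thr <- apply_novel_thresholds(cand, rec, tpm, cfg)
        if (thr$accepted) {
          call <- data.frame(sequence = tag, status = "novel_candidate",
                             matched_known = NA_character_,
                             precursor_id = cand$precursor_id,
                             arm = cand$arm, mismatches = cand$mismatches,
                             stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(call)) {
      for (i in seq_along(libs)) call[[paste0("tpm_", libs[i])]] <- tpm[i]
      for (i in seq_along(libs)) call[[paste0("count_", libs[i])]] <- counts[i]
      calls[[length(calls) + 1L]] <- call
    }
  }
  if (!length(calls)) {
    out <- data.frame(sequence = character(0), status = character(0),
                      matched_known = character(0),
                      precursor_id = character(0), arm = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  cols <- c("sequence", "status", "matched_known", "precursor_id", "arm",
            "mismatches", paste0("tpm_", libs), paste0("count_", libs))
  out <- do.call(rbind, lapply(calls, function(x) x[, cols]))
  rownames(out) <- NULL
  out
}
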