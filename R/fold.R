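## Simplified RNA secondary-structure prediction for precursor screening.
## A Nussinov-style dynamic program with weighted pairs (GC -3.0, AU -2.0,
## GU -1.0 kcal/mol, minimum hairpin loop 3, no pseudoknots) stands in for
## full thermodynamic folding; externally computed (structure, MFE) pairs
## can be supplied to hairpin_record() to use a real folding engine.

# pair reward (positive) indexed by base ints A=1 C=2 G=3 U=4; 0 = no pair
.pair_reward <- local({
  m <- matrix(0, 4, 4)
  m[3, 2] <- m[2, 3] <- 3
  m[1, 4] <- m[4, 1] <- 2
  m[3, 4] <- m[4, 3] <- 1
  m
})

.seq_to_int <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- match(v, c("A", "C", "G", "U"))
  if (anyNA(i))
    stop("sequence must be over {A,C,G,U}: ", sequence, call. = FALSE)
  i
}

#' Fold a sequence with the internal simplified energy model
#'
#' Maximizes total pair reward (GC 3.0, AU 2.0, GU 1.0; MFE is minus the
#' total) over all nested structures with hairpin loops of at least 3 nt.
#' Ties are broken deterministically in the traceback by preferring a
#' pairing whose 5' partner is earliest.
#'
#' @param sequence RNA string (A/C/G/U), length >= 10 for meaningful
#'   hairpins (shorter input folds to the open chain).
#' @return A `fold_result` list: `sequence`, dot-bracket `structure`,
#'   `n_pairs`, `mfe` (kcal/mol, <= 0), `backend = "internal"`.
#' @examples
#' fold_internal("GGGAAACCC")$mfe  # -9: three GC pairs
#' @export
fold_internal <- function(sequence) {
  s <- .seq_to_int(sequence)
  n <- length(s)
  minloop <- 3L
  if (n < minloop + 2L) {
    return(fold_result(sequence, strrep(".", n), 0, backend = "internal"))
  }
  W <- matrix(0, n, n)
  for (span in (minloop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- W[i, j - 1L]
      ks <- i:(j - minloop - 1L)
      rew <- .pair_reward[cbind(s[ks], s[j])]
      ok <- rew > 0
      if (any(ok)) {
        kk <- ks[ok]
        left <- ifelse(kk > i, W[cbind(pmax(i, 1L), pmax(kk - 1L, 1L))], 0)
        # W[i, k-1] only valid when k > i
        left[kk == i] <- 0
        inner <- W[cbind(pmin(kk + 1L, n), pmax(j - 1L, 1L))]
        inner[kk + 1L > j - 1L] <- 0
        best <- max(best, max(left + rew[ok] + inner))
      }
      W[i, j] <- best
    }
  }
  # traceback, preferring the earliest-5' pairing among optimal choices
  pairs <- integer(0)
  partner <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < minloop + 1L) next
    chosen <- NA_integer_
    for (k in i:(j - minloop - 1L)) {
      rew <- .pair_reward[s[k], s[j]]
      if (rew == 0) next
      left <- if (k > i) W[i, k - 1L] else 0
      inner <- if (k + 1L <= j - 1L) W[k + 1L, j - 1L] else 0
      if (left + rew + inner == W[i, j]) { chosen <- k; break }
    }
    if (!is.na(chosen)) {
      partner[chosen] <- j; partner[j] <- chosen
      if (chosen > i) stack[[length(stack) + 1L]] <- c(i, chosen - 1L)
      if (chosen + 1L <= j - 1L)
        stack[[length(stack) + 1L]] <- c(chosen + 1L, j - 1L)
    } else {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    }
  }
  struct <- rep(".", n)
  struct[partner > seq_len(n)] <- "("
  struct[partner < seq_len(n) & partner > 0L] <- ")"
  fold_result(sequence, paste(struct, collapse = ""), -W[1L, n],
              backend = "internal")
}

#' Construct a fold result
#'
#' Validates that the dot-bracket string matches the sequence, brackets
#' balance, every pair is Watson-Crick or G:U, and hairpin loops are at
#' least 3 nt.
#'
#' @param sequence RNA string.
#' @param structure Dot-bracket string of equal length.
#' @param mfe Minimum free energy, kcal/mol (<= 0).
#' @param backend `"internal"` or `"external"`.
#' @return A `fold_result` list.
#' @export
fold_result <- function(sequence, structure, mfe, backend = "external") {
  if (nchar(structure) != nchar(sequence))
    stop("structure and sequence lengths differ", call. = FALSE)
  pr <- structure_pairs(structure)
  if (nrow(pr)) {
    s <- .seq_to_int(sequence)
    if (any(.pair_reward[cbind(s[pr[, 1]], s[pr[, 2]])] == 0))
      stop("structure contains a non-canonical pair", call. = FALSE)
    if (any(pr[, 2] - pr[, 1] < 4L))
      stop("hairpin loop shorter than 3 nt", call. = FALSE)
  }
  if (mfe > 0) stop("mfe must be <= 0", call. = FALSE)
  structure(list(sequence = sequence, structure = structure,
                 n_pairs = nrow(pr), mfe = mfe, backend = backend),
            class = "fold_result")
}

#' Base pairs of a dot-bracket structure
#'
#' @param structure Dot-bracket string.
#' @return Two-column integer matrix (5' position, 3' position).
#' @export
structure_pairs <- function(structure) {
  v <- strsplit(structure, "", fixed = TRUE)[[1]]
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  res <- vector("list", sum(v == ")"))
  nres <- 0L
  for (p in seq_along(v)) {
    if (v[p] == "(") open <- c(open, p)
    else if (v[p] == ")") {
      if (!length(open)) stop("unbalanced brackets", call. = FALSE)
      nres <- nres + 1L
      res[[nres]] <- c(open[length(open)], p)
      open <- open[-length(open)]
    } else if (v[p] != ".")
      stop("invalid structure character: ", v[p], call. = FALSE)
  }
  if (length(open)) stop("unbalanced brackets", call. = FALSE)
  if (nres == 0L) return(matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, res[seq_len(nres)])
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

# number of hairpin (terminal) loops in a dot-bracket string
count_hairpin_loops <- function(structure) {
  length(gregexpr("\\(\\.*\\)", structure)[[1]]) -
    (gregexpr("\\(\\.*\\)", structure)[[1]][1] == -1L)
}

#' Minimal folding free energy index
#'
#' MFEI = (|MFE| / length x 100) / GC%, the hairpin-quality index used to
#' gate novel miRNA precursors (threshold 0.80 by default). |MFE| is used
#' so the threshold reads naturally for negative folding energies.
#'
#' @param fold A `fold_result` (or any list with `sequence` and `mfe`).
#' @param gc_percent GC percentage; computed from the sequence if omitted.
#' @return MFEI as a number; `NA` (with a warning) when GC% is zero, which
#'   downstream is treated as failing the threshold.
#' @export
compute_mfei <- function(fold, gc_percent = NULL) {
  len <- nchar(fold$sequence)
  if (is.null(gc_percent)) gc_percent <- gc_content(fold$sequence)
  if (gc_percent == 0) {
    warning("GC content is zero; MFEI undefined (fails threshold)")
    return(NA_real_)
  }
  (abs(fold$mfe) / len * 100) / gc_percent
}

#' GC percentage of a sequence
#' @param sequence Nucleotide string.
#' @return GC content in percent (0-100).
#' @export
gc_content <- function(sequence) {
  n <- nchar(sequence)
  gc <- n - nchar(gsub("[GC]", "", sequence))
  100 * gc / n
}

#' Build a precursor hairpin record
#'
#' Folds the sequence (internal model) unless an external structure and
#' MFE are supplied, then derives GC%, MFEI, the 5p/3p arm intervals
#' flanking the single terminal loop, and a stem-loop flag.
#'
#' @param sequence Precursor RNA string.
#' @param structure Optional externally computed dot-bracket string.
#' @param mfe External MFE, required with `structure`.
#' @return A `hairpin_record` list: `fold`, `gc_percent`, `mfei`,
#'   `arm5p`/`arm3p` (1-based inclusive intervals or `NA`),
#'   `is_stem_loop`.
#' @export
hairpin_record <- function(sequence, structure = NULL, mfe = NULL) {
  fold <- if (is.null(structure)) fold_internal(sequence)
          else fold_result(sequence, structure, mfe, backend = "external")
  gc <- gc_content(sequence)
  mfei <- if (gc > 0) compute_mfei(fold, gc) else NA_real_
  loops <- count_hairpin_loops(fold$structure)
  arm5p <- arm3p <- c(NA_integer_, NA_integer_)
  is_sl <- loops == 1L && fold$n_pairs > 0L
  if (is_sl) {
    m <- regexpr("\\(\\.*\\)", fold$structure)
    istar <- as.integer(m)
    jstar <- istar + attr(m, "match.length") - 1L
    arm5p <- c(1L, istar)
    arm3p <- c(jstar, nchar(sequence))
  }
  structure(list(fold = fold, gc_percent = gc, mfei = mfei,
                 arm5p = arm5p, arm3p = arm3p, n_loops = loops,
                 is_stem_loop = is_sl),
            class = "hairpin_record")
}

#' Validate a precursor hairpin for a mature span
#'
#' A precursor is accepted when (a) its structure is a single stem-loop,
#' (b) the mature span lies entirely within one arm (never in the terminal
#' loop), (c) at least `mature_pair_min` mature bases are paired, and --
#' in novel mode -- (d) MFEI >= `mfei_min`. Each failed criterion is
#' reported by name.
#'
#' @param record A `hairpin_record`.
#' @param mature_span 1-based inclusive interval `c(start, end)` of the
#'   mature sequence within the precursor.
#' @param cfg A `run_config`.
#' @param novel_mode Apply the MFEI criterion (novel candidates only).
#' @return List with `valid` (logical), `reasons` (character vector of
#'   failed criteria among `"multi_loop"`, `"no_pairs"`, `"loop_overlap"`,
#'   `"pairing"`, `"mfei"`), and `arm` (`"5p"`, `"3p"`, or `NA`).
#' @export
validate_hairpin <- function(record, mature_span, cfg = run_config(),
                             novel_mode = FALSE) {
  len <- nchar(record$fold$sequence)
  if (mature_span[1] < 1L || mature_span[2] > len ||
      mature_span[1] > mature_span[2])
    stop("mature span out of range", call. = FALSE)
  reasons <- character(0)
  arm <- NA_character_
  if (!record$is_stem_loop) {
    reasons <- c(reasons,
                 if (record$n_loops > 1L) "multi_loop" else "no_pairs")
  } else {
    if (mature_span[1] >= record$arm5p[1] &&
        mature_span[2] <= record$arm5p[2]) arm <- "5p"
    else if (mature_span[1] >= record$arm3p[1] &&
             mature_span[2] <= record$arm3p[2]) arm <- "3p"
    else reasons <- c(reasons, "loop_overlap")
  }
  pr <- structure_pairs(record$fold$structure)
  paired_pos <- c(pr[, 1], pr[, 2])
  n_paired <- sum(paired_pos >= mature_span[1] & paired_pos <= mature_span[2])
  if (n_paired < cfg$mature_pair_min) reasons <- c(reasons, "pairing")
  if (novel_mode && (is.na(record$mfei) || record$mfei < cfg$mfei_min))
    reasons <- c(reasons, "mfei")
  list(valid = length(reasons) == 0L, reasons = reasons, arm = arm)
}
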