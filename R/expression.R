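## TPM normalization, the dual chi-square / Fisher differential test with
## a log2 fold-change gate, shared-set (Venn) summaries, and the
## 2^-ddCt relative-expression formula.

#' Tags-per-million normalization
#'
#' @param counts Raw per-miRNA counts.
#' @param library_total The library's valid-read total (the TPM
#'   denominator; summing TPM over all valid tags gives 1e6).
#' @return Numeric TPM values.
#' @export
tpm_normalize <- function(counts, library_total) {
  if (library_total <= 0) stop("library total must be > 0", call. = FALSE)
  counts / library_total * 1e6
}

#' Chi-square test for a 2x2 table
#'
#' Pearson statistic without continuity correction,
#' n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), with the p-value from the
#' chi-square distribution with 1 df. A zero margin leaves the statistic
#' undefined; p is reported as 1 with a warning.
#'
#' @param a,b,c,d Nonnegative cell counts (`a` = miRNA count in library 1,
#'   `b` = rest of library 1, `c`/`d` likewise for library 2).
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("zero margin: chi-square undefined, p = 1")
    return(list(statistic = NA_real_, p = 1))
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (the minimum-likelihood two-sided rule, with the customary 1 + 1e-7
#' relative tolerance on the comparison).
#'
#' @param a,b,c,d Nonnegative cell counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  r1 <- a + b
  n <- a + b + c + d
  k <- a + c
  if (n == 0) return(1)
  lo <- max(0L, k - (c + d))
  hi <- min(r1, k)
  dens <- stats::dhyper(lo:hi, r1, n - r1, k)
  d_obs <- stats::dhyper(a, r1, n - r1, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Log2 expression ratio with library-specific flagging
#'
#' When both TPM values are positive the plain log2 ratio
#' (treatment/control) is returned. When exactly one is zero the miRNA is
#' flagged library-specific and the ratio is computed with the zero side
#' replaced by the TPM of `pseudo` raw reads in that library.
#'
#' @param tpm_treat,tpm_ctrl TPM pair (at least one must be positive).
#' @param pseudo_tpm_treat,pseudo_tpm_ctrl TPM value of `pseudo` raw reads
#'   in each library (raw pseudo-count scaled by that library's total).
#' @return List with `log2` and `library_specific` (logical).
#' @export
log2_ratio <- function(tpm_treat, tpm_ctrl, pseudo_tpm_treat = 1,
                       pseudo_tpm_ctrl = 1) {
  if (tpm_treat == 0 && tpm_ctrl == 0)
    stop("both TPM values are zero; exclude upstream", call. = FALSE)
  if (tpm_treat > 0 && tpm_ctrl > 0)
    return(list(log2 = log2(tpm_treat / tpm_ctrl), library_specific = FALSE))
  t <- if (tpm_treat == 0) pseudo_tpm_treat else tpm_treat
  c <- if (tpm_ctrl == 0) pseudo_tpm_ctrl else tpm_ctrl
  list(log2 = log2(t / c), library_specific = TRUE)
}

#' Call differential expression between two libraries
#'
#' For each miRNA, a 2x2 table of count vs library total minus count per
#' library
#' is tested with the chi-square and the Fisher exact test; a miRNA is
#' called up (down) when both p-values are at or below `alpha` and the
#' log2 ratio is at or above `log2_min` (at or below -`log2_min`). A miRNA
#' detected in exactly one library is flagged `library_specific`. No
#' multiple-testing correction is applied by default (the dual-test +
#' fold-change rule as stated; statistically non-conservative), a
#' Benjamini-Hochberg option sits behind `adjust`.
#'
#' @param mirna_id Identifiers (typically the mature sequence).
#' @param count_treat,count_ctrl Raw counts per miRNA.
#' @param total_treat,total_ctrl Library valid-read totals.
#' @param cfg A `run_config`.
#' @param adjust Apply Benjamini-Hochberg to both p-value vectors before
#'   the verdict (default `FALSE`).
#' @return Data frame of `DEResult` records: `mirna_id`, raw counts, TPM
#'   pair, `log2_ratio`, `p_chisq`, `p_fisher`, `verdict` in
#'   `{up, down, ns, library_specific}`. Rows with both counts zero are
#'   dropped.
#' @export
call_differential <- function(mirna_id, count_treat, count_ctrl,
                              total_treat, total_ctrl,
                              cfg = run_config(), adjust = FALSE) {
  keep <- !(count_treat == 0 & count_ctrl == 0)
  mirna_id <- mirna_id[keep]
  count_treat <- count_treat[keep]
  count_ctrl <- count_ctrl[keep]
  n <- length(mirna_id)
  tpm_treat <- tpm_normalize(count_treat, total_treat)
  tpm_ctrl <- tpm_normalize(count_ctrl, total_ctrl)
  pseudo_t <- tpm_normalize(cfg$pseudo, total_treat)
  pseudo_c <- tpm_normalize(cfg$pseudo, total_ctrl)
  lg <- numeric(n); libspec <- logical(n)
  p_chi <- numeric(n); p_fis <- numeric(n)
  for (i in seq_len(n)) {
    lr <- log2_ratio(tpm_treat[i], tpm_ctrl[i], pseudo_t, pseudo_c)
    lg[i] <- lr$log2; libspec[i] <- lr$library_specific
    ch <- suppressWarnings(
      chi_square_2x2(count_treat[i], total_treat - count_treat[i],
                     count_ctrl[i], total_ctrl - count_ctrl[i]))
    p_chi[i] <- ch$p
    p_fis[i] <- fisher_exact_2x2(count_treat[i], total_treat - count_treat[i],
                                 count_ctrl[i], total_ctrl - count_ctrl[i])
  }
  if (adjust) {
    p_chi <- stats::p.adjust(p_chi, method = "BH")
    p_fis <- stats::p.adjust(p_fis, method = "BH")
  }
  sig <- p_chi <= cfg$alpha & p_fis <= cfg$alpha
  verdict <- rep("ns", n)
  verdict[sig & lg >= cfg$log2_min] <- "up"
  verdict[sig & lg <= -cfg$log2_min] <- "down"
  verdict[libspec] <- "library_specific"
  data.frame(mirna_id = mirna_id, count_treat = count_treat,
             count_ctrl = count_ctrl, tpm_treat = tpm_treat,
             tpm_ctrl = tpm_ctrl, log2_ratio = lg, p_chisq = p_chi,
             p_fisher = p_fis, verdict = verdict, stringsAsFactors = FALSE)
}

#' Venn summary of per-library detection sets
#'
#' Reports the count of every intersection region (membership pattern)
#' and the percentage of items shared by all sets, 100 x |intersection| /
#' |union|, to one decimal.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return List with `regions` (data frame: `pattern`, `count`),
#'   `n_shared`, `n_union`, `shared_pct`.
#' @examples
#' shared_membership(list(A = letters[1:4], B = letters[2:5],
#'                        C = letters[2:6]))
#' @export
shared_membership <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(sets)))
  pattern <- apply(member, 1L, function(z)
    paste(names(sets)[z], collapse = "&"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("pattern", "count")
  n_shared <- sum(rowSums(member) == length(sets))
  n_union <- length(universe)
  list(regions = regions, n_shared = n_shared, n_union = n_union,
       shared_pct = round(100 * n_shared / n_union, 1))
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_treated,ct_ref_treated Cycle thresholds of the target
#'   and reference gene in the treated sample.
#' @param ct_target_control,ct_ref_control Likewise for the control.
#' @return 2^-((Ct_t,treated - Ct_ref,treated) - (Ct_t,control -
#'   Ct_ref,control)).
#' @examples
#' ddct_relative_expression(25, 20, 24, 20)  # 0.5
#' @export
ddct_relative_expression <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
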