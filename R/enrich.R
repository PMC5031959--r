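## Hypergeometric term enrichment of miRNA target genes against a
## supplied gene -> term annotation table.

#' Upper-tail hypergeometric p-value for term enrichment
#'
#' p = P(X >= S) with X ~ hypergeometric(population `TB`, successes `B`,
#' draws `TS`): the probability of seeing at least the observed number of
#' annotated genes among the selected genes.
#'
#' @param TB Total number of annotated (background) genes.
#' @param TS Number of selected genes (targets of the miRNAs of interest).
#' @param B Number of background genes carrying the term.
#' @param S Number of selected genes carrying the term.
#' @return Probability in \[0, 1\].
#' @examples
#' hypergeometric_pvalue(TB = 10, TS = 5, B = 2, S = 2)  # 56/252
#' @export
hypergeometric_pvalue <- function(TB, TS, B, S) {
  if (TS > TB || B > TB || S > min(B, TS) || S < 0)
    stop("invalid enrichment input: need 0 <= S <= min(B, TS), B <= TB, ",
         "TS <= TB", call. = FALSE)
  stats::phyper(S - 1, B, TB - B, TS, lower.tail = FALSE)
}

#' Term enrichment of a selected gene set
#'
#' One result per term carried by at least one selected gene; terms are
#' significant at `alpha` and sorted by ascending p. Genes without any
#' annotation still count in the background total. No multiple-testing
#' correction is applied by default; Benjamini-Hochberg sits behind
#' `adjust`.
#'
#' @param selected Character vector of selected gene ids (must be a subset
#'   of the background).
#' @param annotation Data frame with columns `gene_id`, `term_id`.
#' @param background Character vector of background gene ids; defaults to
#'   all genes in the annotation table.
#' @param alpha Significance threshold.
#' @param adjust Apply BH correction before thresholding.
#' @return Data frame: `term`, `TB`, `TS`, `B`, `S`, `p`, `significant`.
#' @export
enrich_terms <- function(selected, annotation, background = NULL,
                         alpha = 0.05, adjust = FALSE) {
  if (is.null(background)) background <- unique(annotation$gene_id)
  if (!length(background)) stop("empty background", call. = FALSE)
  selected <- unique(selected)
  if (!all(selected %in% background))
    stop("selected genes must be a subset of the background", call. = FALSE)
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  TB <- length(background)
  TS <- length(selected)
  sel_ann <- ann[ann$gene_id %in% selected, , drop = FALSE]
  terms <- unique(sel_ann$term_id)
  if (!length(terms))
    return(data.frame(term = character(0), TB = integer(0), TS = integer(0),
                      B = integer(0), S = integer(0), p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  B <- vapply(terms, function(t) sum(ann$term_id == t), 0L)
  S <- vapply(terms, function(t) sum(sel_ann$term_id == t), 0L)
  p <- mapply(hypergeometric_pvalue, TB = TB, TS = TS, B = B, S = S)
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms, TB = TB, TS = TS, B = as.integer(B),
                    S = as.integer(S), p = p, significant = p <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
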