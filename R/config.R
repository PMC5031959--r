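#' Analysis run configuration
#'
#' Collects the numeric thresholds used throughout the pipeline: the
#' retained insert length window, the mismatch allowance for catalog
#' mapping, the MFEI and copy-number gates for novel miRNA candidates, the
#' significance and fold-change thresholds for differential calls, and the
#' duplex score cap and cleavage position for degradome validation.
#'
#' @param min_len,max_len Retained insert length window in nt. Inserts
#'   shorter than `min_len` or longer than `max_len` are removed.
#' @param max_mismatch Maximum Hamming mismatches allowed when mapping a
#'   tag against a catalog mature sequence.
#' @param mfei_min Minimal folding free energy index required of a novel
#'   candidate's precursor (MFEI = (|MFE| / length * 100) / GC%).
#' @param min_copy Minimum normalized copy number (TPM) a novel candidate
#'   must reach in at least one library.
#' @param alpha Significance threshold applied to both the chi-square and
#'   the Fisher exact test p-values.
#' @param log2_min Minimum |log2 ratio| for an up/down differential call.
#' @param score_cap Maximum duplex penalty score for a predicted target
#'   site.
#' @param cleavage_pos miRNA position (1-based from the 5' end) whose
#'   paired transcript base is taken as the cleavage site.
#' @param pseudo Raw-read pseudo-count used on the zero side of a
#'   library-specific log2 ratio.
#' @param min_overlap Minimum 3' adapter prefix length accepted as a
#'   read-terminal partial adapter match.
#' @param homopolymer_frac Single-nucleotide fraction at or above which an
#'   insert is discarded as junk.
#' @param mature_pair_min Minimum number of paired mature bases for a
#'   precursor hairpin to be considered stable.
#' @param seed Integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$mfei_min
#' @export
run_config <- function(min_len = 19L, max_len = 24L, max_mismatch = 1L,
                       mfei_min = 0.80, min_copy = 10, alpha = 0.05,
                       log2_min = 1.0, score_cap = 4.0, cleavage_pos = 10L,
                       pseudo = 1, min_overlap = 8L,
                       homopolymer_frac = 0.80, mature_pair_min = 16L,
                       seed = 1L) {
  cfg <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
              max_mismatch = as.integer(max_mismatch), mfei_min = mfei_min,
              min_copy = min_copy, alpha = alpha, log2_min = log2_min,
              score_cap = score_cap, cleavage_pos = as.integer(cleavage_pos),
              pseudo = pseudo, min_overlap = as.integer(min_overlap),
              homopolymer_frac = homopolymer_frac,
              mature_pair_min = as.integer(mature_pair_min),
              seed = as.integer(seed))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$min_len > cfg$max_len)
    stop("min_len must not exceed max_len", call. = FALSE)
  num <- c("max_mismatch", "mfei_min", "min_copy", "log2_min", "score_cap",
           "pseudo")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop(sprintf("'%s' must be nonnegative", k), call. = FALSE)
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path Path to a YAML file whose keys are `run_config()` arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' Library specification table
#'
#' @param name Short library labels (e.g. `"NT"`, `"MET"`, `"AET"`).
#' @param reads_path Path to each library's raw reads (FASTA/FASTQ).
#' @param role Condition label, `"control"` or `"treatment"`.
#' @return A data.frame with one row per library.
#' @export
library_spec <- function(name, reads_path, role) {
  if (anyDuplicated(name))
    stop("library names must be unique", call. = FALSE)
  if (length(name) < 1L)
    stop("at least one library is required", call. = FALSE)
  role <- match.arg(role, c("control", "treatment"), several.ok = TRUE)
  data.frame(name = name, reads_path = reads_path, role = role,
             stringsAsFactors = FALSE)
}
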