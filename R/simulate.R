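## Synthetic reference sets, small-RNA libraries and degradome libraries
## with planted ground truth: hairpin precursors hosting mature miRNAs,
## libraries with a 19-24 nt length structure plus adapters, junk and
## contaminants, planted log2 fold changes between conditions, and
## degradome tags piling up opposite miRNA position `cleavage_pos`.

.BASES <- c("A", "C", "G", "U")

rand_rna <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# sample one element from a vector, safe for length-1 vectors
pick1 <- function(x) x[sample.int(length(x), 1L)]

# bases that neither Watson-Crick- nor wobble-pair with `b`
.nonpairing <- list(A = c("A", "C", "G"), C = c("A", "C", "U"),
                    G = c("A", "G"), U = c("C", "U"))

#' Simulation configuration
#'
#' Defaults describe the emulated study design: three libraries (one
#' control, two heat treatments) at 5e5 reads each, planted |log2 fold
#' change| 2 on a fifth of the mature miRNAs, ~30% contaminant reads
#' split across Rfam-style classes, a degradome signal-to-noise ratio of
#' 10, and a TruSeq-style small-RNA 3' adapter.
#'
#' @param n_precursors Number of expressed hairpin precursors.
#' @param n_catalog_extra Catalog entries (precursor + mature) with zero
#'   planted abundance.
#' @param star_fraction Fraction of precursors whose opposite-arm (star)
#'   sequence is also planted (the novel-candidate ground truth).
#' @param n_transcripts Transcriptome size.
#' @param transcript_len Length range `c(min, max)` of transcripts (nt).
#' @param library_depth Total reads per small-RNA library.
#' @param de_fraction Fraction of mature miRNAs with a planted fold
#'   change in each treatment library.
#' @param de_log2fc Magnitude of the planted log2 fold change.
#' @param adapter 3' adapter appended to every legitimate read.
#' @param contaminant_fraction Named read fractions per contaminant class
#'   (`rRNA`, `tRNA`, `snoRNA`, `snRNA`, `other`, `mRNA`, `repeat`).
#' @param junk_fraction Fraction of junk reads (N-containing or
#'   homopolymer inserts).
#' @param length_outlier_fraction Fraction of inserts outside 19-24 nt.
#' @param no_adapter_fraction Fraction of reads emitted without the 3'
#'   adapter (removed by trimming).
#' @param srna_background_fraction Nominal control-library fraction of
#'   valid non-miRNA sRNAs (the 24-nt-dominated siRNA background of plant
#'   libraries); their absolute abundance is identical across libraries.
#' @param n_background Size of the background sRNA sequence pool.
#' @param abundance_sdlog Log-normal sigma of the per-miRNA abundance.
#' @param star_rel Star-strand abundance relative to its mature.
#' @param min_star_tpm Floor on a star's expected TPM so every planted
#'   novel candidate is recoverable under the copy-number threshold.
#' @param target_fraction Fraction of transcripts carrying a planted,
#'   perfectly complementary miRNA target site.
#' @param degradome_signal_to_noise Planted-site tag abundance relative to
#'   the (unit-count) background tags.
#' @param degradome_background_per_nt Expected background degradome tags
#'   per transcript nt (0 = no background).
#' @param n_terms Size of the annotation term vocabulary.
#' @param libraries Library names; the first is the control.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_precursors = 60L, n_catalog_extra = 10L,
                       star_fraction = 0.5, n_transcripts = 100L,
                       transcript_len = c(300L, 600L),
                       library_depth = 5e5, de_fraction = 0.2,
                       de_log2fc = 2, adapter = "UGGAAUUCUCGGGUGCCAAGG",
                       contaminant_fraction = c(
                         rRNA = 0.12, tRNA = 0.05, snoRNA = 0.01,
                         snRNA = 0.01, other = 0.02, mRNA = 0.08,
                         "repeat" = 0.01),
                       junk_fraction = 0.005,
                       length_outlier_fraction = 0.015,
                       no_adapter_fraction = 0.02,
                       srna_background_fraction = 0.40,
                       n_background = 2000L,
                       abundance_sdlog = 1, star_rel = 0.2,
                       min_star_tpm = 50, target_fraction = 0.4,
                       degradome_signal_to_noise = 10,
                       degradome_background_per_nt = 0.02,
                       n_terms = 20L,
                       libraries = c("NT", "MET", "AET"), seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_precursors < 1L) stop("need at least one precursor",
                                  call. = FALSE)
  if (cfg$library_depth < 1) stop("depth must be >= 1", call. = FALSE)
  fr <- c(cfg$contaminant_fraction, cfg$junk_fraction,
          cfg$length_outlier_fraction, cfg$srna_background_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1)
    stop("read-class fractions must lie in [0,1] and sum to below 1",
         call. = FALSE)
  if (length(cfg$libraries) < 2L)
    stop("need a control and at least one treatment library", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Build one valid stem-loop precursor hosting a mature (and star) span.
# Retries until the folded structure passes validate_hairpin with the
# MFEI rule; returns list(sequence, record, mature_span, star_span, arm).
.build_precursor <- function(run_cfg) {
  repeat {
    arm_len <- sample(20:24, 1)
    loop_len <- sample(4:8, 1)
    arm5 <- sample(.BASES, arm_len, replace = TRUE)
    arm3 <- strsplit(chartr("ACGU", "UGCA",
                            paste(rev(arm5), collapse = "")), "",
                     fixed = TRUE)[[1]]
    mature_len <- pick1(20:min(22, arm_len))
    arm <- sample(c("5p", "3p"), 1)
    off <- pick1(0:(arm_len - mature_len))
    # the mature:star duplex window in 5p-arm coordinates; at least one
    # symmetric mismatch falls inside it so the star strand is never the
    # exact reverse complement of the mature (as in real duplexes)
    duplex5 <- if (arm == "5p") (off + 1L):(off + mature_len)
               else (arm_len - off - mature_len + 1L):(arm_len - off)
    pool <- 3:(arm_len - 2)
    n_mm <- sample(1:3, 1)
    at <- pick1(intersect(duplex5, pool))
    if (n_mm > 1L)
      at <- unique(c(at, sample(pool, n_mm - 1L)))
    for (p in at) {
      b <- arm5[p]
      arm3[arm_len - p + 1L] <- sample(.nonpairing[[b]], 1)
    }
    loop <- sample(.BASES, loop_len, replace = TRUE)
    seqv <- c(arm5, loop, arm3)
    sequence <- paste(seqv, collapse = "")
    L <- length(seqv)
    mature_span <- if (arm == "5p") c(1L + off, off + mature_len)
                   else c(arm_len + loop_len + 1L + off,
                          arm_len + loop_len + off + mature_len)
    star_span <- c(L - mature_span[2] + 1L, L - mature_span[1] + 1L)
    record <- hairpin_record(sequence)
    v <- validate_hairpin(record, mature_span, run_cfg, novel_mode = TRUE)
    if (!v$valid || is.na(v$arm) || v$arm != arm) next
    vs <- validate_hairpin(record, star_span, run_cfg, novel_mode = TRUE)
    if (!vs$valid || is.na(vs$arm) || vs$arm == arm) next
    return(list(sequence = sequence, record = record,
                mature_span = mature_span, star_span = star_span,
                arm = arm))
  }
}

#' Generate the synthetic reference set
#'
#' Writes a miRBase-style catalog (precursor + mature FASTA), a
#' transcriptome with planted perfectly complementary target sites,
#' contaminant reference FASTAs, and a gene-to-term annotation table with
#' a known enriched term among target genes; returns the ground-truth
#' manifest that the evaluation helpers compare against.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @param run_cfg A `run_config` (the generated precursors are guaranteed
#'   to pass its hairpin criteria).
#' @return A `ground_truth_manifest` list: `cfg`, `libraries`,
#'   `precursors`, `planted` (per-sequence expected TPM per library),
#'   `planted_de`, `planted_cleavages`, `annotation`, `enriched_term`,
#'   `contaminant_census`, `paths`.
#' @export
generate_reference_set <- function(cfg, out_dir,
                                   run_cfg = run_config(seed = cfg$seed)) {
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_precursors
  fam_pool <- c(156, 159, 160, 166, 167, 168, 171, 172, 319, 396, 398,
                399, 408, 482, 528, 828, 1446, 5303, 6022, 6300, 7972,
                8007, 8029, 8155)
  fam_w <- 1 / sqrt(seq_along(fam_pool))
  fams <- sample(fam_pool, n + cfg$n_catalog_extra, replace = TRUE,
                 prob = fam_w)
  letter_idx <- stats::ave(seq_along(fams), fams, FUN = seq_along)
  has_star <- c(rep(TRUE, round(cfg$star_fraction * n)),
                rep(FALSE, n - round(cfg$star_fraction * n)))

  prec_rows <- list(); mature <- character(0); hairpins <- character(0)
  planted_rows <- list()
  star_i <- 0L
  for (i in seq_len(n + cfg$n_catalog_extra)) {
    p <- .build_precursor(run_cfg)
    expressed <- i <= n
    pid <- sprintf("spi-MIR%d%s", fams[i], letters[letter_idx[i]])
    mname <- sprintf("spi-miR%d%s-%s", fams[i], letters[letter_idx[i]],
                     p$arm)
    mseq <- substr(p$sequence, p$mature_span[1], p$mature_span[2])
    hairpins[pid] <- p$sequence
    mature[mname] <- mseq
    star_name <- NA_character_
    if (expressed && has_star[i]) {
      star_i <- star_i + 1L
      star_name <- sprintf("PC-%d-%s", star_i,
                           if (p$arm == "5p") "3p" else "5p")
    }
    prec_rows[[i]] <- data.frame(
      precursor_id = pid, sequence = p$sequence, mfei = p$record$mfei,
      mature_name = mname, mature_seq = mseq, arm = p$arm,
      mature_start = p$mature_span[1], mature_end = p$mature_span[2],
      star_name = star_name, star_start = p$star_span[1],
      star_end = p$star_span[2], expressed = expressed,
      stringsAsFactors = FALSE)
    if (expressed) {
      planted_rows[[length(planted_rows) + 1L]] <- data.frame(
        seq_id = mname, sequence = mseq, type = "mature",
        precursor_id = pid, arm = p$arm, stringsAsFactors = FALSE)
      if (has_star[i]) {
        sseq <- substr(p$sequence, p$star_span[1], p$star_span[2])
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          seq_id = star_name, sequence = sseq, type = "star",
          precursor_id = pid, arm = if (p$arm == "5p") "3p" else "5p",
          stringsAsFactors = FALSE)
      }
    }
  }
  precursors <- do.call(rbind, prec_rows)
  planted <- do.call(rbind, planted_rows)
  # one alias entry: a second catalog name carrying the same sequence, to
  # exercise sequence-shared expression attribution
  alias <- paste0(planted$seq_id[planted$type == "mature"][1], "_ath")
  mature[alias] <- planted$sequence[planted$type == "mature"][1]

  # per-sequence abundance: log-normal matures, scaled-down stars
  is_mat <- planted$type == "mature"
  base_rel <- numeric(nrow(planted))
  base_rel[is_mat] <- stats::rlnorm(sum(is_mat), meanlog = 0,
                                    sdlog = cfg$abundance_sdlog)
  mat_rel <- stats::setNames(base_rel[is_mat],
                             planted$precursor_id[is_mat])
  base_rel[!is_mat] <- cfg$star_rel *
    mat_rel[planted$precursor_id[!is_mat]]
  planted$base_rel <- base_rel

  # planted fold changes: independent DE sets per treatment library
  ctrl <- cfg$libraries[1]
  treats <- cfg$libraries[-1]
  lfc <- matrix(0, nrow(planted), length(cfg$libraries),
                dimnames = list(planted$seq_id, cfg$libraries))
  de_rows <- list()
  mat_ids <- planted$seq_id[is_mat]
  n_de <- round(cfg$de_fraction * length(mat_ids))
  for (tr in treats) {
    de_ids <- sample(mat_ids, n_de)
    sign <- rep(c(1, -1), length.out = n_de)
    lfc[de_ids, tr] <- sign * cfg$de_log2fc
    if (n_de)
      de_rows[[tr]] <- data.frame(pair = paste0(tr, "_vs_", ctrl),
                                  seq_id = de_ids,
                                  log2fc = sign * cfg$de_log2fc,
                                  stringsAsFactors = FALSE)
  }
  planted_de <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(pair = character(0), seq_id = character(0),
               log2fc = numeric(0))
  rownames(planted_de) <- NULL

  # absolute-concentration model: planted miRNAs change with their fold
  # changes while the background sRNA pool, contaminants and junk keep
  # fixed absolute weights, as in a spiked total-RNA pool. Nominal read
  # fractions apply to the control library.
  f_other <- sum(cfg$contaminant_fraction) + cfg$junk_fraction +
    cfg$length_outlier_fraction + cfg$srna_background_fraction
  f_mirna <- 1 - f_other
  rel <- planted$base_rel * 2^lfc
  tpm_of <- function(rel, w_bg) {
    denom <- colSums(rel) + w_bg   # valid-read weight per library
    sweep(rel, 2, denom, "/") * 1e6
  }
  S_ctrl <- sum(rel[, ctrl])
  w_bg <- S_ctrl * cfg$srna_background_fraction / f_mirna
  tpm <- tpm_of(rel, w_bg)
  low <- !is_mat & apply(tpm, 1, max) < cfg$min_star_tpm
  if (any(low)) {
    scale_up <- cfg$min_star_tpm * 1.3 / tpm[low, ctrl]
    planted$base_rel[low] <- planted$base_rel[low] * scale_up
    rel <- planted$base_rel * 2^lfc
    S_ctrl <- sum(rel[, ctrl])
    w_bg <- S_ctrl * cfg$srna_background_fraction / f_mirna
    tpm <- tpm_of(rel, w_bg)
  }
  for (lib in cfg$libraries) {
    planted[[paste0("rel_", lib)]] <- rel[, lib]
    planted[[paste0("tpm_", lib)]] <- tpm[, lib]
  }
  # background pool: 24-nt-heavy length structure, log-normal abundance
  bg_len <- sample(19:24, cfg$n_background, replace = TRUE,
                   prob = c(0.06, 0.10, 0.16, 0.10, 0.08, 0.50))
  bg_w <- stats::rlnorm(cfg$n_background, 0, cfg$abundance_sdlog)
  background <- data.frame(sequence = vapply(bg_len, rand_rna, ""),
                           weight = bg_w / sum(bg_w) * w_bg,
                           stringsAsFactors = FALSE)
  class_weights <- c(cfg$contaminant_fraction, junk = cfg$junk_fraction,
                     length_out = cfg$length_outlier_fraction) *
    S_ctrl / f_mirna

  # transcriptome with planted target sites (perfect complements)
  tx_len <- sample(cfg$transcript_len[1]:cfg$transcript_len[2],
                   cfg$n_transcripts, replace = TRUE)
  tx <- vapply(tx_len, rand_rna, "")
  names(tx) <- sprintf("gene%03d", seq_len(cfg$n_transcripts))
  n_targets <- round(cfg$target_fraction * cfg$n_transcripts)
  target_tx <- sample(names(tx), n_targets)
  cleav_rows <- list()
  for (tid in target_tx) {
    mi <- sample(which(is_mat), 1)
    mseq <- planted$sequence[mi]
    L <- nchar(mseq)
    len <- nchar(tx[[tid]])
    s <- sample(40:(len - L - 40), 1)
    site_seq <- reverse_complement(mseq)
    tx[[tid]] <- paste0(substr(tx[[tid]], 1, s - 1), site_seq,
                        substr(tx[[tid]], s + L, len))
    cleav_rows[[tid]] <- data.frame(
      seq_id = planted$seq_id[mi], mirna_seq = mseq, transcript_id = tid,
      window_start = s, site = s + L - run_cfg$cleavage_pos,
      stringsAsFactors = FALSE)
  }
  planted_cleavages <- do.call(rbind, cleav_rows)
  rownames(planted_cleavages) <- NULL

  # contaminant references (mRNA class = the transcriptome itself)
  mkref <- function(prefix, k, len)
    stats::setNames(vapply(rep(len, k), rand_rna, ""),
                    paste0(prefix, seq_len(k)))
  references <- list(
    rRNA = mkref("rRNA_", 3, 800), tRNA = mkref("tRNA_", 8, 75),
    snoRNA = mkref("snoRNA_", 4, 110), snRNA = mkref("snRNA_", 4, 140),
    other = mkref("ncRNA_", 5, 200), mRNA = tx,
    "repeat" = mkref("repeat_", 3, 400))

  # annotation with one term enriched among target genes
  terms <- sprintf("T%02d", seq_len(cfg$n_terms))
  enriched_term <- "T_HEAT"
  ann_rows <- lapply(names(tx), function(g) {
    k <- sample(1:4, 1)
    data.frame(gene_id = g, term_id = sample(terms, k),
               stringsAsFactors = FALSE)
  })
  annotation <- do.call(rbind, ann_rows)
  extra <- data.frame(
    gene_id = c(target_tx[stats::runif(n_targets) < 0.8],
                setdiff(names(tx), target_tx)[
                  stats::runif(cfg$n_transcripts - n_targets) < 0.05]),
    term_id = enriched_term, stringsAsFactors = FALSE)
  annotation <- rbind(annotation, extra)
  annotation <- annotation[order(annotation$gene_id, annotation$term_id), ]
  rownames(annotation) <- NULL

  paths <- list(
    precursors = file.path(out_dir, "precursors.fa"),
    mature = file.path(out_dir, "mature.fa"),
    transcriptome = file.path(out_dir, "transcriptome.fa"),
    annotation = file.path(out_dir, "annotation.tsv"),
    contaminants = stats::setNames(
      file.path(out_dir, paste0("contaminant_",
                                gsub(":", "_", names(references)), ".fa")),
      names(references)))
  write_fasta(hairpins, paths$precursors)
  write_fasta(mature, paths$mature)
  write_fasta(tx, paths$transcriptome, as_dna = TRUE)
  for (cls in names(references))
    write_fasta(references[[cls]], paths$contaminants[[cls]],
                as_dna = TRUE)
  write_report_tsv(annotation, paths$annotation)
  write_report_tsv(planted[, c("seq_id", "type", "precursor_id", "arm",
                               paste0("tpm_", cfg$libraries))],
                   file.path(out_dir, "manifest_planted.tsv"))
  write_report_tsv(planted_de, file.path(out_dir, "manifest_de.tsv"))
  write_report_tsv(planted_cleavages,
                   file.path(out_dir, "manifest_cleavages.tsv"))

  structure(list(
    cfg = cfg,
    libraries = data.frame(name = cfg$libraries,
                           role = c("control",
                                    rep("treatment",
                                        length(cfg$libraries) - 1L)),
                           stringsAsFactors = FALSE),
    precursors = precursors, planted = planted, planted_de = planted_de,
    planted_cleavages = planted_cleavages, annotation = annotation,
    enriched_term = enriched_term, references = references,
    background = background, class_weights = class_weights,
    contaminant_census = lengths(references), catalog_alias = alias,
    paths = paths), class = "ground_truth_manifest")
}

#' Generate one synthetic small-RNA library
#'
#' Reads are drawn from a single multinomial over planted sequences
#' (log-normal abundance times the planted fold change for treatment
#' libraries), contaminant fragments, junk reads and length outliers;
#' every read carries the 3' adapter except a stated no-adapter fraction.
#'
#' @param cfg The `sim_config` used for the reference set.
#' @param manifest The [generate_reference_set()] manifest.
#' @param library Library name (must be one of `cfg$libraries`).
#' @param path Output FASTQ path.
#' @return Invisibly, a list with `path`, `n_reads`, and
#'   `planted_counts` (named sampled read counts per planted sequence).
#' @export
generate_srna_library <- function(cfg, manifest, library, path) {
  li <- match(library, cfg$libraries)
  if (is.na(li)) stop("unknown library: ", library, call. = FALSE)
  set.seed(cfg$seed + 7919L * li)
  planted <- manifest$planted
  rel <- planted[[paste0("rel_", library)]]
  cont <- cfg$contaminant_fraction
  weights <- c(rel, manifest$background$weight, manifest$class_weights)
  counts <- as.integer(stats::rmultinom(1, cfg$library_depth,
                                        weights / sum(weights)))
  np <- nrow(planted)
  nbg <- nrow(manifest$background)
  names(counts) <- c(planted$seq_id, rep("", nbg),
                     names(manifest$class_weights))

  # planted miRNA/star copies and fixed-abundance background sRNAs
  reads <- c(rep(planted$sequence, counts[seq_len(np)]),
             rep(manifest$background$sequence,
                 counts[np + seq_len(nbg)]))
  # contaminant fragments: random 19-24 nt substrings of class references
  for (cls in names(cont)) {
    m <- counts[[cls]]
    if (m == 0) next
    refs <- manifest$references[[cls]]
    ri <- sample(length(refs), m, replace = TRUE)
    len <- sample(19:24, m, replace = TRUE)
    maxs <- nchar(refs)[ri] - len + 1L
    st <- 1L + floor(stats::runif(m) * pmax(maxs, 1L))
    reads <- c(reads, substr(refs[ri], st, st + len - 1L))
  }
  # junk: N-containing or >= 80% homopolymer inserts
  m <- counts[["junk"]]
  if (m > 0) {
    jl <- sample(19:24, m, replace = TRUE)
    junk <- vapply(jl, function(l) {
      if (stats::runif(1) < 0.5) {
        s <- sample(.BASES, l, replace = TRUE)
        s[sample(l, sample(1:3, 1))] <- "N"
      } else {
        s <- rep(sample(.BASES, 1), l)
        s[sample(l, sample(0:2, 1))] <- sample(.BASES, 1)
      }
      paste(s, collapse = "")
    }, "")
    reads <- c(reads, junk)
  }
  # length outliers (removed by the 19-24 nt filter)
  m <- counts[["length_out"]]
  if (m > 0) {
    ol <- sample(c(15:18, 25:28), m, replace = TRUE)
    reads <- c(reads, vapply(ol, rand_rna, ""))
  }
  with_adapter <- stats::runif(length(reads)) >= cfg$no_adapter_fraction
  reads[with_adapter] <- paste0(reads[with_adapter], cfg$adapter)
  reads <- sample(reads)
  write_fastq(reads, path,
              ids = sprintf("%s_read%d", library, seq_along(reads)))
  invisible(list(path = path, n_reads = length(reads),
                 planted_counts = counts[seq_len(np)]))
}

#' Generate a synthetic degradome library
#'
#' For every planted cleavage site, tags of 20-21 nt whose 5' end is
#' exactly the planted site are emitted at `degradome_signal_to_noise`
#' times the unit background count; background tags start uniformly along
#' transcripts (expected `degradome_background_per_nt` per nt, each one
#' read). Written as collapsed FASTA (`dtag<N>_x<COUNT>` headers).
#'
#' @param cfg The `sim_config`.
#' @param manifest The [generate_reference_set()] manifest.
#' @param path Output FASTA path.
#' @param label Optional library label mixed into the random stream so
#'   several degradome libraries from one manifest differ in their noise.
#' @return Invisibly, a list with `path` and the collapsed `tags` data
#'   frame (`sequence`, `count`, `transcript_id`, `position`, `planted`).
#' @export
generate_degradome_library <- function(cfg, manifest, path, label = "D1") {
  if (is.null(manifest$planted_cleavages) ||
      !nrow(manifest$planted_cleavages))
    stop("manifest has no planted cleavages", call. = FALSE)
  set.seed(cfg$seed + 104729L +
             sum(utf8ToInt(label)) * 131L)
  tx <- manifest$references$mRNA
  rows <- list()
  sig <- max(1L, as.integer(round(cfg$degradome_signal_to_noise)))
  pc <- manifest$planted_cleavages
  for (r in seq_len(nrow(pc))) {
    tid <- pc$transcript_id[r]
    pos <- pc$site[r]
    len <- sample(20:21, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = substr(tx[[tid]], pos, pos + len - 1L), count = sig,
      transcript_id = tid, position = pos, planted = TRUE,
      stringsAsFactors = FALSE)
  }
  if (cfg$degradome_background_per_nt > 0) {
    for (tid in names(tx)) {
      len <- nchar(tx[[tid]])
      nbg <- stats::rpois(1, len * cfg$degradome_background_per_nt)
      if (nbg == 0) next
      st <- sample(len - 21L, nbg, replace = TRUE)
      tl <- sample(20:21, nbg, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(rep(tx[[tid]], nbg), st, st + tl - 1L),
        count = 1L, transcript_id = tid, position = st, planted = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  tags <- do.call(rbind, rows)
  # collapse identical tag sequences (background can stack on a site)
  agg <- stats::aggregate(count ~ sequence, tags, sum)
  write_collapsed_fasta(chartr("U", "T", agg$sequence), agg$count, path,
                        ids = paste0("dtag", seq_len(nrow(agg))))
  invisible(list(path = path, tags = tags, collapsed = agg))
}
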