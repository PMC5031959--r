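small_cfg <- function(seed = 9L, ...) {
  sim_config(n_precursors = 6L, n_catalog_extra = 1L, n_transcripts = 15L,
             library_depth = 2e4, n_background = 200L, seed = seed, ...)
}

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  m1 <- generate_reference_set(cfg, d1)
  m2 <- generate_reference_set(cfg, d2)
  for (f in c("precursors", "mature", "transcriptome", "annotation"))
    expect_identical(readLines(m1$paths[[f]]), readLines(m2$paths[[f]]))
  p1 <- file.path(d1, "r.fastq"); p2 <- file.path(d2, "r.fastq")
  generate_srna_library(cfg, m1, "NT", p1)
  generate_srna_library(cfg, m2, "NT", p2)
  expect_identical(readLines(p1), readLines(p2))
  q1 <- file.path(d1, "d.fa"); q2 <- file.path(d2, "d.fa")
  generate_degradome_library(cfg, m1, q1)
  generate_degradome_library(cfg, m2, q2)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("the manifest matches the requested design", {
  cfg <- small_cfg(seed = 10L)
  man <- generate_reference_set(cfg, file.path(tempdir(), "design"))
  expect_identical(sum(man$precursors$expressed), 6L)
  expect_identical(nrow(man$precursors), 7L)   # + catalog extras
  expect_identical(sum(man$planted$type == "mature"), 6L)
  # every planted cleavage site is the base paired to miRNA position 10
  # of a perfectly complementary window
  tx <- man$references$mRNA
  pc <- man$planted_cleavages
  for (r in seq_len(nrow(pc))) {
    L <- nchar(pc$mirna_seq[r])
    win <- substr(tx[[pc$transcript_id[r]]], pc$window_start[r],
                  pc$window_start[r] + L - 1L)
    expect_identical(win, reverse_complement(pc$mirna_seq[r]))
    expect_identical(pc$site[r], pc$window_start[r] + L - 10L)
  }
  # generated precursors satisfy the novel-mode hairpin criteria
  for (r in which(man$precursors$expressed)) {
    rec <- hairpin_record(man$precursors$sequence[r])
    v <- validate_hairpin(rec, c(man$precursors$mature_start[r],
                                 man$precursors$mature_end[r]),
                          novel_mode = TRUE)
    expect_true(v$valid)
  }
  expect_error(sim_config(n_precursors = 0), "at least one")
  expect_error(sim_config(junk_fraction = 1), "fractions")
  expect_error(generate_srna_library(small_cfg(), man, "XX", tempfile()),
               "unknown library")
})

test_that("no-noise libraries pass preprocessing unscathed", {
  cfg <- small_cfg(seed = 11L,
                   contaminant_fraction = c(rRNA = 0, tRNA = 0, snoRNA = 0,
                                            snRNA = 0, other = 0, mRNA = 0,
                                            "repeat" = 0),
                   junk_fraction = 0, length_outlier_fraction = 0,
                   no_adapter_fraction = 0)
  man <- generate_reference_set(cfg, file.path(tempdir(), "nonoise"))
  p <- file.path(tempdir(), "nonoise", "NT.fastq")
  generate_srna_library(cfg, man, "NT", p)
  reads <- read_sequences(p)
  inserts <- trim_adapter(reads, cfg$adapter)
  expect_false(anyNA(inserts))
  expect_true(all(quality_filter(inserts) == "kept"))
})

test_that("sampled planted counts track the manifest expectation", {
  cfg <- sim_config(n_precursors = 6L, n_catalog_extra = 1L,
                    n_transcripts = 15L, library_depth = 1e5,
                    n_background = 200L, seed = 12L)
  man <- generate_reference_set(cfg, file.path(tempdir(), "abund"))
  lib <- generate_srna_library(cfg, man, "NT",
                               file.path(tempdir(), "abund", "NT.fastq"))
  w <- c(man$planted$rel_NT, man$background$weight, man$class_weights)
  p <- man$planted$rel_NT / sum(w)
  expected <- cfg$library_depth * p
  sd <- sqrt(cfg$library_depth * p * (1 - p))
  z <- abs(lib$planted_counts - expected) / sd
  expect_true(all(z < 4))
  expect_gte(mean(z < 3), 0.9)
  # zero planted abundance means the sequence is absent from the library
  man0 <- man
  man0$planted$rel_NT[1] <- 0
  p0 <- file.path(tempdir(), "abund", "NT0.fastq")
  generate_srna_library(cfg, man0, "NT", p0)
  reads <- read_sequences(p0)
  ins <- trim_adapter(reads, cfg$adapter)
  expect_false(man0$planted$sequence[1] %in% ins)
})

test_that("planted miRNAs survive the full discovery chain end to end", {
  st <- small_study()
  man <- st$manifest
  # star tags: degradome signal never contaminates the sRNA ground truth
  expect_true(all(man$planted$tpm_NT[man$planted$type == "star"] >=
                    st$cfg$min_star_tpm * 0.99))
  # planted DE table covers each treatment pair at the configured size
  n_mat <- sum(man$planted$type == "mature")
  for (pair in unique(man$planted_de$pair))
    expect_equal(sum(man$planted_de$pair == pair),
                 round(st$cfg$de_fraction * n_mat))
})
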