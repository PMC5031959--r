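adapter <- "UGGAAUUCUCGGGUGCCAAGG"

test_that("adapter trimming matches exhaustive search on random reads", {
  insert <- "ACGUACGUACGUACGUACGUA"
  expect_identical(trim_adapter(paste0(insert, adapter), adapter), insert)
  expect_true(is.na(trim_adapter(insert, adapter)))
  # terminal partial match of exactly 8 adapter bases
  r8 <- paste0(insert, substr(adapter, 1, 8))
  expect_identical(trim_adapter(r8, adapter), insert)
  expect_true(is.na(trim_adapter(paste0(insert, substr(adapter, 1, 7)),
                                 adapter)))
  set.seed(21)
  reads <- replicate(300, {
    ins <- rand_rna_seq(sample(10:30, 1))
    k <- sample(0:nchar(adapter), 1)
    tail <- if (k > 0) substr(adapter, 1, k) else ""
    paste0(ins, tail, if (k == nchar(adapter)) rand_rna_seq(sample(0:10, 1))
           else "")
  })
  got <- trim_adapter(reads, adapter)
  want <- vapply(reads, oracle_trim, "", adapter = adapter,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("length and junk filters hit their stated boundaries", {
  cfg <- run_config()
  expect_identical(quality_filter(rand_rna_seq(18), cfg), "removed:length")
  expect_identical(quality_filter("ACGUACGUACGUACGUACGUACGU", cfg), "kept")
  expect_identical(quality_filter(rand_rna_seq(25), cfg), "removed:length")
  # 19 of 21 A: homopolymer fraction 0.905 >= 0.80
  expect_identical(quality_filter("AAAAAAAAAAAAAAAAAAAGU", cfg),
                   "removed:junk")
  expect_identical(quality_filter("ACGUACGUACGUACGUACGNA", cfg),
                   "removed:junk")
})

test_that("contaminant annotation is exact-substring with fixed precedence", {
  refs <- list(rRNA = "ACGUACGUACGUACGUACGUACGUACGUAAAA",
               mRNA = c("ACGUACGUACGUACGUACGUA", "UUUUGGGGCCCCAAAAUUUUG"))
  tags <- c("ACGUACGUACGUACGUACGUA",  # in both -> rRNA by precedence
            "UUUUGGGGCCCCAAAAUUUUG",  # mRNA only
            "GCGCGCGCAUAUAUAUGCGCG")  # nothing
  expect_identical(annotate_contaminants(tags, refs),
                   c("rfam:rRNA", "mRNA", "valid"))
})

test_that("collapsing conserves read counts and is annotation-order free", {
  out <- collapse_tags(c("NT", "NT", "NT"),
                       c("ACGUA", "ACGUA", "GGGUU"))
  expect_identical(out$NT[match(c("ACGUA", "GGGUU"), out$sequence)],
                   c(2L, 1L))
  expect_identical(nrow(collapse_tags(character(0), character(0), "NT")), 0L)
  set.seed(5)
  pool <- replicate(80, rand_rna_seq(21))
  libs <- sample(c("A", "B"), 1e4, replace = TRUE)
  ins <- sample(pool, 1e4, replace = TRUE)
  tags <- collapse_tags(libs, ins, libraries = c("A", "B"))
  expect_identical(sum(tags$A) + sum(tags$B), 10000L)
  # class totals identical whether computed before or after collapsing
  refs <- list(rRNA = paste(pool[1:10], collapse = ""))
  per_read <- annotate_contaminants(ins, refs)
  per_tag <- annotate_contaminants(tags$sequence, refs)
  expect_identical(sum(per_read == "rfam:rRNA"),
                   sum((tags$A + tags$B)[per_tag == "rfam:rRNA"]))
})

test_that("library summary recomputes percentages from counts", {
  tc <- c(raw = 10850996, adapter_length = 3985067, junk = 21863,
          rRNA = 568456, tRNA = 111052, snoRNA = 3106, snRNA = 2354,
          other = 35549, mRNA = 2989464, "repeat" = 9757, valid = 3333687)
  uc <- c(raw = 1937422, adapter_length = 878490, junk = 10187,
          rRNA = 34268, tRNA = 9357, snoRNA = 925, snRNA = 1237,
          other = 4752, mRNA = 183508, "repeat" = 774, valid = 829756)
  s <- library_summary(tc, uc)
  expect_equal(s$pct_total[s$category == "valid"], 30.72)
  expect_equal(s$pct_unique[s$category == "valid"], 42.83)
  expect_equal(s$count[s$category == "rfam_total"],
               568456 + 111052 + 3106 + 2354 + 35549)
  tc0 <- tc; tc0["valid"] <- 0
  uc0 <- uc; uc0["valid"] <- 0
  expect_equal(library_summary(tc0, uc0)$pct_total[12], 0.00)
  tc_bad <- tc; tc_bad["raw"] <- 0
  expect_error(library_summary(tc_bad, uc), "raw total")
})

test_that("length distribution fractions sum to one for both weightings", {
  d <- length_distribution(c(rand_rna_seq(21), rand_rna_seq(24)), c(3, 1))
  expect_equal(d$total_frac[d$length == 21], 0.75)
  expect_equal(d$total_frac[d$length == 24], 0.25)
  expect_equal(d$unique_frac[d$length %in% c(21, 24)], c(0.5, 0.5))
  expect_equal(sum(d$total_frac), 1)
  expect_equal(sum(d$unique_frac), 1)
  expect_error(length_distribution(character(0), numeric(0)), "no tags")
})

test_that("preprocessing conserves raw reads across the filter cascade", {
  st <- small_study()
  libs <- library_spec(st$cfg$libraries, unname(st$manifest$paths$reads),
                       c("control", "treatment", "treatment"))
  pre <- preprocess_libraries(libs, st$cfg$adapter,
                              st$manifest$references, run_config())
  for (lib in st$cfg$libraries) {
    s <- pre$summaries[[lib]]
    parts <- s$count[s$category %in% c("adapter_length", "junk", "rRNA",
                                       "tRNA", "snoRNA", "snRNA", "other",
                                       "mRNA", "repeat", "valid")]
    expect_equal(sum(parts), s$count[s$category == "raw"])
    expect_equal(s$count[s$category == "rfam_total"],
                 sum(s$count[s$category %in% c("rRNA", "tRNA", "snoRNA",
                                               "snRNA", "other")]))
  }
})
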