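test_that("duplex scoring applies the stated penalties and doubling", {
  m <- "ACGUACGUACGUACGUACGUA"
  comp <- chartr("ACGU", "UGCA", m)   # aligned complementary strand
  expect_equal(score_duplex(m, comp)$score, 0)
  # G:U at position 15 (outside 2-13): 0.5
  w <- comp
  stopifnot(substr(m, 15, 15) == "G")
  substr(w, 15, 15) <- "U"
  expect_equal(score_duplex(m, w)$score, 0.5)
  # mismatch at position 5 (inside 2-13): doubled to 2
  w2 <- comp
  substr(w2, 5, 5) <- "A"   # A opposite A: mismatch
  expect_equal(score_duplex(m, w2)$pairing[5], "mismatch")
  expect_equal(score_duplex(m, w2)$score, 2)
  # G:U at position 3 (0.5 x 2) + mismatch at 15 (1) = 2
  w3 <- comp
  stopifnot(substr(m, 3, 3) == "G")
  substr(w3, 3, 3) <- "U"
  substr(w3, 15, 15) <- "G"   # G opposite G: mismatch
  expect_equal(score_duplex(m, w3)$score, 2)
  expect_error(score_duplex("ACGU", "ACG"), "lengths differ")
  # monotonicity: adding a mismatch never decreases the score
  set.seed(61)
  for (k in 1:20) {
    mi <- rand_rna_seq(21)
    wi <- chartr("ACGU", "UGCA", mi)
    s0 <- score_duplex(mi, wi)$score
    pos <- sample(21, 1)
    wj <- wi
    substr(wj, pos, pos) <- substr(mi, pos, pos)  # same base: mismatch
    expect_gte(score_duplex(mi, wj)$score, s0)
  }
})

test_that("target-site scanning finds complementary windows", {
  cfg <- run_config()
  set.seed(62)
  m <- rand_rna_seq(21)
  tx <- paste0(rand_rna_seq(100), reverse_complement(m), rand_rna_seq(80))
  hits <- find_target_sites(m, tx, cfg)
  perfect <- hits[hits$score == 0, ]
  expect_identical(perfect$window_start, 101L)
  # cleavage site = transcript base paired to miRNA position 10
  expect_identical(perfect$site, 101L + 21L - 10L)
  # cap 0 returns only perfect windows
  cfg0 <- run_config(score_cap = 0)
  expect_identical(find_target_sites(m, tx, cfg0)$window_start, 101L)
  # random transcript: no hit under the default cap
  expect_identical(nrow(find_target_sites(m, rand_rna_seq(500), cfg)), 0L)
})

test_that("degradome tags map at their 5' ends, multi-mapping included", {
  tx <- c(t1 = paste0(strrep("A", 10), "GCGCGCAUAUGCGCAUAUGC",
                      strrep("U", 10)),
          t2 = paste0("GCGCGCAUAUGCGCAUAUGC", strrep("C", 15)))
  tag <- "GCGCGCAUAUGCGCAUAUGC"
  prof <- map_degradome_tags(tag, 5L, tx)
  expect_identical(prof$t1[11], 5L)
  expect_identical(prof$t2[1], 5L)
  expect_identical(attr(prof, "n_mapped"), 5L)
  nomatch <- map_degradome_tags("GCGCGCAUAUGCGCAUAUGU", 3L, tx["t2"])
  expect_identical(sum(nomatch$t2), 0L)
  expect_error(map_degradome_tags("ACGUACGUACGU", 1L, tx), ">= 15")
})

test_that("target plots expose max and covered-position median", {
  v <- integer(20)
  v[c(1, 5, 9, 12)] <- c(10L, 4L, 2L, 2L)
  tp <- build_tplot(v)
  expect_identical(tp$max_count, 10L)
  expect_equal(tp$median_count, 3.0)
  single <- build_tplot(c(0L, 7L, 0L))
  expect_identical(single$max_count, 7L)
  expect_equal(single$median_count, 7)
  empty <- build_tplot(integer(5))
  expect_identical(empty$max_count, 0L)
})

test_that("category classification matches the brute-force oracle", {
  # rule-forced examples
  v <- integer(15); v[1] <- 5L
  expect_identical(classify_category(5L, build_tplot(v)), 0L)
  v2 <- integer(15); v2[c(1, 3, 7)] <- c(10L, 10L, 2L)
  expect_identical(classify_category(10L, build_tplot(v2)), 1L)
  v3 <- integer(15); v3[c(1, 5, 9, 12)] <- c(10L, 4L, 2L, 2L)
  expect_identical(classify_category(4L, build_tplot(v3)), 2L)
  expect_identical(classify_category(2L, build_tplot(v3)), 3L)
  expect_identical(classify_category(1L, build_tplot(c(1L, 9L))), 4L)
  expect_error(classify_category(3L, build_tplot(v3)), "absent")
  # randomized profiles against the independently coded oracle
  set.seed(63)
  for (k in 1:400) {
    len <- sample(1:30, 1)
    v <- integer(len)
    ncov <- sample(seq_len(len), 1)
    v[sample(len, ncov)] <- sample(1:50, ncov, replace = TRUE)
    tp <- build_tplot(v)
    covered <- v[v > 0]
    site <- covered[sample(length(covered), 1)]
    expect_identical(classify_category(site, tp),
                     oracle_category(site, covered))
  }
})

test_that("target report counts sites once per library and sums by category", {
  ev <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2", "m2"),
    mirna_seq = "x", transcript_id = c("t1", "t1", "t2", "t3", "t3"),
    site = c(5L, 5L, 9L, 2L, 2L), site_count = 3L, score = 0,
    category = c(0L, 0L, 2L, 4L, 4L),
    library = c("NT", "NT", "NT", "NT", "MET"), stringsAsFactors = FALSE)
  rep <- compile_target_report(ev)
  s <- rep$summary
  nt <- s[s$library == "NT", ]
  expect_identical(nt$total, 3L)    # duplicate row collapsed
  expect_identical(nt$category_0 + nt$category_1 + nt$category_2 +
                     nt$category_3 + nt$category_4, nt$total)
  expect_identical(rep$union_count, 3L)
  expect_gte(rep$union_count, max(s$total))
})

test_that("planted cleavages are recovered at strong categories", {
  st <- small_study()
  man <- st$manifest
  cfg <- run_config()
  tx <- man$references$mRNA
  mirnas <- setNames(man$planted$sequence, man$planted$seq_id)
  dseq <- read_sequences(man$paths$degradome[["NT"]])
  parsed <- parse_count_header(names(dseq))
  profiles <- map_degradome_tags(dseq, parsed$count, tx)
  events <- validate_cleavage_events(mirnas, tx, profiles, "NT", cfg)
  ev <- evaluate_degradome(events, man)
  expect_equal(ev$recovered, 1)
  expect_equal(ev$recovered_cat01, 1)
  # no-background library: every planted site is the unique maximum
  cfg_nb <- st$cfg
  cfg_nb$degradome_background_per_nt <- 0
  nb <- generate_degradome_library(cfg_nb, man,
                                   file.path(tempdir(), "deg_nb.fa"))
  s2 <- read_sequences(nb$path)
  p2 <- parse_count_header(names(s2))
  if (is.list(p2) && !is.data.frame(p2))
    p2 <- data.frame(id = p2$id, count = p2$count)
  prof2 <- map_degradome_tags(s2, p2$count, tx)
  ev2 <- evaluate_degradome(
    validate_cleavage_events(mirnas, tx, prof2, "NB", cfg), man)
  expect_equal(ev2$recovered_cat0, 1)
  # unit-abundance planted site, no background -> category 4
  cfg_u <- cfg_nb
  cfg_u$degradome_signal_to_noise <- 1
  u <- generate_degradome_library(cfg_u, man,
                                  file.path(tempdir(), "deg_u.fa"))
  s3 <- read_sequences(u$path)
  p3 <- parse_count_header(names(s3))
  if (is.list(p3) && !is.data.frame(p3))
    p3 <- data.frame(id = p3$id, count = p3$count)
  prof3 <- map_degradome_tags(s3, p3$count, tx)
  ev3 <- validate_cleavage_events(mirnas, tx, prof3, "U", cfg)
  planted_keys <- paste(man$planted_cleavages$mirna_seq,
                        man$planted_cleavages$transcript_id,
                        man$planted_cleavages$site)
  got <- ev3[paste(ev3$mirna_seq, ev3$transcript_id, ev3$site) %in%
               planted_keys, ]
  expect_true(all(got$category == 4L))
})

test_that("degradome summary recomputes mapping percentages", {
  s <- degradome_summary(11774232, 3596303, 9441429, 2537930, 34727, 22865)
  expect_equal(s$pct_mapped, 80.19)
  expect_equal(s$pct_unique_mapped, 70.57)
  expect_equal(s$pct_covered, 65.84)
  expect_error(degradome_summary(0, 1, 0, 0, 1, 0), "positive")
})
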