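test_that("TPM normalization follows its identity", {
  expect_equal(tpm_normalize(c(2, 2), 4), c(5e5, 5e5))
  expect_equal(tpm_normalize(c(1, 3), 4), c(2.5e5, 7.5e5))
  set.seed(51)
  x <- rpois(50, 20) + 1
  expect_equal(sum(tpm_normalize(x, sum(x))), 1e6)
  expect_error(tpm_normalize(1, 0), "> 0")
})

test_that("chi-square matches the closed form and reference implementation", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p, 1)
  expect_equal(chi_square_2x2(20, 80, 40, 60)$statistic, 9.524,
               tolerance = 1e-4)
  # invariance under row swap + column swap
  expect_equal(chi_square_2x2(20, 80, 40, 60)$statistic,
               chi_square_2x2(60, 40, 80, 20)$statistic)
  expect_warning(z <- chi_square_2x2(0, 0, 5, 5), "zero margin")
  expect_equal(z$p, 1)
  set.seed(52)
  for (k in 1:25) {
    t <- sample(1:60, 4, replace = TRUE)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(t, 2, byrow = TRUE), correct = FALSE))
    mine <- chi_square_2x2(t[1], t[2], t[3], t[4])
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
  }
})

test_that("Fisher two-sided p matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1.0)
  expect_equal(fisher_exact_2x2(2, 8, 8, 2), 0.023014, tolerance = 1e-5)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / 184756)
  set.seed(53)
  for (k in 1:50) {
    t <- sample(0:25, 4, replace = TRUE)
    if (sum(t) == 0) next
    mine <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(mine, oracle_fisher_p(t[1], t[2], t[3], t[4]))
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("log2 ratio flags single-library detection", {
  expect_equal(log2_ratio(400, 100)$log2, 2)
  expect_equal(log2_ratio(100, 400)$log2, -2)
  ls <- log2_ratio(50, 0, pseudo_tpm_treat = 2, pseudo_tpm_ctrl = 2)
  expect_true(ls$library_specific)
  expect_equal(ls$log2, log2(50 / 2))
  expect_error(log2_ratio(0, 0), "both")
})

test_that("differential verdicts require both tests and the fold gate", {
  cfg <- run_config()
  # counts chosen so each rule fires: clear up, sub-gate ratio, clear down,
  # and a single-library miRNA
  de <- call_differential(
    mirna_id = c("up", "gate", "down", "only"),
    count_treat = c(400, 380, 100, 50),
    count_ctrl = c(100, 200, 400, 0),
    total_treat = 1e5, total_ctrl = 1e5, cfg = cfg)
  expect_identical(de$verdict, c("up", "ns", "down", "library_specific"))
  expect_true(all(de$p_chisq[c(1, 3)] <= 0.05))
  expect_true(de$p_chisq[2] <= 0.05 && de$p_fisher[2] <= 0.05)
  expect_lt(abs(de$log2_ratio[2]), 1)
  # verdict invariant: up implies all three conditions
  up <- de[de$verdict == "up", ]
  expect_true(all(up$log2_ratio >= 1 & up$p_chisq <= 0.05 &
                    up$p_fisher <= 0.05))
  # both-zero rows are excluded upstream
  de0 <- call_differential("z", 0, 0, 10, 10, cfg)
  expect_identical(nrow(de0), 0L)
})

test_that("shared membership reproduces printed-style percentages", {
  # 469 of 662 conserved miRNAs shared across three libraries -> 70.8%
  shared <- sprintf("s%03d", 1:469)
  only1 <- sprintf("a%03d", 1:80)
  only2 <- sprintf("b%03d", 1:60)
  only3 <- sprintf("c%03d", 1:53)
  v <- shared_membership(list(NT = c(shared, only1),
                              MET = c(shared, only2),
                              AET = c(shared, only3)))
  expect_identical(v$n_shared, 469L)
  expect_identical(v$n_union, 662L)
  expect_equal(v$shared_pct, 70.8)
  v2 <- shared_membership(list(x = c("a", "b"), y = c("b", "c"),
                               z = c("b", "d")))
  expect_equal(v2$shared_pct, 25.0)
  expect_identical(v2$regions$count[v2$regions$pattern == "x&y&z"], 1L)
  v3 <- shared_membership(list(p = letters[1:5], q = letters[1:5]))
  expect_equal(v3$shared_pct, 100.0)
})

test_that("2^-ddCt follows the definition", {
  expect_equal(ddct_relative_expression(25, 20, 24, 20), 0.5)
  expect_equal(ddct_relative_expression(24, 20, 24, 20), 1.0)
  expect_equal(ddct_relative_expression(22, 20, 24, 20), 4.0)
})

test_that("no planted effect keeps the significant fraction below alpha", {
  # null libraries: identical composition, only multinomial noise; the
  # fold-change gate makes the dual test conservative
  set.seed(54)
  p <- rlnorm(120); p <- p / sum(p)
  c1 <- as.integer(rmultinom(1, 2e5, p))
  c2 <- as.integer(rmultinom(1, 2e5, p))
  keep <- c1 + c2 > 0
  de <- call_differential(sprintf("m%d", which(keep)), c1[keep], c2[keep],
                          2e5, 2e5)
  expect_lt(mean(de$verdict %in% c("up", "down")), 0.05)
})
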