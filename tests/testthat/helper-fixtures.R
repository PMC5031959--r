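# Shared fixtures built in code: a perfect stem-loop with a known mature
# span, and a small simulated study cached per test run.

# perfect hairpin: arm + loop + reverse complement of the arm
make_perfect_hairpin <- function(arm = "GCGCAUAUGCGCAUAUGCGCA", loop = "GAAAAC") {
  paste0(arm, loop, reverse_complement(arm))
}

# small end-to-end simulated study (cheap settings), memoised so several
# test files can share one copy
small_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_precursors = 12L, n_catalog_extra = 2L,
                      n_transcripts = 30L, library_depth = 4e4,
                      n_background = 400L, seed = 7L)
    dir <- file.path(tempdir(), "heatmir-small-study")
    man <- simulate_study(cfg, dir)
    cache <<- list(cfg = cfg, manifest = man, dir = dir)
    cache
  }
})
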