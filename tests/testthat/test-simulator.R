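test_that("sample_truth plants the requested structure", {
  tr <- sample_truth(100, 15, seed = 1)
  expect_length(tr$pairs, 15)
  expect_false(anyDuplicated(vapply(tr$pairs, paste, "", collapse = ",")) > 0)
  expect_true(all(unlist(tr$pairs) %in% 1:100))

  tr0 <- sample_truth(50, 0, seed = 2)
  expect_length(tr0$pairs, 0)
  expect_length(tr0$singletons, 0)

  # hub_bias = 1: every pair is anchored on the hub set
  trh <- sample_truth(100, 5, hub_bias = 1, seed = 3, n_hubs = 3)
  hubs <- unique(unlist(trh$pairs))
  shared <- table(unlist(trh$pairs))
  expect_lte(length(names(shared)[shared >= 1]), 5 + 3)
  # structural check: at least one compound participates in >= 2 pairs
  expect_gte(max(shared), 2)

  # roles are disjoint: singletons and triples never overlap pair members
  trm <- sample_truth(60, 4, n_singletons = 2, n_triples = 1, seed = 4)
  pm <- unlist(trm$pairs)
  expect_length(intersect(trm$singletons, pm), 0)
  expect_length(intersect(unlist(trm$triples), c(pm, trm$singletons)), 0)

  expect_error(sample_truth(5, 10, seed = 1), "infeasible")
})

test_that("screen_set reflects entities, background, and threshold", {
  tr <- sample_truth(20, 0, seed = 1)
  tr$pairs <- list(c(2L, 5L)); tr$fractions$pairs <- 1.0
  m <- noiseless_model()
  ksv0 <- rep(0, 20)

  r_hit <- screen_set(c(1, 2, 5, 9), tr, m, ksv = ksv0)
  expect_equal(r_hit$quench_percent, 100)
  expect_true(r_hit$call)

  r_half <- screen_set(c(2, 9), tr, m, ksv = ksv0) # one member only
  expect_equal(r_half$quench_percent, 0)
  expect_false(r_half$call)

  r_none <- screen_set(c(1, 3, 4), tr, m, ksv = ksv0)
  expect_equal(r_none$quench_percent, 0)

  # background-only pool quenches by the Stern-Volmer formula
  ksv_bg <- rep(0.25, 20)
  r_bg <- screen_set(1:4, tr, m, ksv = ksv_bg)
  expect_equal(r_bg$quench_percent, combined_background(rep(0.25, 4)))

  # partial quencher: fraction < 1 scales the readout
  tr$fractions$pairs <- 0.7
  r_part <- screen_set(c(2, 5), tr, m, ksv = ksv0)
  expect_equal(r_part$quench_percent, 70)
})

test_that("noiseless campaigns recover the truth exactly for all strategies", {
  m <- noiseless_model()
  design <- greedy_design(60, 8, restarts = 30, seed = 5)
  tr <- sample_truth(60, 6, seed = 10)
  for (strat in c("iterative", "onestep", "parallel")) {
    r <- run_campaign(60, 8, tr, m, strat, seed = 2, design = design)
    expect_identical(length(r$recovered_pairs), 6L)
    expect_length(r$false_positives, 0)
    expect_length(r$false_negatives, 0)
    expect_identical(r$total_tests, r$design_tests + r$deconv_tests)
  }
})

test_that("parallel strategy always costs exactly C(n,2)", {
  m <- noiseless_model()
  for (n in c(12, 20)) {
    tr <- sample_truth(n, 2, seed = n)
    r <- run_campaign(n, 5, tr, m, "parallel", seed = 1)
    expect_identical(r$total_tests, as.integer(choose(n, 2)))
    expect_identical(r$deconv_tests, 0L)
  }
})

test_that("campaigns are reproducible byte-for-byte given the seed", {
  m <- quench_model() # realistic background + noise
  tr <- sample_truth(40, 3, seed = 8)
  r1 <- run_campaign(40, 6, tr, m, "iterative", seed = 33, restarts = 10)
  r2 <- run_campaign(40, 6, tr, m, "iterative", seed = 33, restarts = 10)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("mixed-entity truths are recovered with detection flags on", {
  m <- noiseless_model()
  tr <- sample_truth(40, 2, n_singletons = 1, seed = 21)
  r <- run_campaign(40, 6, tr, m, "iterative", seed = 3, restarts = 10,
                    detect_singletons = TRUE)
  expect_identical(length(r$recovered_pairs), 2L)
  expect_identical(r$singletons_found, tr$singletons)
  expect_length(r$false_positives, 0)
})

test_that("summarize_campaigns aggregates per strategy", {
  m <- noiseless_model()
  tr <- sample_truth(30, 2, seed = 5)
  rs <- list(run_campaign(30, 5, tr, m, "iterative", seed = 1, restarts = 5),
             run_campaign(30, 5, tr, m, "iterative", seed = 1, restarts = 5),
             run_campaign(30, 5, tr, m, "parallel", seed = 1))
  s <- summarize_campaigns(rs)
  expect_identical(nrow(s), 2L)
  it <- s[s$strategy == "iterative", ]
  expect_identical(it$n, 2L)
  expect_identical(it$sensitivity, 1)
  expect_identical(it$q25_total, it$q75_total) # identical replicates
  expect_error(summarize_campaigns(list()), "no campaign")
})

test_that("sensitivity degrades as readout noise grows", {
  sens_at <- function(noise_sd) {
    m <- quench_model(background_ksv_log_mean = -20,
                      background_ksv_log_sd = 0,
                      readout_noise_sd = noise_sd)
    hits <- 0; total <- 0
    for (s in 1:6) {
      tr <- sample_truth(30, 3, seed = 100 + s)
      r <- run_campaign(30, 6, tr, m, "iterative", seed = s, restarts = 5)
      hits <- hits + length(r$recovered_pairs)
      total <- total + 3
    }
    hits / total
  }
  s_clean <- sens_at(0)
  s_noisy <- sens_at(40)
  expect_identical(s_clean, 1)
  expect_lt(s_noisy, s_clean)
})
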