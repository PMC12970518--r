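test_that("schedule follows the ceil(2k/3) cascade", {
  expect_identical(schedule(10), c(7L, 5L, 4L, 3L, 2L))
  expect_identical(schedule(2), integer(0))
  expect_identical(schedule(3), 2L)
  expect_identical(schedule(7), c(5L, 4L, 3L, 2L))
  expect_error(schedule(1), "integer")
})

test_that("make_children covers every parent pair (parent sizes 3-12)", {
  for (m in 3:12) {
    parent <- sort(sample(100, m))
    cs <- as.integer(ceiling(2 * m / 3))
    kids <- make_children(parent, cs, seed = m)
    expect_length(kids, 3)
    expect_true(all(lengths(kids) <= cs))
    expect_true(all(unlist(kids) %in% parent))
    prs <- combn(parent, 2, simplify = FALSE)
    covered <- vapply(prs, function(p)
      any(vapply(kids, function(kid) all(p %in% kid), TRUE)), TRUE)
    expect_true(all(covered))
  }
  # parent of 3 yields its three pairs
  kids3 <- make_children(1:3, 2, seed = 1)
  expect_identical(sort(vapply(kids3, paste, "", collapse = ",")),
                   c("1,2", "1,3", "2,3"))
  expect_error(make_children(1:10, 6, seed = 1), "infeasible")
  expect_error(make_children(1:10, 10, seed = 1), "below the parent")
})

test_that("a single planted pair is recovered within the per-level bound", {
  for (s in 1:10) {
    pair <- sort(sample(10, 2))
    res <- run_iterative(1:10, entity_oracle(list(pair)), seed = s)
    expect_identical(res$active_pairs, list(pair))
    expect_length(res$active_singletons, 0)
    expect_length(res$unresolved, 0)
    expect_lte(res$tests_used, 3 * length(schedule(10)))
  }
})

test_that("pair-sized groups behave per the leaf protocol", {
  r <- run_iterative(1:2, function(S) TRUE, seed = 1)
  expect_identical(r$active_pairs, list(1:2))
  expect_identical(r$tests_used, 1L)
  r3 <- run_iterative(1:2, entity_oracle(list(1:2)), seed = 1,
                      detect_singletons = TRUE)
  expect_identical(r3$tests_used, 3L)
  expect_identical(r3$active_pairs, list(1:2))
  # an always-positive oracle means both members quench alone
  r4 <- run_iterative(1:2, function(S) TRUE, seed = 1,
                      detect_singletons = TRUE)
  expect_identical(sort(r4$active_singletons), 1:2)
  expect_length(r4$active_pairs, 0)
  r0 <- run_iterative(1:10, function(S) FALSE, seed = 1)
  expect_length(r0$active_pairs, 0)
  expect_identical(r0$tests_used, 1L) # only the root was queried
})

test_that("planted entity mixtures are recovered exactly", {
  # exhaustive-ish randomized sweep: up to 3 entities per group of 10,
  # mixing pairs, singletons and triples with matching detection flags
  set.seed(99)
  for (rep in 1:25) {
    n_p <- sample(0:2, 1)
    n_s <- sample(0:1, 1)
    n_t <- sample(0:1, 1)
    if (n_p + n_s + n_t == 0) n_p <- 1
    pool <- sample(10)
    ents <- list()
    used <- integer(0)
    for (i in seq_len(n_p)) {
      p <- sort(pool[(2 * i - 1):(2 * i)])
      ents <- c(ents, list(p)); used <- c(used, p)
    }
    rest <- setdiff(pool, used)
    if (n_s) { ents <- c(ents, list(rest[1])); rest <- rest[-1] }
    if (n_t && length(rest) >= 3) ents <- c(ents, list(sort(rest[1:3])))
    res <- run_iterative(1:10, entity_oracle(ents), seed = rep,
                         detect_singletons = TRUE, detect_triples = TRUE)
    found <- c(res$active_pairs, as.list(res$active_singletons),
               res$active_triples)
    expect_setequal(vapply(found, paste, "", collapse = ","),
                    vapply(ents, paste, "", collapse = ","))
    expect_length(res$unresolved, 0)
  }
})

test_that("pruning changes tests_used but never the result", {
  set.seed(7)
  for (rep in 1:12) {
    n_ent <- sample(1:2, 1)
    ents <- lapply(seq_len(n_ent), function(i) sort(sample(10, 2)))
    o <- entity_oracle(ents)
    rp <- run_iterative(1:10, o, seed = rep, prune = TRUE,
                        detect_singletons = TRUE)
    rn <- run_iterative(1:10, o, seed = rep, prune = FALSE,
                        detect_singletons = TRUE)
    expect_identical(rp$active_pairs, rn$active_pairs)
    expect_identical(rp$active_singletons, rn$active_singletons)
    expect_lte(rp$tests_used, rn$tests_used)
  }
})

test_that("a positive root with all-negative children is reported unresolved", {
  # oracle positive only for the full group: no pair/singleton explains it
  res <- run_iterative(1:10, function(S) length(S) == 10, seed = 1,
                       detect_singletons = TRUE, root_known_positive = TRUE)
  expect_length(res$active_pairs, 0)
  expect_length(res$active_singletons, 0)
  expect_gte(length(res$unresolved), 1)
})

test_that("oracle failures abort with the partial log preserved", {
  calls <- 0L
  bad_oracle <- function(S) {
    calls <<- calls + 1L
    if (calls >= 3L) stop("spectrometer offline")
    TRUE
  }
  err <- tryCatch(run_iterative(1:10, bad_oracle, seed = 1),
                  cooppool_oracle_error = function(e) e)
  expect_s3_class(err, "cooppool_oracle_error")
  expect_match(conditionMessage(err), "spectrometer")
  expect_gte(length(err$log), 2)
  expect_identical(err$tests_used, 2L)
})

test_that("shared knowledge prunes repeat work across pools", {
  pair <- c(3L, 7L)
  o <- entity_oracle(list(pair))
  kn <- new_knowledge(20)
  r1 <- run_iterative(1:10, o, seed = 1, knowledge = kn)
  expect_identical(r1$active_pairs, list(pair))
  # second pool containing the same pair: positivity fully explained
  r2 <- run_iterative(c(pair, 11:18), o, seed = 2, knowledge = kn,
                      root_known_positive = TRUE)
  expect_identical(r2$active_pairs, list(pair))
  expect_lt(r2$tests_used, r1$tests_used)
})

test_that("expected_tests is exact for pairs and grows like log(k0)", {
  expect_identical(expected_tests(2, n_sim = 10, seed = 1), 1)
  expect_lte(expected_tests(10, n_sim = 100, seed = 1), 15)
})
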