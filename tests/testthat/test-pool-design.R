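test_that("count_combinations matches binomial coefficients and validates input", {
  expect_identical(count_combinations(100, 2), 4950)
  expect_identical(count_combinations(10, 2), 45)
  expect_identical(count_combinations(2, 2), 1)
  expect_identical(count_combinations(5, 0), 1)
  expect_error(count_combinations(-1, 2), "integer")
  expect_error(count_combinations(4.5, 2), "integer")
  expect_error(count_combinations(3, 4), "exceed")
})

test_that("schonheim_bound follows the recursion", {
  expect_identical(schonheim_bound(100, 10, 2), 110L)
  expect_identical(schonheim_bound(4, 3, 2), 3L)
  for (n in c(3, 7, 12)) expect_identical(schonheim_bound(n, n, 2), 1L)
  # base case t = 1 is a plain ceiling
  expect_identical(schonheim_bound(10, 3, 1), 4L)
  expect_error(schonheim_bound(5, 6, 2), "t <= k <= n")
})

test_that("greedy_design covers, respects bounds, and is deterministic", {
  d <- greedy_design(4, 3, restarts = 50, seed = 1)
  expect_length(d$blocks, 3)
  expect_true(verify_cover(d)$covered)

  # whole library in one pool
  d1 <- greedy_design(6, 6, restarts = 5, seed = 1)
  expect_length(d1$blocks, 1)

  # random parameter sweep: coverage certificate + Schoenheim bound +
  # independent uncovered recount
  set.seed(42)
  for (i in 1:8) {
    n <- sample(5:14, 1)
    k <- sample(3:min(6, n), 1)
    d <- greedy_design(n, k, restarts = 30, seed = i)
    v <- verify_cover(d)
    expect_true(v$covered)
    expect_equal(count_uncovered(d$blocks, n), 0)
    expect_gte(length(d$blocks), schonheim_bound(n, k, 2))
  }

  expect_identical(greedy_design(20, 5, restarts = 40, seed = 7),
                   greedy_design(20, 5, restarts = 40, seed = 7))
  expect_error(greedy_design(5, 6), "exceed")
  expect_error(greedy_design(10, 3, t = 4), "t")
})

test_that("greedy_design block count is non-increasing in k (n = 20)", {
  sizes <- vapply(3:6, function(k)
    length(greedy_design(20, k, restarts = 200, seed = 11)$blocks), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("greedy_design handles triple coverage and multiplicity", {
  d3 <- greedy_design(7, 4, t = 3, restarts = 30, seed = 2)
  v <- verify_cover(d3)
  expect_true(v$covered)
  expect_equal(count_uncovered(d3$blocks, 7, t = 3), 0)

  d2 <- greedy_design(8, 4, t = 2, lam = 2, restarts = 30, seed = 3)
  expect_true(verify_cover(d2)$covered)
  expect_equal(count_uncovered(d2$blocks, 8, t = 2, lam = 2), 0)
  # lambda counts distinct blocks, so each pair occurs in >= 2 blocks
  keys <- vapply(d2$blocks, paste, "", collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("swap_design completes feasible sizes and reports failures", {
  s <- swap_design(4, 3, n_blocks = 3, seed = 2)
  expect_s3_class(s, "pool_design")
  expect_true(verify_cover(s)$covered)

  f <- swap_design(4, 3, n_blocks = 2, max_iters = 500, seed = 2)
  expect_s3_class(f, "swap_failure")
  expect_gte(f$uncovered, 1)

  s1 <- swap_design(5, 5, n_blocks = 1, seed = 1)
  expect_s3_class(s1, "pool_design")
  expect_length(s1$blocks, 1)

  # size search by bisection lands between the bound and the greedy witness
  sb <- swap_design(9, 3, seed = 4)
  expect_s3_class(sb, "pool_design")
  expect_true(verify_cover(sb)$covered)
  expect_gte(length(sb$blocks), schonheim_bound(9, 3, 2))
})

test_that("verify_cover certifies and rejects correctly", {
  all_triples <- new_cover <- combn(4, 3, simplify = FALSE)
  d <- cooppool:::new_pool_design(4, 3, 2, 1, all_triples)
  v <- verify_cover(d)
  expect_true(v$covered)
  expect_length(v$uncovered, 0)

  d_bad <- cooppool:::new_pool_design(4, 3, 2, 1, list(c(1, 2, 3)))
  v2 <- verify_cover(d_bad)
  expect_false(v2$covered)
  expect_length(v2$uncovered, 3) # pairs involving candidate 4
  expect_true(all(vapply(v2$uncovered, function(p) 4 %in% p, TRUE)))

  d_oob <- cooppool:::new_pool_design(4, 3, 2, 1, list(c(1, 2, 5)))
  expect_error(verify_cover(d_oob), "indices")
  d_dup <- cooppool:::new_pool_design(4, 3, 2, 1, list(c(1, 2), c(1, 2)))
  expect_error(verify_cover(d_dup), "duplicate")
})

test_that("design JSON round-trips with 0-based blocks on disk", {
  d <- greedy_design(8, 3, restarts = 20, seed = 5)
  path <- tempfile(fileext = ".json")
  write_design(d, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(raw$n, 8L)
  expect_identical(min(unlist(raw$blocks)), 0L) # 0-based interchange
  d2 <- read_design(path)
  expect_identical(d$blocks, d2$blocks)
  expect_identical(d[c("n", "k", "t", "lam")], d2[c("n", "k", "t", "lam")])
})

test_that("library CSV reading and plate-map export work", {
  lib_path <- tempfile(fileext = ".csv")
  writeLines(c("id,label", paste0("S", 1:6, ",compound", 1:6)), lib_path)
  lib <- read_library(lib_path)
  expect_identical(nrow(lib), 6L)

  d <- greedy_design(6, 3, restarts = 10, seed = 1)
  map_path <- tempfile(fileext = ".csv")
  write_plate_map(d, map_path, library = lib)
  map <- read.csv(map_path)
  expect_identical(sort(unique(map$block)), seq_along(d$blocks))
  expect_identical(nrow(map), sum(lengths(d$blocks)))
  expect_true(all(map$label %in% lib$label))

  dup_path <- tempfile(fileext = ".csv")
  writeLines(c("id,label", "S1,x", "S2,x"), dup_path)
  expect_error(read_library(dup_path), "unique")
})
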