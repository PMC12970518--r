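#' @useDynLib cooppool, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rlnorm rnorm runif setNames
#' @importFrom utils combn read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

#' Number of t-subsets of an n-candidate library
#'
#' Exact binomial coefficient `choose(n, t)`: the number of combinations that
#' a fully parallel screen would have to test individually. For a library of
#' 100 compounds there are 4,950 pairs.
#'
#' @param n Library size (non-negative integer).
#' @param t Subset size, `0 <= t <= n`.
#' @return The number of t-subsets, as a numeric scalar (integer-valued).
#' @examples
#' count_combinations(100, 2) # 4950
#' @export
count_combinations <- function(n, t) {
  n <- assert_count(n, "n")
  t <- assert_count(t, "t")
  if (t > n) stop("`t` must not exceed `n`", call. = FALSE)
  round(choose(n, t))
}

#' Schoenheim lower bound on covering-design size
#'
#' Recursive lower bound on the minimum number of k-blocks needed so that
#' every t-subset of an n-set lies in at least one block:
#' `C(n, k, t) >= ceiling(n/k * C(n-1, k-1, t-1))`, with
#' `C(n, k, 1) = ceiling(n/k)`. Reported alongside constructed designs since
#' no general method builds optimal coverings.
#'
#' @param n Library size.
#' @param k Block size, `t <= k <= n`.
#' @param t Coverage order.
#' @return Integer lower bound on the block count.
#' @examples
#' schonheim_bound(100, 10, 2) # 110
#' @export
schonheim_bound <- function(n, k, t) {
  n <- assert_count(n, "n", 1L)
  k <- assert_count(k, "k", 1L)
  t <- assert_count(t, "t", 1L)
  if (t > k || k > n) stop("need t <= k <= n", call. = FALSE)
  if (t == 1L) return(as.integer(ceiling(n / k)))
  as.integer(ceiling(n / k * schonheim_bound(n - 1L, k - 1L, t - 1L)))
}

new_pool_design <- function(n, k, t, lam, blocks, labels = NULL) {
  structure(
    list(n = as.integer(n), k = as.integer(k), t = as.integer(t),
         lam = as.integer(lam),
         blocks = lapply(blocks, function(b) sort(as.integer(b))),
         labels = labels),
    class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("Pooling design: n = %d, k = %d, t = %d, lambda = %d\n",
              x$n, x$k, x$t, x$lam))
  cat(sprintf("  %d blocks (Schoenheim lower bound: %d)\n",
              length(x$blocks), schonheim_bound(x$n, x$k, x$t)))
  invisible(x)
}

validate_design_params <- function(n, k, t, lam) {
  n <- assert_count(n, "n", 2L)
  k <- assert_count(k, "k", 1L)
  t <- assert_count(t, "t", 2L)
  lam <- assert_count(lam, "lam", 1L)
  if (!t %in% c(2L, 3L)) stop("coverage order `t` must be 2 or 3", call. = FALSE)
  if (t > k) stop("need t <= k", call. = FALSE)
  if (k > n) stop("block size `k` must not exceed library size `n`", call. = FALSE)
  list(n = n, k = k, t = t, lam = lam)
}

#' Greedy construction of a covering pooling design
#'
#' Builds pools of at most `k` compounds such that every t-subset of the
#' n-compound library occurs in at least `lam` pools. Each pool position is
#' filled by a three-stage rule: (1) keep the candidates that would newly
#' cover the most still-uncovered t-subsets, (2) among those, keep the
#' candidates occurring in the most uncovered t-subsets, (3) pick one
#' uniformly at random. Every pool is filled to `k` members -- a position
#' covering nothing new still receives the highest-incidence candidate, which
#' pays off at later positions of the same pool -- and only the final pool
#' may stay smaller, when coverage completes mid-pool. Pools are appended
#' until coverage is complete; the construction is restarted `restarts` times
#' and the smallest design wins.
#'
#' @param n Library size (candidates are `1..n`).
#' @param k Maximum pool size.
#' @param t Coverage order: 2 covers all pairs, 3 all triples.
#' @param lam Required coverage multiplicity (distinct pools per t-subset).
#' @param restarts Number of randomized restarts (default 1000).
#' @param seed Integer seed for the constructor's own RNG stream; identical
#'   arguments give identical designs.
#' @param labels Optional character vector of compound labels, length `n`.
#' @return A `pool_design` object; its `blocks` are sorted integer vectors of
#'   1-based candidate indices.
#' @examples
#' d <- greedy_design(10, 4, restarts = 50, seed = 1)
#' verify_cover(d)$covered
#' @export
greedy_design <- function(n, k, t = 2, lam = 1, restarts = 1000, seed = 1,
                          labels = NULL) {
  p <- validate_design_params(n, k, t, lam)
  restarts <- assert_count(restarts, "restarts", 1L)
  seed <- assert_count(seed, "seed")
  if (!is.null(labels) && length(labels) != p$n)
    stop("`labels` must have length n", call. = FALSE)
  blocks <- greedy_design_cpp(p$n, p$k, p$t, p$lam, restarts, seed)
  blocks <- lapply(blocks, function(b) b + 1L)
  new_pool_design(p$n, p$k, p$t, p$lam, blocks, labels)
}

#' Swap-based local search for a covering design of fixed size
#'
#' Starts from `n_blocks` random pools of size `k` and repeatedly applies the
#' single-element swap (pool member against a non-member) that most increases
#' the number of covered t-subsets, breaking ties at random and restarting
#' from a fresh random family when no improving swap exists, within a budget
#' of `max_iters` moves. Slower than [greedy_design()] but searches designs
#' of a prescribed size.
#'
#' @inheritParams greedy_design
#' @param n_blocks Number of pools to use. `NULL` searches the smallest
#'   feasible count by bisection between [schonheim_bound()] and the size of
#'   a greedy solution.
#' @param max_iters Total budget of applied swap moves per attempted size.
#' @return A `pool_design` if full coverage was reached; otherwise a
#'   `swap_failure` object with fields `design` (best incomplete family) and
#'   `uncovered` (count of t-subsets still below multiplicity `lam`).
#' @export
swap_design <- function(n, k, t = 2, lam = 1, n_blocks = NULL,
                        max_iters = 20000, seed = 1, labels = NULL) {
  p <- validate_design_params(n, k, t, lam)
  max_iters <- assert_count(max_iters, "max_iters", 1L)
  seed <- assert_count(seed, "seed")

  run_one <- function(nb, sd) {
    res <- swap_design_cpp(p$n, p$k, p$t, p$lam, nb, max_iters, sd)
    blocks <- lapply(res$blocks, function(b) b + 1L)
    list(design = new_pool_design(p$n, p$k, p$t, p$lam, blocks, labels),
         complete = res$complete, uncovered = res$uncovered)
  }

  if (!is.null(n_blocks)) {
    n_blocks <- assert_count(n_blocks, "n_blocks", 1L)
    res <- run_one(n_blocks, seed)
    if (res$complete) return(res$design)
    return(structure(list(design = res$design, uncovered = res$uncovered),
                     class = "swap_failure"))
  }

  # bisection on the design size between the lower bound and a greedy witness
  lo <- schonheim_bound(p$n, p$k, p$t)
  greedy <- greedy_design(p$n, p$k, p$t, p$lam, restarts = 50, seed = seed)
  hi <- length(greedy$blocks)
  best <- greedy
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    res <- run_one(mid, seed + mid)
    if (res$complete) {
      best <- res$design
      hi <- mid
    } else {
      lo <- mid + 1L
    }
  }
  best
}

#' @export
print.swap_failure <- function(x, ...) {
  cat(sprintf("Swap search failed: %d t-subset(s) below required coverage\n",
              x$uncovered))
  invisible(x)
}

#' Certify coverage of a pooling design
#'
#' Checks that every t-subset of the library is contained in at least `lam`
#' distinct pools of the design.
#'
#' @param design A `pool_design`.
#' @return A list with `covered` (logical) and `uncovered`, a list of the
#'   t-subsets (sorted integer vectors) whose coverage falls short.
#' @export
verify_cover <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  n <- design$n; t <- design$t
  for (b in design$blocks) {
    if (anyDuplicated(b) || any(b < 1L) || any(b > n))
      stop("block contains indices outside 1..n or duplicates", call. = FALSE)
  }
  keys <- vapply(design$blocks, function(b) paste(b, collapse = ","), "")
  if (anyDuplicated(keys)) stop("design contains duplicate blocks", call. = FALSE)

  if (t == 2L) {
    cnt <- matrix(0L, n, n)
    for (b in design$blocks) {
      if (length(b) >= 2L) {
        pr <- combn(b, 2L)
        for (i in seq_len(ncol(pr))) cnt[pr[1L, i], pr[2L, i]] <-
            cnt[pr[1L, i], pr[2L, i]] + 1L
      }
    }
    short <- which(upper.tri(cnt) & cnt < design$lam, arr.ind = TRUE)
    uncovered <- lapply(seq_len(nrow(short)),
                        function(i) as.integer(short[i, c(1L, 2L)]))
  } else {
    cnt <- array(0L, dim = c(n, n, n))
    for (b in design$blocks) {
      if (length(b) >= 3L) {
        tr <- combn(b, 3L)
        for (i in seq_len(ncol(tr)))
          cnt[tr[1L, i], tr[2L, i], tr[3L, i]] <-
            cnt[tr[1L, i], tr[2L, i], tr[3L, i]] + 1L
      }
    }
    all_tr <- combn(n, 3L)
    miss <- which(cnt[t(all_tr)] < design$lam)
    uncovered <- lapply(miss, function(i) all_tr[, i])
  }
  list(covered = length(uncovered) == 0L, uncovered = uncovered)
}

# ------------------------------------------------------------------- file IO

#' Read a compound library from CSV/TSV
#'
#' Expects a header with columns `id` and `label`; the separator is taken
#' from the file extension (`.tsv`/`.tab` use tab, otherwise comma).
#'
#' @param path File path.
#' @return A data frame with columns `id` and `label`; labels must be unique.
#' @export
read_library <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("library file needs `id` and `label` columns", call. = FALSE)
  if (anyDuplicated(df$label)) stop("library labels must be unique", call. = FALSE)
  if (nrow(df) < 2L) stop("library must contain at least 2 candidates", call. = FALSE)
  df
}

#' Write / read a pooling design as JSON
#'
#' The JSON interchange format stores 0-based candidate indices
#' (`{"n":..,"k":..,"t":..,"lam":..,"blocks":[[..],..]}`); in-memory
#' `pool_design` objects use 1-based indices.
#'
#' @param design A `pool_design`.
#' @param path Output path.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   `pool_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "pool_design"))
  obj <- list(n = design$n, k = design$k, t = design$t, lam = design$lam,
              blocks = lapply(design$blocks, function(b) b - 1L))
  if (!is.null(design$labels)) obj$labels <- design$labels
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- obj$blocks
  if (is.matrix(blocks)) blocks <- lapply(seq_len(nrow(blocks)), function(i) blocks[i, ])
  new_pool_design(obj$n, obj$k, obj$t, obj$lam,
                  lapply(blocks, function(b) as.integer(b) + 1L),
                  labels = obj$labels)
}

#' Export a bench-facing plate map
#'
#' One row per compound per pool: `block,position,id,label`.
#'
#' @param design A `pool_design`.
#' @param path Output CSV path.
#' @param library Optional data frame from [read_library()] supplying ids and
#'   labels; defaults to candidate indices.
#' @export
write_plate_map <- function(design, path, library = NULL) {
  stopifnot(inherits(design, "pool_design"))
  ids <- if (!is.null(library)) library$id else seq_len(design$n)
  labs <- if (!is.null(library)) library$label else
    design$labels %||% as.character(seq_len(design$n))
  rows <- do.call(rbind, lapply(seq_along(design$blocks), function(i) {
    b <- design$blocks[[i]]
    data.frame(block = i, position = seq_along(b), id = ids[b],
               label = labs[b], stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
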