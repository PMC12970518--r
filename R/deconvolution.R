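# Adaptive iterative-sectioning deconvolution of a positive pool.
#
# A positive pool is split into three overlapping subsets built from a
# tripartition (A, B, C) of its members as {A+B, B+C, A+C}; any pair of the
# pool survives in at least one subset, so recursing on positive subsets down
# to pairs locates every active pair.  Knowledge gathered along the way
# (negative tests exclude all entities they contain; confirmed entities imply
# positivity of their supersets) prunes queries that carry no information.

set_key <- function(v) paste(sort(as.integer(v)), collapse = ",")

# deterministic per-node seed so that the sectioning tree does not depend on
# how many queries were pruned (pruned and unpruned runs traverse the same
# tree, which the paired pruning tests rely on)
node_seed <- function(seed, members) {
  h <- (seed %% 65536) * 31 + length(members)
  for (m in sort(as.integer(members))) h <- (h * 131 + m) %% 2147483647
  as.integer(h)
}

# evaluate `code` under a temporary RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Subset-size cascade of the sectioning tree
#'
#' Level sizes follow `k[i] = ceiling(2/3 * k[i-1])` starting below the root
#' pool size `k0` and stopping at a pair. For the working pool size of 10
#' this gives five levels of sizes 7, 5, 4, 3, 2.
#'
#' @param k0 Root pool size (>= 2).
#' @return Integer vector of subset sizes, empty when `k0 = 2`.
#' @examples
#' schedule(10) # 7 5 4 3 2
#' @export
schedule <- function(k0) {
  k0 <- assert_count(k0, "k0", 2L)
  sizes <- integer(0)
  k <- k0
  while (k > 2L) {
    k <- as.integer(ceiling(2 * k / 3))
    sizes <- c(sizes, k)
  }
  sizes
}

#' Split a positive pool into three pair-covering subsets
#'
#' Sorts the parent members, cuts them into three contiguous near-equal parts
#' A, B, C (sizes differing by at most 1) and returns the unions A+B, B+C,
#' A+C in seeded random order. Any two members fall together in at least one
#' union, so the three children jointly cover every pair of the parent; each
#' union has at most `ceiling(2|parent|/3)` members.
#'
#' @param parent Integer vector of pool members (>= 3 of them).
#' @param child_size Maximum child size; must be at least
#'   `ceiling(2|parent|/3)` (and below `|parent|`).
#' @param seed Integer seed controlling only the output order.
#' @return List of three sorted integer vectors.
#' @export
make_children <- function(parent, child_size, seed = 1) {
  parent <- sort(unique(as.integer(parent)))
  m <- length(parent)
  if (m < 3L) stop("parent must have at least 3 members", call. = FALSE)
  child_size <- assert_count(child_size, "child_size", 2L)
  if (child_size >= m) stop("child_size must be below the parent size", call. = FALSE)
  if (child_size < ceiling(2 * m / 3))
    stop(sprintf("child_size %d infeasible: pair-covering tripartition needs >= %d",
                 child_size, ceiling(2 * m / 3)), call. = FALSE)
  q <- m %/% 3L; r <- m %% 3L
  sizes <- c(q + (r >= 1L), q + (r >= 2L), q)
  cuts <- cumsum(sizes)
  A <- parent[seq_len(cuts[1L])]
  B <- parent[(cuts[1L] + 1L):cuts[2L]]
  C <- parent[(cuts[2L] + 1L):cuts[3L]]
  kids <- list(sort(c(A, B)), sort(c(B, C)), sort(c(A, C)))
  ord <- with_seed(seed, sample.int(3L))
  kids[ord]
}

# ------------------------------------------------------------- knowledge base

#' Create an empty deconvolution knowledge base
#'
#' Holds everything learned from queries: excluded entities (every pair,
#' singleton and triple inside a negatively tested set is inactive),
#' confirmed entities, memoized query outcomes, and the full query log.
#' Passing one knowledge base across several [run_iterative()] sessions makes
#' cross-pool implication prune repeated queries.
#'
#' @param n Library size (largest candidate index that can occur).
#' @return An environment of class `deconv_knowledge`.
#' @export
new_knowledge <- function(n) {
  n <- assert_count(n, "n", 2L)
  kn <- new.env(parent = emptyenv())
  kn$n <- n
  kn$excl_pair <- matrix(FALSE, n, n)   # upper triangle
  kn$excl_single <- rep(FALSE, n)
  kn$conf_pair_mat <- matrix(FALSE, n, n)
  kn$conf_single_mask <- rep(FALSE, n)
  kn$conf_pairs <- list()
  kn$conf_singles <- integer(0)
  kn$conf_triples <- list()
  kn$conf_keys <- new.env(parent = emptyenv())
  kn$tested <- new.env(parent = emptyenv())
  kn$neg_sets <- list()
  kn$log <- list()
  class(kn) <- "deconv_knowledge"
  kn
}

kn_add_negative <- function(kn, s) {
  s <- sort(as.integer(s))
  kn$neg_sets[[length(kn$neg_sets) + 1L]] <- s
  kn$excl_single[s] <- TRUE
  if (length(s) >= 2L) {
    pr <- combn(s, 2L)
    kn$excl_pair[t(pr)] <- TRUE
  }
  invisible(kn)
}

kn_pair_excluded <- function(kn, a, b) kn$excl_pair[min(a, b), max(a, b)]

# triple exclusions are looked up lazily in the negative sets (triples are
# only chased inside small pools, and most sessions never enable them)
kn_triple_excluded <- function(kn, tr) {
  for (s in kn$neg_sets) if (all(tr %in% s)) return(TRUE)
  FALSE
}

kn_confirm <- function(kn, ent) {
  key <- set_key(ent)
  if (isTRUE(get0(key, envir = kn$conf_keys))) return(FALSE)
  assign(key, TRUE, envir = kn$conf_keys)
  ent <- sort(as.integer(ent))
  if (length(ent) == 1L) {
    kn$conf_singles <- c(kn$conf_singles, ent)
    kn$conf_single_mask[ent] <- TRUE
  } else if (length(ent) == 2L) {
    kn$conf_pairs <- c(kn$conf_pairs, list(ent))
    kn$conf_pair_mat[ent[1L], ent[2L]] <- TRUE
  } else {
    kn$conf_triples <- c(kn$conf_triples, list(ent))
  }
  TRUE
}

kn_is_confirmed <- function(kn, ent)
  isTRUE(get0(set_key(ent), envir = kn$conf_keys))

# does S contain any confirmed entity (its positivity is then uninformative)?
kn_explained <- function(kn, S) {
  if (any(kn$conf_single_mask[S])) return(TRUE)
  if (length(S) >= 2L && any(kn$conf_pair_mat[t(combn(S, 2L))])) return(TRUE)
  for (tr in kn$conf_triples) if (all(tr %in% S)) return(TRUE)
  FALSE
}

# non-excluded candidate entities inside S, per detection flags; these are
# the possible explanations of a positive outcome of S
kn_possible_entities <- function(kn, S, singletons, triples) {
  pairs <- if (length(S) >= 2L) {
    pr <- combn(S, 2L)
    pr[, !kn$excl_pair[t(pr)], drop = FALSE]
  } else matrix(integer(0), nrow = 2L)
  singles <- if (singletons) S[!kn$excl_single[S]] else integer(0)
  trips <- list()
  if (triples && length(S) >= 3L) {
    tr <- combn(S, 3L)
    for (i in seq_len(ncol(tr)))
      if (!kn_triple_excluded(kn, tr[, i])) trips <- c(trips, list(tr[, i]))
  }
  list(pairs = pairs, singles = singles, triples = trips,
       count = ncol(pairs) + length(singles) + length(trips))
}

kn_has_unresolved <- function(kn, S, triples) {
  if (length(S) >= 2L) {
    pr <- combn(S, 2L)
    idx <- t(pr)
    open <- !kn$excl_pair[idx] & !kn$conf_pair_mat[idx] &
      !(kn$conf_single_mask[pr[1L, ]] | kn$conf_single_mask[pr[2L, ]])
    if (any(open)) return(TRUE)
  }
  if (triples && length(S) >= 3L) {
    tr <- combn(S, 3L)
    for (i in seq_len(ncol(tr))) {
      v <- tr[, i]
      if (kn_triple_excluded(kn, v) || kn_is_confirmed(kn, v)) next
      if (kn_explained(kn, v)) next # masked by a confirmed sub-entity
      return(TRUE)
    }
  }
  FALSE
}

# ------------------------------------------------------------ main algorithm

#' Iterative-sectioning deconvolution of a positive pool
#'
#' Explores the sectioning tree depth-first, querying the oracle only for
#' subsets whose outcome is not already implied: a set containing a confirmed
#' entity must be positive; a set all of whose candidate entities have been
#' excluded by negative tests must be negative; and when all remaining
#' candidate entities of a positive parent sit inside one child, that child
#' must be positive. Entities themselves are only reported after a positive
#' query of exactly that entity (a memoized earlier query, e.g. the initial
#' screen of a pool that happens to be a pair, counts).
#'
#' A positive leaf pair is optionally disambiguated against single quenchers
#' by testing its members alone (at most 2 extra queries). A positive node
#' whose three children are all negative can only be explained by a
#' three-way interaction spanning the tripartition; with `detect_triples`
#' those candidate triples are tested directly, otherwise the node is
#' reported unresolved.
#'
#' @param group Integer vector: the positive pool to resolve.
#' @param oracle Function taking an integer vector and returning `TRUE`
#'   (quenching above threshold) or `FALSE`. An error raised by the oracle
#'   aborts the run with a condition of class `cooppool_oracle_error` whose
#'   `log` field preserves the partial query log.
#' @param find_all Continue until every pair of the pool is excluded or
#'   covered by a confirmed entity (`TRUE`, default), or stop at the first
#'   confirmed entity (`FALSE`).
#' @param detect_singletons Disambiguate positive leaf pairs against single
#'   quenchers.
#' @param detect_triples Chase three-way interactions left unexplained after
#'   pair exclusion.
#' @param seed Integer seed; all internal randomness (tripartition order,
#'   child exploration order) derives from it and the node members, so runs
#'   are reproducible and independent of pruning.
#' @param knowledge A `deconv_knowledge` to share across pools, or `NULL` for
#'   a fresh one.
#' @param prune Use implication logic to skip queries (default). With
#'   `FALSE`, every traversed set is queried; reported entities are unchanged
#'   and only `tests_used` grows (the no-pruning reference).
#' @param root_known_positive The pool is already known positive (it was
#'   screened); do not spend a query on it.
#' @return A `deconv_result` list: `active_pairs`, `active_singletons`,
#'   `active_triples` (restricted to the pool), `unresolved` (sets whose
#'   positivity could not be explained), `tests_used` (oracle calls made in
#'   this session), `log`, and the updated `knowledge`.
#' @export
run_iterative <- function(group, oracle, find_all = TRUE,
                          detect_singletons = FALSE, detect_triples = FALSE,
                          seed = 1, knowledge = NULL, prune = TRUE,
                          root_known_positive = FALSE) {
  group <- sort(unique(as.integer(group)))
  if (length(group) < 2L) stop("group must have at least 2 members", call. = FALSE)
  seed <- assert_count(seed, "seed")
  kn <- knowledge %||% new_knowledge(max(group))
  if (max(group) > kn$n) stop("group exceeds knowledge base library size", call. = FALSE)

  st <- new.env(parent = emptyenv())
  st$tests <- 0L
  st$stop <- FALSE
  st$unresolved <- list()
  st$log_start <- length(kn$log)

  query <- function(S, level) {
    key <- set_key(S)
    memo <- get0(key, envir = kn$tested)
    if (prune && !is.null(memo)) {
      kn$log[[length(kn$log) + 1L]] <- list(set = S, result = memo,
                                            level = level, implied = TRUE)
      return(memo)
    }
    res <- tryCatch(isTRUE(oracle(S)), error = function(e) {
      cond <- structure(
        class = c("cooppool_oracle_error", "error", "condition"),
        list(message = paste0("oracle failed: ", conditionMessage(e)),
             call = NULL, log = kn$log, tests_used = st$tests))
      stop(cond)
    })
    st$tests <- st$tests + 1L
    assign(key, res, envir = kn$tested)
    kn$log[[length(kn$log) + 1L]] <- list(set = S, result = res,
                                          level = level, implied = FALSE)
    if (!res) kn_add_negative(kn, S)
    res
  }

  confirm <- function(ent) {
    if (kn_confirm(kn, ent)) {
      if (find_all) st$restart <- TRUE else st$stop <- TRUE
    }
  }

  halted <- function() st$stop || st$restart

  # a pair is settled when excluded, confirmed, or masked by a confirmed
  # singleton member (no experiment can then isolate it)
  pair_resolved <- function(a, b) {
    kn$excl_pair[a, b] || kn$conf_pair_mat[a, b] ||
      kn$conf_single_mask[a] || kn$conf_single_mask[b]
  }

  leaf <- function(P, level) {
    a <- P[1L]; b <- P[2L]
    if (prune && pair_resolved(a, b)) return(invisible())
    pos <- query(P, level)
    if (!pos) return(invisible())
    if (detect_singletons) {
      pa <- if (prune && kn$excl_single[a]) FALSE else query(a, level + 1L)
      pb <- if (prune && kn$excl_single[b]) FALSE else query(b, level + 1L)
      if (pa) confirm(a)
      if (pb) confirm(b)
      if (!pa && !pb) confirm(P)
    } else {
      confirm(P)
    }
    invisible()
  }

  try_triples <- function(S, level) {
    if (length(S) < 3L) return(invisible())
    tr <- combn(S, 3L)
    ord <- with_seed(node_seed(seed, S) + 2L, sample.int(ncol(tr)))
    for (i in ord) {
      if (halted()) return(invisible())
      v <- tr[, i]
      if (kn_triple_excluded(kn, v) || kn_is_confirmed(kn, v)) next
      if (kn_explained(kn, v)) next # contains a confirmed sub-entity
      # only conclusive once every sub-entity is excluded
      prs <- combn(v, 2L)
      if (!all(kn$excl_pair[t(prs)])) next
      if (detect_singletons && !all(kn$excl_single[v])) next
      if (query(v, level)) confirm(v)
    }
    invisible()
  }

  descend <- function(S, level) {
    kids <- make_children(S, as.integer(ceiling(2 * length(S) / 3)),
                          seed = node_seed(seed, S))
    for (child in kids) {
      if (halted()) return(invisible())
      forced <- FALSE
      if (prune) {
        ents <- kn_possible_entities(kn, S, detect_singletons, detect_triples)
        if (ents$count > 0L &&
            all(ents$pairs %in% child) && all(ents$singles %in% child) &&
            all(vapply(ents$triples, function(e) all(e %in% child), TRUE)))
          forced <- TRUE
      }
      explore(child, level + 1L, known_pos = forced)
    }
    if (detect_triples && !halted()) try_triples(S, level + 1L)
    invisible()
  }

  # continuation below a set that contains a confirmed entity: its own
  # outcome is uninformative and its tripartition children mostly inherit the
  # confirmed entity, so instead drop one entity member at a time.  The
  # masked sets S \ {m} jointly cover every pair of S except the confirmed
  # entity itself, and a single negative masked test excludes all remaining
  # partner pairs of m wholesale -- the step an experimentalist would take to
  # hunt further hits in an already-explained pool.
  masked_descend <- function(S, level) {
    if (!kn_has_unresolved(kn, S, detect_triples)) return(invisible())
    ent <- NULL
    for (s in kn$conf_singles) if (s %in% S) { ent <- s; break }
    if (is.null(ent))
      for (p in kn$conf_pairs) if (all(p %in% S)) { ent <- p; break }
    if (is.null(ent))
      for (tr in kn$conf_triples) if (all(tr %in% S)) { ent <- tr; break }
    for (m in ent) {
      if (halted()) return(invisible())
      child <- setdiff(S, m)
      if (length(child) >= 2L) explore(child, level + 1L)
    }
    if (detect_triples && !halted()) try_triples(S, level + 1L)
    invisible()
  }

  explore <- function(S, level, known_pos = FALSE) {
    if (halted()) return(invisible())
    if (length(S) == 2L) return(leaf(S, level))

    if (kn_explained(kn, S)) {
      # physically positive but uninformative: never query when pruning
      if (!prune && !known_pos) query(S, level)
      masked_descend(S, level)
      return(invisible())
    }
    ents <- kn_possible_entities(kn, S, detect_singletons, detect_triples)
    if (ents$count == 0L) {
      # implied negative: everything inside already excluded
      if (!prune) query(S, level)
      return(invisible())
    }
    pos <- if (known_pos) TRUE else query(S, level)
    if (!pos) return(invisible())
    descend(S, level)
    if (!halted() && !kn_explained(kn, S) &&
        !kn_has_unresolved(kn, S, detect_triples)) {
      already <- any(vapply(st$unresolved, function(u) all(u %in% S), TRUE))
      if (!already)
        st$unresolved <- c(st$unresolved, list(S))
    }
    invisible()
  }

  if (root_known_positive)
    assign(set_key(group), TRUE, envir = kn$tested)
  # each new confirmation unwinds to the root: the cheapest continuation
  # after a hit is a masked sweep of the whole pool, not finishing the
  # interrupted sibling walk
  repeat {
    st$restart <- FALSE
    explore(group, 0L, known_pos = root_known_positive)
    if (!st$restart) break
  }

  in_group <- function(ents) ents[vapply(ents, function(e) all(e %in% group), TRUE)]
  structure(
    list(active_pairs = in_group(kn$conf_pairs),
         active_singletons = kn$conf_singles[kn$conf_singles %in% group],
         active_triples = in_group(kn$conf_triples),
         unresolved = st$unresolved,
         tests_used = st$tests,
         log = if (length(kn$log) > st$log_start)
           kn$log[(st$log_start + 1L):length(kn$log)] else list(),
         knowledge = kn),
    class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  fmt <- function(l) if (length(l) == 0) "none" else
    paste(vapply(l, function(e) paste0("{", paste(e, collapse = ","), "}"), ""),
          collapse = " ")
  cat("Deconvolution result\n")
  cat("  active pairs:     ", fmt(x$active_pairs), "\n")
  cat("  active singletons:", if (length(x$active_singletons)) paste(x$active_singletons, collapse = " ") else "none", "\n")
  cat("  active triples:   ", fmt(x$active_triples), "\n")
  cat("  unresolved sets:  ", length(x$unresolved), "\n")
  cat("  oracle queries:   ", x$tests_used, "\n")
  invisible(x)
}

#' Mean query count to locate one active pair
#'
#' Monte-Carlo estimate of the expected number of oracle queries
#' [run_iterative()] spends on a pool of size `k0` containing exactly one
#' uniformly placed active pair, under a noiseless oracle. Grows with
#' `log(k0)` since each tree level shrinks the live set by a factor 2/3.
#'
#' @param k0 Pool size.
#' @param n_sim Number of simulated placements.
#' @param seed Integer seed.
#' @param root_known_positive Passed through to [run_iterative()]; use `TRUE`
#'   to cost deconvolution of a pool already screened positive.
#' @param find_all,detect_singletons Passed through to [run_iterative()].
#' @return Mean `tests_used` across simulations.
#' @export
expected_tests <- function(k0, n_sim = 500, seed = 1,
                           root_known_positive = FALSE, find_all = TRUE,
                           detect_singletons = FALSE) {
  k0 <- assert_count(k0, "k0", 2L)
  n_sim <- assert_count(n_sim, "n_sim", 1L)
  tests <- vapply(seq_len(n_sim), function(i) {
    pair <- with_seed(seed * 7919L %% 2147483647L + i, sample.int(k0, 2L))
    oracle <- function(S) all(pair %in% S)
    res <- run_iterative(seq_len(k0), oracle, find_all = find_all,
                         detect_singletons = detect_singletons,
                         seed = (seed + i) %% 2147483647L,
                         root_known_positive = root_known_positive)
    res$tests_used
  }, 1)
  mean(tests)
}
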