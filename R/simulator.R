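# End-to-end campaign simulator: plant a ground truth, build pools, screen
# them through the quenching model, deconvolve the positives, and account for
# every experiment.

#' Plant a synthetic ground truth
#'
#' Samples the active entities of a simulated library: cooperative pairs,
#' single quenchers and three-way interactions. Roles are kept disjoint so
#' that every planted entity is identifiable in principle: singletons are
#' never members of planted pairs (a pair containing an active singleton can
#' never be isolated experimentally), and triples contain no planted pair or
#' singleton.
#'
#' With `hub_bias > 0` pairs preferentially share members of a small "hub"
#' set, emulating privileged compounds that appear in many cooperative pairs;
#' at `hub_bias = 1` every pair contains a hub member.
#'
#' @param n Library size.
#' @param n_pairs,n_singletons,n_triples Entity counts to plant.
#' @param hub_bias Probability in `[0, 1]` that a pair is anchored on a hub
#'   compound.
#' @param seed Integer seed.
#' @param n_hubs Size of the hub set (default 3).
#' @param quench_fraction Per-entity fractional emission loss (default 1.0,
#'   full extinction).
#' @return A `ground_truth` list with fields `n`, `pairs`, `singletons`,
#'   `triples`, `fractions`.
#' @export
sample_truth <- function(n, n_pairs, n_singletons = 0, n_triples = 0,
                         hub_bias = 0, seed = 1, n_hubs = 3,
                         quench_fraction = 1.0) {
  n <- assert_count(n, "n", 2L)
  n_pairs <- assert_count(n_pairs, "n_pairs")
  n_singletons <- assert_count(n_singletons, "n_singletons")
  n_triples <- assert_count(n_triples, "n_triples")
  stopifnot(hub_bias >= 0, hub_bias <= 1,
            quench_fraction > 0, quench_fraction <= 1)
  if (n_pairs > choose(n, 2) / 2 || n_singletons + 3 * n_triples + 2 > n)
    stop("infeasible entity counts for library size n", call. = FALSE)

  with_seed(seed, {
    hubs <- sample.int(n, min(n_hubs, n))
    pairs <- list()
    seen <- new.env(parent = emptyenv())
    while (length(pairs) < n_pairs) {
      p <- if (hub_bias > 0 && stats::runif(1) < hub_bias) {
        h <- hubs[sample.int(length(hubs), 1L)]
        sort(c(h, sample(setdiff(seq_len(n), h), 1L)))
      } else {
        sort(sample.int(n, 2L))
      }
      key <- set_key(p)
      if (is.null(get0(key, envir = seen))) {
        assign(key, TRUE, envir = seen)
        pairs <- c(pairs, list(p))
      }
    }
    pair_members <- unique(unlist(pairs))
    free <- setdiff(seq_len(n), pair_members)
    if (length(free) < n_singletons + 3 * n_triples)
      stop("not enough candidates left for singletons/triples", call. = FALSE)
    singles <- if (n_singletons > 0) sort(sample(free, n_singletons)) else integer(0)
    free <- setdiff(free, singles)
    triples <- list()
    for (i in seq_len(n_triples)) {
      tr <- sort(sample(free, 3L))
      free <- setdiff(free, tr)
      triples <- c(triples, list(tr))
    }
    structure(list(n = n, pairs = pairs, singletons = singles,
                   triples = triples,
                   fractions = list(
                     pairs = rep(quench_fraction, n_pairs),
                     singletons = rep(quench_fraction, n_singletons),
                     triples = rep(quench_fraction, n_triples))),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth over %d candidates: %d pairs, %d singletons, %d triples\n",
              x$n, length(x$pairs), length(x$singletons), length(x$triples)))
  invisible(x)
}

truth_entities <- function(truth) {
  c(truth$pairs, lapply(truth$singletons, identity), truth$triples)
}

truth_fractions <- function(truth) {
  c(truth$fractions$pairs, truth$fractions$singletons, truth$fractions$triples)
}

#' Simulate the quenching readout of one pool
#'
#' Emission is reduced multiplicatively by the cumulative background of the
#' pooled compounds and by every planted entity fully contained in the pool:
#' `quench = 100 * (1 - prod(1 - fraction_e) * (1 - background/100)) + noise`,
#' clipped to `[0, 100]`. The positive call is `quench >= threshold`.
#'
#' @param members Integer vector of pooled candidates.
#' @param truth A [sample_truth()] object.
#' @param model A [quench_model()].
#' @param seed Optional integer seed for noise (and for the background draw
#'   when `ksv` is not supplied); `NULL` uses the current RNG stream.
#' @param ksv Optional numeric vector of per-compound background
#'   Stern-Volmer products for the whole library; drawn for the pool members
#'   when missing.
#' @param set_id Identifier copied into the readout.
#' @return A `readout` list: `set_id`, `quench_percent`, `call`.
#' @export
screen_set <- function(members, truth, model = quench_model(), seed = NULL,
                       ksv = NULL, set_id = set_key(members)) {
  members <- sort(unique(as.integer(members)))
  stopifnot(inherits(truth, "ground_truth"), all(members >= 1),
            all(members <= truth$n))
  run <- function() {
    k <- if (is.null(ksv)) draw_background_ksv(length(members), model)
         else ksv[members]
    bg <- combined_background(k)
    ents <- truth_entities(truth)
    fr <- truth_fractions(truth)
    active <- vapply(ents, function(e) all(e %in% members), TRUE)
    keep <- prod(1 - fr[active]) # emission fraction surviving active entities
    q <- 100 * (1 - keep * (1 - bg / 100))
    q <- q + rnorm(1, 0, model$readout_noise_sd)
    q <- min(100, max(0, q))
    structure(list(set_id = set_id, quench_percent = q,
                   call = q >= model$threshold),
              class = "readout")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# vectorized screen of a list of pools (same model and RNG stream as
# per-pool screen_set calls, without the per-call overhead)
screen_blocks <- function(blocks, truth, model, ksv) {
  bg <- vapply(blocks, function(b) 100 * (1 - 1 / (1 + sum(ksv[b]))), 1)
  keep <- rep(1, length(blocks))
  ents <- truth_entities(truth)
  fr <- truth_fractions(truth)
  for (j in seq_along(ents)) {
    hit <- vapply(blocks, function(b) all(ents[[j]] %in% b), TRUE)
    keep[hit] <- keep[hit] * (1 - fr[j])
  }
  q <- 100 * (1 - keep * (1 - bg / 100)) +
    rnorm(length(blocks), 0, model$readout_noise_sd)
  pmin(100, pmax(0, q)) >= model$threshold
}

# one-step signature deconvolution of a positive pool inside a campaign;
# falls back to iterative sectioning when the pattern is ambiguous.
# The subset round is non-adaptive: all subsets are prepared and measured in
# one parallel batch, so every subset costs one experiment even when its
# outcome could have been anticipated.
onestep_deconvolve_group <- function(block, oracle, sig_design, kn, seed,
                                     find_all, detect_singletons) {
  tests <- 0L
  pattern <- integer(0)
  for (i in seq_along(sig_design$subsets)) {
    members <- block[sig_design$subsets[[i]]]
    res <- isTRUE(oracle(members))
    tests <- tests + 1L
    assign(set_key(members), res, envir = kn$tested)
    kn$log[[length(kn$log) + 1L]] <- list(set = members, result = res,
                                          level = 1L, implied = FALSE)
    if (!res) kn_add_negative(kn, members)
    if (res) pattern <- c(pattern, i)
  }
  dec <- onestep_decode(sig_design, pattern)
  if (dec$status == "pair") {
    p <- block[dec$pair]
    if (!kn_pair_excluded(kn, p[1L], p[2L])) {
      kn_confirm(kn, p)
      return(tests)
    }
    # decoded pair contradicts an earlier negative pool: fall through
  }
  # ambiguous (multi-hit, single quencher, or a false-positive pool):
  # resolve adaptively, reusing the subset outcomes recorded above
  res <- run_iterative(block, oracle, find_all = find_all,
                       detect_singletons = detect_singletons,
                       seed = seed, knowledge = kn,
                       root_known_positive = TRUE)
  tests + res$tests_used
}

#' Simulate a full screening campaign
#'
#' Builds the initial pooling design, screens every pool through the
#' quenching model, deconvolves every positive pool with the chosen strategy
#' and reports experiment counts and recovery. Strategies:
#' \describe{
#'   \item{`iterative`}{adaptive sectioning ([run_iterative()]) on each
#'     positive pool.}
#'   \item{`onestep`}{the non-adaptive signature design ([onestep_design()])
#'     on each positive pool, falling back to iterative sectioning when the
#'     observed pattern is ambiguous (multiple pairs, single quenchers).}
#'   \item{`parallel`}{tests all `C(n,2)` pairs directly (the design is the
#'     trivial `k = 2` covering).}
#' }
#'
#' With `share_knowledge` (default), every screen outcome and every
#' deconvolution query feeds one shared knowledge base, so a pool whose
#' positivity is already explained by a confirmed pair is not re-deconvolved
#' from scratch and pairs excluded by negative pools are never chased.
#'
#' @param n Library size.
#' @param k Pool size.
#' @param truth A [sample_truth()] ground truth.
#' @param model A [quench_model()].
#' @param strategy One of `"iterative"`, `"onestep"`, `"parallel"`.
#' @param seed Integer seed covering design construction, screening noise and
#'   deconvolution randomness.
#' @param restarts Greedy restarts for the design.
#' @param find_all,detect_singletons Deconvolution options (both default on:
#'   campaigns must catch multi-hit pools and single quenchers).
#' @param share_knowledge Share exclusions/confirmations across pools.
#' @param design Optional pre-built `pool_design` (skips construction).
#' @param onestep_subsets,onestep_subset_size Signature-design shape for the
#'   onestep strategy (defaults 8 subsets of size `k - 3`).
#' @param sig_design Optional pre-built [onestep_design()] object; building
#'   one is the expensive step, so replicate campaigns should share it.
#' @return A `campaign_result` list: `design_tests`, `deconv_tests`,
#'   `total_tests`, `recovered_pairs`, `false_negatives`, `false_positives`,
#'   `singletons_found`, `triples_found`, `unresolved`, `per_group`,
#'   `n_planted`.
#' @export
run_campaign <- function(n, k, truth, model = quench_model(),
                         strategy = c("iterative", "onestep", "parallel"),
                         seed = 1, restarts = 20, find_all = TRUE,
                         detect_singletons = TRUE, share_knowledge = TRUE,
                         design = NULL, onestep_subsets = 8,
                         onestep_subset_size = NULL, sig_design = NULL) {
  strategy <- match.arg(strategy)
  n <- assert_count(n, "n", 2L)
  seed <- assert_count(seed, "seed")
  stopifnot(inherits(truth, "ground_truth"), truth$n == n)

  if (strategy == "parallel") {
    blocks <- combn(n, 2L, simplify = FALSE)
    design <- new_pool_design(n, 2L, 2L, 1L, blocks)
  } else if (is.null(design)) {
    design <- greedy_design(n, k, restarts = restarts, seed = seed)
  }
  blocks <- design$blocks

  set.seed(seed)
  ksv <- draw_background_ksv(n, model)
  oracle <- function(S) screen_set(S, truth, model, ksv = ksv)$call

  kn_shared <- new_knowledge(n)
  per_group <- list()
  deconv_tests <- 0L
  unresolved <- list()

  # initial screen; outcomes are real experiments and feed the knowledge base
  screens <- screen_blocks(blocks, truth, model, ksv)
  for (i in seq_along(blocks)) {
    assign(set_key(blocks[[i]]), screens[i], envir = kn_shared$tested)
    kn_shared$log[[length(kn_shared$log) + 1L]] <-
      list(set = blocks[[i]], result = screens[i], level = 0L, implied = FALSE)
    if (!screens[i]) kn_add_negative(kn_shared, blocks[[i]])
  }
  design_tests <- length(blocks)

  if (strategy == "parallel") {
    conf <- blocks[screens]
    for (p in conf) kn_confirm(kn_shared, p)
  } else {
    if (strategy == "onestep" && is.null(sig_design)) {
      ss <- onestep_subset_size %||% max(2L, k - 3L)
      sig_design <- onestep_design(k, onestep_subsets, ss,
                                   seed = seed, max_tries = 100000)
    }
    group_kns <- list()
    for (i in which(screens)) {
      block <- blocks[[i]]
      kn <- if (share_knowledge) kn_shared else {
        kb <- new_knowledge(n)
        assign(set_key(block), TRUE, envir = kb$tested)
        group_kns[[length(group_kns) + 1L]] <- kb
        kb
      }
      gseed <- (seed * 131L + i) %% 2147483647L
      if (strategy == "iterative") {
        # a pool already explained by a confirmed entity with nothing left to
        # resolve costs nothing; run_iterative handles that via implication
        res <- run_iterative(block, oracle, find_all = find_all,
                             detect_singletons = detect_singletons,
                             seed = gseed, knowledge = kn,
                             root_known_positive = TRUE)
        deconv_tests <- deconv_tests + res$tests_used
        if (length(res$unresolved) > 0) unresolved <- c(unresolved, res$unresolved)
        else if (!kn_explained(kn, block)) unresolved <- c(unresolved, list(block))
        per_group[[length(per_group) + 1L]] <-
          list(block = i, tests = res$tests_used)
      } else {
        skip <- kn_explained(kn, block) &&
          !kn_has_unresolved(kn, block, FALSE)
        t_used <- if (skip) 0L else
          onestep_deconvolve_group(block, oracle, sig_design, kn, gseed,
                                   find_all, detect_singletons)
        deconv_tests <- deconv_tests + t_used
        if (!kn_explained(kn, block))
          unresolved <- c(unresolved, list(block))
        per_group[[length(per_group) + 1L]] <- list(block = i, tests = t_used)
      }
    }
    if (!share_knowledge) {
      # per-group bases hold the confirmations; merge them for reporting
      for (kb in group_kns) {
        for (p in kb$conf_pairs) kn_confirm(kn_shared, p)
        for (s in kb$conf_singles) kn_confirm(kn_shared, s)
        for (tr in kb$conf_triples) kn_confirm(kn_shared, tr)
      }
    }
  }

  conf_pairs <- kn_shared$conf_pairs
  planted_keys <- vapply(truth$pairs, set_key, "")
  conf_keys <- vapply(conf_pairs, set_key, "")
  recovered <- conf_pairs[conf_keys %in% planted_keys]
  false_pos <- conf_pairs[!conf_keys %in% planted_keys]
  false_neg <- truth$pairs[!planted_keys %in% conf_keys]

  structure(list(strategy = strategy,
                 design_tests = design_tests,
                 deconv_tests = deconv_tests,
                 total_tests = design_tests + deconv_tests,
                 recovered_pairs = recovered,
                 false_negatives = false_neg,
                 false_positives = false_pos,
                 singletons_found = kn_shared$conf_singles,
                 triples_found = kn_shared$conf_triples,
                 unresolved = unresolved,
                 per_group = per_group,
                 log = kn_shared$log,
                 n_planted = length(truth$pairs),
                 seed = seed),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("Campaign (%s): %d screen + %d deconvolution = %d experiments\n",
              x$strategy, x$design_tests, x$deconv_tests, x$total_tests))
  cat(sprintf("  pairs: %d/%d recovered, %d false positive(s), %d unresolved set(s)\n",
              length(x$recovered_pairs), x$n_planted,
              length(x$false_positives), length(x$unresolved)))
  invisible(x)
}

#' Summarize replicate campaigns
#'
#' @param results List of `campaign_result` objects.
#' @return Data frame, one row per strategy: mean/median/quartiles of total
#'   tests, mean sensitivity, mean false-positive and unresolved counts.
#' @export
summarize_campaigns <- function(results) {
  if (length(results) == 0) stop("no campaign results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, TRUE, "campaign_result")))
  strat <- vapply(results, function(r) r$strategy, "")
  do.call(rbind, lapply(unique(strat), function(s) {
    rs <- results[strat == s]
    tot <- vapply(rs, function(r) r$total_tests, 1)
    sens <- vapply(rs, function(r)
      if (r$n_planted == 0) 1 else length(r$recovered_pairs) / r$n_planted, 1)
    data.frame(strategy = s, n = length(rs),
               mean_total = mean(tot), median_total = median(tot),
               q25_total = unname(quantile(tot, 0.25)),
               q75_total = unname(quantile(tot, 0.75)),
               sensitivity = mean(sens),
               mean_false_positives = mean(vapply(rs, function(r)
                 length(r$false_positives), 1)),
               mean_unresolved = mean(vapply(rs, function(r)
                 length(r$unresolved), 1)))
  }))
}
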