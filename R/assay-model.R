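# Phenomenological model of the luminescence-quenching readout.
#
# Each inactive compound contributes a small Stern-Volmer product K_sv * [Q]
# (dimensionless at working concentration); quenching channels add, so a pool
# with total background B shows a relative emission of 1/(1 + B).  An active
# cooperative entity removes a fraction of the remaining emission (1.0 = full
# extinction).  The positive/negative call is a threshold on the quenching
# percentage.

#' Luminescence quenching model parameters
#'
#' @param background_ksv_log_mean,background_ksv_log_sd Meanlog and sdlog of
#'   the log-normal distribution of per-compound background Stern-Volmer
#'   products. Defaults are calibrated so that a pool of 10 inactive
#'   compounds exceeds the 60% threshold with probability of roughly 1-5%.
#' @param active_quench_fraction Fractional emission loss caused by an active
#'   entity (1.0 = total extinction).
#' @param readout_noise_sd Additive Gaussian noise on the quenching
#'   percentage, in percentage points.
#' @param threshold Quenching percentage at or above which a pool is called
#'   positive.
#' @return A `quench_model` list.
#' @export
quench_model <- function(background_ksv_log_mean = log(0.055),
                         background_ksv_log_sd = 0.9,
                         active_quench_fraction = 1.0,
                         readout_noise_sd = 2.0,
                         threshold = 60) {
  stopifnot(active_quench_fraction >= 0, active_quench_fraction <= 1,
            readout_noise_sd >= 0, threshold > 0, threshold < 100,
            background_ksv_log_sd >= 0)
  structure(list(background_ksv_log_mean = background_ksv_log_mean,
                 background_ksv_log_sd = background_ksv_log_sd,
                 active_quench_fraction = active_quench_fraction,
                 readout_noise_sd = readout_noise_sd,
                 threshold = threshold),
            class = "quench_model")
}

#' Quenching percentage from emission intensities
#'
#' `100 * (1 - intensity / reference_intensity)`; intensities above the
#' reference are clipped to it (0% quenching).
#'
#' @param intensity Emission counts with analytes present (>= 0).
#' @param reference_intensity Emission counts of the photosensitizer alone
#'   (> 0).
#' @return Quenching percentage in `[0, 100]`.
#' @examples
#' quench_percent(40, 100) # 60
#' @export
quench_percent <- function(intensity, reference_intensity) {
  if (!is.numeric(reference_intensity) || any(reference_intensity <= 0))
    stop("`reference_intensity` must be positive", call. = FALSE)
  if (!is.numeric(intensity) || any(intensity < 0))
    stop("`intensity` must be non-negative", call. = FALSE)
  100 * (1 - pmin(intensity, reference_intensity) / reference_intensity)
}

#' Cumulative background quenching of co-pooled inactive compounds
#'
#' Quenching channels add on the Stern-Volmer scale: a pool with per-compound
#' products `ksv_values` retains relative emission `1/(1 + sum(ksv))`, i.e.
#' the background quenching percentage is `100 * (1 - 1/(1 + sum(ksv)))`.
#' Two compounds of strength 0.5 therefore quench exactly as much as one of
#' strength 1.0.
#'
#' @param ksv_values Numeric vector of per-compound Stern-Volmer products
#'   (>= 0); may be empty.
#' @return Background quenching percentage.
#' @export
combined_background <- function(ksv_values) {
  if (length(ksv_values) == 0) return(0)
  if (!is.numeric(ksv_values) || any(ksv_values < 0))
    stop("Stern-Volmer products must be non-negative", call. = FALSE)
  100 * (1 - 1 / (1 + sum(ksv_values)))
}

draw_background_ksv <- function(n, model, seed = NULL) {
  draw <- function() rlnorm(n, model$background_ksv_log_mean,
                            model$background_ksv_log_sd)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Probability that background alone triggers a positive call
#'
#' Monte-Carlo probability that a pool of `k` inactive compounds exceeds the
#' model threshold through cumulative background quenching plus readout
#' noise. Non-decreasing in `k`; drives the choice of pool size.
#'
#' @param k Pool size (>= 0).
#' @param model A [quench_model()].
#' @param n_sim Number of simulated pools.
#' @param seed Integer seed.
#' @return Estimated false-positive probability.
#' @export
false_positive_prob <- function(k, model = quench_model(), n_sim = 10000,
                                seed = 1) {
  k <- assert_count(k, "k")
  n_sim <- assert_count(n_sim, "n_sim", 1L)
  if (k == 0L) return(0)
  with_seed(seed, {
    ksv <- matrix(rlnorm(k * n_sim, model$background_ksv_log_mean,
                         model$background_ksv_log_sd), nrow = n_sim)
    bg <- 100 * (1 - 1 / (1 + rowSums(ksv)))
    q <- pmin(100, pmax(0, bg + rnorm(n_sim, 0, model$readout_noise_sd)))
    mean(q >= model$threshold)
  })
}

#' Probability that a pool contains at least one active pair
#'
#' Under independent per-pair activation with probability `p_pair`, a pool of
#' size `k` holds `C(k,2)` pairs and is positive with probability
#' `1 - (1 - p_pair)^C(k,2)`.
#'
#' @param p_pair Per-pair hit probability in `[0, 1]`.
#' @param k Pool size.
#' @return Hit probability of the pool.
#' @examples
#' positive_group_prob(0.005, 10) # 1 - 0.995^45
#' @export
positive_group_prob <- function(p_pair, k) {
  if (!is.numeric(p_pair) || any(p_pair < 0) || any(p_pair > 1))
    stop("`p_pair` must be in [0, 1]", call. = FALSE)
  k <- assert_count(k, "k")
  1 - (1 - p_pair)^choose(k, 2)
}

#' Expected total experiment count of a pooled campaign
#'
#' Initial screen plus expected deconvolution effort:
#' `design_size + design_size * positive_group_prob(p_pair, k) *
#' deconv_cost_fn(k)`.
#'
#' @param n Library size.
#' @param k Pool size.
#' @param p_pair Per-pair hit probability.
#' @param deconv_cost_fn Function `k -> expected deconvolution queries per
#'   positive pool`.
#' @param design_size_fn Function `(n, k) -> number of pools`.
#' @return Expected total number of experiments.
#' @export
expected_total_tests <- function(n, k, p_pair,
                                 deconv_cost_fn, design_size_fn) {
  ds <- design_size_fn(n, k)
  ds + ds * positive_group_prob(p_pair, k) * deconv_cost_fn(k)
}

# mean deconvolution cost of a positive pool of size k at per-pair hit rate
# p: pair count drawn Binomial(C(k,2), p) conditioned on >= 1 (multi-hit
# pools are exactly what penalizes large k), uniform placement, noiseless
# oracle, pool already known positive from the screen
conditional_deconv_cost <- function(k, p_pair, n_sim, seed) {
  if (k == 2L) return(0)
  npairs <- choose(k, 2)
  all_pairs <- combn(k, 2L, simplify = FALSE)
  tests <- vapply(seq_len(n_sim), function(i) {
    planted <- with_seed(seed * 7717L %% 2147483647L + i, {
      m <- 0L
      while (m == 0L) m <- stats::rbinom(1L, npairs, p_pair)
      all_pairs[sample.int(npairs, m)]
    })
    oracle <- function(S) any(vapply(planted, function(e) all(e %in% S), TRUE))
    run_iterative(seq_len(k), oracle, seed = (seed + i) %% 2147483647L,
                  root_known_positive = TRUE)$tests_used
  }, 1)
  mean(tests)
}

#' Tabulate the pool-size trade-off
#'
#' For each pool size `k`, builds a greedy covering design, estimates the
#' expected deconvolution cost of a positive pool by simulation (with the
#' number of planted pairs drawn from the hit rate, conditioned on the pool
#' being positive), and reports the expected total experiment count
#' `design_size * (1 + p_positive * expected_deconv)`. `p_positive` combines
#' genuine hits with background false positives under `model`. At low hit
#' rates the curve first falls with `k` (fewer pools) and then rises again as
#' multi-hit pools and cumulative background quenching take over -- the
#' trade-off that selects the working pool size.
#'
#' @param n Library size.
#' @param p_pair Per-pair hit probability (default 0.005).
#' @param k_range Integer vector of pool sizes to tabulate.
#' @param model A [quench_model()] supplying the background distribution and
#'   threshold for the false-positive term; `NULL` drops that term.
#' @param restarts Greedy restarts per design (kept modest: the table needs
#'   relative sizes, not record solutions).
#' @param n_sim Simulations for the per-pool deconvolution cost and the
#'   false-positive probability.
#' @param seed Integer seed.
#' @return Data frame with columns `k`, `design_size`, `p_positive`,
#'   `expected_deconv`, `expected_total`.
#' @export
tradeoff_table <- function(n, p_pair = 0.005, k_range = 4:20,
                           model = quench_model(), restarts = 20,
                           n_sim = 200, seed = 1) {
  n <- assert_count(n, "n", 2L)
  rows <- lapply(k_range, function(k) {
    ds <- length(greedy_design(n, k, restarts = restarts, seed = seed)$blocks)
    dc <- conditional_deconv_cost(k, p_pair, n_sim, seed)
    pp <- positive_group_prob(p_pair, k)
    if (!is.null(model))
      pp <- 1 - (1 - pp) * (1 - false_positive_prob(k, model,
                                                    n_sim = max(n_sim, 2000),
                                                    seed = seed))
    data.frame(k = k, design_size = ds, p_positive = pp,
               expected_deconv = dc,
               expected_total = ds * (1 + pp * dc))
  })
  do.call(rbind, rows)
}
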