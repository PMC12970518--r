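# Non-adaptive ("one-step") deconvolution: a fixed family of subsets of a
# positive pool whose positive/negative pattern uniquely identifies a single
# active pair.  The pair {a, b} lights up exactly the subsets containing both
# members; the family is valid when those signatures are pairwise distinct
# and non-empty.

#' Search a one-step signature design
#'
#' Random-restart search for `n_subsets` subsets of size `subset_size` within
#' a pool of `group_size` members such that every pair of the pool has a
#' distinct, non-empty signature (the set of subsets containing both pair
#' members). For the working pool size of 10, eight subsets of seven suffice.
#'
#' @param group_size Pool size.
#' @param n_subsets Number of subsets to test in parallel.
#' @param subset_size Members per subset (< `group_size`).
#' @param seed Integer seed.
#' @param max_tries Random families to try before giving up.
#' @return A `signature_design` list: `group_size`, `subsets` (list of
#'   integer vectors of within-pool positions 1..group_size), and
#'   `signature_map` (named list, key `"a,b"` over pool positions, value the
#'   integer vector of subset indices).
#' @export
onestep_design <- function(group_size, n_subsets, subset_size, seed = 1,
                           max_tries = 10000) {
  group_size <- assert_count(group_size, "group_size", 3L)
  n_subsets <- assert_count(n_subsets, "n_subsets", 1L)
  subset_size <- assert_count(subset_size, "subset_size", 2L)
  max_tries <- assert_count(max_tries, "max_tries", 1L)
  if (subset_size >= group_size)
    stop("subset_size must be below group_size", call. = FALSE)
  n_pairs <- choose(group_size, 2)
  if (2^n_subsets - 1 < n_pairs)
    stop(sprintf(paste("infeasible: %d subsets give at most %d distinct",
                       "non-empty patterns for %d pairs"),
                 n_subsets, 2^n_subsets - 1, n_pairs), call. = FALSE)

  pairs <- combn(group_size, 2L)
  weights <- 2^(seq_len(n_subsets) - 1L)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # membership matrix M: n_subsets x group_size
      M <- t(vapply(seq_len(n_subsets), function(i) {
        v <- numeric(group_size)
        v[sample.int(group_size, subset_size)] <- 1
        v
      }, numeric(group_size)))
      both <- M[, pairs[1L, ], drop = FALSE] * M[, pairs[2L, ], drop = FALSE]
      code <- as.vector(weights %*% both) # numeric pattern id per pair
      if (all(code > 0) && !anyDuplicated(code)) {
        subsets <- lapply(seq_len(n_subsets), function(i) which(M[i, ] == 1))
        sig_map <- lapply(seq_len(ncol(pairs)), function(j)
          which(both[, j] == 1))
        names(sig_map) <- apply(pairs, 2L, paste, collapse = ",")
        return(structure(list(group_size = group_size, subsets = subsets,
                              signature_map = sig_map),
                         class = "signature_design"))
      }
    }
    stop(sprintf(paste("no valid signature design found in %d tries",
                       "(group_size=%d, n_subsets=%d, subset_size=%d)"),
         max_tries, group_size, n_subsets, subset_size), call. = FALSE)
  })
}

#' @export
print.signature_design <- function(x, ...) {
  cat(sprintf("One-step signature design: pool of %d, %d subsets of size %d\n",
              x$group_size, length(x$subsets),
              length(x$subsets[[1]])))
  invisible(x)
}

#' Decode a one-step readout pattern
#'
#' An observed positive-subset pattern matching the signature of exactly one
#' pair identifies that pair. Any other pattern is ambiguous and is returned
#' with its candidate explanations: all sets of up to `max_combo` pairs whose
#' signature union equals the observation (multi-hit hypothesis) and all
#' single pool members whose subset-membership pattern equals it
#' (single-quencher hypothesis).
#'
#' @param design A [onestep_design()] result.
#' @param positive_subsets Integer vector of subset indices observed positive
#'   (may be empty).
#' @param max_combo Largest number of simultaneous pairs considered when
#'   enumerating explanations of an ambiguous pattern.
#' @return For a unique match, `list(status = "pair", pair = c(a, b))` (pool
#'   positions). Otherwise `status = "ambiguous"` (or `"no_pair"` for an
#'   empty pattern) with `pair_sets` (list of lists of pairs) and
#'   `singletons` (integer vector) of consistent explanations.
#' @export
onestep_decode <- function(design, positive_subsets, max_combo = 2) {
  stopifnot(inherits(design, "signature_design"))
  positive_subsets <- sort(unique(as.integer(positive_subsets)))
  if (length(positive_subsets) > 0 &&
      (min(positive_subsets) < 1 || max(positive_subsets) > length(design$subsets)))
    stop("positive_subsets outside subset indices", call. = FALSE)

  obs <- paste(positive_subsets, collapse = ",")
  sig_keys <- vapply(design$signature_map, function(s) paste(s, collapse = ","), "")
  hit <- which(sig_keys == obs)
  if (length(hit) == 1L)
    return(list(status = "pair",
                pair = as.integer(strsplit(names(design$signature_map)[hit], ",")[[1]])))

  pair_list <- lapply(names(design$signature_map), function(k)
    as.integer(strsplit(k, ",")[[1]]))
  explanations <- list()
  if (length(positive_subsets) > 0) {
    for (m in seq_len(max_combo)) {
      idx_comb <- combn(length(pair_list), m, simplify = FALSE)
      for (idx in idx_comb) {
        u <- sort(unique(unlist(design$signature_map[idx])))
        if (identical(u, positive_subsets))
          explanations <- c(explanations, list(pair_list[idx]))
      }
    }
  }
  membership <- vapply(seq_len(design$group_size), function(cand)
    paste(which(vapply(design$subsets, function(s) cand %in% s, TRUE)),
          collapse = ","), "")
  singles <- which(membership == obs)

  list(status = if (length(positive_subsets) == 0) "no_pair" else "ambiguous",
       pair_sets = explanations, singletons = as.integer(singles))
}
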