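# Reaction-vs-control comparison of GC-MS peak tables.
#
# Input is tabular: one row per chromatographic peak with a retention time
# (minutes) and a base-peak intensity, optionally followed by a unit-m/z
# spectrum vector.  A reaction peak "matches" a control peak when their
# retention times agree within a tolerance (and, when spectra are available,
# their spectral cosine is high enough); prominent unmatched reaction peaks
# are the candidate new products.

#' Construct a peak table
#'
#' @param run_id Run identifier.
#' @param rt Retention times in minutes (non-negative; stored sorted).
#' @param intensity Base-peak intensities (> 0).
#' @param spectra Optional numeric matrix, one row per peak, columns unit-m/z
#'   intensity bins.
#' @return A `peak_table` object.
#' @export
peak_table <- function(run_id, rt, intensity, spectra = NULL) {
  stopifnot(is.character(run_id), length(run_id) == 1L,
            length(rt) == length(intensity))
  if (length(rt) > 0 && (any(rt < 0) || any(intensity <= 0)))
    stop("retention times must be >= 0 and intensities > 0", call. = FALSE)
  ord <- order(rt)
  if (!is.null(spectra)) {
    spectra <- as.matrix(spectra)
    stopifnot(nrow(spectra) == length(rt))
    spectra <- spectra[ord, , drop = FALSE]
  }
  structure(list(run_id = run_id, rt = as.numeric(rt[ord]),
                 intensity = as.numeric(intensity[ord]), spectra = spectra),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table `%s`: %d peaks%s\n", x$run_id, length(x$rt),
              if (is.null(x$spectra)) "" else " (with spectra)"))
  invisible(x)
}

#' Read / write a peak table CSV
#'
#' Format: `run_id,rt_min,intensity[,mz_0,mz_1,...]`; spectrum columns are
#' optional and must share the `mz_` prefix.
#'
#' @param path CSV path.
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("run_id", "rt_min", "intensity") %in% names(df)))
    stop("peak table needs columns run_id, rt_min, intensity", call. = FALSE)
  mz_cols <- grep("^mz_", names(df), value = TRUE)
  spectra <- if (length(mz_cols) > 0) as.matrix(df[, mz_cols, drop = FALSE]) else NULL
  peak_table(df$run_id[1] %||% "run", df$rt_min, df$intensity, spectra)
}

#' @rdname read_peak_table
#' @param table A `peak_table`.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(run_id = table$run_id, rt_min = table$rt,
                   intensity = table$intensity)
  if (!is.null(table$spectra)) {
    sp <- as.data.frame(table$spectra)
    names(sp) <- paste0("mz_", seq_len(ncol(sp)) - 1L)
    df <- cbind(df, sp)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

spectral_cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# greedy nearest-rt assignment of reaction peaks to the peaks of ONE control;
# returns for each reaction peak the matched control peak index or NA
match_one_control <- function(reaction, control, rt_tolerance,
                              spectrum_min_cosine) {
  nr <- length(reaction$rt); nc <- length(control$rt)
  assign_r <- rep(NA_integer_, nr)
  if (nr == 0 || nc == 0) return(assign_r)
  cand <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  cand$d <- abs(reaction$rt[cand$r] - control$rt[cand$c])
  cand <- cand[cand$d <= rt_tolerance, , drop = FALSE]
  if (!is.null(spectrum_min_cosine) && !is.null(reaction$spectra) &&
      !is.null(control$spectra) && nrow(cand) > 0) {
    cos <- vapply(seq_len(nrow(cand)), function(i)
      spectral_cosine(reaction$spectra[cand$r[i], ],
                      control$spectra[cand$c[i], ]), 1)
    cand <- cand[cos >= spectrum_min_cosine, , drop = FALSE]
  }
  cand <- cand[order(cand$d), , drop = FALSE]
  used_c <- rep(FALSE, nc)
  for (i in seq_len(nrow(cand))) {
    r <- cand$r[i]; cc <- cand$c[i]
    if (is.na(assign_r[r]) && !used_c[cc]) {
      assign_r[r] <- cc
      used_c[cc] <- TRUE
    }
  }
  assign_r
}

#' Compare a reaction peak table against its controls
#'
#' Each control is matched independently against the reaction table by greedy
#' nearest-retention-time assignment (each control peak used at most once;
#' optional spectral-cosine gate). A reaction peak matched in no control is
#' "new"; new peaks at or above `intensity_floor_fraction` times the largest
#' reaction intensity are the prominent candidates reported in `new_peaks`,
#' quieter ones land in `low_unmatched`. Control peaks never matched by any
#' reaction peak are reported as `disappeared_peaks`.
#'
#' @param reaction A `peak_table` for the reaction run.
#' @param controls List of `peak_table`s (solvent blank first, by
#'   convention).
#' @param rt_tolerance Maximum retention-time difference for a match
#'   (minutes).
#' @param intensity_floor_fraction Fraction of the maximum reaction intensity
#'   below which an unmatched peak is not called prominent.
#' @param spectrum_min_cosine Minimum spectral cosine for a match, or `NULL`
#'   to match on retention time alone.
#' @return A `peak_diff_report` with data-frame fields `new_peaks`,
#'   `matched_peaks` (reaction rt/intensity, control rt, control id),
#'   `low_unmatched` and `disappeared_peaks`.
#' @export
match_peaks <- function(reaction, controls, rt_tolerance = 0.05,
                        intensity_floor_fraction = 0.05,
                        spectrum_min_cosine = NULL) {
  stopifnot(inherits(reaction, "peak_table"),
            rt_tolerance > 0, intensity_floor_fraction >= 0,
            intensity_floor_fraction <= 1)
  if (inherits(controls, "peak_table")) controls <- list(controls)
  stopifnot(all(vapply(controls, inherits, TRUE, "peak_table")))

  nr <- length(reaction$rt)
  empty <- data.frame(rt = numeric(0), intensity = numeric(0))
  if (nr == 0) {
    return(structure(list(run_id = reaction$run_id, new_peaks = empty,
                          matched_peaks = cbind(empty, control_rt = numeric(0),
                                                control = character(0)),
                          low_unmatched = empty,
                          disappeared_peaks = cbind(empty, control = character(0))),
                     class = "peak_diff_report"))
  }

  assigns <- lapply(controls, function(ctrl)
    match_one_control(reaction, ctrl, rt_tolerance, spectrum_min_cosine))
  matched_any <- Reduce(`|`, lapply(assigns, function(a) !is.na(a)))

  # best (nearest-rt) control match per matched reaction peak, for reporting
  best_ctrl <- rep(NA_integer_, nr); best_peak <- rep(NA_integer_, nr)
  best_d <- rep(Inf, nr)
  for (ci in seq_along(controls)) {
    a <- assigns[[ci]]
    hit <- which(!is.na(a))
    d <- abs(reaction$rt[hit] - controls[[ci]]$rt[a[hit]])
    upd <- hit[d < best_d[hit]]
    best_d[upd] <- abs(reaction$rt[upd] - controls[[ci]]$rt[a[upd]])
    best_ctrl[upd] <- ci
    best_peak[upd] <- a[upd]
  }

  floor_abs <- intensity_floor_fraction * max(reaction$intensity)
  is_new <- !matched_any & reaction$intensity >= floor_abs
  is_low <- !matched_any & reaction$intensity < floor_abs

  mk <- function(sel) data.frame(rt = reaction$rt[sel],
                                 intensity = reaction$intensity[sel])
  matched <- mk(matched_any)
  if (any(matched_any)) {
    matched$control_rt <- vapply(which(matched_any), function(i)
      controls[[best_ctrl[i]]]$rt[best_peak[i]], 1)
    matched$control <- vapply(which(matched_any), function(i)
      controls[[best_ctrl[i]]]$run_id, "")
  } else {
    matched$control_rt <- numeric(0)
    matched$control <- character(0)
  }

  disappeared <- do.call(rbind, lapply(seq_along(controls), function(ci) {
    ctrl <- controls[[ci]]
    used <- assigns[[ci]][!is.na(assigns[[ci]])]
    sel <- setdiff(seq_along(ctrl$rt), used)
    if (length(sel) == 0) return(NULL)
    data.frame(rt = ctrl$rt[sel], intensity = ctrl$intensity[sel],
               control = ctrl$run_id)
  }))
  if (is.null(disappeared))
    disappeared <- cbind(empty, control = character(0))

  structure(list(run_id = reaction$run_id,
                 new_peaks = mk(is_new),
                 matched_peaks = matched,
                 low_unmatched = mk(is_low),
                 disappeared_peaks = disappeared),
            class = "peak_diff_report")
}

#' @export
print.peak_diff_report <- function(x, ...) {
  cat(sprintf("Peak diff `%s`: %d new, %d matched, %d low unmatched, %d disappeared\n",
              x$run_id, nrow(x$new_peaks), nrow(x$matched_peaks),
              nrow(x$low_unmatched), nrow(x$disappeared_peaks)))
  invisible(x)
}

#' Batch reaction-vs-control comparison over a screening grid
#'
#' Applies [match_peaks()] to every reaction run of a (pair x acceptor) grid
#' and ranks the cells by evidence of new products. A missing control is
#' recorded as a per-run error and the batch continues.
#'
#' @param grid Data frame with columns `pair`, `acceptor`, `run_id`.
#' @param tables Named list of `peak_table`s covering all run and control
#'   ids.
#' @param control_map Named list: reaction `run_id` -> character vector of
#'   control run ids (solvent blank first, by convention).
#' @param ... Passed to [match_peaks()].
#' @return A list with `reports` (named list of `peak_diff_report`s) and
#'   `hits`, a data frame ranked by new-peak count then top new-peak
#'   intensity, with any per-run `error` messages.
#' @export
batch_compare <- function(grid, tables, control_map, ...) {
  stopifnot(is.data.frame(grid),
            all(c("pair", "acceptor", "run_id") %in% names(grid)))
  reports <- list()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run <- grid$run_id[i]
    out <- data.frame(run_id = run, pair = grid$pair[i],
                      acceptor = grid$acceptor[i], n_new = NA_integer_,
                      top_new_intensity = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      ctrl_ids <- control_map[[run]]
      if (is.null(ctrl_ids) || length(ctrl_ids) == 0)
        stop("no controls mapped for run ", run)
      if (is.null(tables[[run]])) stop("missing peak table for run ", run)
      missing <- ctrl_ids[!ctrl_ids %in% names(tables)]
      if (length(missing) > 0)
        stop("missing control table(s): ", paste(missing, collapse = ", "))
      match_peaks(tables[[run]], tables[ctrl_ids], ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      reports[[run]] <<- res
      out$n_new <- nrow(res$new_peaks)
      out$top_new_intensity <- if (nrow(res$new_peaks) > 0)
        max(res$new_peaks$intensity) else 0
    }
    out
  })
  hits <- do.call(rbind, rows)
  ok <- !is.na(hits$n_new)
  hits <- rbind(hits[ok, ][order(-hits$n_new[ok], -hits$top_new_intensity[ok]), ],
                hits[!ok, ])
  rownames(hits) <- NULL
  list(reports = reports, hits = hits)
}

#' Write a peak-diff report to JSON
#'
#' @param report A `peak_diff_report`.
#' @param path Output path.
#' @export
write_peak_diff <- function(report, path) {
  stopifnot(inherits(report, "peak_diff_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}
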