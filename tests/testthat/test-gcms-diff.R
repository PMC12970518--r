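mk_table <- function(id, rt, intensity, spectra = NULL)
  peak_table(id, rt, intensity, spectra)

test_that("identical reaction and control yield no new peaks", {
  tb <- mk_table("r", c(1.0, 2.5, 4.2), c(100, 500, 80))
  rep <- match_peaks(tb, list(mk_table("c", tb$rt, tb$intensity)))
  expect_identical(nrow(rep$new_peaks), 0L)
  expect_identical(nrow(rep$matched_peaks), 3L)
  expect_identical(nrow(rep$disappeared_peaks), 0L)
})

test_that("an extra prominent peak is flagged as new; quiet ones are not", {
  ctrl <- mk_table("c", c(1.0, 2.5), c(100, 500))
  rxn <- mk_table("r", c(1.0, 2.5, 4.2, 6.0), c(100, 500, 300, 1))
  rep <- match_peaks(rxn, list(ctrl), intensity_floor_fraction = 0.05)
  expect_identical(rep$new_peaks$rt, 4.2)
  expect_identical(rep$low_unmatched$rt, 6.0) # below 5% of max intensity
  # every reaction peak lands in exactly one bucket
  expect_identical(nrow(rep$new_peaks) + nrow(rep$matched_peaks) +
                     nrow(rep$low_unmatched), 4L)
})

test_that("greedy matching assigns the nearest peak; each control peak once", {
  ctrl <- mk_table("c", 2.00, 100)
  rxn <- mk_table("r", c(1.98, 2.03), c(400, 300))
  rep <- match_peaks(rxn, list(ctrl), rt_tolerance = 0.05)
  expect_identical(rep$matched_peaks$rt, 1.98) # nearer of the two
  expect_identical(rep$new_peaks$rt, 2.03)
})

test_that("disappeared control peaks are reported", {
  ctrl <- mk_table("c", c(1.0, 3.0), c(50, 70))
  rxn <- mk_table("r", 1.0, 60)
  rep <- match_peaks(rxn, list(ctrl))
  expect_identical(rep$disappeared_peaks$rt, 3.0)
  expect_identical(rep$disappeared_peaks$control, "c")
})

test_that("raising the intensity floor never adds new peaks", {
  set.seed(4)
  rxn <- mk_table("r", sort(runif(20, 0, 10)), rlnorm(20, 4, 1))
  ctrl <- mk_table("c", sort(runif(12, 0, 10)), rlnorm(12, 4, 1))
  floors <- c(0, 0.02, 0.1, 0.3, 0.8)
  counts <- vapply(floors, function(f)
    nrow(match_peaks(rxn, list(ctrl), intensity_floor_fraction = f)$new_peaks),
    1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("match_peaks is invariant to control order and idempotent", {
  set.seed(9)
  rxn <- mk_table("r", sort(runif(15, 0, 8)), rlnorm(15, 4, 1))
  c1 <- mk_table("c1", sort(runif(10, 0, 8)), rlnorm(10, 4, 1))
  c2 <- mk_table("c2", sort(runif(10, 0, 8)), rlnorm(10, 4, 1))
  r12 <- match_peaks(rxn, list(c1, c2))
  r21 <- match_peaks(rxn, list(c2, c1))
  expect_identical(r12$new_peaks, r21$new_peaks)
  expect_identical(r12$low_unmatched, r21$low_unmatched)
  expect_identical(match_peaks(rxn, list(c1, c2))$new_peaks, r12$new_peaks)
})

test_that("spectral cosine gates matches when spectra are present", {
  sp_a <- matrix(c(10, 0, 5, 0), nrow = 1)
  sp_b <- matrix(c(0, 8, 0, 4), nrow = 1) # orthogonal spectrum
  rxn <- mk_table("r", 2.0, 100, sp_a)
  ctrl_same <- mk_table("c", 2.01, 90, sp_a)
  ctrl_diff <- mk_table("c", 2.01, 90, sp_b)
  expect_identical(
    nrow(match_peaks(rxn, list(ctrl_same), spectrum_min_cosine = 0.9)$matched_peaks),
    1L)
  rep2 <- match_peaks(rxn, list(ctrl_diff), spectrum_min_cosine = 0.9)
  expect_identical(nrow(rep2$matched_peaks), 0L)
  expect_identical(nrow(rep2$new_peaks), 1L)
})

test_that("empty reaction tables produce an empty report", {
  rep <- match_peaks(mk_table("r", numeric(0), numeric(0)),
                     list(mk_table("c", 1, 10)))
  expect_identical(nrow(rep$new_peaks), 0L)
  expect_identical(nrow(rep$matched_peaks), 0L)
})

test_that("batch_compare ranks the planted product first and survives missing controls", {
  set.seed(11)
  base_rt <- sort(runif(8, 0, 10))
  base_int <- rlnorm(8, 4, 0.5)
  tables <- list(blank = mk_table("blank", base_rt, base_int))
  grid <- expand.grid(pair = paste0("P", 1:3), acceptor = paste0("A", 1:4),
                      stringsAsFactors = FALSE)
  grid$run_id <- paste(grid$pair, grid$acceptor, sep = "_")
  control_map <- list()
  for (i in seq_len(nrow(grid))) {
    run <- grid$run_id[i]
    rt <- base_rt; int <- base_int
    if (run == "P2_A3") { rt <- c(rt, 5.55); int <- c(int, max(int) * 3) }
    tables[[run]] <- mk_table(run, rt, int)
    control_map[[run]] <- "blank"
  }
  control_map[["P3_A4"]] <- "missing_control"
  out <- batch_compare(grid, tables, control_map)
  expect_identical(out$hits$run_id[1], "P2_A3")
  expect_identical(out$hits$n_new[1], 1L)
  expect_true(all(out$hits$n_new[2:10] == 0, na.rm = TRUE))
  err_row <- out$hits[out$hits$run_id == "P3_A4", ]
  expect_match(err_row$error, "missing control")
  expect_length(out$reports, 11) # 12 cells minus the failed one
})

test_that("peak tables round-trip through CSV including spectra", {
  sp <- matrix(rpois(6, 20), nrow = 2)
  tb <- mk_table("runX", c(1.5, 3.2), c(120, 340), sp)
  path <- tempfile(fileext = ".csv")
  write_peak_table(tb, path)
  tb2 <- read_peak_table(path)
  expect_equal(tb$rt, tb2$rt)
  expect_equal(tb$intensity, tb2$intensity)
  expect_equal(unname(tb$spectra), unname(tb2$spectra))
  expect_error(peak_table("x", c(2, 1), c(5, -1)), "intensities")
})
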