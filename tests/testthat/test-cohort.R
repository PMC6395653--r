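# short measurement windows keep the per-mouse simulations cheap
short_design <- function(...) {
  cohort_design(measurement_days = seq(10, 24, by = 3.5), ...)
}

test_that("degenerate noise makes all mice identical to the scenario mean", {
  model <- ll2_model()
  d <- short_design(n_mice = 3, v0_sd = 0, growth_cv = 0, noise_cv = 0, seed = 3)
  ch <- generate_cohort(d, model = model)
  wide <- tidyr::pivot_wider(tibble::as_tibble(ch)[c("mouse_id", "time_day", "volume_mm3")],
                             names_from = "mouse_id", values_from = "volume_mm3")
  expect_equal(wide$`2`, wide$`1`, tolerance = 1e-10)
  expect_equal(wide$`3`, wide$`1`, tolerance = 1e-10)
  expect_equal(ch$volume_mm3, ch$volume_true_mm3)
})

test_that("cohorts are bit-reproducible from the seed and vary across seeds", {
  model <- ll2_model()
  a <- generate_cohort(short_design(n_mice = 3, seed = 11), model = model)
  b <- generate_cohort(short_design(n_mice = 3, seed = 11), model = model)
  c <- generate_cohort(short_design(n_mice = 3, seed = 12), model = model)
  expect_identical(a$volume_mm3, b$volume_mm3)
  expect_false(identical(a$volume_mm3, c$volume_mm3))
})

test_that("cohort summaries reproduce hand-computed mean and SD", {
  model <- ll2_model()
  ch <- generate_cohort(short_design(n_mice = 2, seed = 1), model = model)
  ch$volume_mm3 <- rep(c(100, 200), each = length(unique(ch$time_day)))
  ser <- summarize_cohort(ch)
  expect_true(all(ser$volume_mm3 == 150))
  expect_equal(ser$sigma_mm3, rep(70.71068, nrow(ser)), tolerance = 1e-6)
  # mean curve invariant under mouse relabelling
  ch2 <- ch
  ch2$mouse_id <- 3 - ch2$mouse_id
  ser2 <- summarize_cohort(ch2)
  expect_equal(ser2$volume_mm3, ser$volume_mm3)
})

test_that("a single-mouse cohort falls back to noise_cv-based sigma with a warning", {
  model <- ll2_model()
  ch <- generate_cohort(short_design(n_mice = 1, noise_cv = 0.07, seed = 2),
                        model = model)
  expect_warning(ser <- summarize_cohort(ch), "single-mouse")
  expect_equal(ser$sigma_mm3, pmax(0.07 * ser$volume_mm3, 1))
})

test_that("marginal distributions match the design at large n", {
  model <- ll2_model()
  d <- cohort_design(n_mice = 400, measurement_days = c(10, 12),
                     v0_mean = 154, v0_sd = 16, growth_cv = 0,
                     noise_cv = 0.05, seed = 21)
  ch <- generate_cohort(d, model = model)
  first <- ch[ch$time_day == 10, ]
  # observed day-10 volume = v0 * lognormal noise (mean 1)
  se <- sqrt(16^2 + (154 * 0.05)^2) / sqrt(400)
  expect_lt(abs(mean(first$volume_mm3) - 154), 3 * se)
  noise_ratio <- first$volume_mm3 / first$volume_true_mm3
  cv_hat <- stats::sd(noise_ratio) / mean(noise_ratio)
  expect_lt(abs(cv_hat - 0.05) / 0.05, 0.10)
})

test_that("cohort CSV export records data and provenance", {
  model <- ll2_model()
  ch <- generate_cohort(short_design(n_mice = 2, seed = 4), model = model)
  path <- tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(names(back), c("mouse_id", "time_day", "volume_mm3", "censored"))
  prov <- jsonlite::read_json(paste0(path, ".provenance.json"))
  expect_equal(prov$design$seed, 4)
  expect_equal(length(prov$ground_truth$multipliers), 2)
})

test_that("lethal-volume censoring flags trajectories from the crossing onward", {
  model <- ll2_model()
  d <- cohort_design(measurement_days = seq(10, 59, by = 7), n_mice = 2,
                     censor_at = 1000, seed = 5)
  ch <- generate_cohort(d, model = model)
  for (i in 1:2) {
    flags <- ch$censored[ch$mouse_id == i]
    expect_true(all(diff(flags) >= 0))  # once censored, stays censored
    expect_true(any(flags))             # control crosses 1000 mm^3
  }
})

test_that("default cohorts land in the experimental envelopes", {
  model <- ll2_model()
  pbs <- generate_cohort(cohort_design("pbs", seed = 1), model = model)
  day59 <- pbs$volume_mm3[pbs$time_day == max(pbs$time_day)]
  expect_gt(mean(day59), 4076 - 297)
  expect_lt(mean(day59), 4076 + 297)
  ther <- generate_cohort(cohort_design("metablocs_full", seed = 2), model = model)
  late <- ther$volume_mm3[ther$time_day >= 45]
  expect_gt(mean(late), 873 - 70)
  expect_lt(mean(late), 873 + 70)
})
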