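test_that("the simulated mean structure pins e and the zero-dose control", {
  tab <- sim_dose_response(b = 2, d = 80, e = 50, doses = c(0, 50),
                           n_reps = 4, noise_sd = 0, seed = 1)
  expect_true(all(tab$area[tab$dose == 50] == 40))
  expect_true(all(tab$area[tab$dose == 0] == 80))
  expect_error(sim_dose_response(b = 2, d = 80, e = 50, doses = c(0, 50),
                                 n_reps = 2, noise_sd = -1), "non-negative")
  expect_error(sim_dose_response(b = 2, d = 80, e = -1, doses = c(0, 50),
                                 n_reps = 2, noise_sd = 0), "positive")
})

test_that("noiseless data recover the generating parameters almost exactly", {
  tab <- sim_dose_response(b = 2, d = 100, e = 50,
                           doses = c(0, 10, 25, 50, 100, 200, 400),
                           n_reps = 3, noise_sd = 0, seed = 1)
  fit <- fit_log_logistic_4p(tab)
  expect_true(fit$converged)
  expect_lt(abs(fit$e - 50) / 50, 1e-6)
  expect_lt(abs(fit$b - 2) / 2, 1e-6)
  expect_lt(abs(fit$d - 100) / 100, 1e-6)
})

test_that("degenerate fits fail loudly instead of silently", {
  all_dead <- tibble::tibble(dose = c(0, 1, 2, 3), area = 0)
  expect_error(fit_log_logistic_4p(all_dead), "surviving")
  few <- tibble::tibble(dose = c(0, 1, 1, 2), area = c(9, 5, 6, 2))
  expect_error(fit_log_logistic_4p(few), "4 distinct doses")
})

test_that("scaling all doses rescales e and leaves b, d and RI unchanged", {
  tab <- sim_dose_response(b = 1.6, d = 90, e = 30,
                           doses = c(0, 5, 15, 30, 60, 120, 240),
                           n_reps = 3, noise_sd = 3, seed = 4)
  f1 <- fit_log_logistic_4p(tab)
  s <- 1000
  f2 <- fit_log_logistic_4p(dplyr::mutate(tab, dose = dose * s))
  expect_equal(f2$e, f1$e * s, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
  expect_equal(f2$d, f1$d, tolerance = 1e-4)
  ri1 <- compute_resistance_index(f1, list(wt = f1), "resistance")
  ri2 <- compute_resistance_index(f2, list(wt = f2), "resistance")
  expect_equal(ri1$ri, ri2$ri, tolerance = 1e-8)
})

test_that("tidy, glance and autoplot expose the fit in standard shapes", {
  tab <- sim_dose_response(b = 2, d = 100, e = 50,
                           doses = c(0, 10, 25, 50, 100, 200, 400),
                           n_reps = 3, noise_sd = 2, seed = 2)
  fit <- fit_log_logistic_4p(tab)
  td <- tidy(fit)
  expect_equal(td$term, c("b", "d", "e"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$ic50, fit$e)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("LD100 is the lowest all-replicates-dead dose, else right-censored", {
  tab <- tibble::tibble(
    dose = rep(c(0, 1000, 5000, 10000), each = 3),
    area = c(9, 10, 11, 2, 0, 1, 0, 0, 0, 0, 0, 0)
  )
  ld <- estimate_ld100(tab)
  expect_equal(ld$ld100, 5000)
  expect_false(ld$censored)
  alive <- tibble::tibble(dose = rep(c(0, 10, 20), each = 2),
                          area = c(9, 9, 5, 4, 2, 1))
  ld2 <- estimate_ld100(alive)
  expect_true(ld2$censored)
  expect_equal(ld2$label, "> 20")
  # zero_epsilon relaxes what counts as dead
  ld3 <- estimate_ld100(alive, zero_epsilon = 2)
  expect_equal(ld3$ld100, 20)
})

test_that("on noiseless monotone data LD100 is at or above the IC50", {
  tab <- sim_dose_response(b = 3, d = 100, e = 20,
                           doses = c(0, 5, 10, 20, 40, 80, 160, 320),
                           n_reps = 3, noise_sd = 0, seed = 1)
  fit <- fit_log_logistic_4p(tab)
  ld <- estimate_ld100(tab)
  expect_gte(ld$ld100, fit$e)
})

test_that("the RI uses the conservative wild-type reference in both directions", {
  mk_fit <- function(e, se = 1) {
    structure(list(b = 2, d = 100, e = e,
                   se = c(b = 0.1, d = 1, e = se),
                   converged = TRUE, n_obs = 21, sigma = 1,
                   data = NULL), class = "ll4_fit")
  }
  wt <- list(tak1 = mk_fit(56, 6), tak2 = mk_fit(135, 24))
  mut <- mk_fit(550, 50)
  r <- compute_resistance_index(mut, wt, "resistance")
  expect_equal(r$reference_line, "tak2")
  expect_equal(r$ri, 550 / 135, tolerance = 1e-9)
  # conservative: any other reference gives a larger RI
  expect_gt(550 / 56, r$ri)
  s <- compute_resistance_index(mut, wt, "sensitivity")
  expect_equal(s$reference_line, "tak1")
  # identical IC50s give RI 1; delta-method SE matches the formula
  self <- compute_resistance_index(mk_fit(135, 24), wt, "resistance")
  expect_equal(self$ri, 1)
  expect_equal(r$ri_se,
               r$ri * sqrt((50 / 550)^2 + (24 / 135)^2), tolerance = 1e-9)
  bad <- list(wt = mk_fit(-1))
  expect_error(compute_resistance_index(mut, bad, "resistance"), "positive")
})

test_that("noisy simulations recover e with small median relative error", {
  errs <- vapply(1:25, function(s) {
    tab <- sim_dose_response(b = 2, d = 100, e = 50,
                             doses = c(0, 10, 25, 50, 100, 200, 400),
                             n_reps = 3, noise_sd = 5, seed = s)
    abs(fit_log_logistic_4p(tab)$e - 50) / 50
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("resistance calls require beating both wild types", {
  set.seed(10)
  wt <- list(tak1 = rnorm(6, 50, 5), tak2 = rnorm(6, 80, 5))
  clear <- classify_line_response(rnorm(6, 150, 5), wt)
  expect_equal(clear$classification, "resistant")
  expect_true(all(clear$p_values < 0.05))
  half <- classify_line_response(rnorm(6, 80, 5), wt)
  expect_equal(half$classification, "not_resistant")
  tie <- classify_line_response(rep(5, 3), list(a = rep(5, 3), b = rep(5, 3)))
  expect_equal(unname(tie$p_values), c(1, 1))
  expect_equal(tie$classification, "not_resistant")
  expect_error(classify_line_response(c(1), wt), "2 replicates")
})

test_that("the cohort-level classifier matches the single-line interface", {
  set.seed(11)
  tab <- dplyr::bind_rows(
    tibble::tibble(line_id = "wt1", dose = 5, area = rnorm(5, 50, 5)),
    tibble::tibble(line_id = "wt2", dose = 5, area = rnorm(5, 60, 5)),
    tibble::tibble(line_id = "mut", dose = 5, area = rnorm(5, 150, 5)),
    tibble::tibble(line_id = "weak", dose = 5, area = rnorm(5, 62, 5))
  )
  out <- classify_cohort_response(tab, 5, c("wt1", "wt2"))
  expect_equal(out$classification[out$line_id == "mut"], "resistant")
  expect_equal(out$classification[out$line_id == "weak"], "not_resistant")
})
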