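#' Four-parameter log-logistic mean with fixed lower asymptote 0
#'
#' `f(x) = d / (1 + exp(b * (log(x) - log(e))))`, with `f(0)` defined as
#' `d` (the limit as dose tends to 0 for positive slope `b`). `e` is the
#' dose at half-maximal response, i.e. the IC50.
#'
#' @param dose Dose vector (0 allowed for vehicle controls).
#' @param b Slope.
#' @param d Upper asymptote (response of untreated tissue).
#' @param e Half-maximal dose; must be positive.
#' @return Mean response at each dose.
#' @export
ll4_mean <- function(dose, b, d, e) {
  out <- d / (1 + exp(b * (log(pmax(dose, .Machine$double.xmin)) - log(e))))
  out[dose == 0] <- d
  out
}

#' Simulate a replicated dose-response table
#'
#' Generates living-tissue areas from the fixed-lower-limit log-logistic
#' curve with additive Gaussian noise truncated to stay non-negative
#' (sampled from the conditional distribution on `[0, Inf)`, so live doses
#' never report exactly zero by chance). Mean responses that fall below the
#' detection floor `zero_floor` are recorded as 0 for every replicate --
#' the imaging pipeline reports 0 when no autofluorescing tissue remains --
#' which makes the simulated LD100 well defined.
#'
#' @param b,d,e Curve parameters (see [ll4_mean()]); `e > 0`.
#' @param doses Dose vector, all `>= 0`.
#' @param n_reps Replicates per dose.
#' @param noise_sd Additive noise standard deviation, in area units;
#'   must be non-negative.
#' @param seed Integer seed (its own labelled stream).
#' @param zero_floor Detection floor in area units (default 0.2).
#' @param line_id,compound,dose_units Metadata columns for the output.
#' @return A tibble: `line_id`, `compound`, `dose`, `dose_units`,
#'   `replicate`, `area`.
#' @examples
#' sim_dose_response(b = 2, d = 100, e = 50,
#'                   doses = c(0, 10, 25, 50, 100, 200, 400),
#'                   n_reps = 3, noise_sd = 5, seed = 1)
#' @export
sim_dose_response <- function(b, d, e, doses, n_reps, noise_sd, seed = 1L,
                              zero_floor = 0.2, line_id = "line",
                              compound = "compound", dose_units = "") {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (e <= 0) abort("`e` must be positive.")
  if (any(doses < 0)) abort("Doses must be non-negative.")
  with_stream(seed, "dose", {
    grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(n_reps))
    mu <- ll4_mean(grid$dose, b, d, e)
    dead <- mu < zero_floor
    area <- numeric(nrow(grid))
    if (noise_sd > 0) {
      p0 <- pnorm(0, mean = mu, sd = noise_sd)
      u <- runif(nrow(grid), min = p0, max = 1)
      area <- qnorm(u, mean = mu, sd = noise_sd)
    } else {
      area <- mu
    }
    area[dead] <- 0
    tibble(line_id = line_id, compound = compound, dose = grid$dose,
           dose_units = dose_units, replicate = grid$replicate,
           area = pmax(area, 0))
  })
}

# One assay = several lines sharing doses/reps/noise; params is a tibble
# with line_id, b, d, e.
sim_assay <- function(params, doses, n_reps, noise_sd, seed, compound,
                      dose_units, zero_floor = 0.2) {
  purrr::map_dfr(seq_len(nrow(params)), function(i) {
    sim_dose_response(
      b = params$b[i], d = params$d[i], e = params$e[i], doses = doses,
      n_reps = n_reps, noise_sd = noise_sd,
      seed = seed + 17L * i, zero_floor = zero_floor,
      line_id = params$line_id[i], compound = compound,
      dose_units = dose_units
    )
  })
}

#' Synthetic stand-ins for the screen's growth-assay workbook
#'
#' The quantitative growth data behind the screen's headline resistance
#' numbers live in a supplementary spreadsheet that is not redistributed
#' with this package. This generator produces *synthetic* replacement
#' tables: for each assay the generating log-logistic parameters are set to
#' the study's reported values (wild-type thaxtomin A IC50 of 56 and 135
#' nM with LD100 at 5 uM; mutant thaxtomin A resistance indices 9.1 and
#' 4.1 against the more resistant wild type; an H2O2 resistance index of
#' 0.64 against the more sensitive wild type; a paraquat LD100 of 3.3 uM
#' for the stronger mutant; isoxaben resistance indices 4.22 and 3.94;
#' a 2,4-D resistance index of 0.33; a UV exposure half-lethal time of
#' 110 s), with replicate noise on top. Refitting these tables therefore
#' checks that the package's fitting and metric conventions recover the
#' designed values -- it does not reproduce the original measurements.
#'
#' Lines `wt1` and `wt2` play the two wild-type accessions (`wt1` the more
#' sensitive on thaxtomin A); `mutA` and `mutB` play the two CRISPR
#' knockout mutants (`mutA` the more resistant).
#'
#' @param seed Integer seed.
#' @param noise_sd Replicate noise in area units (response scale d = 100).
#' @return Named list of growth tibbles: `thaxtomin_wt` (n = 18),
#'   `thaxtomin_mutants`, `h2o2`, `paraquat`, `isoxaben`, `twofour_d`
#'   (n = 3 each), and `uv_exposure` (dose = seconds of UV-B, n = 3).
#' @export
sim_benchmark_assays <- function(seed = 1L, noise_sd = 5) {
  s <- as.integer(seed)
  list(
    thaxtomin_wt = sim_assay(
      tibble(line_id = c("wt1", "wt2"), b = 2, d = 100, e = c(56, 135)),
      doses = c(0, 10, 30, 100, 300, 1000, 5000), n_reps = 18,
      noise_sd = noise_sd, seed = s + 1000L,
      compound = "thaxtomin A", dose_units = "nM"
    ),
    thaxtomin_mutants = sim_assay(
      tibble(line_id = c("wt1", "wt2", "mutA", "mutB"),
             b = c(2, 2, 2.2, 2.2), d = 100,
             e = c(56, 135, 9.1 * 135, 4.1 * 135)),
      doses = c(0, 10, 30, 100, 300, 1000, 5000, 25000), n_reps = 3,
      noise_sd = noise_sd, seed = s + 2000L,
      compound = "thaxtomin A", dose_units = "nM"
    ),
    h2o2 = sim_assay(
      tibble(line_id = c("wt1", "wt2", "mutA", "mutB"),
             b = 2.5, d = 100,
             e = c(3, 4, 0.64 * 3, 0.88 * 3)),
      doses = c(0, 0.5, 1, 2, 4, 8, 16, 32), n_reps = 3,
      noise_sd = noise_sd, seed = s + 3000L,
      compound = "H2O2", dose_units = "mM"
    ),
    paraquat = sim_assay(
      tibble(line_id = c("wt1", "wt2", "mutA", "mutB"),
             b = 4, d = 100, e = c(1.2, 1.4, 0.6, 0.85)),
      doses = c(0, 0.1, 0.33, 1, 2.2, 3.3, 5, 7.5, 10), n_reps = 3,
      noise_sd = noise_sd, seed = s + 4000L,
      compound = "paraquat", dose_units = "uM"
    ),
    isoxaben = sim_assay(
      tibble(line_id = c("wt1", "wt2", "mutA", "mutB"),
             b = 2.2, d = 100, e = c(0.8, 1.0, 4.22, 3.94)),
      doses = c(0, 0.2, 0.6, 2, 6, 20, 60), n_reps = 3,
      noise_sd = noise_sd, seed = s + 5000L,
      compound = "isoxaben", dose_units = "uM"
    ),
    twofour_d = sim_assay(
      tibble(line_id = c("wt1", "wt2", "mutA", "mutB"),
             b = 2, d = 100, e = c(30, 40, 0.33 * 40, 0.5 * 40)),
      doses = c(0, 1, 3, 10, 30, 100, 300), n_reps = 3,
      noise_sd = noise_sd, seed = s + 6000L,
      compound = "2,4-D", dose_units = "uM"
    ),
    uv_exposure = sim_assay(
      tibble(line_id = "spores", b = 2, d = 100, e = 110),
      doses = c(0, 15, 30, 60, 120, 240, 480), n_reps = 3,
      noise_sd = noise_sd, seed = s + 7000L,
      compound = "UV-B", dose_units = "s"
    )
  )
}
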