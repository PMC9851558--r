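#' Fit the fixed-lower-limit four-parameter log-logistic curve
#'
#' Least-squares fit of `f(x) = d / (1 + exp(b * (log x - log e)))` with the
#' lower asymptote fixed at 0 and `f(0) := d`, so vehicle controls (dose 0)
#' enter the fit at the upper asymptote. `e` is the IC50. Standard errors
#' come from the local curvature of the least-squares objective. Starting
#' values are `d0` = largest mean area, `e0` = tested dose whose mean area
#' is nearest `d0 / 2`, `b0 = 1`, with three perturbed restarts on
#' non-convergence; a fit that still fails is returned flagged, never
#' silently replaced.
#'
#' @param measurements Growth tibble with `dose` and `area` columns (one
#'   line, one compound).
#' @return An object of class `ll4_fit`: coefficients `b`, `d`, `e`,
#'   their standard errors, `converged`, `n_obs`, residual `sigma`, and the
#'   data used.
#' @examples
#' tab <- sim_dose_response(b = 2, d = 100, e = 50,
#'                          doses = c(0, 10, 25, 50, 100, 200, 400),
#'                          n_reps = 3, noise_sd = 2, seed = 1)
#' fit <- fit_log_logistic_4p(tab)
#' tidy(fit)
#' @export
fit_log_logistic_4p <- function(measurements) {
  df <- measurements %>%
    filter(!is.na(.data$dose), !is.na(.data$area))
  if (dplyr::n_distinct(df$dose) < 4L) {
    abort("Need at least 4 distinct doses to fit the log-logistic curve.")
  }
  if (all(df$area == 0)) {
    abort("No surviving tissue at any dose; nothing to fit.")
  }
  means <- df %>%
    group_by(.data$dose) %>%
    summarise(m = mean(.data$area), .groups = "drop")
  d0 <- max(means$m)
  pos <- means %>% filter(.data$dose > 0)
  e0 <- pos$dose[which.min(abs(pos$m - d0 / 2))]
  starts <- list(
    c(b = 1, d = d0, e = e0),
    c(b = 0.5, d = d0, e = e0 * 2),
    c(b = 2, d = d0 * 1.1, e = e0 / 2),
    c(b = 1, d = d0, e = stats::quantile(pos$dose, 0.5, names = FALSE))
  )
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        area ~ ll4_mean(dose, b, d, e),
        data = df, start = as.list(st),
        lower = c(b = -50, d = 1e-9, e = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(err) NULL
    )
    if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) break
  }
  if (is.null(fit)) {
    return(structure(
      list(b = NA_real_, d = NA_real_, e = NA_real_,
           se = c(b = NA_real_, d = NA_real_, e = NA_real_),
           converged = FALSE, n_obs = nrow(df), sigma = NA_real_,
           data = df),
      class = "ll4_fit"
    ))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(err) c(b = NA_real_, d = NA_real_,
                                         e = NA_real_))
  structure(
    list(b = unname(cf["b"]), d = unname(cf["d"]), e = unname(cf["e"]),
         se = se[c("b", "d", "e")],
         converged = isTRUE(fit$convInfo$isConv),
         n_obs = nrow(df),
         sigma = summary(fit)$sigma,
         data = df),
    class = "ll4_fit"
  )
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat("<ll4_fit> fixed-lower-limit log-logistic\n")
  cat(sprintf("  b = %.4g (se %.3g), d = %.4g (se %.3g), e = IC50 = %.4g (se %.3g)\n",
              x$b, x$se[["b"]], x$d, x$se[["d"]], x$e, x$se[["e"]]))
  cat(sprintf("  converged: %s, n = %d\n", x$converged, x$n_obs))
  invisible(x)
}

#' @rdname fit_log_logistic_4p
#' @param x An `ll4_fit` object.
#' @param ... Ignored.
#' @export
tidy.ll4_fit <- function(x, ...) {
  tibble(
    term = c("b", "d", "e"),
    estimate = c(x$b, x$d, x$e),
    std.error = unname(x$se)
  )
}

#' @rdname fit_log_logistic_4p
#' @export
glance.ll4_fit <- function(x, ...) {
  tibble(ic50 = x$e, ic50_se = unname(x$se[["e"]]), sigma = x$sigma,
         converged = x$converged, n_obs = x$n_obs)
}

#' @rdname fit_log_logistic_4p
#' @param object An `ll4_fit` object.
#' @export
autoplot.ll4_fit <- function(object, ...) {
  df <- object$data
  pos <- df$dose[df$dose > 0]
  grid <- tibble(dose = c(0, exp(seq(log(min(pos)), log(max(pos)),
                                     length.out = 200))))
  grid$area <- ll4_mean(grid$dose, object$b, object$d, object$e)
  floor_dose <- min(pos) / 3
  plot_df <- df %>% mutate(dose_plot = pmax(.data$dose, floor_dose))
  grid <- grid %>% mutate(dose_plot = pmax(.data$dose, floor_dose))
  ggplot2::ggplot(plot_df, ggplot2::aes(x = .data$dose_plot, y = .data$area)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$e, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (0 plotted at left edge, log scale)",
                  y = "living-tissue area",
                  title = sprintf("IC50 = %.3g", object$e)) +
    ggplot2::theme_minimal()
}

#' Fit dose-response curves for every line/compound in a table
#'
#' @param measurements Growth tibble with `line_id`, `compound`, `dose`,
#'   `area`.
#' @return A tibble with one row per (line, compound): the `ll4_fit` in a
#'   list-column `fit` plus unpacked `ic50`, `ic50_se`, `converged`.
#' @export
fit_dose_response_curves <- function(measurements) {
  measurements %>%
    group_by(.data$line_id, .data$compound) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(
      fit = purrr::map(.data$data, fit_log_logistic_4p),
      ic50 = purrr::map_dbl(.data$fit, "e"),
      ic50_se = purrr::map_dbl(.data$fit, ~ unname(.x$se[["e"]])),
      converged = purrr::map_lgl(.data$fit, "converged")
    ) %>%
    select(-"data")
}

#' Lowest fully lethal tested dose (LD100)
#'
#' The smallest tested dose at which every replicate's area is at or below
#' `zero_epsilon` (default exactly 0, matching an imaging pipeline that
#' reports 0 for no autofluorescence). If no tested dose kills all
#' replicates the LD100 is right-censored at the maximum tested dose.
#'
#' @param measurements Growth tibble with `dose` and `area` (one line, one
#'   compound).
#' @param zero_epsilon Area at or below which a replicate counts as dead.
#' @return One-row tibble: `ld100` (NA when censored), `censored`,
#'   `max_dose`, and a display `label` such as `"5000"` or `"> 400"`.
#' @export
estimate_ld100 <- function(measurements, zero_epsilon = 0) {
  by_dose <- measurements %>%
    group_by(.data$dose) %>%
    summarise(all_dead = all(.data$area <= zero_epsilon), .groups = "drop") %>%
    arrange(.data$dose)
  dead <- by_dose$dose[by_dose$all_dead]
  max_dose <- max(by_dose$dose)
  if (length(dead) == 0L) {
    tibble(ld100 = NA_real_, censored = TRUE, max_dose = max_dose,
           label = paste(">", format(max_dose)))
  } else {
    tibble(ld100 = min(dead), censored = FALSE, max_dose = max_dose,
           label = format(min(dead)))
  }
}

#' Resistance index against a conservatively chosen wild-type reference
#'
#' `RI = IC50_mutant / IC50_reference`. For a resistance claim the
#' reference is the wild type with the *largest* IC50; for a sensitivity
#' claim, the smallest -- in both cases the choice that makes the claim
#' hardest to reach. The RI standard error is first-order (delta-method)
#' propagation of the two IC50 standard errors:
#' `se(RI) = RI * sqrt((se_m / e_m)^2 + (se_r / e_r)^2)`.
#'
#' @param fit_mutant `ll4_fit` for the mutant line.
#' @param wild_type_fits Named list of `ll4_fit` objects, one per wild-type
#'   line.
#' @param direction `"resistance"` or `"sensitivity"`.
#' @return One-row tibble: `ri`, `ri_se`, `ic50`, `ic50_se`,
#'   `reference_line`, `reference_ic50`, `direction`.
#' @export
compute_resistance_index <- function(fit_mutant, wild_type_fits,
                                     direction = c("resistance",
                                                   "sensitivity")) {
  direction <- match.arg(direction)
  if (length(wild_type_fits) == 0L) {
    abort("At least one wild-type fit is required.")
  }
  if (is.null(names(wild_type_fits)) || any(names(wild_type_fits) == "")) {
    names(wild_type_fits) <- paste0("wt", seq_along(wild_type_fits))
  }
  ok <- vapply(wild_type_fits,
               function(f) isTRUE(f$converged) && is.finite(f$e) && f$e > 0,
               logical(1))
  if (!any(ok)) {
    abort("No converged wild-type fit with positive IC50 available.")
  }
  e_wt <- vapply(wild_type_fits, function(f) f$e, numeric(1))
  e_wt[!ok] <- NA_real_
  ref <- if (direction == "resistance") which.max(e_wt) else which.min(e_wt)
  ref_fit <- wild_type_fits[[ref]]
  if (!isTRUE(fit_mutant$converged)) {
    abort("Mutant fit did not converge; refusing to compute an RI from it.")
  }
  ri <- fit_mutant$e / ref_fit$e
  ri_se <- ri * sqrt((fit_mutant$se[["e"]] / fit_mutant$e)^2 +
                     (ref_fit$se[["e"]] / ref_fit$e)^2)
  tibble(
    ri = ri, ri_se = ri_se,
    ic50 = fit_mutant$e, ic50_se = unname(fit_mutant$se[["e"]]),
    reference_line = names(wild_type_fits)[ref],
    reference_ic50 = ref_fit$e,
    direction = direction
  )
}

pooled_t_p <- function(x, y, welch = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  t.test(x, y, var.equal = !welch)$p.value
}

#' Classify a line as resistant from areas at a single dose
#'
#' A line is called resistant when its living-tissue area at the screening
#' dose is significantly larger than *each* wild-type line: a two-sided
#' two-sample Student's t-test (pooled variance; Welch available via
#' `welch = TRUE`) against every wild type must give `p < alpha` *and* the
#' mutant mean must exceed every wild-type mean. Groups with zero variance
#' and identical means get p = 1 by convention.
#'
#' @param line_areas Numeric vector of the focal line's replicate areas.
#' @param wt_areas_by_line Named list of numeric vectors, one per wild-type
#'   line (at least 2 replicates each).
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch (unpooled) test instead.
#' @return A list: `classification` (`"resistant"` / `"not_resistant"`),
#'   `p_values` (named, one per wild type), `mean_area`, `wt_means`.
#' @export
classify_line_response <- function(line_areas, wt_areas_by_line,
                                   alpha = 0.05, welch = FALSE) {
  if (length(line_areas) < 2L ||
      any(vapply(wt_areas_by_line, length, integer(1)) < 2L)) {
    abort("Every group needs at least 2 replicates.")
  }
  p <- vapply(wt_areas_by_line,
              function(w) pooled_t_p(line_areas, w, welch = welch),
              numeric(1))
  wt_means <- vapply(wt_areas_by_line, mean, numeric(1))
  larger <- mean(line_areas) > wt_means
  resistant <- all(p < alpha) && all(larger)
  list(
    classification = if (resistant) "resistant" else "not_resistant",
    p_values = p,
    mean_area = mean(line_areas),
    wt_means = wt_means
  )
}

#' Classify every non-wild-type line in a growth table
#'
#' Tidy wrapper around [classify_line_response()]: at one screening dose,
#' tests every line that is not a wild type against all wild-type lines.
#'
#' @param measurements Growth tibble (`line_id`, `dose`, `area`).
#' @param screening_dose The dose at which to compare areas.
#' @param wt_lines Character vector of wild-type line ids.
#' @param alpha,welch Passed to [classify_line_response()].
#' @return Tibble: `line_id`, `classification`, `max_p` (largest of the
#'   per-wild-type p-values), `mean_area`.
#' @export
classify_cohort_response <- function(measurements, screening_dose, wt_lines,
                                     alpha = 0.05, welch = FALSE) {
  at_dose <- measurements %>% filter(.data$dose == screening_dose)
  wt_areas <- lapply(setNames(wt_lines, wt_lines), function(w) {
    at_dose$area[at_dose$line_id == w]
  })
  focal <- setdiff(unique(at_dose$line_id), wt_lines)
  purrr::map_dfr(focal, function(lid) {
    res <- classify_line_response(at_dose$area[at_dose$line_id == lid],
                                  wt_areas, alpha = alpha, welch = welch)
    tibble(line_id = lid, classification = res$classification,
           max_p = max(res$p_values), mean_area = res$mean_area)
  })
}
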