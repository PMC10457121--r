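#' Ordinary least squares with slope test and Pearson correlation
#'
#' The comparison machinery used throughout the package: a simple
#' regression `y = a + b x` with the two-sided t-test of the slope on
#' `n - 2` degrees of freedom and the Pearson correlation between the two
#' variables. With two variables the slope p-value and the correlation
#' p-value coincide, so only the slope p is reported. For `n = 2` the line
#' interpolates and the p-value is undefined (`NA`).
#'
#' @param data Data frame holding the two variables.
#' @param x,y Column names (tidy-eval); `x` is the regressor.
#' @return A one-row tibble with `slope`, `intercept`, `pearson_r`,
#'   `slope_p` and `n`.
#' @examples
#' ols_with_test(tibble::tibble(a = 0:2, b = c(1, 3, 5)), a, b)
#' @export
ols_with_test <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) abort("x and y differ in length.")
  n <- length(xv)
  if (n < 2) abort("Regression needs at least 2 points.")
  if (diff(range(xv)) == 0) abort("Regressor x is constant.")
  fit <- lm(yv ~ xv)
  slope <- coef(fit)[["xv"]]
  intercept <- coef(fit)[[1]]
  r <- cor(xv, yv)
  if (n > 2) {
    sxx <- sum((xv - mean(xv))^2)
    se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
    p <- if (se > 0) {
      2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
    } else 0  # exact fit: slope infinitely many sds from zero
  } else {
    p <- NA_real_
  }
  tibble(slope = slope, intercept = intercept, pearson_r = r,
         slope_p = p, n = n)
}

#' Bonferroni adjustment helper
#'
#' Raw p-values are reported by default; this wrapper adjusts a set of
#' them for multiple comparisons.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (Bonferroni).
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Corpus-callosum effective-radius table
#'
#' Per-ROI mean effective axon radii (um) for eleven midsagittal
#' corpus-callosum ROIs: the histological reference values and the radii
#' predicted from the intra-axonal T2 and T1 relaxation times. Shipped as
#' a plain CSV fixture; radii are printed to three decimals.
#'
#' @return A tibble with columns `roi_id`, `hist_reff_um`, `t2_pred_um`,
#'   `t1_pred_um`.
#' @examples
#' cc_radius_table()
#' @export
cc_radius_table <- function() {
  path <- system.file("extdata", "cc_effective_radii.csv",
                      package = "axonrelax", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    roi_id = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Reproduce the radius comparison regressions
#'
#' Runs the six regressions comparing predicted and histological
#' effective radii over the packaged corpus-callosum table: T2- and
#' T1-predicted radii against histology over all eleven ROIs, the
#' T1-predicted against T2-predicted radii, and the T2/T1 regressions on
#' the seven-ROI subset that excludes the four calibration ROIs
#' (ROI2, ROI5, ROI8, ROI10). In every comparison against histology the
#' predicted radius is the response and the histological radius the
#' regressor; the T1-vs-T2 comparison regresses the T1 prediction on the
#' T2 prediction. Also reports the min/max of each predicted column.
#'
#' @param table Radius table as from [cc_radius_table()]; defaults to the
#'   packaged fixture.
#' @return A list of class `radius_comparison` with `regressions` (tibble,
#'   one row per comparison) and `ranges` (tibble of per-column min/max).
#' @examples
#' reproduce_table1()
#' @export
reproduce_table1 <- function(table = cc_radius_table()) {
  calib_rois <- c("ROI2", "ROI5", "ROI8", "ROI10")
  sub <- dplyr::filter(table, !.data$roi_id %in% calib_rois)

  runs <- list(
    t2_vs_hist_11roi = ols_with_test(table, hist_reff_um, t2_pred_um),
    t1_vs_hist_11roi = ols_with_test(table, hist_reff_um, t1_pred_um),
    t1_vs_t2_11roi   = ols_with_test(table, t2_pred_um, t1_pred_um),
    t2_vs_hist_7roi  = ols_with_test(sub, hist_reff_um, t2_pred_um),
    t1_vs_hist_7roi  = ols_with_test(sub, hist_reff_um, t1_pred_um)
  )
  regressions <- dplyr::bind_rows(runs, .id = "comparison")

  ranges <- table |>
    tidyr::pivot_longer(c("t2_pred_um", "t1_pred_um"),
                        names_to = "column", values_to = "radius_um") |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(min_um = min(.data$radius_um),
                     max_um = max(.data$radius_um), .groups = "drop")

  structure(list(regressions = regressions, ranges = ranges,
                 n_subset = nrow(sub)),
            class = "radius_comparison")
}

#' @export
print.radius_comparison <- function(x, ...) {
  cat("Radius comparison regressions (predicted ~ reference):\n")
  print(as.data.frame(dplyr::mutate(
    x$regressions,
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))
  )), row.names = FALSE)
  cat("\nPredicted radius ranges (um):\n")
  print(as.data.frame(dplyr::mutate(
    x$ranges, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))
  )), row.names = FALSE)
  invisible(x)
}

#' @export
autoplot.radius_comparison <- function(object, table = cc_radius_table(),
                                       ...) {
  long <- table |>
    tidyr::pivot_longer(c("t2_pred_um", "t1_pred_um"),
                        names_to = "channel", values_to = "pred_um") |>
    dplyr::mutate(channel = ifelse(.data$channel == "t2_pred_um",
                                   "T2-predicted", "T1-predicted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hist_reff_um,
                                     y = .data$pred_um)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "black") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "Histological effective radius (um)",
                  y = "Predicted effective radius (um)") +
    ggplot2::theme_minimal()
}
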