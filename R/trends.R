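#' Collect a per-structure scalar metric into a temperature series
#'
#' Evaluates one metric on every structure of a temperature series:
#' `waters` (ordered-water count, [water_count()]), `cell_volume`
#' ([unit_cell_volume()]; every model must carry a cell) or
#' `protein_volume` ([protein_volume()]).
#'
#' @param models list of `structure_model`.
#' @param metric `"waters"`, `"cell_volume"`, or `"protein_volume"`.
#' @param ... passed on to the metric function.
#' @return an object of class `thermal_series`: data.frame with columns
#'   `temperature` (kelvin) and `value`, sorted by temperature, with
#'   attributes `metric` and `units`.
#' @export
collect_series <- function(models, metric = c("waters", "cell_volume",
                                              "protein_volume"), ...) {
  metric <- match.arg(metric)
  stopifnot(length(models) >= 1)
  vals <- vapply(seq_along(models), function(k) {
    m <- models[[k]]
    switch(metric,
      waters = as.numeric(water_count(m)),
      cell_volume = {
        if (is.null(m$cell)) {
          stop(sprintf("structure %d ('%s', %g K) has no unit cell",
                       k, m$label, m$temperature))
        }
        unit_cell_volume(m$cell)
      },
      protein_volume = protein_volume(m, ...))
  }, 0)
  out <- data.frame(temperature = vapply(models, `[[`, 0, "temperature"),
                    value = vals)
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "units") <- switch(metric, waters = "count",
                               cell_volume = "A^3", protein_volume = "A^3")
  class(out) <- c("thermal_series", "data.frame")
  out
}

#' Build a thermal series from raw (temperature, value) data
#'
#' @param temperature temperatures in kelvin.
#' @param value metric values.
#' @param metric,units metadata strings.
#' @return a `thermal_series`; see [collect_series()].
#' @export
thermal_series <- function(temperature, value, metric = "value", units = "") {
  stopifnot(length(temperature) == length(value))
  ord <- order(temperature)
  out <- data.frame(temperature = temperature[ord], value = value[ord])
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  class(out) <- c("thermal_series", "data.frame")
  out
}

#' Linear thermal-expansion fit
#'
#' Ordinary least squares of value on temperature. Besides the absolute
#' slope, two derived quantities are reported in the units used for thermal
#' expansion of protein crystals: the relative slope
#' `100 * slope * 100 / fitted(Tmin)` in percent per 100 K, referenced to
#' the fitted value at the series' lowest temperature, and the endpoint
#' percent change `100 * (v(Tmax) - v(Tmin)) / v(Tmin)` computed from the
#' raw endpoint values (the natural reading of "x% increase from Tmin to
#' Tmax").
#'
#' @param series a `thermal_series` with at least 2 distinct temperatures.
#' @return object of class `expansion_fit`: list with `slope` (units/K),
#'   `intercept`, `fitted_at_tmin`, `relative_slope_pct_per_100K`,
#'   `endpoint_pct_change`, `residual_sd`, and `n`.
#' @export
expansion_fit <- function(series) {
  stopifnot(inherits(series, "thermal_series"))
  if (nrow(series) < 2) stop("need at least 2 points")
  if (length(unique(series$temperature)) < 2) {
    stop("all temperatures equal: singular design")
  }
  fit <- stats::lm(value ~ temperature, data = series)
  co <- stats::coef(fit)
  tmin <- min(series$temperature); tmax <- max(series$temperature)
  f_tmin <- unname(co[1] + co[2] * tmin)
  v_tmin <- series$value[which.min(series$temperature)]
  v_tmax <- series$value[which.max(series$temperature)]
  dof <- nrow(series) - 2
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    fitted_at_tmin = f_tmin,
    relative_slope_pct_per_100K = 100 * unname(co[2]) * 100 / f_tmin,
    endpoint_pct_change = 100 * (v_tmax - v_tmin) / v_tmin,
    residual_sd = if (dof > 0) sqrt(sum(stats::resid(fit)^2) / dof) else 0,
    n = nrow(series)), class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf(paste0("expansion fit (n=%d): slope %.4g per K, ",
                     "%.2f%%/100 K, endpoints %+.2f%%\n"),
              x$n, x$slope, x$relative_slope_pct_per_100K,
              x$endpoint_pct_change))
  invisible(x)
}

#' Two-segment continuous changepoint fit
#'
#' Continuous piecewise-linear least squares with one breakpoint, fitted by
#' exhaustive scan of candidate breakpoints on a 1 K grid between the 2nd
#' and (n-1)th observed temperatures; at each candidate the model
#' `value ~ T + max(T - bp, 0)` is solved by OLS, and the breakpoint with
#' the smallest total squared error wins (ties go to the lowest
#' breakpoint). Used to locate, e.g., the drop in ordered-water count at
#' the protein dynamical transition near 240 K. When the best two-segment
#' fit improves on a single line by less than a relative tolerance the fit
#' is flagged as having no detectable changepoint.
#'
#' @param series a `thermal_series` with at least 5 points.
#' @param tol relative SSE improvement below which `no_changepoint` is set
#'   (default 1e-6; compared as `(SSE_line - SSE_best) <= tol * TSS` where
#'   TSS is the total sum of squares about the mean, a scale that stays
#'   meaningful when a single line already fits exactly; absolute `tol` is
#'   used for a constant series).
#' @return object of class `changepoint_fit`: list with `breakpoint`
#'   (kelvin), `slope_left`, `slope_right`, `intercept`, `sse`,
#'   `sse_single_line`, `no_changepoint` (logical), and `n`.
#' @export
changepoint_fit <- function(series, tol = 1e-6) {
  stopifnot(inherits(series, "thermal_series"))
  n <- nrow(series)
  if (n < 5) stop("need at least 5 points for a changepoint fit")
  Tv <- series$temperature; v <- series$value
  line <- stats::lm(v ~ Tv)
  sse_line <- sum(stats::resid(line)^2)
  cand <- seq(ceiling(Tv[2]), floor(Tv[n - 1]), by = 1)
  if (!length(cand)) cand <- mean(Tv[c(2, n - 1)])
  best <- NULL
  for (bp in cand) {
    h <- pmax(Tv - bp, 0)
    fit <- stats::lm(v ~ Tv + h)
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      co <- stats::coef(fit)
      co[is.na(co)] <- 0
      best <- list(breakpoint = bp, slope_left = unname(co[2]),
                   slope_right = unname(co[2] + co[3]),
                   intercept = unname(co[1]), sse = sse)
    }
  }
  improve <- sse_line - best$sse
  tss <- sum((v - mean(v))^2)
  best$sse_single_line <- sse_line
  best$no_changepoint <- if (tss > 0) improve <= tol * tss
                         else improve <= tol
  best$n <- n
  class(best) <- "changepoint_fit"
  best
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf("changepoint fit (n=%d): breakpoint %g K, slopes %.4g / %.4g%s\n",
              x$n, x$breakpoint, x$slope_left, x$slope_right,
              if (x$no_changepoint) "  [no detectable changepoint]" else ""))
  invisible(x)
}

#' Write a thermal series or table as TSV
#'
#' Tab separators, '.' decimal point, header row.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}
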