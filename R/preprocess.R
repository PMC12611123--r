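#' Fill missing cells by linear interpolation in time
#'
#' Replaces `NA` cells of every variable with values linearly interpolated
#' against `month_index`; leading and trailing gaps take the nearest
#' observed value.
#'
#' @param series A `site_series`.
#' @return The gap-free series.
#' @export
fill_missing <- function(series) {
  vars <- c(PANEL_VARS, "survival_pct")
  for (v in vars) {
    x <- series[[v]]
    obs <- which(!is.na(x))
    if (length(obs) == length(x)) next
    if (length(obs) < 2)
      stop(sprintf("variable '%s' has fewer than 2 observed values at site %s",
                   v, series$site_id[1]))
    series[[v]] <- approx(series$month_index[obs], x[obs],
                          xout = series$month_index, rule = 2)$y
  }
  series
}

#' Mask and re-interpolate outlying cells
#'
#' Flags cells whose absolute z-score within the site-variable series
#' exceeds `z_thresh`, masks them, and re-fills them with
#' [fill_missing()].  Zero-variance variables are skipped with a warning.
#'
#' @param series A gap-free `site_series`.
#' @param z_thresh Robust z threshold (default 3.5).
#' @return The cleaned series, with attribute `removed`: a data frame of
#'   (variable, month_index, value) for each replaced cell.
#' @export
remove_outliers <- function(series, z_thresh = 3.5) {
  vars <- c(PANEL_VARS, "survival_pct")
  removed <- list()
  for (v in vars) {
    x <- series[[v]]
    if (anyNA(x)) stop("remove_outliers requires a gap-free series")
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("variable '%s' has zero variance; outlier scan skipped", v))
      next
    }
    z <- abs(x - mean(x)) / s
    bad <- which(z > z_thresh)
    if (length(bad)) {
      removed[[v]] <- data.frame(variable = v,
                                 month_index = series$month_index[bad],
                                 value = x[bad])
      series[[v]][bad] <- NA_real_
    }
  }
  out <- fill_missing(series)
  attr(out, "removed") <- if (length(removed))
    do.call(rbind, unname(removed))
  else
    data.frame(variable = character(), month_index = integer(),
               value = numeric())
  out
}

#' Calendar-month climatology of the meteorological variables
#'
#' Means of temperature and precipitation per calendar month, computed from
#' a set of rows (normally the training period only, to avoid temporal
#' leakage).
#'
#' @param panel A `vegr_panel`.
#' @param max_month_index Last 0-based month index to include (inclusive);
#'   `Inf` uses every row.
#' @return A data frame with columns `calendar_month`, `temp_c`,
#'   `precip_mm`.
#' @export
climatology <- function(panel, max_month_index = Inf) {
  rows <- do.call(rbind, lapply(panel, function(s)
    s[s$month_index <= max_month_index,
      c("month_index", "temp_c", "precip_mm")]))
  cal <- rows$month_index %% 12 + 1
  data.frame(
    calendar_month = 1:12,
    temp_c = vapply(1:12, function(m) mean(rows$temp_c[cal == m]), 0),
    precip_mm = vapply(1:12, function(m) mean(rows$precip_mm[cal == m]), 0)
  )
}

#' Subtract (or restore) the seasonal cycle of temperature and precipitation
#'
#' Removes each calendar month's climatological mean from `temp_c` and
#' `precip_mm`, leaving the other variables untouched.  The operation is
#' exactly invertible given the same climatology.
#'
#' @param series A `site_series`.
#' @param clim A climatology from [climatology()]; must cover all 12
#'   calendar months.
#' @param invert If `TRUE`, adds the climatology back instead.
#' @return The adjusted series.
#' @export
seasonal_adjust <- function(series, clim, invert = FALSE) {
  if (!all(1:12 %in% clim$calendar_month))
    stop("climatology is missing calendar months")
  cal <- series$month_index %% 12 + 1
  sgn <- if (invert) 1 else -1
  for (v in c("temp_c", "precip_mm")) {
    series[[v]] <- series[[v]] +
      sgn * clim[[v]][match(cal, clim$calendar_month)]
  }
  series
}

#' Align a coarser-cadence series to a monthly cadence
#'
#' Linearly interpolates values observed every `k` months onto a monthly
#' grid (observed months preserved exactly; months beyond the last
#' observation held at the last observed value), mirroring the temporal
#' alignment applied to satellite products before modelling.
#'
#' @param values Observed values at months `0, k, 2k, ...`.
#' @param cadence Observation cadence `k` in months (integer >= 1).
#' @param n_months Length of the monthly output grid.
#' @return Numeric vector of length `n_months`.
#' @export
align_frequency <- function(values, cadence, n_months) {
  if (length(values) < 2) stop("align_frequency needs at least 2 observations")
  if (cadence < 1 || cadence != round(cadence))
    stop("cadence must be a positive integer number of months")
  obs_months <- (seq_along(values) - 1) * cadence
  approx(obs_months, values, xout = seq_len(n_months) - 1, rule = 2)$y
}

#' Run the per-site cleaning chain over a panel
#'
#' [fill_missing()] then [remove_outliers()] for every site.  The chain is
#' idempotent: applying it twice equals applying it once.
#'
#' @param panel A `vegr_panel`.
#' @param z_thresh Outlier threshold passed to [remove_outliers()].
#' @return The cleaned panel.
#' @export
preprocess_panel <- function(panel, z_thresh = 3.5) {
  msgs <- character()
  cleaned <- withCallingHandlers(
    lapply(panel, function(s) remove_outliers(fill_missing(s), z_thresh)),
    warning = function(w) {
      msgs <<- union(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (m in msgs) warning(m, call. = FALSE)  # each distinct message once
  structure(cleaned, class = "vegr_panel", config = attr(panel, "config"))
}
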