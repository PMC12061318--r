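# Daily environmental parameters (EPs) from raw weather.
#
# Nine EPs are tracked throughout the package, in this fixed order:
#   DL  day length (h)
#   GDD growing degree days (thermal time, degree-days)
#   PRE precipitation (mm)
#   PAR photosynthetically active radiation (MJ m-2 d-1)
#   RH  air relative humidity (%)
#   PTT photothermal time, GDD * DL
#   PTR photothermal ratio, GDD / DL
#   DTR diurnal temperature range, Tmax - Tmin (raw, uncapped)
#   PTS photothermal sensitivity (formula configurable, see pts_value)

#' Names of the nine environmental parameters
#'
#' @return Character vector of the nine EP names in canonical order.
#' @export
ep_names <- function() {
  c("DL", "GDD", "PRE", "PAR", "RH", "PTT", "PTR", "DTR", "PTS")
}

#' Daily growing degree days
#'
#' Thermal time accumulated in one day: `(Tmax' + Tmin')/2 - tbase`, where
#' `Tmax'` is `tmax` capped above at `tcap` and `Tmin'` is `tmin` floored at
#' `tbase`. With the Fahrenheit defaults (base 50, cap 86) this is the
#' standard maize GDD; `units = "C"` switches to base 10 / cap 30 for
#' Celsius inputs.
#'
#' @param tmax,tmin Daily maximum and minimum temperature (same units as
#'   `tbase`/`tcap`). Vectorised.
#' @param tbase Base temperature below which no thermal time accrues.
#' @param tcap Upper cap applied to `tmax`.
#' @param units `"F"` (default, base 50/cap 86) or `"C"` (base 10/cap 30);
#'   ignored when `tbase`/`tcap` are given explicitly.
#' @return Numeric vector of daily GDD, always `>= 0`.
#' @examples
#' compute_gdd(86, 50)   # 18
#' compute_gdd(95, 60)   # 23: tmax capped at 86
#' compute_gdd(50, 40)   # 0: tmin floored at the base
#' @export
compute_gdd <- function(tmax, tmin, tbase = NULL, tcap = NULL,
                        units = c("F", "C")) {
  units <- match.arg(units)
  if (is.null(tbase)) tbase <- if (units == "F") 50 else 10
  if (is.null(tcap)) tcap <- if (units == "F") 86 else 30
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop("invalid weather record: tmax < tmin")
  }
  tmax2 <- pmin(tmax, tcap)
  tmin2 <- pmax(tmin, tbase)
  pmax((tmax2 + tmin2) / 2 - tbase, 0)
}

#' Photothermal sensitivity for one day
#'
#' The PTS formula is typographically ambiguous in the agronomic literature
#' (superscripts vs. halving); both readings are provided and the choice is
#' a configuration knob everywhere PTS is computed.
#'
#' @param tmax,tmin Raw (uncapped) daily temperatures.
#' @param day_length Day length in hours.
#' @param formula `"squares"` (default): `(tmax^2 - tmin^2) * day_length^2`;
#'   `"halves"`: `(tmax/2 - tmin/2) * day_length/2`; or a function
#'   `f(tmax, tmin, day_length)`.
#' @return Numeric vector of daily PTS.
#' @export
pts_value <- function(tmax, tmin, day_length, formula = "squares") {
  if (is.function(formula)) return(formula(tmax, tmin, day_length))
  switch(match.arg(formula, c("squares", "halves")),
    squares = (tmax^2 - tmin^2) * day_length^2,
    halves = (tmax / 2 - tmin / 2) * day_length / 2
  )
}

#' Derived daily environmental parameters
#'
#' Computes DTR, PTS, PTR and PTT from raw temperatures, day length and the
#' day's GDD. DTR and PTS use the raw (uncapped) temperatures; PTR/PTT use
#' the capped-and-floored GDD.
#'
#' @param tmax,tmin Raw daily temperatures (vectorised).
#' @param day_length Day length (h).
#' @param gdd Daily GDD as returned by [compute_gdd()].
#' @param pts_formula Passed to [pts_value()].
#' @return A data frame with columns `DTR`, `PTS`, `PTR`, `PTT`. Where
#'   `day_length == 0` PTR is undefined (returned as `NaN` with a warning);
#'   PTT is 0 there.
#' @export
compute_derived_eps <- function(tmax, tmin, day_length, gdd,
                                pts_formula = "squares") {
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop("invalid weather record: tmax < tmin")
  }
  ptr <- ifelse(day_length > 0, gdd / day_length, NaN)
  if (any(day_length == 0, na.rm = TRUE)) {
    warning("PTR undefined where day_length = 0")
  }
  data.frame(
    DTR = tmax - tmin,
    PTS = pts_value(tmax, tmin, day_length, pts_formula),
    PTR = ptr,
    PTT = gdd * day_length
  )
}

#' Build the nine daily EP series for one environment
#'
#' Takes one environment's daily weather table from sowing to season end and
#' returns the nine EP series plus cumulative GDD. Days before `sowing_date`
#' are dropped; the remaining days must form a gap-free, duplicate-free
#' daily sequence. A missing value inside a single weather column is
#' linearly interpolated (with a warning); whole missing days are an error.
#'
#' @param weather Data frame with columns `env_id`, `date` (Date or
#'   ISO-8601 string), `tmax`, `tmin`, `day_length`, `rh`, `pre`, `par`.
#'   Temperatures in the units implied by `units`.
#' @param sowing_date Sowing date (first day of thermal-time accumulation).
#' @param tbase,tcap,units Passed to [compute_gdd()].
#' @param pts_formula Passed to [pts_value()].
#' @return An object of class `ep_series`: a list with `env_id`, `dates`,
#'   `eps` (days x 9 matrix, columns [ep_names()]), and `cumulative_gdd`.
#' @export
build_ep_series <- function(weather, sowing_date = NULL, tbase = NULL,
                            tcap = NULL, units = c("F", "C"),
                            pts_formula = "squares") {
  units <- match.arg(units)
  need <- c("env_id", "date", "tmax", "tmin", "day_length", "rh", "pre", "par")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather table lacks columns: ",
                         paste(miss, collapse = ", "))
  env_id <- unique(as.character(weather$env_id))
  if (length(env_id) != 1) {
    stop("build_ep_series() expects a single environment; got: ",
         paste(env_id, collapse = ", "))
  }
  dates <- as.Date(weather$date)
  ord <- order(dates)
  weather <- weather[ord, , drop = FALSE]
  dates <- dates[ord]
  if (anyDuplicated(dates)) {
    stop("duplicated weather dates: ",
         paste(unique(dates[duplicated(dates)]), collapse = ", "))
  }
  if (is.null(sowing_date)) sowing_date <- dates[1]
  sowing_date <- as.Date(sowing_date)
  keep <- dates >= sowing_date
  weather <- weather[keep, , drop = FALSE]
  dates <- dates[keep]
  if (!length(dates)) stop("no weather on or after the sowing date")
  gaps <- seq(dates[1], dates[length(dates)], by = "day")
  absent <- setdiff(as.character(gaps), as.character(dates))
  if (length(absent)) {
    stop("missing weather days: ", paste(absent, collapse = ", "))
  }

  num_cols <- c("tmax", "tmin", "day_length", "rh", "pre", "par")
  for (cl in num_cols) {
    v <- as.numeric(weather[[cl]])
    if (anyNA(v)) {
      if (all(is.na(v))) stop("weather column entirely missing: ", cl)
      warning(sprintf("interpolating %d missing '%s' value(s) in %s",
                      sum(is.na(v)), cl, env_id))
      v <- stats::approx(seq_along(v), v, xout = seq_along(v), rule = 2)$y
    }
    weather[[cl]] <- v
  }
  if (any(weather$tmax < weather$tmin)) {
    stop("invalid weather record: tmax < tmin")
  }

  gdd <- compute_gdd(weather$tmax, weather$tmin, tbase, tcap, units)
  der <- compute_derived_eps(weather$tmax, weather$tmin, weather$day_length,
                             gdd, pts_formula)
  eps <- cbind(
    DL = weather$day_length, GDD = gdd, PRE = weather$pre,
    PAR = weather$par, RH = weather$rh, PTT = der$PTT, PTR = der$PTR,
    DTR = der$DTR, PTS = der$PTS
  )
  rownames(eps) <- as.character(dates)
  structure(
    list(env_id = env_id, dates = dates, eps = eps,
         cumulative_gdd = cumsum(gdd)),
    class = "ep_series"
  )
}

#' @export
print.ep_series <- function(x, ...) {
  cat(sprintf("<ep_series> env %s: %d days, cumulative GDD %.1f\n",
              x$env_id, length(x$dates),
              x$cumulative_gdd[length(x$cumulative_gdd)]))
  invisible(x)
}

#' Build EP series for every environment in a weather table
#'
#' @param weather Combined daily weather table for several environments
#'   (same columns as [build_ep_series()]).
#' @param sowing_dates Optional named vector/list of sowing dates per
#'   environment; default is each environment's first weather day.
#' @param ... Passed to [build_ep_series()].
#' @return Named list of `ep_series`, one per environment.
#' @export
build_ep_series_all <- function(weather, sowing_dates = NULL, ...) {
  envs <- unique(as.character(weather$env_id))
  out <- lapply(envs, function(e) {
    sd <- if (!is.null(sowing_dates)) sowing_dates[[e]] else NULL
    build_ep_series(weather[weather$env_id == e, , drop = FALSE],
                    sowing_date = sd, ...)
  })
  names(out) <- envs
  out
}

#' Long-format table of daily EP values
#'
#' @param series An `ep_series` or list of them.
#' @return Data frame `env_id`, `date`, `ep`, `value`, `cumulative_gdd`.
#' @export
ep_series_table <- function(series) {
  if (inherits(series, "ep_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s) {
    data.frame(
      env_id = s$env_id,
      date = rep(s$dates, times = ncol(s$eps)),
      ep = rep(colnames(s$eps), each = nrow(s$eps)),
      value = as.vector(s$eps),
      cumulative_gdd = rep(s$cumulative_gdd, times = ncol(s$eps)),
      row.names = NULL
    )
  }))
}
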