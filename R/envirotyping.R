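# Stage segmentation along cumulative thermal time, reduction of daily EPs
# to stage-window means (the RD_EP profile), sliding-window critical-window
# search, and environment clustering.

#' Stage-threshold tables
#'
#' A stage-threshold table maps cumulative GDD (from sowing) to ordered
#' developmental stages: a day belongs to the first stage whose upper bound
#' exceeds its cumulative GDD. The default maize table has 36 stages
#' (V0..V29, R1..R6) spanning 100 to 2700 degree-days Fahrenheit: emergence
#' near 100, vegetative leaf stages every ~62 degree-days, and six longer
#' reproductive stages to physiological maturity. The bounds are
#' configuration, not biology shipped in stone: real pipelines should
#' supply a calibrated table for their hybrids.
#'
#' @param n_stages 36 (maize default) or any count when `gdd_bounds` given.
#' @param stage_labels Optional labels (length `n_stages`).
#' @param gdd_bounds Optional strictly increasing upper bounds.
#' @return Object of class `stage_table`: data frame `stage`, `gdd_upper`.
#' @export
stage_table <- function(n_stages = 36, stage_labels = NULL,
                        gdd_bounds = NULL) {
  if (is.null(gdd_bounds)) {
    if (n_stages != 36) {
      stop("default bounds exist only for the 36-stage maize table; ",
           "supply gdd_bounds")
    }
    # V0 (sowing to emergence) ends at 100 F-degree-days; V1..V29 every
    # 62; R1..R6 in six steps up to 2700.
    gdd_bounds <- c(100, 100 + 62 * seq_len(29),
                    seq(2000, 2700, length.out = 6))
    if (is.null(stage_labels)) {
      stage_labels <- c(paste0("V", 0:29), paste0("R", 1:6))
    }
  }
  if (is.null(stage_labels)) stage_labels <- paste0("S", seq_along(gdd_bounds))
  if (length(stage_labels) != length(gdd_bounds)) {
    stop("stage_labels and gdd_bounds lengths differ")
  }
  if (any(diff(gdd_bounds) <= 0)) {
    stop("stage GDD bounds must be strictly increasing")
  }
  structure(data.frame(stage = stage_labels, gdd_upper = gdd_bounds,
                       stringsAsFactors = FALSE),
            class = c("stage_table", "data.frame"))
}

#' Example 11-stage wheat stage-threshold table
#'
#' Celsius-based thermal time (base 0 is common for wheat; here base 10 /
#' cap 30 if used with `units = "C"`), 11 stages to maturity. Illustrative
#' defaults for non-maize use; replace with crop-specific calibration.
#'
#' @return A `stage_table` with 11 stages.
#' @export
wheat_stage_table <- function() {
  stage_table(
    n_stages = 11,
    stage_labels = c("emergence", "tillering", "stem_ext", "booting",
                     "heading", "anthesis", "milk", "dough", "ripening",
                     "maturity", "post_maturity"),
    gdd_bounds = c(120, 350, 600, 800, 950, 1100, 1350, 1600, 1850,
                   2050, 2250)
  )
}

#' Segment a season into developmental-stage day windows
#'
#' Each day is assigned to the first stage whose cumulative-GDD upper bound
#' exceeds the day's cumulative GDD; days beyond the final bound stay in
#' the final stage. Stages the season never reaches are returned empty and
#' flagged.
#'
#' @param cumulative_gdd Non-decreasing daily cumulative GDD (from an
#'   [build_ep_series()] result).
#' @param thresholds A [stage_table()].
#' @return Object of class `stage_windows`: list with `stage` (labels),
#'   `days` (list of integer day indices per stage), `n_days`,
#'   `unreached` (logical flag per stage).
#' @export
segment_stages <- function(cumulative_gdd, thresholds) {
  if (!inherits(thresholds, "stage_table")) {
    thresholds <- stage_table(gdd_bounds = thresholds$gdd_upper,
                              stage_labels = thresholds$stage)
  }
  if (any(diff(cumulative_gdd) < 0)) {
    stop("cumulative_gdd must be non-decreasing")
  }
  bounds <- thresholds$gdd_upper
  # stage index = 1 + number of bounds <= cumGDD, clamped to the last stage
  idx <- findInterval(cumulative_gdd, bounds, left.open = FALSE) + 1L
  idx[cumulative_gdd < bounds[1]] <- 1L
  # findInterval counts bounds <= x; a day exactly on a bound belongs to
  # the next stage (the bound is an exclusive upper limit)
  idx <- pmin(idx, length(bounds))
  days <- lapply(seq_along(bounds), function(s) which(idx == s))
  n_days <- lengths(days)
  structure(
    list(stage = thresholds$stage, days = days, n_days = n_days,
         unreached = n_days == 0L),
    class = "stage_windows"
  )
}

#' @export
print.stage_windows <- function(x, ...) {
  cat(sprintf("<stage_windows> %d stages, %d day(s), %d unreached\n",
              length(x$stage), sum(x$n_days), sum(x$unreached)))
  invisible(x)
}

#' Reduce daily EP series to the stage-window RD_EP matrix
#'
#' Cell (ep, w) is the arithmetic mean of that EP over the days of stage
#' window w; windows with no days are `NA` (never 0).
#'
#' @param ep_series An `ep_series` from [build_ep_series()].
#' @param windows A `stage_windows` from [segment_stages()].
#' @return Object of class `rdep`: list with `env_id`, `matrix`
#'   (9 x W, rows [ep_names()]), `window_days`, `stage` labels.
#' @export
reduce_eps <- function(ep_series, windows) {
  stopifnot(inherits(ep_series, "ep_series"),
            inherits(windows, "stage_windows"))
  W <- length(windows$stage)
  m <- matrix(NA_real_, nrow = ncol(ep_series$eps), ncol = W,
              dimnames = list(colnames(ep_series$eps), windows$stage))
  for (w in seq_len(W)) {
    d <- windows$days[[w]]
    if (length(d)) m[, w] <- colMeans(ep_series$eps[d, , drop = FALSE])
  }
  structure(list(env_id = ep_series$env_id, matrix = m,
                 window_days = windows$n_days, stage = windows$stage),
            class = "rdep")
}

#' @export
print.rdep <- function(x, ...) {
  cat(sprintf("<rdep> env %s: %d EPs x %d stage windows (%d empty)\n",
              x$env_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$window_days == 0)))
  invisible(x)
}

#' One-call RD_EP profile for an environment
#'
#' @param ep_series An `ep_series`.
#' @param thresholds A [stage_table()].
#' @return An `rdep` object.
#' @export
rdep_profile <- function(ep_series, thresholds) {
  reduce_eps(ep_series, segment_stages(ep_series$cumulative_gdd, thresholds))
}

#' All sliding-window means of an RD_EP profile
#'
#' Enumerates every stage span A..B (A <= B) for each EP; the A..B value is
#' the day-count-weighted mean of the member window means (equivalently,
#' the plain mean of the underlying daily values). For W stages this gives
#' W(W+1)/2 spans per EP (666 for W = 36).
#'
#' @param rdep An `rdep` object.
#' @return Data frame `ep`, `start`, `end`, `value`, `n_days`.
#' @export
sliding_window_means <- function(rdep) {
  stopifnot(inherits(rdep, "rdep"))
  m <- rdep$matrix
  d <- rdep$window_days
  W <- ncol(m)
  wm <- sweep(m, 2, d, `*`)
  wm[, d == 0] <- 0 # empty windows contribute nothing
  pairs <- which(upper.tri(matrix(0, W, W), diag = TRUE), arr.ind = TRUE)
  A <- pairs[, 1]; B <- pairs[, 2]
  cs <- apply(wm, 1, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1, dimnames = list(NULL, names(cs)))
  csum <- cbind(0, t(cs))
  cdays <- c(0, cumsum(d))
  nd <- cdays[B + 1] - cdays[A]
  out <- do.call(rbind, lapply(rownames(m), function(ep) {
    tot <- csum[ep, B + 1] - csum[ep, A]
    data.frame(ep = ep, start = A, end = B,
               value = ifelse(nd > 0, tot / nd, NA_real_),
               n_days = nd, row.names = NULL)
  }))
  out[order(out$ep, out$start, out$end), , drop = FALSE]
}

#' Search for critical stage windows driving a trait
#'
#' For every EP and stage span A..B, computes the Pearson correlation
#' between per-environment trait means and the per-environment A..B mean
#' EP, and returns the spans with `|r| >=` the threshold. Overlapping
#' qualifying spans of the same EP are collapsed to the single best-|r|
#' span (ties broken by smaller span, then earlier start);
#' non-overlapping qualifying spans of one EP are all kept. Environments
#' with a missing span value are dropped pairwise; constant vectors are
#' skipped with a message.
#'
#' @param env_trait_means Named numeric vector of per-environment trait
#'   means (names = environment ids); see [environment_trait_means()].
#' @param rdeps Named list of `rdep` objects covering those environments.
#' @param r_threshold Absolute-correlation threshold (default 0.90).
#' @param trait Trait name recorded in the output.
#' @return Object of class `critical_windows`: data frame `trait`, `ep`,
#'   `start`, `end`, `r`, sorted by `|r|` decreasing. Attribute
#'   `all_windows` carries the full correlation table.
#' @export
critical_window_search <- function(env_trait_means, rdeps,
                                   r_threshold = 0.90, trait = "trait") {
  envs <- names(env_trait_means)
  if (is.null(envs) || !all(envs %in% names(rdeps))) {
    stop("env_trait_means must be named by environments present in rdeps")
  }
  if (length(envs) < 3) {
    stop("critical_window_search needs >= 3 environments")
  }
  if (stats::sd(env_trait_means) == 0) {
    stop("trait environment means are constant; correlation undefined")
  }
  sw <- lapply(rdeps[envs], sliding_window_means)
  key <- sw[[1]][, c("ep", "start", "end")]
  vals <- vapply(sw, function(s) s$value, numeric(nrow(key)))
  y <- as.numeric(env_trait_means)
  r <- vapply(seq_len(nrow(key)), function(i) {
    x <- vals[i, ]
    ok <- is.finite(x)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  n_skipped <- sum(is.na(r))
  if (n_skipped) {
    message(sprintf("skipped %d (ep, A, B) spans with undefined correlation",
                    n_skipped))
  }
  all_win <- cbind(trait = trait, key, r = r)
  qual <- all_win[!is.na(r) & abs(r) >= r_threshold, , drop = FALSE]
  qual <- qual[order(-abs(qual$r), qual$end - qual$start, qual$start), ,
               drop = FALSE]
  # per EP, greedily keep the best window, dropping later ones overlapping it
  keep <- rep(TRUE, nrow(qual))
  for (ep in unique(qual$ep)) {
    rows <- which(qual$ep == ep)
    taken <- list()
    for (i in rows) {
      ov <- any(vapply(taken, function(t) {
        qual$start[i] <= t[2] && qual$end[i] >= t[1]
      }, logical(1)))
      if (ov) keep[i] <- FALSE
      else taken[[length(taken) + 1]] <- c(qual$start[i], qual$end[i])
    }
  }
  out <- qual[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("critical_windows", "data.frame"),
            all_windows = all_win, r_threshold = r_threshold)
}

#' Cluster environments on their RD_EP profiles
#'
#' Flattens each environment's 9 x W RD_EP matrix, imputes missing cells
#' by the cross-environment mean of that cell (logged), standardises each
#' cell across environments, and applies Ward agglomeration
#' (`hclust(method = "ward.D2")`) on Euclidean distances.
#'
#' @param rdeps Named list of `rdep` objects.
#' @param k Number of clusters to cut.
#' @return List with `assignments` (named integer vector), `hclust` (the
#'   linkage object, sufficient to redraw the dendrogram), `profile`
#'   (the environment x feature matrix used).
#' @export
cluster_environments <- function(rdeps, k) {
  if (length(rdeps) < k) stop("fewer environments than clusters requested")
  X <- t(vapply(rdeps, function(r) as.vector(r$matrix),
                numeric(length(rdeps[[1]]$matrix))))
  rownames(X) <- names(rdeps)
  nmiss <- sum(is.na(X))
  if (nmiss) {
    message(sprintf("imputing %d missing RD_EP cell(s) by cross-environment means",
                    nmiss))
    for (j in which(colSums(is.na(X)) > 0)) {
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
    }
    X[is.na(X)] <- 0 # cells missing in every environment
  }
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0 | !is.finite(colSums(Z))] <- 0
  hc <- stats::hclust(stats::dist(Z, method = "euclidean"),
                      method = "ward.D2")
  list(assignments = stats::cutree(hc, k = k), hclust = hc, profile = X)
}
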