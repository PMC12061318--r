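# Feature assembly, cross-validation schemes, stacked-ensemble training
# (gradient-boosted trees + Bayesian ridge, sequential model-based tuning,
# non-negative-least-squares meta-learner), evaluation and attribution.

#' Pearson correlation coefficient between observed and predicted values
#'
#' The accuracy metric used throughout: plain Pearson r. A constant vector
#' makes the correlation undefined; it is reported as `NA` with a warning
#' (missing accuracy, not zero).
#'
#' @param observed,predicted Numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA` when undefined.
#' @export
pcc <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("pcc needs length >= 3")
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3 || stats::sd(observed[ok]) == 0 ||
      stats::sd(predicted[ok]) == 0) {
    warning("pcc undefined (constant or too-short vector); returning NA")
    return(NA_real_)
  }
  stats::cor(observed[ok], predicted[ok])
}

#' Percent change between a baseline and an improved accuracy
#'
#' `(improved - baseline) / baseline * 100`.
#'
#' @param baseline,improved Numeric (baseline non-zero).
#' @return Percent change.
#' @examples
#' percent_change(0.736, 0.878) # 19.29
#' @export
percent_change <- function(baseline, improved) {
  if (any(baseline == 0)) stop("percent change undefined for baseline 0")
  (improved - baseline) / baseline * 100
}

#' Assemble a genetic + environmental feature set
#'
#' One row per observed (genotype, environment) phenotype; columns are the
#' selected marker dosages plus, optionally, environmental features shared
#' by all genotypes of an environment: the flattened 9 x W RD_EP profile
#' (`ep_mode = "reduced"`) or per-day raw EP values truncated to the
#' shortest common season (`ep_mode = "raw"`).
#'
#' @param geno Post-QC `geno_matrix`.
#' @param marker_set Character vector of marker ids (subset of the map).
#' @param pheno Long phenotype data frame `genotype_id`, `env_id`, `value`.
#' @param rdeps Named list of `rdep` profiles (required unless
#'   `ep_mode = "none"`; used by `"reduced"`).
#' @param ep_series Named list of `ep_series` (required for `"raw"`).
#' @param ep_mode `"none"`, `"reduced"` or `"raw"`.
#' @param marker_class Provenance tag for marker columns (default
#'   `"marker"`; e.g. `"Main-TAM"`, `"random"`).
#' @return Object of class `feature_set`: list with `X` (numeric matrix),
#'   `y`, `rows` (data frame `genotype_id`, `env_id`), `provenance`
#'   (per-column tag).
#' @export
assemble_features <- function(geno, marker_set, pheno, rdeps = NULL,
                              ep_series = NULL,
                              ep_mode = c("none", "reduced", "raw"),
                              marker_class = "marker") {
  ep_mode <- match.arg(ep_mode)
  bad <- setdiff(marker_set, colnames(geno$dosage))
  if (length(bad)) stop("marker(s) not in genotype matrix: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  g <- as.character(pheno$genotype_id)
  e <- as.character(pheno$env_id)
  miss_g <- setdiff(unique(g), rownames(geno$dosage))
  if (length(miss_g)) stop("genotype(s) without marker data: ",
                           paste(utils::head(miss_g, 5), collapse = ", "))
  X <- geno$dosage[g, marker_set, drop = FALSE]
  prov <- rep(marker_class, length(marker_set))
  if (ep_mode == "reduced") {
    if (is.null(rdeps)) stop("ep_mode = 'reduced' needs rdeps")
    miss_e <- setdiff(unique(e), names(rdeps))
    if (length(miss_e)) stop("environment(s) without an RD_EP profile: ",
                             paste(miss_e, collapse = ", "))
    flat <- lapply(rdeps, function(r) as.vector(r$matrix))
    E <- do.call(rbind, flat)[match(e, names(rdeps)), , drop = FALSE]
    r1 <- rdeps[[1]]
    colnames(E) <- paste0("RDEP_", rep(rownames(r1$matrix), ncol(r1$matrix)),
                          "_w", rep(seq_len(ncol(r1$matrix)),
                                    each = nrow(r1$matrix)))
    if (anyNA(E)) { # empty stage windows: impute by cross-env mean
      for (j in which(colSums(is.na(E)) > 0)) {
        E[is.na(E[, j]), j] <- mean(E[, j], na.rm = TRUE)
      }
      E[is.na(E)] <- 0
    }
    X <- cbind(X, E)
    prov <- c(prov, rep("RD_EP", ncol(E)))
  } else if (ep_mode == "raw") {
    if (is.null(ep_series)) stop("ep_mode = 'raw' needs ep_series")
    miss_e <- setdiff(unique(e), names(ep_series))
    if (length(miss_e)) stop("environment(s) without EP series: ",
                             paste(miss_e, collapse = ", "))
    dmin <- min(vapply(ep_series, function(s) nrow(s$eps), integer(1)))
    flat <- lapply(ep_series, function(s) as.vector(s$eps[seq_len(dmin), ]))
    E <- do.call(rbind, flat)[match(e, names(ep_series)), , drop = FALSE]
    colnames(E) <- paste0("RAW_", rep(colnames(ep_series[[1]]$eps),
                                      each = dmin), "_d", seq_len(dmin))
    X <- cbind(X, E)
    prov <- c(prov, rep("Raw_EP", ncol(E)))
  }
  rownames(X) <- NULL
  structure(list(X = X, y = pheno$value,
                 rows = data.frame(genotype_id = g, env_id = e),
                 provenance = prov),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d rows x %d columns (%s)\n", nrow(x$X),
              ncol(x$X), paste(sprintf("%s:%d", names(table(x$provenance)),
                                       table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Cross-validation schemes for multi-environment prediction
#'
#' `fivefold`: unstratified random partition of rows into `n_folds`.
#' `scenario1` (untested genotypes, tested environments): each fold holds
#' out all rows of a random half of the genotypes; repeated `n_repeats`
#' times. `scenario2` (tested genotypes, untested environments):
#' leave-one-environment-out. `scenario3` (untested genotypes, untested
#' environments): for each environment, hold out that environment x a
#' random genotype half; training drops the held environment and the held
#' genotypes entirely.
#'
#' @param rows Data frame `genotype_id`, `env_id` (one per feature row).
#' @param scheme One of `"fivefold"`, `"scenario1"`, `"scenario2"`,
#'   `"scenario3"`.
#' @param n_folds Folds for `fivefold` (default 5).
#' @param n_repeats Random genotype halvings for scenarios 1 and 3
#'   (default 10 and 1 per environment respectively).
#' @param seed Integer seed.
#' @return Object of class `cv_scheme`: list with `scheme`, `seed`,
#'   `folds` — a list of `list(train, test)` integer row indices.
#' @export
make_cv_scheme <- function(rows, scheme = c("fivefold", "scenario1",
                                            "scenario2", "scenario3"),
                           n_folds = 5, n_repeats = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(rows)
  g <- as.character(rows$genotype_id)
  e <- as.character(rows$env_id)
  genos <- unique(g); envs <- unique(e)
  if (scheme != "fivefold") {
    if (length(genos) < 2 || length(envs) < 2) {
      stop("scenario schemes need >= 2 genotypes and >= 2 environments")
    }
  }
  if (scheme %in% c("scenario2", "scenario3") && length(envs) < 2) {
    stop("scenario 2/3 need more than one environment")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  folds <- switch(scheme,
    fivefold = {
      grp <- sample(rep(seq_len(n_folds), length.out = n))
      lapply(seq_len(n_folds), function(k) {
        list(train = which(grp != k), test = which(grp == k))
      })
    },
    scenario1 = {
      R <- if (is.null(n_repeats)) 10 else n_repeats
      lapply(seq_len(R), function(r) {
        half <- sample(genos, floor(length(genos) / 2))
        list(train = which(!g %in% half), test = which(g %in% half))
      })
    },
    scenario2 = {
      lapply(envs, function(ev) {
        list(train = which(e != ev), test = which(e == ev))
      })
    },
    scenario3 = {
      R <- if (is.null(n_repeats)) 1 else n_repeats
      out <- list()
      for (ev in envs) for (r in seq_len(R)) {
        half <- sample(genos, floor(length(genos) / 2))
        out[[length(out) + 1]] <- list(
          train = which(e != ev & !g %in% half),
          test = which(e == ev & g %in% half)
        )
      }
      out
    }
  )
  structure(list(scheme = scheme, seed = seed, folds = folds, rows = rows),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(sprintf("<cv_scheme> %s: %d fold(s) over %d rows (seed %d)\n",
              x$scheme, length(x$folds), nrow(x$rows), x$seed))
  invisible(x)
}

# ---- base learners ---------------------------------------------------------

#' Documented hyperparameter search spaces for the base learners
#'
#' Each space is a list of parameter definitions
#' `list(type = "num"|"int", lower, upper, log = FALSE)`. The gradient
#' boosted tree variants share learning-rate/round/sampling dimensions and
#' differ in growth policy: `xgb_depth` grows depth-wise (tunable
#' `max_depth`), `xgb_loss` grows loss-guided (tunable `max_leaves`),
#' `xgb_dart` adds dropout over boosting rounds. `bayes_ridge` tunes its
#' own regularisation by evidence maximisation, so its space is empty.
#'
#' @param nrounds_max Upper bound on boosting rounds (default 200; lower
#'   it for quick experiments).
#' @param max_depth_max Upper bound on tree depth (default 7).
#' @return Named list of spaces keyed by learner name.
#' @export
learner_spaces <- function(nrounds_max = 200, max_depth_max = 7) {
  gbt <- list(
    eta = list(type = "num", lower = 0.03, upper = 0.3, log = TRUE),
    nrounds = list(type = "int", lower = 50, upper = nrounds_max),
    subsample = list(type = "num", lower = 0.6, upper = 1),
    colsample_bytree = list(type = "num", lower = 0.5, upper = 1),
    lambda = list(type = "num", lower = 1e-3, upper = 10, log = TRUE)
  )
  list(
    xgb_depth = c(gbt, list(
      max_depth = list(type = "int", lower = 2, upper = max_depth_max))),
    xgb_loss = c(gbt, list(
      max_leaves = list(type = "int", lower = 8, upper = 64))),
    xgb_dart = c(gbt, list(
      max_depth = list(type = "int", lower = 2, upper = max_depth_max),
      rate_drop = list(type = "num", lower = 0, upper = 0.3))),
    bayes_ridge = list()
  )
}

fit_learner <- function(name, params, X, y, seed = 1) {
  if (name == "bayes_ridge") return(fit_bayes_ridge(X, y))
  p <- list(objective = "reg:squarederror", nthread = 1, seed = seed,
            tree_method = "hist", eta = params$eta,
            subsample = params$subsample,
            colsample_bytree = params$colsample_bytree,
            lambda = params$lambda)
  if (name == "xgb_depth") {
    p$max_depth <- params$max_depth
  } else if (name == "xgb_loss") {
    p$grow_policy <- "lossguide"
    p$max_depth <- 0
    p$max_leaves <- params$max_leaves
  } else if (name == "xgb_dart") {
    p$booster <- "dart"
    p$max_depth <- params$max_depth
    p$rate_drop <- params$rate_drop
  } else stop("unknown learner: ", name)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = p, data = dtrain,
                                nrounds = params$nrounds, verbose = 0)
  list(kind = "xgb", booster = booster, nrounds = params$nrounds)
}

predict_learner <- function(model, X) {
  if (inherits(model, "bayes_ridge")) return(predict_bayes_ridge(model, X))
  dm <- xgboost::xgb.DMatrix(X, nthread = 1)
  stats::predict(model$booster, dm)
}

#' Bayesian ridge regression by evidence maximisation
#'
#' Linear regression with a Gaussian prior on the (standardised)
#' coefficients; the prior precision `alpha` and noise precision `beta`
#' are set by iterating the evidence (type-II maximum likelihood) update
#' equations on the SVD of the centred design. Deterministic, no tunable
#' hyperparameters.
#'
#' @param X Numeric feature matrix.
#' @param y Response.
#' @param max_iter,tol Convergence controls.
#' @return Object of class `bayes_ridge` with coefficients on the
#'   original feature scale.
#' @export
fit_bayes_ridge <- function(X, y, max_iter = 100, tol = 1e-8) {
  n <- nrow(X)
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  ym <- mean(y); yc <- y - ym
  sv <- svd(Xs, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)
  alpha <- 1; beta <- 1 / max(stats::var(yc), 1e-12)
  for (i in seq_len(max_iter)) {
    denom <- alpha + beta * d2
    w_eig <- beta * sv$d * uty / denom
    gamma <- sum(beta * d2 / denom)
    fitted_eig <- sv$d * w_eig
    rss <- sum((yc - sv$u %*% fitted_eig)^2)
    alpha_new <- gamma / max(sum(w_eig^2), 1e-12)
    beta_new <- max(n - gamma, 1e-6) / max(rss, 1e-12)
    if (abs(alpha_new - alpha) < tol * alpha &&
        abs(beta_new - beta) < tol * beta) {
      alpha <- alpha_new; beta <- beta_new; break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  denom <- alpha + beta * d2
  w_eig <- beta * sv$d * uty / denom
  w_std <- sv$v %*% w_eig
  coef <- drop(w_std) / xs
  structure(list(kind = "bayes_ridge", coef = coef,
                 intercept = ym - sum(coef * xc),
                 alpha = alpha, beta = beta),
            class = "bayes_ridge")
}

predict_bayes_ridge <- function(model, X) {
  drop(X %*% model$coef) + model$intercept
}

# ---- sequential model-based tuner -----------------------------------------

sample_from_space <- function(space, n) {
  out <- lapply(seq_len(n), function(i) {
    p <- lapply(space, function(s) {
      if (isTRUE(s$log)) {
        v <- exp(stats::runif(1, log(s$lower), log(s$upper)))
      } else {
        v <- stats::runif(1, s$lower, s$upper)
      }
      if (s$type == "int") v <- as.integer(round(v))
      v
    })
    names(p) <- names(space)
    p
  })
  out
}

param_to_num <- function(space, params) {
  vapply(names(space), function(nm) {
    v <- params[[nm]]
    if (isTRUE(space[[nm]]$log)) log(v) else as.numeric(v)
  }, numeric(1))
}

# Parzen density-ratio score: density under "good" trials over density
# under the rest, per dimension with range-scaled Gaussian kernels.
parzen_score <- function(x, good, bad, widths) {
  dens <- function(centres) {
    if (!nrow(centres)) return(1e-12)
    k <- vapply(seq_len(nrow(centres)), function(i) {
      prod(stats::dnorm(x, centres[i, ], widths) + 1e-12)
    }, numeric(1))
    mean(k)
  }
  dens(good) / dens(bad)
}

#' Sequential model-based hyperparameter search
#'
#' Minimises `objective(params)` over a documented space within a trial
#' budget. The first third of the budget is random exploration; each later
#' trial draws candidates from the prior and picks the one with the best
#' Parzen good/bad density ratio (good = top quartile of past trials), a
#' tree-structured-Parzen-style acquisition.
#'
#' @param space A space from [learner_spaces()].
#' @param objective Function taking a named parameter list, returning a
#'   scalar loss to minimise.
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed.
#' @param n_candidates Candidate draws per guided trial.
#' @return List `best_params`, `best_loss`, `trials` (data frame).
#' @export
tune_params <- function(space, objective, budget = 50, seed = 1,
                        n_candidates = 20) {
  if (budget < 1) stop("tuning budget must be >= 1")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  if (!length(space)) {
    loss <- objective(list())
    return(list(best_params = list(), best_loss = loss,
                trials = data.frame(trial = 1, loss = loss)))
  }
  n0 <- max(3, ceiling(budget / 3))
  trials <- list(); losses <- numeric(0)
  widths <- vapply(space, function(s) {
    r <- if (isTRUE(s$log)) log(s$upper) - log(s$lower) else s$upper - s$lower
    r / 4
  }, numeric(1))
  for (t in seq_len(budget)) {
    if (t <= n0 || length(losses) < 4) {
      cand <- sample_from_space(space, 1)[[1]]
    } else {
      cands <- sample_from_space(space, n_candidates)
      ord <- order(losses)
      n_good <- max(2, ceiling(length(losses) / 4))
      mat <- do.call(rbind, lapply(trials, function(p) param_to_num(space, p)))
      good <- mat[ord[seq_len(n_good)], , drop = FALSE]
      bad <- mat[ord[-seq_len(n_good)], , drop = FALSE]
      scores <- vapply(cands, function(p) {
        parzen_score(param_to_num(space, p), good, bad, widths)
      }, numeric(1))
      cand <- cands[[which.max(scores)]]
    }
    trials[[t]] <- cand
    losses[t] <- objective(cand)
  }
  best <- which.min(losses)
  list(best_params = trials[[best]], best_loss = losses[best],
       trials = data.frame(trial = seq_len(budget), loss = losses))
}

# Exact non-negative least squares (plus free intercept) by enumeration of
# active sets; exact for the small column counts of a stacking meta-learner.
nnls_fit <- function(Z, y) {
  p <- ncol(Z)
  if (p > 20) stop("nnls_fit is for small column counts")
  best <- list(rss = Inf)
  for (mask in 0:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    A <- cbind(1, Z[, S, drop = FALSE])
    cf <- tryCatch(qr.coef(qr(A), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    if (length(S) && any(cf[-1] < 0)) next
    rss <- sum((y - A %*% cf)^2)
    if (rss < best$rss - 1e-12) {
      w <- numeric(p)
      if (length(S)) w[S] <- cf[-1]
      best <- list(rss = rss, intercept = cf[1], weights = w)
    }
  }
  best
}

# ---- stacked ensemble ------------------------------------------------------

#' Train a stacked ensemble regressor
#'
#' Each base learner is tuned by [tune_params()] on an internal
#' train/validation split (objective: validation RMSE), then produces
#' out-of-fold predictions under an internal `k_oof`-fold split; a
#' non-negative least-squares meta-learner (free intercept) combines the
#' base predictions; finally each tuned base learner is refit on all
#' training rows. Fully deterministic under `seed`.
#'
#' @param features A `feature_set` (or a plain list with `X` and `y`).
#' @param base_learners Subset of
#'   `c("xgb_depth", "xgb_loss", "xgb_dart", "bayes_ridge")`.
#' @param tuning_budget Trials per tuned learner (>= 1).
#' @param seed Integer seed.
#' @param k_oof Internal folds for the meta-learner (default 5).
#' @param spaces Hyperparameter spaces ([learner_spaces()]).
#' @return Object of class `stacked_model`.
#' @export
train_stacked_ensemble <- function(features,
                                   base_learners = c("xgb_depth", "xgb_loss",
                                                     "xgb_dart",
                                                     "bayes_ridge"),
                                   tuning_budget = 50, seed = 1, k_oof = 5,
                                   spaces = learner_spaces()) {
  X <- features$X; y <- features$y
  if (nrow(X) < 50) stop("need >= 50 training rows")
  if (tuning_budget < 1) stop("tuning budget must be >= 1")
  base_learners <- match.arg(base_learners, names(learner_spaces()),
                             several.ok = TRUE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- nrow(X)
  # internal validation split for tuning
  val <- sample(n, max(10, floor(n / 5)))
  tr <- setdiff(seq_len(n), val)
  tuned <- list(); failed <- character(0)
  for (nm in base_learners) {
    res <- tryCatch({
      obj <- function(params) {
        m <- fit_learner(nm, params, X[tr, , drop = FALSE], y[tr], seed)
        pr <- predict_learner(m, X[val, , drop = FALSE])
        sqrt(mean((y[val] - pr)^2))
      }
      budget <- if (!length(spaces[[nm]])) 1 else tuning_budget
      tune_params(spaces[[nm]], obj, budget = budget,
                  seed = seed + match(nm, base_learners))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("base learner '%s' failed and is excluded: %s",
                      nm, conditionMessage(res)))
      failed <- c(failed, nm)
    } else tuned[[nm]] <- res
  }
  if (!length(tuned)) stop("all base learners failed to fit")
  learners <- names(tuned)
  # out-of-fold base predictions for the meta-learner
  grp <- sample(rep(seq_len(k_oof), length.out = n))
  Z <- matrix(NA_real_, n, length(learners),
              dimnames = list(NULL, learners))
  for (k in seq_len(k_oof)) {
    it <- which(grp != k); io <- which(grp == k)
    for (nm in learners) {
      m <- fit_learner(nm, tuned[[nm]]$best_params,
                       X[it, , drop = FALSE], y[it], seed)
      Z[io, nm] <- predict_learner(m, X[io, , drop = FALSE])
    }
  }
  meta <- nnls_fit(Z, y)
  # refit tuned base learners on all rows
  fits <- lapply(learners, function(nm) {
    fit_learner(nm, tuned[[nm]]$best_params, X, y, seed)
  })
  names(fits) <- learners
  config <- list(base_learners = learners,
                 params = lapply(tuned, `[[`, "best_params"),
                 tuning_budget = tuning_budget, k_oof = k_oof, seed = seed)
  model <- structure(
    list(fits = fits, meta = meta, schema = colnames(X), seed = seed,
         config = config,
         config_hash = config_hash(config),
         oof = Z, tuned = tuned),
    class = "stacked_model"
  )
  model$fitted <- predict(model, X)
  model
}

config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # small rolling hash; stable across sessions for identical configs
  h <- 17
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.stacked_model <- function(x, ...) {
  w <- x$meta$weights
  cat(sprintf("<stacked_model> %d base learner(s), %d feature(s), seed %d, config %s\n",
              length(x$fits), length(x$schema), x$seed, x$config_hash))
  cat("  meta weights:", paste(sprintf("%s=%.3f", names(x$fits), w),
                               collapse = ", "),
      sprintf("(intercept %.3f)\n", x$meta$intercept))
  invisible(x)
}

#' Predict from a stacked ensemble
#'
#' @param object A `stacked_model`.
#' @param newdata Feature matrix or `feature_set` whose columns match the
#'   training schema exactly (an error lists missing/extra columns).
#' @param ... Unused.
#' @return Numeric vector of predictions (no clipping).
#' @export
predict.stacked_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_set")) newdata$X else newdata
  missing_cols <- setdiff(object$schema, colnames(X))
  extra <- setdiff(colnames(X), object$schema)
  if (length(missing_cols) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  X <- X[, object$schema, drop = FALSE]
  Z <- vapply(object$fits, function(m) predict_learner(m, X),
              numeric(nrow(X)))
  if (nrow(X) == 1) Z <- matrix(Z, nrow = 1)
  drop(Z %*% object$meta$weights) + object$meta$intercept
}

#' Cross-validated evaluation of a stacked ensemble
#'
#' Trains a fresh ensemble on each fold's training rows and scores its
#' predictions on the fold's test rows with [pcc()].
#'
#' @param features A `feature_set`.
#' @param cv A `cv_scheme` built on the same rows.
#' @param ... Passed to [train_stacked_ensemble()].
#' @return Object of class `prediction_result`: list with `fold_pcc`,
#'   `mean_pcc` (arithmetic mean over folds, `NA` folds dropped),
#'   `predictions` (per-fold observed/predicted), `scheme`.
#' @export
evaluate_cv <- function(features, cv, ...) {
  stopifnot(inherits(cv, "cv_scheme"))
  res <- lapply(seq_along(cv$folds), function(k) {
    f <- cv$folds[[k]]
    tr_fs <- list(X = features$X[f$train, , drop = FALSE],
                  y = features$y[f$train])
    model <- train_stacked_ensemble(tr_fs, ...)
    pred <- predict(model, features$X[f$test, , drop = FALSE])
    obs <- features$y[f$test]
    list(fold = k, observed = obs, predicted = pred,
         pcc = suppressWarnings(pcc(obs, pred)))
  })
  fold_pcc <- vapply(res, `[[`, numeric(1), "pcc")
  structure(list(fold_pcc = fold_pcc,
                 mean_pcc = mean(fold_pcc, na.rm = TRUE),
                 predictions = res, scheme = cv$scheme, seed = cv$seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s: mean PCC %.4f over %d fold(s)\n",
              x$scheme, x$mean_pcc, length(x$fold_pcc)))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_pcc), collapse = " "), "\n")
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of a feature = mean drop in prediction PCC when that column
#' is permuted (`n_repeats` independent permutations), measured on the
#' supplied rows. Model-agnostic and deterministic under `seed`.
#'
#' @param model A `stacked_model`.
#' @param X Feature matrix matching the model schema (>= 30 rows).
#' @param y Observed response.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Integer seed.
#' @param features Optional subset of columns to score (default all).
#' @return Data frame `feature`, `importance`, `sign` (sign of the mean
#'   marginal effect of the feature on predictions), `rank`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5, seed = 1,
                                   features = NULL) {
  if (nrow(X) < 30) stop("permutation importance needs >= 30 rows")
  if (is.null(features)) features <- colnames(X)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  base_pred <- predict(model, X)
  base <- suppressWarnings(pcc(y, base_pred))
  imp <- vapply(features, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, f] <- Xp[sample(nrow(X)), f]
      base - suppressWarnings(pcc(y, predict(model, Xp)))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  sgn <- vapply(features, function(f) {
    v <- X[, f]
    if (stats::sd(v) == 0) return(0)
    sign(stats::cor(v, base_pred))
  }, numeric(1))
  out <- data.frame(feature = features, importance = imp, sign = sgn,
                    row.names = NULL)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
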