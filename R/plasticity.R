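# Reaction-norm phenotypic-plasticity parameters, variance decomposition
# and broad-sense heritability for genotype x environment trait tables.

#' Genotype x environment trait matrix from a long phenotype table
#'
#' @param pheno Long data frame `genotype_id`, `env_id`, `value` (plus an
#'   optional `trait` column filtered by `trait`).
#' @param trait Optional trait name to select.
#' @return Numeric matrix, rows = genotypes, columns = environments,
#'   `NA` where unobserved.
#' @export
trait_matrix <- function(pheno, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(pheno)) {
    pheno <- pheno[pheno$trait == trait, , drop = FALSE]
  }
  g <- sort(unique(as.character(pheno$genotype_id)))
  e <- sort(unique(as.character(pheno$env_id)))
  m <- matrix(NA_real_, length(g), length(e), dimnames = list(g, e))
  m[cbind(match(as.character(pheno$genotype_id), g),
          match(as.character(pheno$env_id), e))] <- pheno$value
  m
}

#' Per-environment trait means
#'
#' @param trait_mat Genotype x environment matrix ([trait_matrix()]).
#' @return Named vector of per-environment means (missing values skipped).
#'   An environment with no observations at all is an error naming it.
#' @export
environment_trait_means <- function(trait_mat) {
  empty <- colnames(trait_mat)[colSums(!is.na(trait_mat)) == 0]
  if (length(empty)) {
    stop("environment(s) with no observations: ",
         paste(empty, collapse = ", "))
  }
  colMeans(trait_mat, na.rm = TRUE)
}

#' Per-genotype reaction norms on a critical-window EP
#'
#' Ordinary least squares of each genotype's phenotypes on the
#' per-environment EP value of one critical window. The intercept and slope
#' are the two phenotypic-plasticity (PP) parameters: the slope measures how
#' strongly the genotype's phenotype tracks that environmental signal
#' (steeper = more plastic), the intercept its performance at EP = 0.
#'
#' @param trait_mat Genotype x environment matrix.
#' @param ep_values Named per-environment EP means for the window (names
#'   must cover the matrix's environments).
#' @param min_envs Minimum environments with both phenotype and EP for a
#'   genotype to be fitted (default 3); genotypes below it are skipped
#'   with a message.
#' @param trait,window Optional labels stored in the output.
#' @return Data frame `genotype_id`, `intercept`, `slope`, `r2_fit`,
#'   `n_env` (class `pp_params`). Genotypes whose environments show zero
#'   EP variance are degenerate and skipped with a message.
#' @export
fit_reaction_norms <- function(trait_mat, ep_values, min_envs = 3,
                               trait = "trait", window = NULL) {
  envs <- colnames(trait_mat)
  if (!all(envs %in% names(ep_values))) {
    stop("ep_values missing environments: ",
         paste(setdiff(envs, names(ep_values)), collapse = ", "))
  }
  x_all <- as.numeric(ep_values[envs])
  res <- lapply(rownames(trait_mat), function(g) {
    y <- trait_mat[g, ]
    ok <- !is.na(y) & !is.na(x_all)
    if (sum(ok) < min_envs) return(NULL)
    x <- x_all[ok]; yy <- y[ok]
    vx <- stats::var(x)
    if (vx == 0) return(list(degenerate = g))
    slope <- stats::cov(x, yy) / vx
    intercept <- mean(yy) - slope * mean(x)
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst == 0) 1 else 1 - sum((yy - intercept - slope * x)^2) / sst
    data.frame(genotype_id = g, intercept = intercept, slope = slope,
               r2_fit = r2, n_env = sum(ok), row.names = NULL)
  })
  degen <- unlist(lapply(res, function(r) if (is.list(r) && !is.data.frame(r)) r$degenerate))
  if (length(degen)) {
    message(sprintf("degenerate regressor (zero EP variance) for %d genotype(s): %s",
                    length(degen), paste(utils::head(degen, 5), collapse = ", ")))
  }
  fits <- Filter(is.data.frame, res)
  n_skip <- nrow(trait_mat) - length(fits) - length(degen)
  if (n_skip > 0) {
    message(sprintf("skipped %d genotype(s) with < %d environments",
                    n_skip, min_envs))
  }
  out <- do.call(rbind, fits)
  if (is.null(out)) out <- data.frame(genotype_id = character(),
                                      intercept = numeric(), slope = numeric(),
                                      r2_fit = numeric(), n_env = integer())
  out$trait <- rep(trait, nrow(out))
  if (!is.null(window)) attr(out, "window") <- window
  class(out) <- c("pp_params", "data.frame")
  out
}

#' PP parameters for every critical window of a trait
#'
#' @param trait_mat Genotype x environment matrix.
#' @param windows A `critical_windows` object ([critical_window_search()]).
#' @param rdeps Named list of `rdep` profiles.
#' @param ... Passed to [fit_reaction_norms()].
#' @return Data frame stacking [fit_reaction_norms()] output per window,
#'   with `ep`, `start`, `end` columns identifying the window.
#' @export
pp_parameters <- function(trait_mat, windows, rdeps, ...) {
  do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ep_vals <- vapply(rdeps, function(r) window_mean(r, w$ep, w$start, w$end),
                      numeric(1))
    fits <- fit_reaction_norms(trait_mat, ep_vals, trait = w$trait, ...)
    if (!nrow(fits)) return(NULL)
    fits$ep <- w$ep; fits$start <- w$start; fits$end <- w$end
    fits
  }))
}

#' Day-weighted mean of one EP over a stage span
#'
#' @param rdep An `rdep` object.
#' @param ep EP name.
#' @param start,end Stage indices (A <= B).
#' @return The day-count-weighted mean over windows `start..end`.
#' @export
window_mean <- function(rdep, ep, start, end) {
  idx <- start:end
  d <- rdep$window_days[idx]
  v <- rdep$matrix[ep, idx]
  ok <- d > 0 & is.finite(v)
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * d[ok]) / sum(d[ok])
}

#' Variance decomposition of a genotype x environment trait table
#'
#' Splits phenotypic variance into genotype, environment, and
#' G-by-E-plus-residual components for a two-way crossed random-effects
#' model with one observation per cell. The default estimator is
#' method-of-moments on the two-way ANOVA mean squares (exact on balanced
#' data; negative estimates truncated to 0). `method = "reml"` refits by
#' REML via `lme4::lmer(value ~ (1|genotype) + (1|env))`, which handles
#' unbalanced tables gracefully.
#'
#' @param trait_mat Genotype x environment matrix (>= 2 of each).
#' @param method `"moments"` (default) or `"reml"`.
#' @return Object of class `variance_components`: list with `var_g`,
#'   `var_e`, `var_gxe_residual`, `shares` (proportions summing to 1) and
#'   `h2` (broad-sense line-mean heritability, see [heritability()]; the
#'   error term is the G-by-E-plus-residual component).
#' @export
variance_decomposition <- function(trait_mat, method = c("moments", "reml")) {
  method <- match.arg(method)
  if (ncol(trait_mat) < 2) stop("var_e inestimable with a single environment")
  if (nrow(trait_mat) < 2) stop("need >= 2 genotypes")
  if (method == "moments") {
    m <- trait_mat
    nG <- nrow(m); nE <- ncol(m)
    if (anyNA(m)) {
      # moments estimator assumes (near-)balance; complete rows only
      keep <- rowSums(is.na(m)) == 0
      if (sum(keep) < 2) stop("too few complete genotypes for moments; use method = 'reml'")
      m <- m[keep, , drop = FALSE]
      nG <- nrow(m)
    }
    gm <- mean(m)
    rg <- rowMeans(m); ce <- colMeans(m)
    ss_g <- nE * sum((rg - gm)^2)
    ss_e <- nG * sum((ce - gm)^2)
    ss_res <- sum((m - outer(rg, rep(1, nE)) - outer(rep(1, nG), ce) + gm)^2)
    ms_g <- ss_g / (nG - 1)
    ms_e <- ss_e / (nE - 1)
    ms_res <- ss_res / ((nG - 1) * (nE - 1))
    var_res <- ms_res
    var_g <- max((ms_g - ms_res) / nE, 0)
    var_e <- max((ms_e - ms_res) / nG, 0)
    L <- nE
  } else {
    long <- data.frame(
      value = as.vector(trait_mat),
      genotype = factor(rep(rownames(trait_mat), ncol(trait_mat))),
      env = factor(rep(colnames(trait_mat), each = nrow(trait_mat)))
    )
    long <- long[!is.na(long$value), , drop = FALSE]
    fit <- lme4::lmer(value ~ (1 | genotype) + (1 | env), data = long,
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_g <- vc$vcov[vc$grp == "genotype"]
    var_e <- vc$vcov[vc$grp == "env"]
    var_res <- vc$vcov[vc$grp == "Residual"]
    L <- ncol(trait_mat)
  }
  tot <- var_g + var_e + var_res
  shares <- if (tot > 0) c(G = var_g, E = var_e, GxE = var_res) / tot else
    c(G = NA_real_, E = NA_real_, GxE = NA_real_)
  h2 <- if (var_g + var_res > 0) heritability(var_g, var_res, L) else NA_real_
  structure(list(var_g = var_g, var_e = var_e, var_gxe_residual = var_res,
                 shares = shares, h2 = h2, n_env = L, method = method),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> (%s) G %.4g | E %.4g | GxE+res %.4g\n",
              x$method, x$var_g, x$var_e, x$var_gxe_residual))
  cat(sprintf("  shares G %.3f E %.3f GxE %.3f; H2 = %.3f (L = %d)\n",
              x$shares["G"], x$shares["E"], x$shares["GxE"], x$h2, x$n_env))
  invisible(x)
}

#' Broad-sense line-mean heritability
#'
#' `H2 = var_g / (var_g + var_e / L)`: the share of variance among
#' genotype means (averaged over `L` environments) that is genetic. With
#' no error variance H2 = 1; error variance is divided by the number of
#' environments because averaging over environments shrinks it.
#'
#' @param var_g Genetic variance (>= 0).
#' @param var_e Error variance entering the line-mean denominator (>= 0).
#' @param n_env Number of environments L (>= 1).
#' @return H2 in `[0, 1]`.
#' @export
heritability <- function(var_g, var_e, n_env) {
  stopifnot(var_g >= 0, var_e >= 0, n_env >= 1)
  if (var_g + var_e == 0) stop("H2 undefined: both variances are zero")
  var_g / (var_g + var_e / n_env)
}
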