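# Synthetic multi-environment trials with a known reaction-norm genetic
# architecture: LD-blocked SNP genotypes, per-environment seasonal weather,
# and phenotypes built as genotype main effects + genotype-specific slopes
# on a chosen EP stage-window + environment main effects + noise. Every
# component is stored so downstream estimates can be checked against truth.

#' Simulation configuration
#'
#' Defaults emulate a moderate hybrid multi-environment trial: 1000
#' genotypes phenotyped in 7 environments, SNPs in LD blocks, a handful of
#' main-effect and slope (plasticity) QTL acting through the GDD mean of
#' an early-vegetative stage window. The weather template is a seasonal
#' temperature sinusoid with environment-specific offsets, a latitude-like
#' day-length curve and showery rainfall; a 150-day season comfortably
#' crosses the final maize stage bound.
#'
#' @param n_genotypes,n_markers,n_envs Population sizes.
#' @param n_chrom Chromosomes the markers are spread over.
#' @param maf_range Anchor minor-allele-frequency range.
#' @param ld_block_len Markers per LD block (1 = independent markers).
#' @param flip_prob Per-haplotype allele flip probability between adjacent
#'   markers of a block (controls within-block LD decay).
#' @param marker_spacing_bp Distance between adjacent markers.
#' @param n_main_qtl,n_slope_qtl Numbers of main-effect and slope QTL.
#' @param main_effect_sd,slope_effect_sd Per-QTL effect SDs (trait units,
#'   and trait units per EP unit).
#' @param mean_slope Population-mean response to the target EP (drives the
#'   environment-mean signal the critical-window search looks for).
#' @param target_ep,window_start,window_end The EP and stage span through
#'   which slope QTL act.
#' @param env_effect_sd SD of environment main effects independent of the
#'   target EP.
#' @param residual_sd Residual SD.
#' @param mu Trait grand mean.
#' @param season_days Season length (days).
#' @param temp_mean,temp_amp,temp_noise_sd Seasonal Tmax sinusoid (deg F).
#' @param traj_sd SD of the environment-specific low-frequency temperature
#'   trajectory deviations (deg F). Real locations/years differ in the
#'   shape of the season, not only its mean; this is what makes individual
#'   stage windows carry distinguishable cross-environment signals.
#' @param dtr_mean Mean diurnal range (Tmax - Tmin).
#' @param env_offset_sd SD of environment temperature offsets (deg F).
#' @param sowing_doy Sowing day of year (drives the day-length curve).
#' @param rain_prob,rain_mean Daily rain probability and mean depth (mm).
#' @param stage_thresholds A [stage_table()].
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 1000, n_markers = 5000, n_envs = 7,
                       n_chrom = 10, maf_range = c(0.1, 0.5),
                       ld_block_len = 10, flip_prob = 0.05,
                       marker_spacing_bp = 10000,
                       n_main_qtl = 20, n_slope_qtl = 10,
                       main_effect_sd = 0.5, slope_effect_sd = 0.2,
                       mean_slope = 1, target_ep = "GDD",
                       window_start = 4, window_end = 8,
                       env_effect_sd = 0.5, residual_sd = 1, mu = 100,
                       season_days = 150, temp_mean = 75, temp_amp = 12,
                       temp_noise_sd = 3, traj_sd = 3, dtr_mean = 20,
                       env_offset_sd = 4, sowing_doy = 120,
                       rain_prob = 0.3, rain_mean = 6,
                       stage_thresholds = stage_table(), seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genotypes > 0, cfg$n_markers > 0, cfg$n_envs > 0,
            cfg$n_main_qtl + cfg$n_slope_qtl <= cfg$n_markers,
            cfg$window_start <= cfg$window_end,
            cfg$window_end <= nrow(cfg$stage_thresholds),
            cfg$target_ep %in% ep_names())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate LD-blocked SNP genotypes
#'
#' Two haplotypes per genotype; within each LD block the anchor marker's
#' allele frequency is drawn from `maf_range` and each subsequent marker
#' copies the previous allele with per-haplotype flip probability
#' `flip_prob`, giving geometric LD decay within blocks and independence
#' across blocks. Dosages are 0/1/2.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix` with a `truth` attribute (block ids).
#' @export
simulate_genotypes <- function(config) {
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  nG <- config$n_genotypes; nM <- config$n_markers
  bl <- config$ld_block_len
  H <- matrix(0L, nrow = 2 * nG, ncol = nM)
  block <- (seq_len(nM) - 1) %/% bl
  for (b in unique(block)) {
    idx <- which(block == b)
    p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    h <- stats::rbinom(2 * nG, 1, p)
    H[, idx[1]] <- h
    for (j in idx[-1]) {
      flip <- stats::rbinom(2 * nG, 1, config$flip_prob)
      h <- ifelse(flip == 1, 1L - h, h)
      H[, j] <- h
    }
  }
  dosage <- H[seq(1, 2 * nG, by = 2), , drop = FALSE] +
    H[seq(2, 2 * nG, by = 2), , drop = FALSE]
  rownames(dosage) <- sprintf("G%04d", seq_len(nG))
  per_chr <- ceiling(nM / config$n_chrom)
  chrom <- ((seq_len(nM) - 1) %/% per_chr) + 1
  pos_in <- (seq_len(nM) - 1) %% per_chr
  map <- data.frame(
    marker = sprintf("S%d_%d", chrom, (pos_in + 1) * config$marker_spacing_bp),
    chrom = chrom,
    pos = (pos_in + 1) * config$marker_spacing_bp
  )
  colnames(dosage) <- map$marker
  g <- geno_matrix(dosage, map)
  attr(g, "truth") <- list(block = block)
  g
}

#' Simulate per-environment daily weather
#'
#' @param config A [sim_config()].
#' @return Named list per environment with `weather` (a daily table in
#'   [build_ep_series()] layout) and `offset` (the environment's
#'   temperature offset). A config whose season never reaches the final
#'   stage bound is flagged with a warning.
#' @export
simulate_weather <- function(config) {
  rng <- local_rng(config$seed + 1000L)
  on.exit(rng(), add = TRUE)
  nD <- config$season_days
  d <- seq_len(nD)
  out <- list()
  for (i in seq_len(config$n_envs)) {
    env_id <- sprintf("E%02d", i)
    offset <- stats::rnorm(1, 0, config$env_offset_sd)
    # environment-specific trajectory shape: low-order Fourier deviations
    fc <- stats::rnorm(4, 0, config$traj_sd)
    traj <- fc[1] * sin(2 * pi * d / nD) + fc[2] * cos(2 * pi * d / nD) +
      fc[3] * sin(4 * pi * d / nD) + fc[4] * cos(4 * pi * d / nD)
    base <- config$temp_mean + offset + traj +
      config$temp_amp * sin(pi * d / nD)
    tmax <- base + config$dtr_mean / 2 +
      stats::rnorm(nD, 0, config$temp_noise_sd)
    tmin <- base - config$dtr_mean / 2 +
      stats::rnorm(nD, 0, config$temp_noise_sd)
    tmin <- pmin(tmin, tmax)
    doy <- config$sowing_doy + d - 1
    dl <- 12 + 2.5 * sin(2 * pi * (doy - 80) / 365)
    rain <- stats::rbinom(nD, 1, config$rain_prob) *
      stats::rexp(nD, 1 / config$rain_mean)
    par <- pmax(15 + 8 * sin(pi * d / nD) + stats::rnorm(nD, 0, 2), 1)
    rh <- pmin(pmax(60 + 15 * (rain > 0) + stats::rnorm(nD, 0, 5), 5), 100)
    weather <- data.frame(
      env_id = env_id,
      date = as.Date("2020-01-01") + config$sowing_doy + d - 2,
      tmax = tmax, tmin = tmin, day_length = dl, rh = rh, pre = rain,
      par = par
    )
    out[[env_id]] <- list(weather = weather, offset = offset)
  }
  final_bound <- max(config$stage_thresholds$gdd_upper)
  for (env_id in names(out)) {
    gdd <- compute_gdd(out[[env_id]]$weather$tmax, out[[env_id]]$weather$tmin)
    if (sum(gdd) < final_bound) {
      warning(sprintf("environment %s never reaches the final stage bound (%.0f < %.0f)",
                      env_id, sum(gdd), final_bound))
    }
  }
  out
}

#' Simulate phenotypes with a reaction-norm architecture
#'
#' `y_ge = mu + sum(main QTL effects) + (mean_slope + genotype slope
#' deviation) * (EP_e - mean(EP)) + u_e + eps_ge`, where `EP_e` is the
#' target EP's day-weighted mean over the configured stage window,
#' computed through the package's own envirotyping path (EP series ->
#' stage segmentation -> window mean). Genotype main and slope scores are
#' centred so the genotype, environment and interaction variance
#' components are separately controllable.
#'
#' @param geno A `geno_matrix` from [simulate_genotypes()].
#' @param weather Output of [simulate_weather()].
#' @param config The same [sim_config()].
#' @return List with `pheno` (long data frame `genotype_id`, `env_id`,
#'   `value`), `trait_mat`, `truth` (QTL ids/effects, per-genotype true
#'   intercept/slope, per-environment EP value and main effect, residual
#'   matrix), `rdeps` and `ep_series` (per environment).
#' @export
simulate_phenotypes <- function(geno, weather, config) {
  rng <- local_rng(config$seed + 2000L)
  on.exit(rng(), add = TRUE)
  nG <- nrow(geno$dosage)
  markers <- colnames(geno$dosage)
  qtl <- sample(markers, config$n_main_qtl + config$n_slope_qtl)
  main_qtl <- qtl[seq_len(config$n_main_qtl)]
  slope_qtl <- qtl[config$n_main_qtl + seq_len(config$n_slope_qtl)]
  beta_main <- stats::rnorm(config$n_main_qtl, 0, config$main_effect_sd)
  gamma_slope <- stats::rnorm(config$n_slope_qtl, 0, config$slope_effect_sd)
  g_main <- drop(geno$dosage[, main_qtl, drop = FALSE] %*% beta_main)
  g_slope <- drop(geno$dosage[, slope_qtl, drop = FALSE] %*% gamma_slope)
  g_main <- g_main - mean(g_main)
  g_slope <- g_slope - mean(g_slope)

  ep_series <- lapply(weather, function(w) build_ep_series(w$weather))
  rdeps <- lapply(ep_series, rdep_profile, thresholds = config$stage_thresholds)
  ep_val <- vapply(rdeps, window_mean, numeric(1), ep = config$target_ep,
                   start = config$window_start, end = config$window_end)
  ep_centered <- ep_val - mean(ep_val)
  u_env <- stats::rnorm(config$n_envs, 0, config$env_effect_sd)
  names(u_env) <- names(weather)
  eps_mat <- matrix(stats::rnorm(nG * config$n_envs, 0, config$residual_sd),
                    nG, config$n_envs,
                    dimnames = list(rownames(geno$dosage), names(weather)))
  slope_g <- config$mean_slope + g_slope
  tm <- outer(rep(config$mu, nG), rep(1, config$n_envs)) +
    outer(g_main, rep(1, config$n_envs)) +
    outer(slope_g, ep_centered) +
    outer(rep(1, nG), u_env) + eps_mat
  dimnames(tm) <- dimnames(eps_mat)
  pheno <- data.frame(
    genotype_id = rep(rownames(tm), ncol(tm)),
    env_id = rep(colnames(tm), each = nrow(tm)),
    value = as.vector(tm)
  )
  truth <- list(
    main_qtl = main_qtl, beta_main = beta_main,
    slope_qtl = slope_qtl, gamma_slope = gamma_slope,
    g_main = g_main, slope = slope_g,
    intercept = config$mu + g_main - slope_g * mean(ep_val),
    ep_value = ep_val, ep_centered = ep_centered, u_env = u_env,
    residuals = eps_mat, mu = config$mu,
    target_ep = config$target_ep,
    window = c(config$window_start, config$window_end)
  )
  list(pheno = pheno, trait_mat = tm, truth = truth, rdeps = rdeps,
       ep_series = ep_series)
}

#' One-call synthetic multi-environment trial
#'
#' @param config A [sim_config()].
#' @return List with `geno`, `weather`, plus everything from
#'   [simulate_phenotypes()].
#' @export
simulate_trial <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  weather <- simulate_weather(config)
  c(list(geno = geno, weather = weather, config = config),
    simulate_phenotypes(geno, weather, config))
}
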