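# Readers/writers for the standard interchange formats and the top-level
# pipeline driver.

#' Read a daily weather table
#'
#' CSV/TSV with header `env_id,date,tmax,tmin,day_length,rh,pre,par`,
#' ISO-8601 dates.
#'
#' @param path File path.
#' @return Data frame ready for [build_ep_series_all()].
#' @export
read_weather <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  w <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("env_id", "date", "tmax", "tmin", "day_length", "rh", "pre",
            "par")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weather file lacks columns: ",
                         paste(miss, collapse = ", "))
  w$date <- as.Date(w$date)
  w
}

#' Read a long phenotype table
#'
#' CSV/TSV with header `genotype_id,env_id,trait,value` (the `trait`
#' column is optional for single-trait files).
#'
#' @param path File path.
#' @return Long data frame.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  p <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("genotype_id", "env_id", "value"), names(p))
  if (length(miss)) stop("phenotype file lacks columns: ",
                         paste(miss, collapse = ", "))
  p
}

#' Read genotypes from VCF, HapMap or a dosage matrix
#'
#' `"vcf"`: diploid GT fields are mapped to alternate-allele dosage 0/1/2
#' (missing `./.` to `NA`); sites with more than one ALT allele are kept
#' but flagged multiallelic so [qc_filter()] removes them; ploidy other
#' than 2 is an error. `"hapmap"`: standard HapMap text (tab-separated,
#' `rs# alleles chrom pos ...` then genotype columns of two-letter calls).
#' `"dosage"`: CSV with genotypes in rows, markers in columns, plus a map
#' CSV `marker,chrom,pos` given via `map_path`.
#'
#' @param path Genotype file path.
#' @param format `"vcf"`, `"hapmap"` or `"dosage"`.
#' @param map_path Marker map path (dosage format only).
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "dosage"),
                           map_path = NULL) {
  format <- match.arg(format)
  switch(format,
    vcf = read_genotypes_vcf(path),
    hapmap = read_genotypes_hapmap(path),
    dosage = {
      if (is.null(map_path)) stop("dosage format needs map_path")
      d <- as.matrix(utils::read.csv(path, row.names = 1,
                                     check.names = FALSE))
      map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
      geno_matrix(d, map)
    }
  )
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  n_alleles <- 1L + vapply(strsplit(ifelse(is.na(alt), "", alt), ","),
                           length, integer(1))
  to_dosage <- function(x) {
    x <- sub("\\|", "/", x)
    if (is.na(x) || x %in% c("./.", ".")) return(NA_real_)
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("unsupported ploidy in GT field: ", x)
    sum(as.numeric(parts) > 0)
  }
  d <- apply(gt, c(1, 2), to_dosage)
  marker <- rownames(gt)
  if (is.null(marker) || anyNA(marker)) {
    marker <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  }
  map <- data.frame(marker = marker, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]), n_alleles = n_alleles,
                    stringsAsFactors = FALSE)
  dosage <- t(d)
  colnames(dosage) <- marker
  geno_matrix(dosage, map)
}

read_genotypes_hapmap <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "", check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta_cols <- 11 # rs# alleles chrom pos strand assembly center protLSID assayLSID panelLSID QCcode
  calls <- as.matrix(h[, -(seq_len(meta_cols)), drop = FALSE])
  alleles <- strsplit(h$alleles, "/", fixed = TRUE)
  n_alleles <- lengths(alleles)
  dos <- matrix(NA_real_, nrow = ncol(calls), ncol = nrow(h),
                dimnames = list(colnames(calls), h[[1]]))
  for (i in seq_len(nrow(h))) {
    ref <- alleles[[i]][1]
    cc <- calls[i, ]
    known <- cc != "NN" & !is.na(cc)
    a1 <- substr(cc, 1, 1); a2 <- substr(cc, 2, 2)
    dos[known, i] <- (a1[known] != ref) + (a2[known] != ref)
  }
  map <- data.frame(marker = h[[1]], chrom = h$chrom, pos = h$pos,
                    n_alleles = n_alleles, stringsAsFactors = FALSE)
  geno_matrix(dos, map)
}

#' Write a dosage matrix and its map to CSV
#'
#' @param geno A `geno_matrix`.
#' @param path,map_path Output CSVs (matrix and `marker,chrom,pos` map).
#' @export
write_genotypes <- function(geno, path, map_path) {
  utils::write.csv(geno$dosage, path)
  utils::write.csv(geno$map, map_path, row.names = FALSE)
}

#' Pipeline configuration
#'
#' Collects the knobs of the full analysis; `from` may be a YAML file.
#'
#' @param ... Named overrides of the defaults (see source).
#' @param from Optional YAML path read first.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(..., from = NULL) {
  cfg <- list(
    r_threshold = 0.90,
    tbase = 50, tcap = 86, units = "F", pts_formula = "squares",
    flank_mode = "fixed_bp", flank_bp = 37000,
    ep_mode = "reduced",
    base_learners = c("xgb_depth", "xgb_loss", "xgb_dart", "bayes_ridge"),
    tuning_budget = 50, cv_scheme = "fivefold", n_folds = 5,
    seed = 1, trait = "trait",
    out_dir = NULL
  )
  if (!is.null(from)) {
    y <- yaml::read_yaml(from)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full envirotype-aware prediction pipeline
#'
#' Executes: EP derivation -> stage-window reduction -> critical-window
#' search -> PP parameters and variance decomposition -> marker feature
#' extraction (TAM flanks when a TAM table is given, otherwise an
#' association screen on PP slopes) -> stacked-ensemble cross-validated
#' prediction. With `r_threshold` set above 1 no critical window
#' qualifies; the pipeline warns, skips PP parameters and proceeds with
#' markers + RD_EPs.
#'
#' @param weather Daily weather table (all environments) or an
#'   [read_weather()] path.
#' @param geno A `geno_matrix` or a VCF path.
#' @param pheno Long phenotype table or a [read_phenotypes()] path.
#' @param config A [pipeline_config()].
#' @param tams Optional externally supplied `tam_table`.
#' @param stage_thresholds A [stage_table()].
#' @return List of artifacts: `rdeps`, `critical_windows`, `pp_params`,
#'   `variance`, `features` provenance summary, `cv` result, `tams`,
#'   `meta` (seed + config hash). When `config$out_dir` is set each
#'   artifact is also written there as CSV/JSON.
#' @export
run_pipeline <- function(weather, geno, pheno, config = pipeline_config(),
                         tams = NULL, stage_thresholds = stage_table()) {
  if (is.character(weather)) weather <- read_weather(weather)
  if (is.character(geno)) geno <- read_genotypes(geno, "vcf")
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)

  series <- build_ep_series_all(weather, tbase = config$tbase,
                                tcap = config$tcap, units = config$units,
                                pts_formula = config$pts_formula)
  rdeps <- lapply(series, rdep_profile, thresholds = stage_thresholds)
  geno <- qc_filter(geno)
  tmat <- trait_matrix(pheno)
  env_means <- environment_trait_means(tmat)

  cw <- tryCatch(
    critical_window_search(env_means, rdeps,
                           r_threshold = config$r_threshold,
                           trait = config$trait),
    error = function(e) NULL)
  pp <- NULL
  if (is.null(cw) || !nrow(cw)) {
    warning("no critical window at |r| >= ", config$r_threshold,
            "; proceeding without PP parameters")
    cw <- cw[0, ]
  } else {
    pp <- pp_parameters(tmat, cw, rdeps)
  }
  vd <- variance_decomposition(tmat)

  if (is.null(tams) && !is.null(pp) && nrow(pp)) {
    w1 <- cw[1, ]
    slopes <- pp[pp$ep == w1$ep & pp$start == w1$start & pp$end == w1$end, ]
    resp <- slopes$slope[match(rownames(geno$dosage), slopes$genotype_id)]
    scr <- association_screen(geno, resp)
    hits <- scr$marker[scr$significant]
    if (length(hits)) {
      tams <- tam_table(hits, config$trait, "PP_slope")
    }
  }
  if (!is.null(tams) && nrow(tams)) {
    fl <- extract_tam_flanks(tams, geno, mode = config$flank_mode,
                             flank_bp = config$flank_bp)
    marker_set <- fl$all
    marker_class <- "TAM"
  } else {
    marker_set <- geno$map$marker
    marker_class <- "All-SNP"
  }
  fs <- assemble_features(geno, marker_set, pheno, rdeps = rdeps,
                          ep_series = series, ep_mode = config$ep_mode,
                          marker_class = marker_class)
  cv <- make_cv_scheme(fs$rows, config$cv_scheme,
                       n_folds = config$n_folds, seed = config$seed)
  res <- evaluate_cv(fs, cv, base_learners = config$base_learners,
                     tuning_budget = config$tuning_budget,
                     seed = config$seed)
  meta <- list(seed = config$seed,
               config_hash = config_hash(unclass(config)))
  out <- list(rdeps = rdeps, critical_windows = cw, pp_params = pp,
              variance = vd, features = table(fs$provenance), cv = res,
              tams = tams, meta = meta)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config)
  out
}

write_pipeline_artifacts <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  rd <- do.call(rbind, lapply(out$rdeps, function(r) {
    data.frame(env_id = r$env_id,
               ep = rep(rownames(r$matrix), ncol(r$matrix)),
               window = rep(seq_len(ncol(r$matrix)), each = nrow(r$matrix)),
               value = as.vector(r$matrix))
  }))
  utils::write.csv(rd, p("rdep.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(out$critical_windows),
                   p("critical_windows.csv"), row.names = FALSE)
  if (!is.null(out$pp_params)) {
    utils::write.csv(as.data.frame(out$pp_params), p("pp_params.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(component = c("G", "E", "GxE_res"),
               variance = c(out$variance$var_g, out$variance$var_e,
                            out$variance$var_gxe_residual),
               share = as.numeric(out$variance$shares),
               h2 = out$variance$h2),
    p("variance_components.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(fold = seq_along(out$cv$fold_pcc), pcc = out$cv$fold_pcc),
    p("fold_pcc.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(out$meta, list(mean_pcc = out$cv$mean_pcc)),
    p("run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
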