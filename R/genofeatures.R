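# Genotype QC, linkage disequilibrium, trait-associated-marker (TAM)
# feature extraction, QTL-interval merging / co-localization, random
# baselines and a simple association screen.

#' Construct a genotype matrix object
#'
#' @param dosage Genotype x marker matrix of 0/1/2 allele dosages
#'   (`NA` allowed pre-QC); dimnames are genotype and marker ids.
#' @param map Data frame `marker`, `chrom`, `pos` (1-based bp), optional
#'   `n_alleles` (markers with > 2 are multiallelic and removed by QC).
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(map))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$marker
  stopifnot(identical(colnames(dosage), as.character(map$marker)))
  if (any(map$pos < 0)) stop("negative marker positions")
  if (is.null(map$n_alleles)) map$n_alleles <- 2L
  ord <- order(map$chrom, map$pos)
  structure(list(dosage = dosage[, ord, drop = FALSE],
                 map = map[ord, , drop = FALSE]),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d genotypes x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Quality-control filter for a genotype matrix
#'
#' Applies, in order: (1) drop markers with missing rate above
#' `max_missing`; (2) drop multiallelic markers; (3) impute remaining
#' missing calls by the marker's most frequent genotype class (a simple
#' modal-class imputation; production pipelines would impute externally
#' before import); (4) drop markers where any observed genotype class
#' (0/1/2 present post-imputation) has frequency below `min_class_freq`.
#' A class entirely absent at a locus does not trigger rule 4.
#'
#' @param geno A `geno_matrix`.
#' @param max_missing Maximum tolerated missing rate (default 0.30).
#' @param min_class_freq Minimum frequency of each observed genotype class
#'   (default 0.02).
#' @return Filtered `geno_matrix` with a `qc_report` attribute (list of
#'   counts dropped per rule and number of imputed calls).
#' @export
qc_filter <- function(geno, max_missing = 0.30, min_class_freq = 0.02) {
  d <- geno$dosage
  miss_rate <- colMeans(is.na(d))
  drop_missing <- miss_rate > max_missing
  multi <- geno$map$n_alleles > 2
  keep1 <- !drop_missing & !multi
  d <- d[, keep1, drop = FALSE]
  n_imputed <- sum(is.na(d))
  if (n_imputed) {
    for (j in which(colSums(is.na(d)) > 0)) {
      cl <- table(d[, j])
      d[is.na(d[, j]), j] <- as.numeric(names(cl)[which.max(cl)])
    }
  }
  n <- nrow(d)
  rare <- vapply(seq_len(ncol(d)), function(j) {
    f <- table(d[, j]) / n
    any(f < min_class_freq)
  }, logical(1))
  d <- d[, !rare, drop = FALSE]
  if (!ncol(d)) stop("all markers removed by QC")
  out <- geno_matrix(d, geno$map[match(colnames(d), geno$map$marker), ,
                                 drop = FALSE])
  attr(out, "qc_report") <- list(
    n_input = ncol(geno$dosage),
    dropped_missing = sum(drop_missing),
    dropped_multiallelic = sum(multi & !drop_missing),
    dropped_class_freq = sum(rare),
    n_imputed = n_imputed,
    n_retained = ncol(d)
  )
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two markers' dosage vectors.
#'
#' @param geno A post-QC `geno_matrix`.
#' @param marker_a,marker_b Marker ids.
#' @return r^2 in `[0, 1]`.
#' @export
pairwise_ld_r2 <- function(geno, marker_a, marker_b) {
  a <- geno$dosage[, marker_a]
  b <- geno$dosage[, marker_b]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("LD undefined: zero-variance marker")
  }
  stats::cor(a, b)^2
}

#' Distance-binned LD decay curve and half-max decay distance
#'
#' Computes r^2 for all intra-chromosome marker pairs within
#' `max_dist_bp`, averages per distance bin, and reports the half-max
#' decay distance (smallest bin midpoint where the mean r^2 has fallen to
#' half the first bin's mean) and, optionally, where the curve first drops
#' below `r2_threshold`.
#'
#' @param geno Post-QC `geno_matrix`, positions sorted within chromosome.
#' @param max_dist_bp Maximum pair distance considered.
#' @param bin_width Distance bin width in bp.
#' @param r2_threshold Optional absolute r^2 threshold to locate (e.g. 0.2).
#' @return List with `curve` (data frame `dist_mid`, `mean_r2`, `n_pairs`),
#'   `halfmax_dist` (`NA` with `flat = TRUE` when the curve never falls to
#'   half its initial value) and `threshold_dist`.
#' @export
ld_decay_halfmax <- function(geno, max_dist_bp = 2e6, bin_width = 1e5,
                             r2_threshold = NULL) {
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    if (length(idx) < 2) next
    pos <- geno$map$pos[idx]
    D <- geno$dosage[, idx, drop = FALSE]
    sds <- apply(D, 2, stats::sd)
    cm <- suppressWarnings(stats::cor(D[, sds > 0, drop = FALSE]))
    pos2 <- pos[sds > 0]
    if (length(pos2) < 2) next
    pr <- which(upper.tri(cm), arr.ind = TRUE)
    dd <- abs(pos2[pr[, 2]] - pos2[pr[, 1]])
    ok <- dd <= max_dist_bp
    dists <- c(dists, dd[ok])
    r2s <- c(r2s, cm[pr][ok]^2)
  }
  if (!length(dists)) stop("fewer than 2 usable markers on every chromosome")
  bin <- pmin(floor(dists / bin_width), ceiling(max_dist_bp / bin_width) - 1)
  agg <- tapply(r2s, bin, mean)
  nb <- tapply(r2s, bin, length)
  mids <- (as.numeric(names(agg)) + 0.5) * bin_width
  curve <- data.frame(dist_mid = mids, mean_r2 = as.numeric(agg),
                      n_pairs = as.integer(nb))
  half <- curve$mean_r2[1] / 2
  below <- which(curve$mean_r2 <= half)
  flat <- !length(below)
  halfmax <- if (flat) NA_real_ else curve$dist_mid[min(below)]
  thr_dist <- NA_real_
  if (!is.null(r2_threshold)) {
    b <- which(curve$mean_r2 < r2_threshold)
    if (length(b)) thr_dist <- curve$dist_mid[min(b)]
  }
  list(curve = curve, halfmax_dist = halfmax, flat = flat,
       threshold_dist = thr_dist)
}

#' Build a TAM table
#'
#' @param marker Marker ids (must exist in the genotype map when used).
#' @param trait Trait name per row.
#' @param category One of `"Main"`, `"GxE"`, `"PP_slope"`, `"PP_intercept"`.
#' @param effect Optional effect sizes.
#' @return Data frame of class `tam_table`.
#' @export
tam_table <- function(marker, trait, category, effect = NA_real_) {
  category <- match.arg(category, c("Main", "GxE", "PP_slope",
                                    "PP_intercept"), several.ok = TRUE)
  structure(data.frame(marker = marker, trait = trait,
                       category = category, effect = effect,
                       stringsAsFactors = FALSE),
            class = c("tam_table", "data.frame"))
}

.check_tams_mapped <- function(tams, geno) {
  absent <- setdiff(unique(tams$marker), geno$map$marker)
  if (length(absent)) {
    stop("TAM(s) absent from the genotype map: ",
         paste(absent, collapse = ", "))
  }
}

#' Marker feature sets around TAMs
#'
#' Expands each TAM into a flank of neighbouring markers and returns the
#' de-duplicated marker sets per feature class: `main` (Main-TAMs plus
#' flanks), `e` (G-by-E and PP TAMs plus flanks) and `all` (their union).
#' `fixed_bp` mode takes every marker within `flank_bp` of the TAM;
#' `ld_r2` mode walks outward from the TAM while contiguous markers keep
#' r^2 >= `r2_min` with it.
#'
#' @param tams A `tam_table` (single trait).
#' @param geno Post-QC `geno_matrix`.
#' @param mode `"fixed_bp"` (default) or `"ld_r2"`.
#' @param flank_bp Flank half-width in bp (default 37000).
#' @param r2_min LD threshold for `ld_r2` mode (default 0.5).
#' @return List `all`, `main`, `e` of marker-id character vectors.
#' @export
extract_tam_flanks <- function(tams, geno, mode = c("fixed_bp", "ld_r2"),
                               flank_bp = 37000, r2_min = 0.5) {
  mode <- match.arg(mode)
  .check_tams_mapped(tams, geno)
  map <- geno$map
  expand <- function(mk) {
    i <- match(mk, map$marker)
    ch <- map$chrom[i]; p <- map$pos[i]
    on_ch <- which(map$chrom == ch)
    if (mode == "fixed_bp") {
      map$marker[on_ch[abs(map$pos[on_ch] - p) <= flank_bp]]
    } else {
      j <- which(on_ch == i)
      sel <- j
      for (dir in c(-1L, 1L)) {
        k <- j + dir
        while (k >= 1 && k <= length(on_ch)) {
          r2 <- tryCatch(pairwise_ld_r2(geno, mk, map$marker[on_ch[k]]),
                         error = function(e) 0)
          if (r2 < r2_min) break
          sel <- c(sel, k)
          k <- k + dir
        }
      }
      map$marker[on_ch[sort(sel)]]
    }
  }
  sets <- function(mk) {
    if (!length(mk)) return(character(0))
    unique(unlist(lapply(unique(mk), expand)))
  }
  main_tams <- tams$marker[tams$category == "Main"]
  e_tams <- tams$marker[tams$category %in% c("GxE", "PP_slope",
                                             "PP_intercept")]
  main_set <- sets(main_tams)
  e_set <- sets(e_tams)
  list(all = unique(c(main_set, e_set)), main = main_set, e = e_set)
}

#' Merge TAM-centred QTL intervals
#'
#' Each TAM defines the closed interval `[pos - half_width_bp,
#' pos + half_width_bp]` (clipped below at 1, coordinates 1-based);
#' intervals of the same trait and category on one chromosome are merged
#' when they overlap or touch.
#'
#' @param tams A `tam_table`.
#' @param geno_map Data frame `marker`, `chrom`, `pos` (or a
#'   `geno_matrix`).
#' @param half_width_bp Interval half-width (default 1e6).
#' @param by_category Merge separately per category (default `TRUE`);
#'   `FALSE` pools all categories of a trait.
#' @return Data frame `trait`, `category`, `chrom`, `start`, `end` with
#'   disjoint sorted intervals per group (class `qtl_intervals`).
#' @export
merge_qtl_intervals <- function(tams, geno_map, half_width_bp = 1e6,
                                by_category = TRUE) {
  if (inherits(geno_map, "geno_matrix")) geno_map <- geno_map$map
  absent <- setdiff(unique(tams$marker), geno_map$marker)
  if (length(absent)) {
    stop("TAM(s) absent from the genotype map: ",
         paste(absent, collapse = ", "))
  }
  i <- match(tams$marker, geno_map$marker)
  df <- data.frame(trait = tams$trait,
                   category = if (by_category) tams$category else "all",
                   chrom = geno_map$chrom[i],
                   start = pmax(geno_map$pos[i] - half_width_bp, 1),
                   end = geno_map$pos[i] + half_width_bp)
  grp <- split(df, list(df$trait, df$category, df$chrom), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    st <- g$start[1]; en <- g$end[1]; res <- NULL
    for (r in seq_len(nrow(g))[-1]) {
      if (g$start[r] <= en) en <- max(en, g$end[r])
      else {
        res <- rbind(res, data.frame(start = st, end = en))
        st <- g$start[r]; en <- g$end[r]
      }
    }
    res <- rbind(res, data.frame(start = st, end = en))
    data.frame(trait = g$trait[1], category = g$category[1],
               chrom = g$chrom[1], res, row.names = NULL)
  }))
  rownames(out) <- NULL
  out <- out[order(out$trait, out$category, out$chrom, out$start), ,
             drop = FALSE]
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Co-localization between two QTL interval sets
#'
#' Two intervals co-localize when they share at least 1 bp on the same
#' chromosome. Reports the number of co-localized intervals in each set
#' and their shares of each set's total.
#'
#' @param qtls_a,qtls_b Interval data frames (`chrom`, `start`, `end`)
#'   for the same trait.
#' @return List `n_pairs`, `n_a`, `n_b`, `share_a` (= n_a / |A|),
#'   `share_b` (= n_b / |B|).
#' @export
colocalization_stats <- function(qtls_a, qtls_b) {
  hit_a <- rep(FALSE, nrow(qtls_a))
  hit_b <- rep(FALSE, nrow(qtls_b))
  n_pairs <- 0L
  for (i in seq_len(nrow(qtls_a))) {
    for (j in seq_len(nrow(qtls_b))) {
      if (qtls_a$chrom[i] == qtls_b$chrom[j] &&
          qtls_a$start[i] <= qtls_b$end[j] &&
          qtls_a$end[i] >= qtls_b$start[j]) {
        n_pairs <- n_pairs + 1L
        hit_a[i] <- TRUE; hit_b[j] <- TRUE
      }
    }
  }
  list(n_pairs = n_pairs, n_a = sum(hit_a), n_b = sum(hit_b),
       share_a = if (nrow(qtls_a)) sum(hit_a) / nrow(qtls_a) else NA_real_,
       share_b = if (nrow(qtls_b)) sum(hit_b) / nrow(qtls_b) else NA_real_)
}

#' Random-marker baseline feature sets
#'
#' `random1` draws as many random anchor markers as there are distinct
#' TAMs and expands each by the same flank rule as the TAM sets;
#' `random2` draws exactly `n_target` markers uniformly (matched to the
#' All-TAMs-plus-flanks feature count). Reproducible under `seed`.
#'
#' @param geno Post-QC `geno_matrix`.
#' @param tams A `tam_table` (for `random1`'s anchor count).
#' @param scheme `"random1"` or `"random2"`.
#' @param n_target Feature count to match (`random2`).
#' @param seed Integer seed.
#' @param ... Flank arguments passed to [extract_tam_flanks()]
#'   (`mode`, `flank_bp`, `r2_min`) for `random1`.
#' @return Character vector of marker ids.
#' @export
random_marker_baseline <- function(geno, tams = NULL,
                                   scheme = c("random1", "random2"),
                                   n_target = NULL, seed = 1, ...) {
  scheme <- match.arg(scheme)
  markers <- geno$map$marker
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  if (scheme == "random1") {
    if (is.null(tams)) stop("random1 needs the TAM table for its anchor count")
    n_anchor <- length(unique(tams$marker))
    if (n_anchor > length(markers)) stop("more anchors requested than markers")
    anchors <- sample(markers, n_anchor)
    fl <- extract_tam_flanks(tam_table(anchors, "random", "Main"),
                             geno, ...)
    fl$main
  } else {
    if (is.null(n_target)) stop("random2 needs n_target")
    if (n_target > length(markers)) stop("n_target exceeds available markers")
    sample(markers, n_target)
  }
}

# Scoped RNG: seed the generator, return a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Single-marker association screen
#'
#' A light association screen used to produce TAM tables on synthetic
#' data: per marker, ordinary least squares of the response on the marker
#' dosage plus the top `n_pcs` genotype principal components (population
#' structure), with a Bonferroni significance flag. Not a substitute for a
#' dedicated multi-locus mixed-model GWAS on real data; the TAM table is
#' the interface where external GWAS results enter.
#'
#' @param geno Post-QC `geno_matrix`.
#' @param response Numeric response aligned to the genotype rows (e.g. a
#'   PP slope per genotype).
#' @param n_pcs Number of genotype principal components as covariates.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Data frame `marker`, `beta`, `statistic`, `p`, `significant`.
#' @export
association_screen <- function(geno, response, n_pcs = 3, alpha = 0.05) {
  X <- geno$dosage
  n <- nrow(X)
  if (length(response) != n) stop("response not aligned to genotypes")
  if (n < 10) stop("need >= 10 genotypes")
  if (stats::sd(response) == 0) stop("constant response")
  keep <- !is.na(response)
  X <- X[keep, , drop = FALSE]; y <- response[keep]; n <- length(y)
  C <- matrix(1, n, 1)
  if (n_pcs > 0) {
    pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                             drop = FALSE]
    C <- cbind(C, pcs)
  }
  # project response and dosages off the covariate space, then marginal OLS
  Q <- qr.Q(qr(C))
  yr <- y - Q %*% crossprod(Q, y)
  Xr <- X - Q %*% crossprod(Q, X)
  sy <- drop(crossprod(yr))
  sxx <- colSums(Xr^2)
  sxy <- drop(crossprod(Xr, yr))
  df <- n - ncol(C) - 1
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  r2 <- ifelse(sxx > 0 & sy > 0, sxy^2 / (sxx * sy), NA_real_)
  r2 <- pmin(r2, 1)
  tstat <- sign(beta) * sqrt(pmax(r2, 0) * df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(marker = geno$map$marker, beta = beta, statistic = tstat,
             p = p, significant = !is.na(p) & p <= alpha / sum(!is.na(p)),
             row.names = NULL)
}
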