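test_that("QC drops planted violations and exactly those", {
  set.seed(51)
  n <- 100
  # 10 markers: 7 clean, one 40% missing, one multiallelic, one rare class
  clean <- function() rbinom(n, 2, 0.5)
  d <- sapply(1:10, function(i) clean())
  d[sample(n, 40), 8] <- NA                    # missing rate 0.40
  d[, 9] <- c(rep(0, 50), rep(1, 49), 2)       # class freq 0.01 < 0.02
  colnames(d) <- paste0("M", 1:10)
  g <- geno_matrix(d, data.frame(marker = colnames(d), chrom = 1,
                                 pos = 1:10 * 1e3,
                                 n_alleles = c(rep(2, 9), 3)))
  qc <- qc_filter(g)
  rep_ <- attr(qc, "qc_report")
  expect_equal(rep_$dropped_missing, 1)
  expect_equal(rep_$dropped_multiallelic, 1)
  expect_equal(rep_$dropped_class_freq, 1)
  expect_equal(ncol(qc$dosage), 7)
  expect_false(anyNA(qc$dosage))
})

test_that("QC is idempotent and imputes by the modal class", {
  set.seed(52)
  d <- sapply(1:6, function(i) rbinom(80, 2, 0.4))
  d[1:5, 2] <- NA # 6% missing, below threshold -> imputed
  colnames(d) <- paste0("M", 1:6)
  g <- toy_geno(d)
  q1 <- qc_filter(g)
  modal <- as.numeric(names(which.max(table(d[-(1:5), 2]))))
  expect_true(all(q1$dosage[1:5, "M2"] == modal))
  q2 <- qc_filter(q1)
  expect_equal(q2$dosage, q1$dosage)
  expect_equal(q2$map, q1$map)
  # an absent class does not trigger the frequency rule
  d3 <- cbind(M1 = rep(c(0, 2), 40), M2 = rbinom(80, 2, 0.5))
  expect_equal(ncol(qc_filter(toy_geno(d3))$dosage), 2)
})

test_that("pairwise LD r2 is the squared dosage correlation", {
  x <- rbinom(200, 2, 0.5)
  g <- toy_geno(cbind(M1 = x, M2 = x, M3 = 2 - x,
                      M4 = rbinom(200, 2, 0.5)))
  expect_equal(pairwise_ld_r2(g, "M1", "M2"), 1)
  expect_equal(pairwise_ld_r2(g, "M1", "M3"), 1) # complement: sign-free
  expect_error(pairwise_ld_r2(toy_geno(cbind(M1 = rep(1, 10), M2 = rbinom(10, 2, .5))),
                              "M1", "M2"), "zero-variance")
  # independent markers at n = 2000: r2 near zero
  set.seed(53)
  gi <- toy_geno(cbind(A = rbinom(2000, 2, 0.3), B = rbinom(2000, 2, 0.3)))
  expect_lt(pairwise_ld_r2(gi, "A", "B"), 0.01)
})

test_that("LD decay half-max lands at the simulated block scale", {
  set.seed(54)
  # 40 blocks of 10 tightly linked markers (block span 90 kb), independent
  # across blocks
  cfg <- sim_config(n_genotypes = 300, n_markers = 400, ld_block_len = 10,
                    flip_prob = 0.02, marker_spacing_bp = 10000,
                    n_chrom = 4, seed = 54)
  g <- simulate_genotypes(cfg)
  ld <- ld_decay_halfmax(g, max_dist_bp = 4e5, bin_width = 2e4,
                         r2_threshold = 0.2)
  B <- 10 * 10000 # block length in bp
  expect_gt(ld$halfmax_dist, 0.5 * B * 0.5)
  expect_lt(ld$halfmax_dist, 1.5 * B)
  expect_false(ld$flat)
  expect_true(is.finite(ld$threshold_dist))

  # duplicated marker at all distances: flat curve, half-max undefined
  x <- rbinom(100, 2, 0.5)
  gd <- toy_geno(cbind(M1 = x, M2 = x, M3 = x, M4 = x),
                 pos = c(1e3, 5e4, 2e5, 9e5))
  ldd <- ld_decay_halfmax(gd, max_dist_bp = 1e6, bin_width = 1e5)
  expect_true(ldd$flat)
  expect_true(is.na(ldd$halfmax_dist))
  expect_true(all(ldd$curve$mean_r2 == 1))

  # three markers on one chromosome -> exactly 3 pairs
  set.seed(55)
  g3 <- toy_geno(sapply(1:3, function(i) rbinom(50, 2, 0.5)),
                 pos = c(1e3, 2e3, 3e3))
  l3 <- ld_decay_halfmax(g3, max_dist_bp = 1e4, bin_width = 1e4)
  expect_equal(sum(l3$curve$n_pairs), 3)
})

test_that("fixed-bp TAM flanks select markers by distance", {
  d <- sapply(1:5, function(i) rbinom(50, 2, 0.5))
  colnames(d) <- c("L50", "L10", "TAM", "R10", "R50")
  g <- toy_geno(d, pos = c(100e3 - 5e4, 100e3 - 1e4, 100e3,
                           100e3 + 1e4, 100e3 + 5e4))
  tams <- tam_table("TAM", "t", "Main")
  fl <- extract_tam_flanks(tams, g, mode = "fixed_bp", flank_bp = 37000)
  expect_setequal(fl$main, c("L10", "TAM", "R10"))
  expect_setequal(fl$all, fl$main)
  expect_equal(fl$e, character(0))
  expect_error(extract_tam_flanks(tam_table("nope", "t", "Main"), g),
               "absent")
})

test_that("overlapping flanks union without duplicates; classes compose", {
  d <- sapply(1:6, function(i) rbinom(60, 2, 0.5))
  colnames(d) <- paste0("M", 1:6)
  g <- toy_geno(d, pos = c(1, 2, 3, 4, 5, 6) * 1e4)
  tams <- tam_table(c("M2", "M3", "M5"), "t", c("Main", "Main", "GxE"))
  fl <- extract_tam_flanks(tams, g, flank_bp = 15000)
  expect_equal(anyDuplicated(fl$all), 0)
  expect_setequal(fl$main, c("M1", "M2", "M3", "M4"))
  expect_setequal(fl$e, c("M4", "M5", "M6"))
  expect_setequal(fl$all, paste0("M", 1:6))
})

test_that("LD-mode flanks stop where r2 falls below the threshold", {
  set.seed(56)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  near <- function(p_keep) ifelse(rbinom(n, 1, p_keep) == 1, base,
                                  rbinom(n, 2, 0.5))
  # 5 markers tightly linked to the TAM, then independent ones
  d <- cbind(A1 = near(.95), A2 = near(.95), TAM = base, B1 = near(.95),
             B2 = near(.95), B3 = near(.95),
             FAR1 = rbinom(n, 2, 0.5), FAR2 = rbinom(n, 2, 0.5))
  g <- toy_geno(d, pos = seq_len(8) * 1000)
  fl <- extract_tam_flanks(tam_table("TAM", "t", "Main"), g, mode = "ld_r2",
                           r2_min = 0.5)
  expect_setequal(fl$main, c("A1", "A2", "TAM", "B1", "B2", "B3"))
})

test_that("fixed-bp flanks are symmetric under coordinate reflection", {
  set.seed(57)
  d <- sapply(1:9, function(i) rbinom(40, 2, 0.5))
  colnames(d) <- paste0("M", 1:9)
  pos <- sort(sample(1e6, 9))
  g <- toy_geno(d, pos = pos)
  tams <- tam_table("M5", "t", "Main")
  fl <- extract_tam_flanks(tams, g, flank_bp = 2e5)
  # reflect coordinates around a large constant
  gr <- toy_geno(d[, 9:1], pos = rev(2e6 - pos))
  flr <- extract_tam_flanks(tams, gr, flank_bp = 2e5)
  expect_setequal(fl$main, flr$main)
})

test_that("QTL intervals merge overlapping TAM windows", {
  g <- toy_geno(matrix(rbinom(40 * 4, 2, .5), 40),
                pos = c(5e6, 6e6, 1e6, 10e6))
  tams <- tam_table(c("M1", "M2"), "t", "GxE")
  q <- merge_qtl_intervals(tams, g, half_width_bp = 1e6)
  expect_equal(nrow(q), 1)
  expect_equal(q$start, 4e6)
  expect_equal(q$end, 7e6)

  q2 <- merge_qtl_intervals(tam_table(c("M3", "M4"), "t", "GxE"), g)
  expect_equal(nrow(q2), 2)
  expect_equal(q2$start[1], 1) # clipped at the chromosome start
})

test_that("interval merging matches a sweep-line oracle and is order-invariant", {
  set.seed(58)
  for (rep in 1:20) {
    n <- 10
    pos <- sort(sample(2e7, n))
    d <- matrix(rbinom(10 * n, 2, 0.5), 10)
    colnames(d) <- paste0("M", 1:n)
    g <- toy_geno(d, pos = pos)
    tams <- tam_table(paste0("M", 1:n), "t", "GxE")
    got <- merge_qtl_intervals(tams, g, half_width_bp = 1e6)
    want <- sweep_merge_oracle(pmax(pos - 1e6, 1), pos + 1e6)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want[, 1])
    expect_equal(got$end, want[, 2])
    # disjoint and sorted
    if (nrow(got) > 1) expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    # permutation of TAM rows changes nothing
    perm <- sample(n)
    got2 <- merge_qtl_intervals(tams[perm, ], g, half_width_bp = 1e6)
    expect_equal(got2, got)
  }
})

test_that("co-localization counts overlapping intervals and shares", {
  a <- data.frame(chrom = 1, start = c(1, 100), end = c(10, 110))
  expect_equal(colocalization_stats(a, a)$share_a, 1)
  expect_equal(colocalization_stats(a, a)$share_b, 1)

  b <- data.frame(chrom = 1, start = c(50, 200), end = c(60, 210))
  expect_equal(colocalization_stats(a, b)$n_pairs, 0)

  # planted 5-of-35 vs 5-of-20 overlap: shares 14.3% and 25.0%
  A <- data.frame(chrom = 1, start = (1:35) * 1000, end = (1:35) * 1000 + 10)
  B <- data.frame(chrom = 1, start = (1:20) * 1000 + 500,
                  end = (1:20) * 1000 + 510)
  B$start[1:5] <- A$start[1:5]; B$end[1:5] <- A$end[1:5]
  st <- colocalization_stats(A, B)
  expect_equal(st$n_a, 5); expect_equal(st$n_b, 5)
  expect_equal(round(100 * st$share_a, 1), 14.3)
  expect_equal(round(100 * st$share_b, 1), 25.0)
})

test_that("random baselines are seeded and sized by construction", {
  set.seed(59)
  d <- sapply(1:50, function(i) rbinom(40, 2, 0.5))
  colnames(d) <- paste0("M", 1:50)
  g <- toy_geno(d)
  tams <- tam_table(c("M5", "M20"), "t", c("Main", "GxE"))
  r1a <- random_marker_baseline(g, tams, "random1", seed = 4,
                                flank_bp = 1500)
  r1b <- random_marker_baseline(g, tams, "random1", seed = 4,
                                flank_bp = 1500)
  expect_identical(r1a, r1b)
  r2 <- random_marker_baseline(g, scheme = "random2", n_target = 12,
                               seed = 4)
  expect_equal(length(r2), 12)
  expect_error(random_marker_baseline(g, scheme = "random2", n_target = 99,
                                      seed = 1), "exceeds")
})

test_that("association screen finds planted signals and stays calibrated", {
  set.seed(61)
  n <- 150; m <- 120
  d <- sapply(1:m, function(i) rbinom(n, 2, runif(1, 0.2, 0.5)))
  colnames(d) <- paste0("M", 1:m)
  g <- toy_geno(d)
  # pure planted signal: the causal marker has the top statistic
  y <- 5 * d[, 17]
  scr <- association_screen(g, y, n_pcs = 2)
  expect_equal(scr$marker[which.max(abs(scr$statistic))], "M17")
  expect_true(scr$significant[17])

  expect_error(association_screen(g, rep(1, n)), "constant")

  # null responses: Bonferroni keeps family-wise error near alpha
  set.seed(62)
  fp <- vapply(1:60, function(i) {
    any(association_screen(g, rnorm(n), n_pcs = 0)$significant)
  }, logical(1))
  expect_lt(mean(fp), 0.15) # alpha 0.05 plus binomial slack at 60 reps
})
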