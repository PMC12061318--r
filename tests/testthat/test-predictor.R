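test_that("pcc is plain Pearson r with NA for constants", {
  expect_equal(pcc(1:5, 1:5), 1)
  expect_equal(pcc(1:5, -(1:5)), -1)
  # closed-form check for a small pair
  o <- c(1, 2, 3, 4); p <- c(1.1, 1.9, 3.2, 3.8)
  r_hand <- sum((o - mean(o)) * (p - mean(p))) /
    sqrt(sum((o - mean(o))^2) * sum((p - mean(p))^2))
  expect_equal(pcc(o, p), r_hand, tolerance = 1e-12)
  expect_equal(round(pcc(o, p), 4), 0.9908)
  expect_warning(v <- pcc(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(v))
  expect_error(pcc(1:2, 1:2), "length")
})

test_that("pcc is invariant to positive affine transforms", {
  set.seed(71)
  o <- rnorm(30); p <- o + rnorm(30, 0, 0.5)
  base <- pcc(o, p)
  expect_equal(pcc(2 * o + 3, p), base, tolerance = 1e-12)
  expect_equal(pcc(o, 0.1 * p - 7), base, tolerance = 1e-12)
})

test_that("percent change follows the ratio formula", {
  expect_equal(round(percent_change(0.736, 0.878), 2), 19.29)
  expect_equal(round(percent_change(0.482, 0.619), 2), 28.42)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("feature assembly shapes rows and EP columns correctly", {
  cfg <- sim_config(n_genotypes = 3, n_markers = 20, n_envs = 2,
                    n_main_qtl = 3, n_slope_qtl = 2, seed = 72)
  tr <- simulate_trial(cfg)
  mk <- colnames(tr$geno$dosage)[1:5]

  fs0 <- assemble_features(tr$geno, mk, tr$pheno, ep_mode = "none")
  expect_equal(nrow(fs0$X), 6) # 3 genotypes x 2 envs
  expect_equal(ncol(fs0$X), 5)
  expect_true(all(fs0$provenance == "marker"))

  fsr <- assemble_features(tr$geno, mk, tr$pheno, rdeps = tr$rdeps,
                           ep_mode = "reduced")
  expect_equal(sum(fsr$provenance == "RD_EP"), 9 * 36)
  # EP sub-vectors identical within an environment
  same_env <- which(fsr$rows$env_id == fsr$rows$env_id[1])
  epcols <- fsr$provenance == "RD_EP"
  expect_equal(fsr$X[same_env[1], epcols], fsr$X[same_env[2], epcols])

  fsw <- assemble_features(tr$geno, mk, tr$pheno, ep_series = tr$ep_series,
                           ep_mode = "raw")
  dmin <- min(vapply(tr$ep_series, function(s) nrow(s$eps), integer(1)))
  expect_equal(sum(fsw$provenance == "Raw_EP"), 9 * dmin)

  expect_error(assemble_features(tr$geno, c(mk, "nope"), tr$pheno), "nope")
  expect_error(assemble_features(tr$geno, mk, tr$pheno, rdeps = tr$rdeps[1],
                                 ep_mode = "reduced"), "without an RD_EP")
})

test_that("cross-validation schemes honour their exclusion contracts", {
  rows <- expand.grid(genotype_id = paste0("g", 1:20),
                      env_id = paste0("e", 1:7),
                      stringsAsFactors = FALSE)

  ff <- make_cv_scheme(rows, "fivefold", seed = 3)
  sizes <- lengths(lapply(ff$folds, `[[`, "test"))
  expect_equal(sum(sizes), nrow(rows))
  expect_equal(sort(unique(unlist(lapply(ff$folds, `[[`, "test")))),
               seq_len(nrow(rows)))
  expect_true(max(sizes) - min(sizes) <= 1)

  s2 <- make_cv_scheme(rows, "scenario2", seed = 3)
  expect_equal(length(s2$folds), 7) # one fold per environment
  for (f in s2$folds) {
    expect_equal(length(unique(rows$env_id[f$test])), 1)
    expect_false(rows$env_id[f$test][1] %in% rows$env_id[f$train])
  }

  s1 <- make_cv_scheme(rows, "scenario1", n_repeats = 4, seed = 3)
  expect_equal(length(s1$folds), 4)
  for (f in s1$folds) {
    expect_length(intersect(rows$genotype_id[f$test],
                            rows$genotype_id[f$train]), 0)
  }

  s3 <- make_cv_scheme(rows, "scenario3", seed = 3)
  for (f in s3$folds) {
    expect_length(intersect(rows$genotype_id[f$test],
                            rows$genotype_id[f$train]), 0)
    expect_length(intersect(rows$env_id[f$test], rows$env_id[f$train]), 0)
    expect_length(intersect(f$train, f$test), 0)
  }

  one_env <- rows[rows$env_id == "e1", ]
  expect_error(make_cv_scheme(one_env, "scenario2"), "environment")
})

test_that("a realizable linear target is fit almost perfectly by the ridge", {
  set.seed(73)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] + 10
  m <- train_stacked_ensemble(list(X = X, y = y),
                              base_learners = "bayes_ridge", seed = 1)
  expect_gt(pcc(y, m$fitted), 0.999)
})

test_that("stacking is deterministic and reproducible under a seed", {
  cfg <- sim_config(n_genotypes = 40, n_markers = 60, n_envs = 3, seed = 74)
  tr <- simulate_trial(cfg)
  fs <- assemble_features(tr$geno, colnames(tr$geno$dosage), tr$pheno,
                          rdeps = tr$rdeps, ep_mode = "reduced")
  m1 <- train_stacked_ensemble(fs, base_learners = c("xgb_depth",
                                                     "bayes_ridge"),
                               tuning_budget = 2, seed = 9,
                               spaces = tiny_spaces())
  m2 <- train_stacked_ensemble(fs, base_learners = c("xgb_depth",
                                                     "bayes_ridge"),
                               tuning_budget = 2, seed = 9,
                               spaces = tiny_spaces())
  expect_identical(m1$meta, m2$meta)
  expect_identical(m1$fitted, m2$fitted)
  expect_identical(m1$config_hash, m2$config_hash)
  # meta weights are non-negative
  expect_true(all(m1$meta$weights >= 0))
})

test_that("prediction enforces the training schema and permutes with rows", {
  set.seed(75)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X %*% c(1, -1, 2, 0) + rnorm(60, 0, 0.1)
  m <- train_stacked_ensemble(list(X = X, y = drop(y)),
                              base_learners = "bayes_ridge", seed = 2)
  expect_equal(predict(m, X), m$fitted)
  # single row accepted
  expect_length(predict(m, X[1, , drop = FALSE]), 1)
  # permuting rows permutes predictions
  p <- sample(60)
  expect_equal(predict(m, X[p, ]), m$fitted[p])
  # schema errors name the offending columns
  expect_error(predict(m, X[, 1:3]), "missing.*f4")
  X5 <- cbind(X, extra = 1)
  expect_error(predict(m, X5), "extra")
})

test_that("tuning budget must be positive and trials respect it", {
  expect_error(tune_params(learner_spaces()$xgb_depth, function(p) 1,
                           budget = 0), "budget")
  res <- tune_params(list(x = list(type = "num", lower = -2, upper = 2)),
                     function(p) (p$x - 1)^2, budget = 25, seed = 3)
  expect_equal(nrow(res$trials), 25)
  # guided search concentrates near the optimum on a smooth 1-d problem
  expect_lt(abs(res$best_params$x - 1), 0.5)
})

test_that("the NNLS meta-learner never harms relative to its best base", {
  cfg <- sim_config(n_genotypes = 50, n_markers = 80, n_envs = 4, seed = 76)
  tr <- simulate_trial(cfg)
  fs <- assemble_features(tr$geno, colnames(tr$geno$dosage), tr$pheno,
                          rdeps = tr$rdeps, ep_mode = "reduced")
  cv <- make_cv_scheme(fs$rows, "fivefold", seed = 4)
  ens <- evaluate_cv(fs, cv, base_learners = c("xgb_depth", "bayes_ridge"),
                     tuning_budget = 2, seed = 5, spaces = tiny_spaces())
  single <- evaluate_cv(fs, cv, base_learners = "bayes_ridge",
                        tuning_budget = 1, seed = 5)
  expect_gte(ens$mean_pcc, single$mean_pcc - 0.005)
})

test_that("permutation importance ranks a planted dominant feature first", {
  set.seed(77)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 5 * X[, 3] + rnorm(n, 0, 0.3)
  m <- train_stacked_ensemble(list(X = X, y = y),
                              base_learners = "bayes_ridge", seed = 6)
  imp <- permutation_importance(m, X, y, n_repeats = 3, seed = 8)
  expect_equal(imp$feature[1], "f3")
  expect_gt(imp$importance[1], 10 * max(abs(imp$importance[-1])))
  # determinism
  imp2 <- permutation_importance(m, X, y, n_repeats = 3, seed = 8)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(m, X[1:10, ], y[1:10]), ">= 30")
})
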