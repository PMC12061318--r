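# Shared fixture builders; everything generated in code.

# n days of constant weather for one environment
constant_weather <- function(env_id = "E1", n = 3, tmax = 80, tmin = 60,
                             dl = 12, start = as.Date("2020-05-01")) {
  data.frame(env_id = env_id, date = start + seq_len(n) - 1,
             tmax = tmax, tmin = tmin, day_length = dl, rh = 60, pre = 0,
             par = 20)
}

# rdep object built directly from a window-mean matrix + day counts
manual_rdep <- function(mat, days, env_id = "E1") {
  structure(list(env_id = env_id, matrix = mat, window_days = days,
                 stage = colnames(mat)),
            class = "rdep")
}

# random rdep profiles for n_env environments with W stages and the 9 EPs
random_rdeps <- function(n_env, W, seed = 1) {
  set.seed(seed)
  eps <- envirogs::ep_names()
  out <- lapply(seq_len(n_env), function(i) {
    m <- matrix(rnorm(9 * W), 9, W,
                dimnames = list(eps, paste0("S", seq_len(W))))
    manual_rdep(m, days = sample(1:5, W, replace = TRUE),
                env_id = sprintf("E%02d", i))
  })
  names(out) <- sprintf("E%02d", seq_len(n_env))
  # equal day counts across environments keep the brute-force oracle simple
  for (i in seq_along(out)) out[[i]]$window_days <- out[[1]]$window_days
  out
}

# independent brute-force critical-window enumeration (the oracle):
# plain double loop over every (ep, A, B), day-weighted means, cor()
brute_force_windows <- function(env_means, rdeps, r_threshold) {
  eps <- rownames(rdeps[[1]]$matrix)
  W <- ncol(rdeps[[1]]$matrix)
  res <- list()
  for (ep in eps) {
    for (A in 1:W) {
      for (B in A:W) {
        v <- vapply(names(env_means), function(e) {
          r <- rdeps[[e]]
          d <- r$window_days[A:B]
          sum(r$matrix[ep, A:B] * d) / sum(d)
        }, numeric(1))
        if (sd(v) == 0) next
        r <- cor(v, as.numeric(env_means))
        if (abs(r) >= r_threshold) {
          res[[length(res) + 1]] <- data.frame(ep = ep, start = A, end = B,
                                               r = r)
        }
      }
    }
  }
  if (!length(res)) return(data.frame(ep = character(), start = integer(),
                                      end = integer(), r = numeric()))
  do.call(rbind, res)
}

# small geno matrix from an explicit dosage matrix
toy_geno <- function(dosage, chrom = 1, pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1000
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("M", seq_len(ncol(dosage)))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("G", seq_len(nrow(dosage)))
  }
  envirogs::geno_matrix(dosage, data.frame(marker = colnames(dosage),
                                           chrom = chrom, pos = pos))
}

# sweep-line interval merge oracle over raw (start, end) pairs
sweep_merge_oracle <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out <- rbind(out, c(ms, me)); ms <- start[i]; me <- end[i] }
  }
  rbind(out, c(ms, me))
}

# fast tuning space for tests
tiny_spaces <- function() envirogs::learner_spaces(nrounds_max = 60,
                                                   max_depth_max = 4)
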