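small_training <- function(n = 20L, seed = 3L, noise_sd = 0) {
  ds <- synth_dataset(n = n, seed = seed, noise_sd = noise_sd)
  list(attrs = lapply(ds$data$smiles, extract_attributes),
       y = ds$data$endpoint, ds = ds)
}

test_that("the target function scores correlation with degenerate sentinel", {
  x <- c(1, 2, 3, 4)
  expect_equal(target_function(2 * x + 1, x), 1)
  expect_equal(target_function(rep(1, 4), x), -1)   # zero variance sentinel
  expect_error(target_function(numeric(0), numeric(0)), "empty")
  # planted weights score at least as high as perturbed tables (noiseless)
  tr <- small_training(5L, seed = 12L)
  univ <- sort(unique(unlist(lapply(tr$attrs, names))))
  m <- cwqsar:::attribute_matrix(tr$attrs, univ)
  w_true <- tr$ds$planted$weights[univ]
  t_true <- target_function(as.numeric(m %*% w_true), tr$y)
  set.seed(4)
  for (i in 1:20) {
    w_pert <- w_true + rnorm(length(w_true), sd = 0.3)
    expect_lte(target_function(as.numeric(m %*% w_pert), tr$y),
               t_true + 1e-12)
  }
})

test_that("balance mode rewards agreement between subsets", {
  x <- c(1, 2, 3, 4, 5, 6)
  calib <- c(rep(FALSE, 3), rep(TRUE, 3))
  t_bal <- target_function(2 * x, x, mode = "balance", calib = calib)
  expect_equal(t_bal, 1 + 1 - 0)   # perfect in both halves
})

test_that("zero epochs keep the initialization but still calibrate", {
  tr <- small_training()
  run <- mc_optimize(tr$attrs, tr$y, descriptor_config(epochs_N = 0), seed = 1)
  expect_true(all(run$weights == 1))
  expect_true(is.finite(run$calibration$C0) && is.finite(run$calibration$C1))
  expect_length(run$trace, 1L)
})

test_that("optimization is deterministic in the seed and monotone in epochs", {
  tr <- small_training()
  cfg <- descriptor_config(epochs_N = 6)
  r1 <- mc_optimize(tr$attrs, tr$y, cfg, seed = 42)
  r2 <- mc_optimize(tr$attrs, tr$y, cfg, seed = 42)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$trace, r2$trace)
  r3 <- mc_optimize(tr$attrs, tr$y, cfg, seed = 43)
  expect_false(identical(r1$weights, r3$weights))
  expect_true(all(diff(r1$trace) >= 0))
  # the optimizer leaves the caller's RNG stream untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(mc_optimize(tr$attrs, tr$y, cfg, seed = 1))
  expect_identical(runif(1), before)
})

test_that("all attributes blocked at a high threshold is an error", {
  tr <- small_training(5L)
  expect_error(
    mc_optimize(tr$attrs, tr$y, descriptor_config(threshold_T = 100)),
    "blocked at threshold")
})

test_that("ensembles repeat the optimization across seeds", {
  tr <- small_training()
  cfg <- descriptor_config(epochs_N = 2)
  expect_warning(runs <- run_ensemble(tr$attrs, tr$y, cfg, seeds = c(1, 1)),
                 "duplicate")
  expect_identical(runs[[1]]$weights, runs[[2]]$weights)
  runs3 <- run_ensemble(tr$attrs, tr$y, cfg, seeds = c(1, 2, 3))
  expect_length(runs3, 3L)
  expect_equal(vapply(runs3, `[[`, 1L, "seed"), 1:3)
  expect_error(run_ensemble(tr$attrs, tr$y, cfg, seeds = integer(0)), "seed")
})

test_that("a planted model is recovered on the standard training harness", {
  # 60 training molecules, 5% relative noise, DCW(1, 10)
  ds <- synth_dataset(n = 75, seed = 7)
  fit <- cw_qsar(ds$data, ds$split, descriptor_config(epochs_N = 10), seed = 7)
  tr <- fit$data$set == "training"
  expect_gte(sum(tr), 60L)
  r2 <- cor(fit$data$endpoint[tr], fit$data$predicted[tr])^2
  expect_gte(r2, 0.8)
})

test_that("validation quality varies across random splits of one dataset", {
  ds <- synth_dataset(n = 120, seed = 7)
  r2 <- vapply(1:5, function(k) {
    split <- make_splits(ds$data, "random", c(0.8, 0.2), seed = k)
    fit <- cw_qsar(ds$data, split, descriptor_config(epochs_N = 4), seed = 1)
    v <- fit$data$set == "validation"
    cor(fit$data$endpoint[v], fit$data$predicted[v])^2
  }, numeric(1))
  expect_gt(max(r2) - min(r2), 0)
})
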