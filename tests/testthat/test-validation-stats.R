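test_that("pearson_r matches hand evaluations and handles degeneracy", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, 5:1), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("CCC penalizes location and scale shifts", {
  expect_equal(ccc(1:4, 1:4), 1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(8); y <- rnorm(8)
    r <- pearson_r(x, y)
    expect_lte(abs(ccc(x, y)), abs(r) + 1e-12)
  }
  # any shift of y strictly lowers CCC below |r|
  x <- rnorm(6); y <- x + 2
  expect_lt(abs(ccc(x, y)), abs(pearson_r(x, y)))
})

test_that("through-origin slopes and r0 follow the printed definitions", {
  y <- c(1.2, 2.1, 2.9, 4.2)
  to <- through_origin(y, y)
  expect_equal(to$k, 1); expect_equal(to$k_primed, 1)
  expect_equal(to$r0_sq, 1); expect_equal(to$r0_sq_primed, 1)
  to2 <- through_origin(y, 2 * y)
  expect_equal(to2$k, 0.5)
  expect_equal(to2$k_primed, 2)
  obs <- c(1, 2, 3); pred <- c(1.1, 1.9, 3.2)
  to3 <- through_origin(obs, pred)
  orc <- oracle_through_origin(obs, pred)
  expect_equal(to3$k, orc$k)
  expect_equal(to3$k_primed, orc$k_primed)
  expect_equal(to3$r0_sq, orc$r0_sq)
  expect_equal(to3$r0_sq_primed, orc$r0_sq_primed)
})

test_that("the Q2 family uses the right reference means", {
  obs <- c(0.5, 1.5, 2.5, 3.5)
  q <- q2_family(obs, obs, training_context(c(0, 1, 2, 3)))
  expect_equal(unlist(q), c(q2 = 1, q2_f1 = 1, q2_f2 = 1, q2_f3 = 1))
  # when training and external means coincide, F1 = F2
  ctx <- training_context(c(1, 2, 3))    # mean 2
  q2 <- q2_family(c(1, 2, 3), c(1.1, 2.2, 2.7), ctx)
  expect_equal(q2$q2_f1, q2$q2_f2)
  # hand-oracle case
  q3 <- q2_family(c(0, 1, 2), c(0, 1, 4), training_context(c(0, 1, 2)))
  orc <- oracle_q2(c(0, 1, 2), c(0, 1, 4), c(0, 1, 2))
  expect_equal(q3$q2_f1, orc$q2_f1)
  expect_equal(q3$q2_f2, orc$q2_f2)
  expect_equal(q3$q2_f3, orc$q2_f3)
})

test_that("LOO Q2 of the calibration matches explicit refitting", {
  set.seed(2)
  x <- rnorm(12); y <- 1 + 2 * x + rnorm(12, sd = 0.3)
  press <- 0
  for (i in seq_along(x)) {
    cal <- calibrate_linear(x[-i], y[-i])
    press <- press + (y[i] - cal$C0 - cal$C1 * x[i])^2
  }
  expect_equal(q2_loo(x, y), 1 - press / sum((y - mean(y))^2))
})

test_that("rm2 metrics follow both variants of the formula", {
  obs <- c(1, 2, 3, 4); pred <- obs
  m <- rm2_metrics(obs, pred)
  expect_equal(m$rm2_avg, 1); expect_equal(m$rm2_delta, 0)
  # against the directional formula built from its own components
  obs <- c(0.4, 1.1, 2.3, 2.9, 4.2); pred <- c(0.7, 1.0, 2.0, 3.3, 3.8)
  r2 <- pearson_r(obs, pred)^2
  to <- through_origin(obs, pred)
  m2 <- rm2_metrics(obs, pred, variant = "sqrt")
  expect_equal(m2$rm2, r2 * (1 - sqrt(abs(r2 - to$r0_sq))))
  m3 <- rm2_metrics(obs, pred, variant = "literal")
  expect_equal(m3$rm2, r2 * (1 - abs(r2 - to$r0_sq)))
  # the printed spot value: r2 = 0.81, r0 = 0.77 gives 0.648 (sqrt form)
  expect_equal(0.81 * (1 - sqrt(abs(0.81 - 0.77))), 0.648)
})

test_that("IIC balances the two residual classes", {
  obs <- c(0, 1, 2, 3)
  d <- 0.2
  calc <- obs + c(-d, d, -d, d)
  expect_equal(iic(obs, calc, r_calibration = 0.9), 0.9)
  # one-sided residuals give IIC = 0 by the empty-class rule
  expect_equal(iic(obs, obs - 0.1), 0)
  # hand evaluation: MAE- = 0.15, MAE+ = 0.1, ratio 2/3
  expect_equal(iic(c(0, 1, 2, 3), c(0.1, 0.9, 2.2, 2.9), r_calibration = 1),
               2 / 3)
})

test_that("every statistic matches the brute-force oracle to 1e-12", {
  set.seed(915)
  for (i in 1:100) {
    p <- random_pairing(n = sample(5:30, 1))
    y_train <- rnorm(sample(5:20, 1))
    ctx <- training_context(y_train)
    rep <- criteria_report(p$obs, p$pred, context = ctx)
    expect_equal(rep$r, oracle_pearson(p$obs, p$pred), tolerance = 1e-12)
    expect_equal(rep$ccc, oracle_ccc(p$obs, p$pred), tolerance = 1e-12)
    orc_to <- oracle_through_origin(p$obs, p$pred)
    expect_equal(rep$k, orc_to$k, tolerance = 1e-12)
    expect_equal(rep$k_primed, orc_to$k_primed, tolerance = 1e-12)
    expect_equal(rep$r0_sq, orc_to$r0_sq, tolerance = 1e-12)
    expect_equal(rep$r0_sq_primed, orc_to$r0_sq_primed, tolerance = 1e-12)
    orc_q <- oracle_q2(p$obs, p$pred, y_train)
    expect_equal(rep$q2, orc_q$q2, tolerance = 1e-12)
    expect_equal(rep$q2_f1, orc_q$q2_f1, tolerance = 1e-12)
    expect_equal(rep$q2_f2, orc_q$q2_f2, tolerance = 1e-12)
    expect_equal(rep$q2_f3, orc_q$q2_f3, tolerance = 1e-12)
    orc_rm <- oracle_rm2(p$obs, p$pred)
    expect_equal(rep$rm2_avg, orc_rm$rm2_avg, tolerance = 1e-12)
    expect_equal(rep$rm2_delta, orc_rm$rm2_delta, tolerance = 1e-12)
    expect_equal(rep$iic, oracle_iic(p$obs, p$pred, rep$r), tolerance = 1e-12)
  }
})

test_that("the full report degrades gracefully and flags sensibly", {
  obs <- c(1, 2, 3, 4, 5)
  rep <- criteria_report(obs, obs)
  expect_equal(rep$r, 1); expect_equal(rep$ccc, 1); expect_equal(rep$q2, 1)
  expect_true(rep$flags$gt_pass)
  # without a training context the F1/F3 variants are absent, not zero
  rep2 <- criteria_report(obs, obs + rnorm(5, sd = 0.1))
  expect_true(is.na(rep2$q2_f1))
  expect_true(is.na(rep2$q2_f3))
  # reports on two different splits of the same data can disagree
  ds <- synth_dataset(n = 80, seed = 13)
  q2s <- vapply(1:2, function(k) {
    split <- make_splits(ds$data, "random", c(0.75, 0.25), seed = k)
    fit <- cw_qsar(ds$data, split, descriptor_config(epochs_N = 3), seed = 5)
    v <- fit$data$set == "validation"
    tr <- !v
    criteria_report(fit$data$endpoint[v], fit$data$predicted[v],
                    context = training_context(fit$data$endpoint[tr]))$q2
  }, numeric(1))
  expect_false(isTRUE(all.equal(q2s[1], q2s[2])))
})
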