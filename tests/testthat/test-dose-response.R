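test_that("normalization maps basal to 0 and reference maximum to 100", {
  # basal mean 200, reference max mean 1200 -> raw 700 maps to 50
  ds <- data.frame(
    ligand = c("veh", "veh", "norepi", "norepi", "norepi", "test", "test",
               "test", "test"),
    receptor = "b2ar", pathway = "arrestin",
    dose = c(0, 0, 1e-8, 1e-7, 1e-6, 1e-9, 1e-8, 1e-7, 1e-6),
    signal = c(190, 210, 600, 1150, 1200, 700, 200, 1200, 900),
    replicate = "1", stringsAsFactors = FALSE
  )
  class(ds) <- c("dose_response_dataset", "data.frame")
  curves <- normalize_responses(ds, "norepi")
  test <- curves[[which(vapply(curves, attr, "", "ligand") == "test")]]
  expect_equal(test$response[test$dose == 1e-9], 50)
  expect_equal(test$response[test$dose == 1e-8], 0)    # equals basal mean
  expect_equal(test$response[test$dose == 1e-7], 100)  # equals reference max

  expect_error(normalize_responses(ds[ds$dose > 0, ], "norepi"),
               "vehicle")
  expect_error(normalize_responses(ds, "missing-ref"), "reference ligand")
})

test_that("4PL fit recovers noise-free parameters and enforces preconditions", {
  d <- 10^seq(-10, -4, length.out = 8)
  y <- hill_curve <- 100 / (1 + 10^((-7 - log10(d))))
  fit <- fit_hill(d, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate[["log_ec50"]] - (-7)), 1e-6)
  expect_lt(abs(fit$estimate[["emax"]] - 100), 1e-4)
  expect_lt(abs(fit$estimate[["hill_n"]] - 1), 1e-5)

  expect_error(fit_hill(d[1:3], y[1:3]), "4 distinct doses")

  flat <- fit_hill(d, rep(50, 8))
  expect_false(flat$converged)
  expect_match(flat$status, "unidentifiable")

  fb <- fit_hill(d, y, mode = "fixed_basal_zero")
  expect_equal(fb$estimate[["basal"]], 0)
  expect_lt(abs(fb$estimate[["log_ec50"]] - (-7)), 1e-6)
})

test_that("4PL fit is scale- and dose-unit-equivariant", {
  set.seed(7)
  for (i in 1:4) {
    truth <- c(basal = runif(1, 0, 10), emax = runif(1, 60, 120),
               log_ec50 = runif(1, -8.5, -5.5), hill_n = runif(1, 0.7, 1.6))
    d <- 10^seq(-10, -4, length.out = 9)
    y <- truth[["basal"]] + (truth[["emax"]] - truth[["basal"]]) /
      (1 + 10^(truth[["hill_n"]] * (truth[["log_ec50"]] - log10(d))))
    base <- fit_hill(d, y)
    truth_ord <- truth[names(base$estimate)]
    expect_lt(max(abs(base$estimate - truth_ord) / pmax(abs(truth_ord), 1)),
              1e-4)

    sc <- fit_hill(d, 3.5 * y)
    expect_lt(abs(sc$estimate[["log_ec50"]] - base$estimate[["log_ec50"]]), 1e-7)
    expect_lt(abs(sc$estimate[["hill_n"]] - base$estimate[["hill_n"]]), 1e-7)
    expect_lt(abs(sc$estimate[["emax"]] - 3.5 * base$estimate[["emax"]]), 1e-5)

    du <- fit_hill(d * 1e6, y)  # dose unit scaling shifts log EC50 only
    expect_lt(abs(du$estimate[["log_ec50"]] - (base$estimate[["log_ec50"]] + 6)),
              1e-6)
    expect_lt(abs(du$estimate[["hill_n"]] - base$estimate[["hill_n"]]), 1e-6)
  }
})

test_that("4PL Monte-Carlo recovery is unbiased with calibrated intervals", {
  d <- 10^seq(-10, -4, length.out = 8)
  mu <- 100 / (1 + 10^((-7 - log10(d))))
  set.seed(1)
  est <- se <- dof <- numeric(100)
  for (i in 1:100) {
    fit <- fit_hill(d, mu + rnorm(8, 0, 2))
    est[i] <- fit$estimate[["log_ec50"]]
    se[i] <- fit$se[["log_ec50"]]
    dof[i] <- fit$dof
  }
  expect_lt(abs(mean(est) - (-7)), 0.05)
  # 95% CI with the fit's residual degrees of freedom (t-quantile)
  coverage <- mean(abs(est - (-7)) <= qt(0.975, dof) * se)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("single-exponential fits recover rates and flag misuse", {
  t <- seq(0, 600, by = 20)
  rise <- fit_single_exponential(t, 50 * (1 - exp(-0.01 * t)), mode = "rise")
  expect_lt(abs(rise$rate_k - 0.01) / 0.01, 1e-6)

  decay <- fit_single_exponential(t, 20 + 30 * exp(-0.02 * t), mode = "decay")
  expect_lt(abs(decay$rate_k - 0.02) / 0.02, 1e-6)
  expect_lt(abs(decay$offset - 20), 1e-6)

  const <- fit_single_exponential(t, rep(5, length(t)))
  expect_false(const$converged)
  expect_equal(const$amplitude, 0)

  # decay data fitted in rise mode is detected via amplitude sign
  wrong <- fit_single_exponential(t, 20 + 30 * exp(-0.02 * t), mode = "rise")
  expect_true(wrong$wrong_mode)

  expect_error(fit_single_exponential(t, 50 * (1 - exp(-0.01 * t)),
                                      window = c(1e4, 2e4)),
               "window excludes")
})

test_that("rate-vs-dose pipeline composes the two fitting stages", {
  doses <- 10^seq(-10, -5, length.out = 8)
  k_true <- 0.002 + (0.02 - 0.002) / (1 + 10^((-7.5 - log10(doses))))
  t <- seq(0, 400, by = 13)
  mk <- function(k) 80 * (1 - exp(-k * t))
  dataset <- do.call(rbind, lapply(seq_along(doses), function(i) {
    data.frame(dose = doses[i], time = t, signal = mk(k_true[i]))
  }))
  fit <- camp_rate_dose_response(dataset, window = c(5, 305))
  expect_lt(abs(fit$estimate[["log_ec50"]] - (-7.5)), 1e-4)
  expect_equal(nrow(fit$rates), 8L)

  # a constant trace is excluded with a warning, fit proceeds
  dataset$signal[dataset$dose == doses[1]] <- 10
  expect_warning(fit2 <- camp_rate_dose_response(dataset, window = c(5, 305)),
                 "excluded")
  expect_equal(nrow(fit2$rates), 7L)
  expect_lt(abs(fit2$estimate[["log_ec50"]] - (-7.5)), 0.05)

  # noisy recovery at the study design: 8 concentrations, 3% noise
  set.seed(7)
  noisy <- do.call(rbind, lapply(seq_along(doses), function(i) {
    data.frame(dose = doses[i], time = t,
               signal = mk(k_true[i]) + rnorm(length(t), 0, 0.03 * 80))
  }))
  fit3 <- camp_rate_dose_response(noisy, window = c(5, 305))
  expect_lt(abs(fit3$estimate[["log_ec50"]] - (-7.5)), 0.1)
})

test_that("replicate averaging scheme agrees with pooling on clean data", {
  d <- rep(10^seq(-10, -4, length.out = 8), 2)
  y <- 100 / (1 + 10^((-7 - log10(d))))
  rep_id <- rep(c("r1", "r2"), each = 8)
  pooled <- fit_hill(d, y, replicate = rep_id)
  averaged <- fit_hill(d, y, replicate = rep_id, replicates = "average")
  expect_lt(abs(pooled$estimate[["log_ec50"]] -
                  averaged$estimate[["log_ec50"]]), 1e-6)
})
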