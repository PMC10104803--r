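doses9 <- 10^seq(-10, -4, length.out = 9)

make_pathway <- function(ligand_tab, em = 100, n = 1, pathway = "P1",
                         receptor = "R1", scale = 1) {
  lapply(seq_len(nrow(ligand_tab)), function(i) {
    y <- op_response(doses9, em, n, ligand_tab$log_tau[i],
                     ligand_tab$log_ka[i]) * scale
    normalized_curve(doses9, y, ligand = ligand_tab$ligand[i],
                     receptor = receptor, pathway = pathway)
  })
}

test_that("operational fit recovers log(tau/KA) on noise-free curves", {
  tab <- data.frame(ligand = c("ref", "test"),
                    log_tau = c(1.0, -0.3), log_ka = c(-6.5, -7.0))
  curves <- make_pathway(tab)

  # with the system maximum anchored, tau and KA separate exactly
  anchored <- fit_operational(curves, "ref", full_threshold = 1.5,
                              em_fixed = 100)
  expect_lt(abs(anchored$ligands$log_r[1] - 7.5), 1e-3)
  expect_lt(abs(anchored$ligands$log_r[2] - 6.7), 1e-3)
  expect_lt(abs(anchored$ligands$log_tau[2] - (-0.3)), 1e-3)

  # default classification: reference is full, fitted in the limiting
  # form; Delta log(tau/KA) is recovered exactly even though absolute
  # coefficients shift with the em convention
  fit <- fit_operational(curves, "ref")
  expect_identical(fit$ligands$class, c("full", "partial"))
  delta <- fit$ligands$log_r[2] - fit$ligands$log_r[1]
  expect_lt(abs(delta - (-0.8)), 1e-4)
  # log_r of a full agonist is the directly fitted parameter
  expect_true(is.na(fit$ligands$log_tau[1]))

  expect_error(fit_operational(curves[1], "ref"), "at least 2")
  expect_error(fit_operational(curves, "nope"), "not among")
})

test_that("high-efficacy limit plateaus at the system maximum", {
  tab <- data.frame(ligand = c("ref", "test"),
                    log_tau = c(3, 3), log_ka = c(-6.5, -7.5))
  curves <- make_pathway(tab)
  plateau <- max(curves[[1]]$response)
  fit <- fit_operational(curves, "ref")
  expect_lt(abs(fit$em - plateau) / plateau, 1e-3)
  expect_match(fit$status, "anchored")
})

test_that("delta-method SE of log_r matches the joint covariance", {
  tab <- data.frame(ligand = c("ref", "test"),
                    log_tau = c(1.0, -0.3), log_ka = c(-6.5, -7.0))
  curves <- make_pathway(tab)
  set.seed(11)
  noisy <- lapply(curves, function(cv) {
    normalized_curve(cv$dose, cv$response + rnorm(nrow(cv), 0, 2),
                     ligand = attr(cv, "ligand"),
                     receptor = attr(cv, "receptor"),
                     pathway = attr(cv, "pathway"))
  })
  fit <- fit_operational(noisy, "ref")
  i <- which(fit$ligands$class == "partial")
  nt <- paste0("log_tau.", fit$ligands$ligand[i])
  nk <- paste0("log_ka.", fit$ligands$ligand[i])
  manual <- sqrt(fit$cov[nt, nt] + fit$cov[nk, nk] - 2 * fit$cov[nt, nk])
  expect_equal(fit$ligands$se_log_r[i], manual, tolerance = 1e-12)
})

test_that("bias algebra: self-identity, antisymmetry, chain rule, quadrature", {
  coeffs <- data.frame(
    ligand = rep(c("A", "B", "C"), 2), receptor = "R1",
    pathway = rep(c("P1", "P2"), each = 3),
    log_r = c(7.5, 7.0, 6.2, 7.1, 6.8, 6.9),
    se_log_r = 0.1, stringsAsFactors = FALSE
  )
  self <- bias_factor(coeffs, "A", "A", "P1", "P2")
  expect_identical(unname(self$re), c(1, 1))
  expect_identical(self$bias_factor, 1)

  ab <- bias_factor(coeffs, "A", "B", "P1", "P2")
  ba <- bias_factor(coeffs, "A", "B", "P2", "P1")
  expect_lt(abs(ab$bias_factor * ba$bias_factor - 1), 1e-12)

  # chain rule on delta within a pathway
  d_ab <- ab$delta_log_r[["P1"]]
  d_bc <- bias_factor(coeffs, "B", "C", "P1", "P2")$delta_log_r[["P1"]]
  d_ac <- bias_factor(coeffs, "A", "C", "P1", "P2")$delta_log_r[["P1"]]
  expect_lt(abs(d_ac - (d_ab + d_bc)), 1e-12)

  # SE quadrature: four coefficients at 0.1 -> se(delta delta) = 0.2
  expect_equal(ab$se_delta_delta, 0.2, tolerance = 1e-12)

  # delta_log_r of 0.5 and -0.2 -> bias factor 10^0.7 = 5.012
  c2 <- data.frame(ligand = rep(c("A", "B"), 2), receptor = "R1",
                   pathway = rep(c("P1", "P2"), each = 2),
                   log_r = c(7.5, 7.0, 6.8, 7.0), se_log_r = 0.05)
  b2 <- bias_factor(c2, "A", "B", "P1", "P2")
  expect_equal(b2$delta_delta_log_r, 0.7, tolerance = 1e-12)
  expect_equal(b2$bias_factor, 10^0.7, tolerance = 1e-12)
  expect_equal(round(b2$bias_factor, 3), 5.012)

  bad <- coeffs; bad$receptor <- rep(c("R1", "R2"), 3)
  expect_error(bias_factor(bad, "A", "B", "P1", "P2"), "one receptor")
})

test_that("pathway-level system scaling leaves delta log(tau/KA) unchanged", {
  tab <- data.frame(ligand = c("ref", "test"),
                    log_tau = c(1.0, -0.3), log_ka = c(-6.5, -7.0))
  base <- fit_operational(make_pathway(tab), "ref")
  scaled <- fit_operational(make_pathway(tab, scale = 0.55), "ref")
  d0 <- diff(base$ligands$log_r)
  d1 <- diff(scaled$ligands$log_r)
  expect_lt(abs(d1 - d0), 1e-3)
})

test_that("bias_table reports every test ligand against the reference", {
  coeffs <- data.frame(
    ligand = rep(c("ref", "t1", "t2"), 2), receptor = "R1",
    pathway = rep(c("camp", "arrestin"), each = 3),
    log_r = c(7.3, 6.7, 6.1, 7.3, 7.4, 6.0), se_log_r = 0.08,
    stringsAsFactors = FALSE
  )
  tab <- bias_table(coeffs, "ref", "arrestin", "camp")
  expect_equal(nrow(tab), 2L)
  t1 <- tab[tab$test_ligand == "t1", ]
  expect_equal(t1$delta_delta_log_r, 0.7, tolerance = 1e-12)
  expect_equal(t1$re_a, 10^0.1, tolerance = 1e-12)
  expect_equal(t1$re_b, 10^-0.6, tolerance = 1e-12)
})

test_that("Monte-Carlo calibration: delta log_r unbiased, SEs near-nominal", {
  res <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    c1 <- normalized_curve(doses9,
                           op_response(doses9, 100, 1, 1.0, -6.5) +
                             rnorm(9, 0, 3), ligand = "ref")
    c2 <- normalized_curve(doses9,
                           op_response(doses9, 100, 1, -0.3, -7.0) +
                             rnorm(9, 0, 3), ligand = "test")
    f <- fit_operational(list(c1, c2), "ref")
    c(delta = f$ligands$log_r[2] - f$ligands$log_r[1],
      se = sqrt(sum(f$ligands$se_log_r^2)))
  }, c(delta = 0, se = 0))
  expect_lt(abs(mean(res["delta", ]) - (-0.8)), 0.05)
  ratio <- sd(res["delta", ]) / mean(res["se", ])
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})
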