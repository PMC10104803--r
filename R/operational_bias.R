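# Operational model of agonism and ligand-bias arithmetic.
#
# For one (receptor, pathway) the response to agonist concentration A is
#   E = Em * tau^n * A^n / ((A + KA)^n + tau^n * A^n)
# with Em (system maximum) and n (transducer slope) shared across
# ligands, and tau (efficacy) and KA (functional affinity) per ligand.
# The transduction coefficient log(tau/KA) is the unit of all bias
# arithmetic: Delta log(tau/KA) against a reference agonist gives the
# relative effectiveness RE = 10^Delta, and the difference of Deltas
# across two pathways gives the bias factor 10^DeltaDelta.
#
# For a full agonist (plateau at the system maximum) tau and KA are not
# separately identifiable; the curve is fitted in the limiting form
#   E = Em * (R A)^n / (1 + (R A)^n),  R = tau/KA,
# where only log(R) = log(tau/KA) enters.

op_model_partial <- function(A, em, n, tau, ka) {
  em * (tau * A)^n / ((A + ka)^n + (tau * A)^n)
}

op_model_full <- function(A, em, n, r) {
  em * (r * A)^n / (1 + (r * A)^n)
}

#' Fit the operational model of agonism across ligands in one pathway
#'
#' Global least-squares fit over all ligand curves of one
#' (receptor, pathway), sharing the system maximum `em` and transducer
#' slope `trans_n` across ligands. Ligands whose observed plateau is at
#' least `full_threshold` of the largest plateau in the group are
#' treated as full agonists and fitted in the reparameterized limiting
#' form where only `log_r = log10(tau/KA)` is identifiable; partial
#' agonists get separate `log_tau` and `log_ka`. If every ligand is a
#' full agonist, `em` is anchored to the reference ligand's observed
#' plateau (with a status note), since it is then not separately
#' identifiable.
#'
#' @param curves list of [normalized_curve()] objects for a single
#'   (receptor, pathway); at least two ligands.
#' @param reference_ligand ligand id of the reference agonist.
#' @param full_threshold relative-plateau cutoff classifying full
#'   agonists (default 0.9).
#' @param trans_n_bounds bounds on the transducer slope (default
#'   `c(0.3, 3)`).
#' @param em_fixed optional known system maximum; when supplied, `em` is
#'   held at this value instead of being fitted. Without a full-agonist
#'   anchor (or a slope well away from 1) `em` trades off against the
#'   per-ligand parameters, which shifts all `log_r` by a common
#'   constant — differences `Delta log_r` are unaffected, but absolute
#'   transduction coefficients are only meaningful given the anchor.
#' @return An `operational_params` object: list with `em`, `trans_n`,
#'   a per-ligand data frame `ligands` (`ligand`, `class`, `log_tau`,
#'   `log_ka`, `log_r`, `se_log_r`), the joint covariance `cov` of all
#'   fitted parameters, `receptor`, `pathway`, `reference_ligand`,
#'   `rss`, `dof`, `converged` and `status`.
#' @export
fit_operational <- function(curves, reference_ligand,
                            full_threshold = 0.9,
                            trans_n_bounds = c(0.3, 3),
                            em_fixed = NULL) {
  if (inherits(curves, "normalized_curve")) curves <- list(curves)
  ligs <- vapply(curves, attr, "", which = "ligand")
  if (anyDuplicated(ligs)) stop("one curve per ligand expected", call. = FALSE)
  if (length(curves) < 2L) {
    stop("operational fit requires at least 2 ligands", call. = FALSE)
  }
  if (!reference_ligand %in% ligs) {
    stop("reference ligand `", reference_ligand, "` not among the curves",
         call. = FALSE)
  }
  receptor <- attr(curves[[1]], "receptor")
  pathway <- attr(curves[[1]], "pathway")

  # Observed plateau per ligand: mean response at the highest dose.
  plateau <- vapply(curves, function(cv) {
    mean(cv$response[cv$dose == max(cv$dose)])
  }, 0)
  is_full <- plateau >= full_threshold * max(plateau)
  anchor_em <- all(is_full) || !is.null(em_fixed)

  # Starting values from per-ligand 4PL fits.
  hill <- lapply(curves, fit_hill)
  em0 <- max(plateau)
  start <- c(trans_n = 1)
  if (!anchor_em) start <- c(em = em0, start)
  for (i in seq_along(curves)) {
    h <- hill[[i]]$estimate
    lec <- if (is.finite(h[["log_ec50"]])) h[["log_ec50"]] else
      log10(stats::median(curves[[i]]$dose))
    if (is_full[i]) {
      start[paste0("log_r.", ligs[i])] <- -lec
    } else {
      frac <- min(max(plateau[i] / em0, 0.02), 0.95)
      tau_n <- frac / (1 - frac)          # (tau^n) from plateau fraction
      log_tau <- log10(tau_n)             # with n ~ 1
      ka <- 10^lec * ((2 + tau_n)^1 - 1)  # EC50 -> KA at n = 1
      start[paste0("log_tau.", ligs[i])] <- log_tau
      start[paste0("log_ka.", ligs[i])] <- log10(ka)
    }
  }

  user_anchor <- !is.null(em_fixed)
  em_fixed <- if (user_anchor) em_fixed
              else if (anchor_em) plateau[match(reference_ligand, ligs)]
              else NA_real_
  resid_fn <- function(par) {
    em <- if (anchor_em) em_fixed else par[["em"]]
    n <- par[["trans_n"]]
    unlist(lapply(seq_along(curves), function(i) {
      cv <- curves[[i]]
      pred <- if (is_full[i]) {
        op_model_full(cv$dose, em, n, 10^par[[paste0("log_r.", ligs[i])]])
      } else {
        op_model_partial(cv$dose, em, n,
                         10^par[[paste0("log_tau.", ligs[i])]],
                         10^par[[paste0("log_ka.", ligs[i])]])
      }
      cv$response - pred
    }), use.names = FALSE)
  }
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  names(lower) <- names(upper) <- names(start)
  lower["trans_n"] <- trans_n_bounds[1]; upper["trans_n"] <- trans_n_bounds[2]
  if (!anchor_em) lower["em"] <- 1e-6

  # Deterministic multi-start over the transducer slope.
  starts <- lapply(c(1, 0.6, 1.8), function(n0) {
    s <- start; s["trans_n"] <- n0; s
  })
  fit <- lm_multistart(resid_fn, starts, lower = lower, upper = upper)
  if (is.null(fit$par)) {
    stop("operational fit failed: ", fit$status, call. = FALSE)
  }

  par <- fit$par
  cov <- fit$cov
  em <- if (anchor_em) em_fixed else par[["em"]]
  tab <- data.frame(ligand = ligs,
                    class = ifelse(is_full, "full", "partial"),
                    log_tau = NA_real_, log_ka = NA_real_,
                    log_r = NA_real_, se_log_r = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ligs)) {
    if (is_full[i]) {
      nm <- paste0("log_r.", ligs[i])
      tab$log_r[i] <- par[[nm]]
      tab$se_log_r[i] <- if (is.null(cov)) NA_real_ else sqrt(max(cov[nm, nm], 0))
    } else {
      nt <- paste0("log_tau.", ligs[i]); nk <- paste0("log_ka.", ligs[i])
      tab$log_tau[i] <- par[[nt]]
      tab$log_ka[i] <- par[[nk]]
      tab$log_r[i] <- par[[nt]] - par[[nk]]
      tab$se_log_r[i] <- if (is.null(cov)) NA_real_ else
        sqrt(max(cov[nt, nt] + cov[nk, nk] - 2 * cov[nt, nk], 0))
    }
  }
  status <- fit$status
  if (anchor_em) {
    status <- paste0(status, if (user_anchor) "; em fixed by user" else
      "; em anchored to reference plateau (all ligands full)")
  }
  structure(list(em = em, trans_n = par[["trans_n"]], ligands = tab,
                 cov = cov, receptor = receptor, pathway = pathway,
                 reference_ligand = reference_ligand,
                 rss = fit$rss, dof = fit$dof,
                 converged = fit$converged, status = status),
            class = "operational_params")
}

#' @export
print.operational_params <- function(x, ...) {
  cat(sprintf("Operational model fit  (%s, %s)  em = %.2f, n = %.3f%s\n",
              x$receptor, x$pathway, x$em, x$trans_n,
              if (x$converged) "" else "  [NOT converged]"))
  print(x$ligands, digits = 4)
  invisible(x)
}

#' Extract transduction coefficients log10(tau/KA)
#'
#' One coefficient per ligand, with standard error taken from the joint
#' fit covariance (delta method on `log_tau - log_ka` for partial
#' agonists; directly fitted for full agonists).
#'
#' @param params a converged `operational_params` object.
#' @return data frame with `ligand`, `receptor`, `pathway`, `log_r`,
#'   `se_log_r`.
#' @export
transduction_coefficients <- function(params) {
  stopifnot(inherits(params, "operational_params"))
  if (!params$converged) {
    warning("operational fit did not converge; coefficients carry that status",
            call. = FALSE)
  }
  data.frame(ligand = params$ligands$ligand,
             receptor = params$receptor,
             pathway = params$pathway,
             log_r = params$ligands$log_r,
             se_log_r = params$ligands$se_log_r,
             stringsAsFactors = FALSE)
}

get_coef <- function(coeffs, ligand, pathway) {
  i <- which(coeffs$ligand == ligand & coeffs$pathway == pathway)
  if (length(i) != 1L) {
    stop("need exactly one coefficient for (", ligand, ", ", pathway,
         "); found ", length(i), call. = FALSE)
  }
  coeffs[i, , drop = FALSE]
}

#' Bias factor between two pathways for a (test, reference) agonist pair
#'
#' Within each pathway, `delta_log_r = log_r(test) - log_r(reference)`
#' and the relative effectiveness is `RE = 10^delta_log_r`. Across the
#' two pathways, `delta_delta = delta(pathway_a) - delta(pathway_b)` and
#' the bias factor is `10^delta_delta` (1 = unbiased; swapping the
#' pathways inverts it). Standard errors are combined in quadrature at
#' each subtraction.
#'
#' @param coeffs data frame of transduction coefficients covering both
#'   ligands in both pathways (rbind the outputs of
#'   [transduction_coefficients()] for the two pathway fits).
#' @param test,reference ligand ids.
#' @param pathway_a,pathway_b pathway ids.
#' @return A `bias_result`: list with per-pathway `delta_log_r`,
#'   `se_delta_log_r`, `re`, plus `delta_delta_log_r`,
#'   `se_delta_delta`, `bias_factor` and identifiers.
#' @export
bias_factor <- function(coeffs, test, reference, pathway_a, pathway_b) {
  if (length(unique(coeffs$receptor)) != 1L) {
    stop("bias factors compare pathways on one receptor; got receptors: ",
         paste(unique(coeffs$receptor), collapse = ", "), call. = FALSE)
  }
  ta <- get_coef(coeffs, test, pathway_a)
  ra <- get_coef(coeffs, reference, pathway_a)
  tb <- get_coef(coeffs, test, pathway_b)
  rb <- get_coef(coeffs, reference, pathway_b)
  delta_a <- ta$log_r - ra$log_r
  delta_b <- tb$log_r - rb$log_r
  se_a <- sqrt(ta$se_log_r^2 + ra$se_log_r^2)
  se_b <- sqrt(tb$se_log_r^2 + rb$se_log_r^2)
  dd <- delta_a - delta_b
  structure(list(
    test_ligand = test, reference_ligand = reference,
    receptor = coeffs$receptor[1],
    pathway_a = pathway_a, pathway_b = pathway_b,
    delta_log_r = setNames(c(delta_a, delta_b), c(pathway_a, pathway_b)),
    se_delta_log_r = setNames(c(se_a, se_b), c(pathway_a, pathway_b)),
    re = setNames(10^c(delta_a, delta_b), c(pathway_a, pathway_b)),
    delta_delta_log_r = dd,
    se_delta_delta = sqrt(se_a^2 + se_b^2),
    bias_factor = 10^dd
  ), class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Bias: %s vs %s on %s (%s over %s)\n", x$test_ligand,
              x$reference_ligand, x$receptor, x$pathway_a, x$pathway_b))
  cat(sprintf("  RE[%s] = %.3g, RE[%s] = %.3g\n", x$pathway_a, x$re[1],
              x$pathway_b, x$re[2]))
  cat(sprintf("  ddlog(tau/KA) = %.3f +/- %.3f, bias factor = %.3g\n",
              x$delta_delta_log_r, x$se_delta_delta, x$bias_factor))
  invisible(x)
}

#' Bias table for every test ligand against the reference
#'
#' Convenience wrapper producing one [bias_factor()] row per non-reference
#' ligand, in a layout suitable for a JSON/CSV report.
#'
#' @inheritParams bias_factor
#' @return data frame with one row per test ligand: per-pathway
#'   `log_r`, `delta_log_r`, `re`, and `delta_delta_log_r`,
#'   `bias_factor`, `se_delta_delta`.
#' @export
bias_table <- function(coeffs, reference, pathway_a, pathway_b) {
  tests <- setdiff(unique(coeffs$ligand), reference)
  rows <- lapply(tests, function(lig) {
    b <- bias_factor(coeffs, lig, reference, pathway_a, pathway_b)
    data.frame(test_ligand = lig, reference_ligand = reference,
               receptor = b$receptor,
               log_r_a = get_coef(coeffs, lig, pathway_a)$log_r,
               log_r_b = get_coef(coeffs, lig, pathway_b)$log_r,
               delta_log_r_a = b$delta_log_r[[1]],
               delta_log_r_b = b$delta_log_r[[2]],
               re_a = b$re[[1]], re_b = b$re[[2]],
               delta_delta_log_r = b$delta_delta_log_r,
               se_delta_delta = b$se_delta_delta,
               bias_factor = b$bias_factor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
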