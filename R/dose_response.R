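# Concentration-response analysis: normalization to a reference agonist,
# four-parameter logistic (4PL) fitting, single-exponential time-course
# rates, and the two-stage rate-vs-dose pipeline used for real-time
# second-messenger accumulation assays.

#' Normalize raw signals to basal (0%) and a reference agonist maximum (100%)
#'
#' Within each (receptor, pathway) group the basal level is the mean
#' signal of the vehicle wells (`dose == 0`) and the reference maximum is
#' the mean signal of the reference ligand at its highest dose. Every
#' measurement is mapped to
#' `100 * (signal - basal) / (reference_max - basal)`.
#'
#' @param dataset a `dose_response_dataset` (see
#'   [read_dose_response_csv()]).
#' @param reference_ligand ligand id providing the 100% anchor (e.g. the
#'   endogenous full agonist).
#' @return A list of `normalized_curve` objects, one per
#'   (ligand, receptor, pathway) with non-vehicle doses. Each is a data
#'   frame with columns `dose` (molar, ascending), `response` (percent)
#'   and `replicate`, carrying `ligand`, `receptor`, `pathway` and
#'   `reference_ligand` attributes.
#' @export
normalize_responses <- function(dataset, reference_ligand) {
  stopifnot(is.data.frame(dataset))
  groups <- split(as.data.frame(dataset),
                  list(dataset$receptor, dataset$pathway), drop = TRUE)
  out <- list()
  for (g in groups) {
    gname <- paste0("(", g$receptor[1], ", ", g$pathway[1], ")")
    basal_rows <- g$dose == 0
    if (!any(basal_rows)) {
      stop("no vehicle (dose = 0) wells in group ", gname, call. = FALSE)
    }
    ref_rows <- g$ligand == reference_ligand & g$dose > 0
    if (!any(ref_rows)) {
      stop("no reference ligand `", reference_ligand, "` wells in group ",
           gname, call. = FALSE)
    }
    basal <- mean(g$signal[basal_rows])
    ref <- g[ref_rows, , drop = FALSE]
    top_dose <- max(ref$dose)
    ref_max <- mean(ref$signal[ref$dose == top_dose])
    if (ref_max == basal) {
      stop("reference maximum equals basal in group ", gname, call. = FALSE)
    }
    g$response <- 100 * (g$signal - basal) / (ref_max - basal)
    dosed <- g[g$dose > 0, , drop = FALSE]
    for (lig in unique(dosed$ligand)) {
      d <- dosed[dosed$ligand == lig, , drop = FALSE]
      d <- d[order(d$dose), , drop = FALSE]
      curve <- normalized_curve(
        dose = d$dose, response = d$response, replicate = d$replicate,
        ligand = lig, receptor = d$receptor[1], pathway = d$pathway[1],
        reference_ligand = reference_ligand
      )
      out[[length(out) + 1L]] <- curve
    }
  }
  out
}

#' Construct a normalized concentration-response curve
#'
#' @param dose molar concentrations, strictly positive.
#' @param response responses on the percent scale (vehicle = 0,
#'   reference maximum = 100).
#' @param replicate replicate labels (recycled).
#' @param ligand,receptor,pathway,reference_ligand identifiers.
#' @return a `normalized_curve` data frame.
#' @export
normalized_curve <- function(dose, response, replicate = "1",
                             ligand = "ligand", receptor = "receptor",
                             pathway = "pathway",
                             reference_ligand = NA_character_) {
  stopifnot(length(dose) == length(response), all(dose > 0),
            all(is.finite(response)))
  ord <- order(dose)
  x <- data.frame(dose = dose[ord], response = response[ord],
                  replicate = rep_len(as.character(replicate), length(dose))[ord],
                  stringsAsFactors = FALSE)
  attr(x, "ligand") <- ligand
  attr(x, "receptor") <- receptor
  attr(x, "pathway") <- pathway
  attr(x, "reference_ligand") <- reference_ligand
  class(x) <- c("normalized_curve", "data.frame")
  x
}

# 4PL on the log10-dose scale.
hill_model <- function(dose, basal, emax, log_ec50, hill_n) {
  basal + (emax - basal) / (1 + 10^(hill_n * (log_ec50 - log10(dose))))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares 4PL fit,
#' `y = basal + (emax - basal) / (1 + 10^(n * (logEC50 - log10(dose))))`,
#' parameterized in `log10(EC50)` with the slope kept positive by a log
#' parameterization. The optimizer is Levenberg-Marquardt with a
#' deterministic multi-start: `n_starts` log-spaced EC50 initializations
#' spanning the observed dose range, best residual sum of squares wins,
#' RSS ties broken towards the slope closest to 1. Standard errors come
#' from the Gauss-Newton covariance `(J'J)^-1 * RSS / dof`.
#'
#' @param dose molar doses (strictly positive, >= 4 distinct values).
#' @param response responses (any common scale).
#' @param mode `"free_basal"` fits all four parameters;
#'   `"fixed_basal_zero"` pins `basal = 0`.
#' @param replicate optional replicate labels; with
#'   `replicates = "average"` each replicate is fitted separately and
#'   parameter estimates are averaged (SE = sd/sqrt(n)). The default
#'   pools all points into one fit.
#' @param replicates pooling scheme, `"pooled"` (default) or
#'   `"average"`.
#' @param n_starts number of EC50 multi-start seeds.
#' @return A `hill_fit`: list with `estimate` and `se` (named vectors
#'   over `log_ec50`, `emax`, `basal`, `hill_n`), `cov`, `rss`, `dof`,
#'   `converged` and `status`.
#' @examples
#' d <- 10^seq(-10, -4, length.out = 8)
#' y <- 100 / (1 + 10^(-7 - log10(d)) )  # logEC50 = -7, slope 1
#' fit_hill(d, y)$estimate
#' @export
fit_hill <- function(dose, response, mode = c("free_basal", "fixed_basal_zero"),
                     replicate = NULL, replicates = c("pooled", "average"),
                     n_starts = 7) {
  mode <- match.arg(mode)
  replicates <- match.arg(replicates)
  if (inherits(dose, "normalized_curve")) {
    curve <- dose
    dose <- curve$dose; response <- curve$response
    if (is.null(replicate)) replicate <- curve$replicate
  }
  stopifnot(length(dose) == length(response), all(dose > 0))
  if (length(unique(dose)) < 4L) {
    stop("at least 4 distinct doses are required for a 4PL fit",
         call. = FALSE)
  }
  if (!all(is.finite(response))) stop("responses must be finite", call. = FALSE)

  if (replicates == "average" && !is.null(replicate) &&
      length(unique(replicate)) > 1L) {
    fits <- lapply(split(seq_along(dose), replicate), function(i) {
      fit_hill(dose[i], response[i], mode = mode, n_starts = n_starts)
    })
    fits <- Filter(function(f) f$converged, fits)
    if (!length(fits)) {
      return(hill_fit_failure("no replicate fit converged"))
    }
    est <- do.call(rbind, lapply(fits, `[[`, "estimate"))
    return(structure(list(
      estimate = colMeans(est),
      se = apply(est, 2, stats::sd) / sqrt(nrow(est)),
      cov = NULL, rss = NA_real_, dof = NA_integer_,
      converged = TRUE, status = sprintf("average of %d replicate fits",
                                         nrow(est))
    ), class = "hill_fit"))
  }

  if (stats::sd(response) < 1e-12 * (1 + max(abs(response)))) {
    return(hill_fit_failure("responses constant: EC50 and slope unidentifiable"))
  }

  span <- range(response)
  ec50_starts <- lseq(min(dose), max(dose), n_starts)
  resid_fn <- function(par) {
    basal <- if (mode == "fixed_basal_zero") 0 else par[["basal"]]
    response - hill_model(dose, basal, par[["emax"]], par[["log_ec50"]],
                          exp(par[["log_hill"]]))
  }
  starts <- lapply(ec50_starts, function(e) {
    p <- c(emax = span[2], log_ec50 = log10(e), log_hill = 0)
    if (mode == "free_basal") p <- c(basal = span[1], p)
    p
  })
  fit <- lm_multistart(resid_fn, starts,
                       tie_fn = function(p) abs(exp(p[["log_hill"]]) - 1))
  if (is.null(fit$par)) return(hill_fit_failure(fit$status))

  hill_n <- exp(fit$par[["log_hill"]])
  basal <- if (mode == "fixed_basal_zero") 0 else fit$par[["basal"]]
  est <- c(log_ec50 = fit$par[["log_ec50"]], emax = fit$par[["emax"]],
           basal = basal, hill_n = hill_n)
  se <- c(log_ec50 = unname(fit$se["log_ec50"]),
          emax = unname(fit$se["emax"]),
          basal = if (mode == "fixed_basal_zero") 0 else unname(fit$se["basal"]),
          hill_n = hill_n * unname(fit$se["log_hill"]))  # delta method
  structure(list(estimate = est, se = se, cov = fit$cov, rss = fit$rss,
                 dof = fit$dof, converged = fit$converged,
                 status = fit$status),
            class = "hill_fit")
}

hill_fit_failure <- function(status) {
  nm <- c("log_ec50", "emax", "basal", "hill_n")
  structure(list(estimate = setNames(rep(NA_real_, 4), nm),
                 se = setNames(rep(NA_real_, 4), nm),
                 cov = NULL, rss = NA_real_, dof = NA_integer_,
                 converged = FALSE, status = status),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("4PL fit (", if (x$converged) "converged" else "NOT converged", ")\n",
      sep = "")
  print(round(rbind(estimate = x$estimate, se = x$se), 4))
  invisible(x)
}

#' Fit a single-exponential time course
#'
#' Rise mode fits `y = offset + amplitude * (1 - exp(-k t))`, decay mode
#' `y = offset + amplitude * exp(-k t)`; the rate is kept positive by a
#' log parameterization. A fitted amplitude of the wrong sign (e.g.
#' decaying data fitted in rise mode) is flagged via `wrong_mode`.
#'
#' @param time seconds.
#' @param signal signal values.
#' @param window `(t0, t1)` fit window in seconds; defaults to the full
#'   range.
#' @param mode `"rise"` or `"decay"`.
#' @return An `exp_rate_fit`: list with `rate_k` (1/s), `amplitude`,
#'   `offset`, `se` (named), `rss`, `dof`, `window`, `converged`,
#'   `wrong_mode` and `status`.
#' @export
fit_single_exponential <- function(time, signal, window = NULL,
                                   mode = c("rise", "decay")) {
  mode <- match.arg(mode)
  stopifnot(length(time) == length(signal))
  if (is.null(window)) window <- range(time)
  keep <- time >= window[1] & time <= window[2]
  if (!any(keep)) stop("fit window excludes all points", call. = FALSE)
  t <- time[keep]; y <- signal[keep]
  if (length(t) < 4L) {
    stop("at least 4 points inside the window are required", call. = FALSE)
  }
  if (stats::sd(y) < 1e-12 * (1 + max(abs(y)))) {
    return(exp_fit_failure(window, "signal constant: rate unidentifiable",
                           offset = mean(y)))
  }
  t0 <- t - min(t)  # fit relative to window start for conditioning
  span <- diff(range(t0))
  resid_fn <- function(par) {
    k <- exp(par[["log_k"]])
    pred <- if (mode == "rise") {
      par[["offset"]] + par[["amplitude"]] * (1 - exp(-k * t0))
    } else {
      par[["offset"]] + par[["amplitude"]] * exp(-k * t0)
    }
    y - pred
  }
  amp0 <- if (mode == "rise") y[length(y)] - y[1] else y[1] - y[length(y)]
  off0 <- if (mode == "rise") y[1] else y[length(y)]
  starts <- lapply(log(lseq(0.3 / span, 30 / span, 6)), function(lk) {
    c(log_k = lk, amplitude = amp0, offset = off0)
  })
  fit <- lm_multistart(resid_fn, starts)
  if (is.null(fit$par)) return(exp_fit_failure(window, fit$status))
  k <- exp(fit$par[["log_k"]])
  amplitude <- fit$par[["amplitude"]]
  # Translate offset back to absolute time origin for decay mode
  offset <- fit$par[["offset"]]
  if (mode == "decay" && min(t) > 0) amplitude <- amplitude * exp(k * min(t))
  structure(list(
    rate_k = k, amplitude = amplitude, offset = offset,
    se = c(rate_k = k * unname(fit$se["log_k"]),
           amplitude = unname(fit$se["amplitude"]),
           offset = unname(fit$se["offset"])),
    rss = fit$rss, dof = fit$dof, window = window,
    converged = fit$converged, wrong_mode = amplitude < 0,
    status = fit$status
  ), class = "exp_rate_fit")
}

exp_fit_failure <- function(window, status, offset = NA_real_) {
  structure(list(rate_k = NA_real_, amplitude = 0, offset = offset,
                 se = c(rate_k = NA_real_, amplitude = NA_real_,
                        offset = NA_real_),
                 rss = NA_real_, dof = NA_integer_, window = window,
                 converged = FALSE, wrong_mode = FALSE, status = status),
            class = "exp_rate_fit")
}

#' Rate-constant dose-response from per-dose time courses
#'
#' Two-stage pipeline for real-time accumulation assays: stage 1 fits a
#' single-exponential rise to each agonist concentration's time course
#' inside `window` (default 5-305 s) to extract a rate constant; stage 2
#' fits a 4PL to the (concentration, rate) pairs. Degenerate traces
#' (constant signal) are excluded with a warning.
#'
#' @param dataset data frame with columns `dose` (molar), `time`
#'   (seconds) and `signal`.
#' @param window stage-1 fit window in seconds.
#' @return the stage-2 `hill_fit` with a `rates` data frame
#'   (`dose`, `rate_k`, `se`) attached.
#' @export
camp_rate_dose_response <- function(dataset, window = c(5, 305)) {
  stopifnot(all(c("dose", "time", "signal") %in% names(dataset)))
  doses <- sort(unique(dataset$dose))
  if (length(doses) < 4L) {
    stop("at least 4 agonist concentrations are required", call. = FALSE)
  }
  rates <- lapply(doses, function(d) {
    tc <- dataset[dataset$dose == d, , drop = FALSE]
    fit <- fit_single_exponential(tc$time, tc$signal, window = window,
                                  mode = "rise")
    data.frame(dose = d, rate_k = fit$rate_k, se = unname(fit$se["rate_k"]),
               converged = fit$converged)
  })
  rates <- do.call(rbind, rates)
  bad <- !rates$converged | !is.finite(rates$rate_k)
  if (any(bad)) {
    warning(sum(bad), " concentration(s) excluded from the rate-dose fit ",
            "(degenerate time course)", call. = FALSE)
    rates <- rates[!bad, , drop = FALSE]
  }
  if (nrow(rates) < 4L) {
    stop("fewer than 4 usable rate constants for the stage-2 fit",
         call. = FALSE)
  }
  fit <- fit_hill(rates$dose, rates$rate_k)
  fit$rates <- rates[c("dose", "rate_k", "se")]
  fit
}
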