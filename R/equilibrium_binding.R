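# Equilibrium radioligand binding: one-site saturation (KD, Bmax),
# competition (IC50) and the Cheng-Prusoff conversion to Ki.

#' Fit one-site saturation binding
#'
#' With matched nonspecific measurements, specific binding
#' `total - nonspecific` is fitted to the hyperbola
#' `Bmax * L / (KD + L)`. Without them, a one-step model
#' `total = Bmax * L / (KD + L) + ns_slope * L` treats nonspecific
#' binding as linear in the free radioligand concentration.
#'
#' @param conc free radioligand concentrations, molar (>= 5 values
#'   spanning KD).
#' @param total total binding signal.
#' @param nonspecific optional matched nonspecific binding signal.
#' @return A `saturation_fit`: list with `kd` (molar), `bmax`,
#'   `ns_slope` (signal per molar, `NA` in subtraction mode), `se`
#'   (named), `rss`, `dof`, `converged` and `status`. If the
#'   concentration range shows no curvature (all points quasi-linear),
#'   `converged` is `FALSE` with a KD-unidentifiable status.
#' @examples
#' L <- c(0.01, 0.03, 0.1, 0.3, 1, 3) * 1e-9
#' y <- 2.7 * L / (0.080e-9 + L)
#' fit_saturation(L, y)[c("kd", "bmax")]
#' @export
fit_saturation <- function(conc, total, nonspecific = NULL) {
  stopifnot(length(conc) == length(total), all(conc > 0))
  if (length(unique(conc)) < 5L) {
    stop("at least 5 radioligand concentrations are required", call. = FALSE)
  }
  one_step <- is.null(nonspecific)
  y <- if (one_step) total else total - nonspecific

  resid_fn <- function(par) {
    kd <- 10^par[["log_kd"]]; bmax <- 10^par[["log_bmax"]]
    pred <- bmax * conc / (kd + conc)
    if (one_step) pred <- pred + par[["ns_slope"]] * conc
    y - pred
  }
  n <- length(conc)
  ord <- order(conc)
  tail_slope <- (y[ord[n]] - y[ord[n - 1]]) / (conc[ord[n]] - conc[ord[n - 1]])
  starts <- list()
  for (kd0 in lseq(min(conc), max(conc), 5)) {
    for (ns0 in if (one_step) c(0, max(tail_slope, 0)) else 0) {
      p <- c(log_kd = log10(kd0), log_bmax = log10(max(y)))
      if (one_step) p <- c(p, ns_slope = ns0)
      starts[[length(starts) + 1L]] <- p
    }
  }
  fit <- lm_multistart(resid_fn, starts)
  if (is.null(fit$par)) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, ns_slope = NA_real_,
                          se = NULL, rss = NA_real_, dof = NA_integer_,
                          converged = FALSE, status = fit$status),
                     class = "saturation_fit"))
  }
  kd <- 10^fit$par[["log_kd"]]
  bmax <- 10^fit$par[["log_bmax"]]
  status <- fit$status
  converged <- fit$converged
  if (kd > 3 * max(conc)) {  # no curvature reached: quasi-linear regime
    status <- paste0(status, "; KD above the sampled range: unidentifiable")
    converged <- FALSE
  }
  ln10 <- log(10)
  structure(list(
    kd = kd, bmax = bmax,
    ns_slope = if (one_step) fit$par[["ns_slope"]] else NA_real_,
    se = c(kd = kd * ln10 * unname(fit$se["log_kd"]),
           bmax = bmax * ln10 * unname(fit$se["log_bmax"]),
           ns_slope = if (one_step) unname(fit$se["ns_slope"]) else NA_real_),
    rss = fit$rss, dof = fit$dof, converged = converged, status = status
  ), class = "saturation_fit")
}

#' Fit a competition binding curve (IC50, optional Ki)
#'
#' Descending four-parameter logistic in log10 of the cold-ligand
#' concentration. If the radioligand concentration and its KD are
#' supplied, the IC50 is converted to Ki with [cheng_prusoff()]; a
#' fitted Hill slope outside [0.8, 1.2] sets a `one_site_caveat` flag
#' because that conversion assumes one-site competition.
#'
#' @param conc cold-ligand concentrations, molar (>= 5 values).
#' @param binding binding signal (descending with concentration).
#' @param radioligand_conc,radioligand_kd molar; both required for Ki.
#' @param fix_hill fix the slope at 1 instead of fitting it.
#' @return A `competition_fit`: list with `log_ic50`, `ic50`, `top`,
#'   `bottom`, `hill_n`, `ki`, `se` (named), `rss`, `dof`, `converged`,
#'   `one_site_caveat` and `status`.
#' @export
fit_competition <- function(conc, binding, radioligand_conc = NULL,
                            radioligand_kd = NULL, fix_hill = FALSE) {
  stopifnot(length(conc) == length(binding), all(conc > 0))
  if (length(unique(conc)) < 5L) {
    stop("at least 5 competitor concentrations are required", call. = FALSE)
  }
  if (stats::sd(binding) < 1e-12 * (1 + max(abs(binding)))) {
    return(competition_fit_failure("flat curve: IC50 unidentifiable"))
  }
  lx <- log10(conc)
  resid_fn <- function(par) {
    h <- if (fix_hill) 1 else exp(par[["log_hill"]])
    pred <- par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
      (1 + 10^(h * (lx - par[["log_ic50"]])))
    binding - pred
  }
  starts <- lapply(lseq(min(conc), max(conc), 7), function(ic0) {
    p <- c(top = max(binding), bottom = min(binding),
           log_ic50 = log10(ic0))
    if (!fix_hill) p <- c(p, log_hill = 0)
    p
  })
  fit <- lm_multistart(resid_fn, starts,
                       tie_fn = if (fix_hill) NULL else
                         function(p) abs(exp(p[["log_hill"]]) - 1))
  if (is.null(fit$par)) return(competition_fit_failure(fit$status))
  hill_n <- if (fix_hill) 1 else exp(fit$par[["log_hill"]])
  ic50 <- 10^fit$par[["log_ic50"]]
  ki <- if (!is.null(radioligand_conc) && !is.null(radioligand_kd)) {
    cheng_prusoff(ic50, radioligand_conc, radioligand_kd)
  } else NA_real_
  # warn if binding rises with concentration beyond noise
  mono_flag <- stats::cor(lx, binding) > 0.5
  structure(list(
    log_ic50 = fit$par[["log_ic50"]], ic50 = ic50,
    top = fit$par[["top"]], bottom = fit$par[["bottom"]],
    hill_n = hill_n, ki = ki,
    se = c(log_ic50 = unname(fit$se["log_ic50"]),
           top = unname(fit$se["top"]), bottom = unname(fit$se["bottom"]),
           hill_n = if (fix_hill) 0 else hill_n * unname(fit$se["log_hill"])),
    rss = fit$rss, dof = fit$dof, converged = fit$converged,
    one_site_caveat = hill_n < 0.8 || hill_n > 1.2,
    monotonicity_warning = isTRUE(mono_flag),
    status = fit$status
  ), class = "competition_fit")
}

competition_fit_failure <- function(status) {
  structure(list(log_ic50 = NA_real_, ic50 = NA_real_, top = NA_real_,
                 bottom = NA_real_, hill_n = NA_real_, ki = NA_real_,
                 se = NULL, rss = NA_real_, dof = NA_integer_,
                 converged = FALSE, one_site_caveat = FALSE,
                 monotonicity_warning = FALSE, status = status),
            class = "competition_fit")
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / KD)` where `L` is the free radioligand
#' concentration and `KD` its equilibrium dissociation constant. At
#' `L = 0` this reduces to `Ki = IC50`.
#'
#' @param ic50 molar IC50 (> 0).
#' @param radioligand_conc molar radioligand concentration (>= 0).
#' @param radioligand_kd molar radioligand KD (> 0).
#' @return Ki in molar.
#' @examples
#' cheng_prusoff(3.5e-9, 0.25e-9, 0.125e-9)  # 1.1667 nM
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  if (any(ic50 <= 0)) stop("IC50 must be positive", call. = FALSE)
  if (any(radioligand_conc < 0)) {
    stop("radioligand concentration must be non-negative", call. = FALSE)
  }
  if (any(radioligand_kd <= 0)) {
    stop("radioligand KD must be positive", call. = FALSE)
  }
  ic50 / (1 + radioligand_conc / radioligand_kd)
}
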