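# Kinetics of competitive radioligand binding.
#
# A labeled ligand L (rates k1 on, k2 off) and an unlabeled competitor I
# (rates k3 on, k4 off) bind the same receptor pool under pseudo-first-
# order conditions (no depletion of free ligand). The closed-form time
# course of labeled-ligand binding (Motulsky-Mahan solution of the
# two-species mass-action system) is used to fit the competitor's on/off
# rates from association traces recorded at several competitor
# concentrations; a direct ODE integration serves as the independent
# reference implementation.

#' Fixed kinetic parameters of the labeled radioligand
#'
#' The radioligand's own rates are inputs taken from prior saturation /
#' kinetics work; they are never co-fitted with the competitor's.
#'
#' @param k1 association rate constant, 1/(M s).
#' @param k2 dissociation rate constant, 1/s.
#' @param conc_l free labeled-ligand concentration, molar.
#' @return a `radioligand_kinetics` object (list with `k1`, `k2`,
#'   `conc_l`, and derived `kd_l = k2/k1`).
#' @export
radioligand_kinetics <- function(k1, k2, conc_l) {
  stopifnot(k1 > 0, k2 > 0, conc_l > 0)
  structure(list(k1 = k1, k2 = k2, conc_l = conc_l, kd_l = k2 / k1),
            class = "radioligand_kinetics")
}

#' Closed-form labeled-ligand binding in the presence of a competitor
#'
#' Evaluates the two-ligand mass-action time course
#' with `KA = k1 L + k2`, `KB = k3 I + k4`,
#' `S = sqrt((KA - KB)^2 + 4 k1 k3 L I)`, `KF = (KA + KB + S)/2`,
#' `KS = (KA + KB - S)/2` and `Q = Bmax k1 L / (KF - KS)`:
#'
#' `B(t) = Q * (k4 (KF - KS)/(KF KS) + (k4 - KF)/KF exp(-KF t)
#'            - (k4 - KS)/KS exp(-KS t))`.
#'
#' When the two eigenvalues nearly coincide
#' (`|KF - KS| < 1e-9 * KF`) the removable singularity is evaluated by
#' its series limit instead.
#'
#' @param t times, seconds.
#' @param rl a [radioligand_kinetics()] object.
#' @param k3 competitor association rate, 1/(M s).
#' @param k4 competitor dissociation rate, 1/s.
#' @param competitor_conc competitor concentration, molar (0 allowed).
#' @param bmax_scale signal at receptor saturation by the labeled ligand.
#' @return bound labeled-ligand signal at each `t`.
#' @export
mm_bound <- function(t, rl, k3, k4, competitor_conc, bmax_scale) {
  stopifnot(inherits(rl, "radioligand_kinetics"),
            k3 > 0, k4 > 0, competitor_conc >= 0, bmax_scale > 0)
  L <- rl$conc_l; I <- competitor_conc
  ka <- rl$k1 * L + rl$k2
  kb <- k3 * I + k4
  s <- sqrt((ka - kb)^2 + 4 * rl$k1 * k3 * L * I)
  kf <- (ka + kb + s) / 2
  ks <- (ka + kb - s) / 2
  if (!all(is.finite(c(kf, ks))) || kf <= 0 || ks <= 0) {
    stop("non-finite or non-positive eigenvalues in competitive-kinetics ",
         "closed form (k1L+k2 = ", ka, ", k3I+k4 = ", kb, ")", call. = FALSE)
  }
  pre <- bmax_scale * rl$k1 * L
  if (kf - ks < 1e-9 * kf) {
    k <- (kf + ks) / 2   # coincident-eigenvalue series limit
    return(pre * (k4 / k^2 * (1 - exp(-k * t)) -
                    t * exp(-k * t) * (k4 / k - 1)))
  }
  q <- pre / (kf - ks)
  q * (k4 * (kf - ks) / (kf * ks) +
         (k4 - kf) / kf * exp(-kf * t) -
         (k4 - ks) / ks * exp(-ks * t))
}

#' Equilibrium labeled-ligand binding under competition
#'
#' The `t -> Inf` limit of [mm_bound()]:
#' `Bmax * L / (L + KD_L * (1 + I / KD_I))` with `KD_L = k2/k1` and
#' `KD_I = k4/k3`.
#'
#' @inheritParams mm_bound
#' @return equilibrium bound signal.
#' @export
mm_equilibrium <- function(rl, k3, k4, competitor_conc, bmax_scale) {
  kd_i <- k4 / k3
  bmax_scale * rl$conc_l /
    (rl$conc_l + rl$kd_l * (1 + competitor_conc / kd_i))
}

#' Integrate the two-species mass-action system (reference implementation)
#'
#' Numerically solves
#' `dRL/dt = k1 L (Bmax - RL - RI) - k2 RL` and
#' `dRI/dt = k3 I (Bmax - RL - RI) - k4 RI`
#' from empty receptors at `t = 0`, with free ligand concentrations held
#' constant (no depletion), using a stiff-capable solver at tight
#' tolerances. This is the independent oracle against which the closed
#' form [mm_bound()] is validated.
#'
#' @inheritParams mm_bound
#' @param t_grid increasing time grid, seconds (0 is prepended if
#'   absent).
#' @param rtol,atol solver tolerances.
#' @return labeled-ligand bound signal on `t_grid`.
#' @export
simulate_ode <- function(rl, k3, k4, competitor_conc, bmax_scale, t_grid,
                         rtol = 1e-10, atol = NULL) {
  stopifnot(inherits(rl, "radioligand_kinetics"), !is.unsorted(t_grid))
  if (is.null(atol)) atol <- 1e-12 * bmax_scale
  grid <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  deriv <- function(t, y, p) {
    free <- bmax_scale - y[1] - y[2]
    list(c(rl$k1 * rl$conc_l * free - rl$k2 * y[1],
           k3 * competitor_conc * free - k4 * y[2]))
  }
  sol <- deSolve::lsoda(c(RL = 0, RI = 0), grid, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed (k1=", rl$k1, ", k2=", rl$k2, ", k3=", k3,
         ", k4=", k4, ", I=", competitor_conc, ")", call. = FALSE)
  }
  out <- sol[, "RL"]
  if (t_grid[1] > 0) out <- out[-1]
  unname(out)
}

#' Globally fit competitor on/off rates from association traces
#'
#' Least squares over all association traces simultaneously with shared
#' `k3`, `k4` and `bmax_scale` (log-parameterized), the radioligand's
#' own rates held fixed. The optimizer is multi-started from a
#' deterministic grid of plausible kinetic KD (`k4/k3`) and `k4` values.
#'
#' @param dataset a `kinetic_dataset` (see [read_kinetic_csv()]) or list
#'   of `kinetic_trace` objects; association traces at two or more
#'   distinct competitor concentrations (at least one non-zero) are
#'   required to separate `k3` from `k4`.
#' @param rl a [radioligand_kinetics()] object.
#' @param kd_grid,k4_grid multi-start grids (log10 molar and log10 1/s).
#' @return A `competitor_kinetics_fit`: list with `k3`, `k4`,
#'   `bmax_scale`, `kinetic_kd = k4/k3`, `se` (named), `rss`, `dof`,
#'   `converged`, `status` and `residuals` (per trace).
#' @export
fit_competitor_kinetics <- function(dataset, rl,
                                    kd_grid = c(-8, -7, -6, -5),
                                    k4_grid = c(-4, -3, -2)) {
  stopifnot(inherits(rl, "radioligand_kinetics"))
  traces <- Filter(function(tr) tr$trace_type == "association", dataset)
  concs <- vapply(traces, `[[`, 0, "competitor_conc")
  fail <- function(status, warn = TRUE) {
    if (warn) warning(status, call. = FALSE)
    structure(list(k3 = NA_real_, k4 = NA_real_, bmax_scale = NA_real_,
                   kinetic_kd = NA_real_, se = NULL, rss = NA_real_,
                   dof = NA_integer_, converged = FALSE, status = status,
                   residuals = NULL),
              class = "competitor_kinetics_fit")
  }
  if (length(traces) < 2L || length(unique(concs)) < 2L ||
      all(concs == 0)) {
    return(fail(paste0("identifiability: need association traces at >= 2 ",
                       "distinct competitor concentrations (>= 1 non-zero) ",
                       "to separate k3 from k4 (the profile over k4/k3 is ",
                       "flat otherwise)")))
  }

  resid_fn <- function(par) {
    k3 <- 10^par[["log_k3"]]; k4 <- 10^par[["log_k4"]]
    bm <- 10^par[["log_bmax"]]
    unlist(lapply(traces, function(tr) {
      tr$signal - mm_bound(tr$time, rl, k3, k4, tr$competitor_conc, bm)
    }), use.names = FALSE)
  }
  bmax0 <- max(vapply(traces, function(tr) max(tr$signal), 0))
  starts <- list()
  for (lkd in kd_grid) {
    for (lk4 in k4_grid) {
      starts[[length(starts) + 1L]] <-
        c(log_k3 = lk4 - lkd, log_k4 = lk4, log_bmax = log10(bmax0))
    }
  }
  fit <- lm_multistart(resid_fn, starts)
  if (is.null(fit$par)) return(fail(fit$status, warn = FALSE))
  k3 <- 10^fit$par[["log_k3"]]; k4 <- 10^fit$par[["log_k4"]]
  bm <- 10^fit$par[["log_bmax"]]
  ln10 <- log(10)
  res <- lapply(traces, function(tr) {
    tr$signal - mm_bound(tr$time, rl, k3, k4, tr$competitor_conc, bm)
  })
  names(res) <- vapply(traces, `[[`, "", "trace_id")
  cov <- fit$cov
  se_log_kd <- if (is.null(cov)) NA_real_ else
    sqrt(max(cov["log_k4", "log_k4"] + cov["log_k3", "log_k3"] -
               2 * cov["log_k4", "log_k3"], 0))
  structure(list(
    k3 = k3, k4 = k4, bmax_scale = bm, kinetic_kd = k4 / k3,
    se = c(k3 = k3 * ln10 * unname(fit$se["log_k3"]),
           k4 = k4 * ln10 * unname(fit$se["log_k4"]),
           bmax_scale = bm * ln10 * unname(fit$se["log_bmax"]),
           kinetic_kd = (k4 / k3) * ln10 * se_log_kd),
    rss = fit$rss, dof = fit$dof, converged = fit$converged,
    status = fit$status, residuals = res
  ), class = "competitor_kinetics_fit")
}

#' @export
print.competitor_kinetics_fit <- function(x, ...) {
  if (!x$converged && is.na(x$k3)) {
    cat("Competitor kinetics fit: not estimable (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("Competitor kinetics fit%s\n  k3 = %.4g /M/s, ",
                     "k4 = %.4g /s, kinetic KD = %.4g M\n"),
              if (x$converged) "" else " [NOT converged]",
              x$k3, x$k4, x$kinetic_kd))
  invisible(x)
}

#' Fit a dissociation (chase) trace
#'
#' After blocking re-association with excess unlabeled ligand, bound
#' radioligand decays as `y = ns + (y0 - ns) exp(-koff t)`. A rising
#' trace is rejected.
#'
#' @param trace a `kinetic_trace` of type `"dissociation"` with >= 5
#'   points.
#' @return an `exp_rate_fit` (see [fit_single_exponential()]) whose
#'   `rate_k` is the off-rate `koff` in 1/s, `offset` the nonspecific
#'   plateau `ns` and `amplitude` the specific component `y0 - ns`.
#' @export
fit_dissociation <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$trace_type != "dissociation") {
    stop("fit_dissociation expects a dissociation trace", call. = FALSE)
  }
  if (length(trace$time) < 5L) {
    stop("at least 5 time points are required for a dissociation fit",
         call. = FALSE)
  }
  fit <- fit_single_exponential(trace$time, trace$signal, mode = "decay")
  if (isTRUE(fit$wrong_mode)) {
    stop("trace rises with time: not a dissociation decay (fitted ",
         "amplitude is negative)", call. = FALSE)
  }
  fit
}
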