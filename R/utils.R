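# Internal helpers shared across fitting modules.

#' @importFrom minpack.lm nls.lm nls.lm.control
#' @importFrom stats coef median qnorm rnorm sd setNames
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Levenberg-Marquardt least squares with multiple starts.
#
# residual_fn(par) must return the residual vector. `starts` is a list of
# named numeric start vectors; the best converged solution by RSS wins.
# `tie_fn(par)` breaks RSS ties (smaller wins). Returns a list with
# par, rss, dof, cov, se, converged, status.
lm_multistart <- function(residual_fn, starts, lower = NULL, upper = NULL,
                          tie_fn = NULL, tie_tol = 1e-8,
                          maxiter = 200) {
  best <- NULL
  best_tie <- Inf
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = residual_fn,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = maxiter)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    if (!is.finite(rss)) next
    tie <- if (is.null(tie_fn)) 0 else tie_fn(fit$par)
    if (is.null(best) ||
        rss < best$deviance * (1 - tie_tol) ||
        (abs(rss - best$deviance) <= tie_tol * max(rss, best$deviance) &&
         tie < best_tie)) {
      best <- fit
      best_tie <- tie
    }
  }
  if (is.null(best)) {
    return(list(par = NULL, rss = NA_real_, dof = NA_integer_, cov = NULL,
                se = NULL, converged = FALSE, status = "no start converged"))
  }
  par <- best$par
  n_res <- length(residual_fn(par))
  dof <- n_res - length(par)
  cov <- lm_covariance(best, dof)
  se <- if (is.null(cov)) rep(NA_real_, length(par)) else sqrt(pmax(diag(cov), 0))
  names(se) <- names(par)
  list(par = par, rss = best$deviance, dof = dof, cov = cov, se = se,
       converged = best$info %in% 1:4, status = best$message)
}

# Gauss-Newton covariance (J'J)^-1 * rss / dof from an nls.lm fit.
lm_covariance <- function(fit, dof) {
  if (dof <= 0) return(NULL)
  jtj <- fit$hessian  # nls.lm returns J'J in $hessian
  cov <- tryCatch(solve(jtj) * fit$deviance / dof, error = function(e) NULL)
  if (!is.null(cov)) dimnames(cov) <- list(names(fit$par), names(fit$par))
  cov
}

# log-spaced sequence
lseq <- function(from, to, length.out) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
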