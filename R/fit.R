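#' Fit a two-level one-factor model by maximum likelihood
#'
#' Minimizes the exact balanced two-level normal \eqn{-2\log L} (see
#' [neg2loglik()]) over the free parameters of a model specification,
#' using BFGS with an analytic gradient on the raw (untransformed)
#' parameters. Keeping the parameters untransformed means negative variance
#' estimates (Heywood cases) can occur and are recorded rather than
#' prevented; evaluations where an implied covariance matrix is not
#' positive definite are treated as infinitely bad by the line search.
#' Item means are saturated and profiled out at the grand mean.
#'
#' On failure of the default data-driven start, up to `restarts` jittered
#' restarts are attempted (multiplicative log-normal jitter, sd 0.3); the
#' best converged solution wins. If every start fails a non-converged fit
#' is returned rather than an error, so Monte Carlo bookkeeping can count
#' it.
#'
#' @param spec an [mlcfa_spec()] object.
#' @param data a [two_level_data()] object (ignored if `stats` is given).
#' @param stats optionally, precomputed [suff_stats()].
#' @param start optional start: an [mlcfa_params()] or a free-parameter
#'   vector in [pack_params()] layout.
#' @param restarts maximum number of additional jittered starts.
#' @param maxit iteration cap per start.
#' @param reltol relative convergence tolerance on \eqn{-2\log L}.
#' @return An object of class `"mlcfa"`: list with `spec`, `stats`,
#'   `estimates` (an `mlcfa_params` with means set to the grand mean),
#'   `loglik`, `n2ll`, `n_free`, `converged`, `admissible`,
#'   `n_starts_used`, `gradient_norm`.
#' @seealso [cluster_bias_test()], [lr_test()], [is_admissible()]
#' @export
#' @examples
#' set.seed(1)
#' cond <- bias_condition(L1N = 25, L2N = 50, icc = 0.2)
#' d <- simulate_condition(cond, rep_index = 1)
#' fit <- mlcfa(mlcfa_spec(5), d)
#' fit
#' coef(fit)
mlcfa <- function(spec, data = NULL, stats = NULL, start = NULL,
                  restarts = 5L, maxit = 2000L, reltol = 1e-10) {
  stopifnot(inherits(spec, "mlcfa_spec"))
  if (is.null(stats)) {
    if (is.null(data)) stop("supply 'data' or 'stats'")
    stats <- suff_stats(data)
  }
  if (stats$p != spec$n_items)
    stop("data have ", stats$p, " items but spec has ", spec$n_items)

  map <- spec_index_map(spec)
  A <- stats$pooled_within_sscp
  B <- stats$b_sscp
  N <- stats$N; G <- stats$G; n <- stats$n
  BIG <- 1e10

  fn <- function(x) {
    im <- implied_from_x(map, x)
    v <- n2ll_core(im$SW, im$SB, A, B, N, G, n)
    if (!is.finite(v)) BIG else v
  }
  gr <- function(x) n2ll_grad(map, x, A, B, N, G, n)

  x0 <- if (is.null(start)) start_values(spec, stats)
        else if (inherits(start, "mlcfa_params")) pack_params(spec, start)
        else { stopifnot(length(start) == map$len); as.numeric(start) }

  best <- NULL
  n_used <- 0L
  for (attempt in 0:restarts) {
    xs <- if (attempt == 0L) x0
          else x0 * exp(stats::rnorm(length(x0), 0, 0.3))
    if (!is.finite(fn(xs))) next
    n_used <- n_used + 1L
    res <- tryCatch(
      stats::optim(xs, fn, gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= BIG / 2) next
    ok <- res$convergence == 0L
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && res$value < best$res$value))
      best <- list(res = res, ok = ok)
    if (!is.null(best) && best$ok) break
  }

  if (is.null(best)) {
    fit <- structure(
      list(spec = spec, stats = stats, estimates = NULL,
           loglik = NA_real_, n2ll = NA_real_, n_free = map$len,
           converged = FALSE, admissible = NA,
           n_starts_used = n_used, gradient_norm = NA_real_),
      class = "mlcfa")
    return(fit)
  }

  xhat <- best$res$par
  est <- unpack_params(spec, xhat, mu = stats$grand_mean)
  gnorm <- max(abs(gr(xhat)))
  fit <- structure(
    list(spec = spec, stats = stats, estimates = est,
         loglik = -best$res$value / 2, n2ll = best$res$value,
         n_free = map$len,
         converged = best$ok, admissible = NA,
         n_starts_used = n_used, gradient_norm = gnorm),
    class = "mlcfa")
  fit$admissible <- is_admissible(fit)
  fit
}

#' Admissibility of a fitted solution
#'
#' A converged solution is admissible when every estimated variance is
#' non-negative (up to a tolerance of 1e-8, so exact boundary estimates
#' such as a zero between-factor variance count as admissible) and both
#' implied covariance matrices are positive semidefinite at the estimates.
#' Inadmissible (Heywood) solutions are still used for likelihood-ratio
#' tests; the flag only feeds the Monte Carlo tallies.
#'
#' @param fit an [mlcfa()] fit.
#' @param tol negative-variance tolerance.
#' @return logical (`NA` for non-converged fits).
#' @export
is_admissible <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "mlcfa"))
  if (!isTRUE(fit$converged) || is.null(fit$estimates)) return(NA)
  e <- fit$estimates
  free_tb <- setdiff(seq_len(fit$spec$n_items), fit$spec$zero_between_resid)
  vars <- c(e$phi_w, e$phi_b, e$theta_w, e$theta_b[free_tb])
  if (any(vars < -tol)) return(FALSE)
  psd <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    all(ev >= -tol * max(1, abs(ev[1L])))
  }
  psd(implied_within(e)) && psd(implied_between(e))
}

#' @export
print.mlcfa <- function(x, ...) {
  cat("Two-level one-factor CFA fit (", x$stats$G, " clusters x ",
      x$stats$n, ", p = ", x$stats$p, ")\n", sep = "")
  cat("  logLik: ", format(x$loglik, digits = 8),
      "  free parameters: ", x$n_free, "\n", sep = "")
  cat("  converged: ", x$converged,
      "  admissible: ", x$admissible,
      "  starts: ", x$n_starts_used,
      "  max|grad|: ", format(x$gradient_norm, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mlcfa <- function(object, ...) {
  if (is.null(object$estimates)) return(NULL)
  pack_params(object$spec, object$estimates)
}

#' @export
logLik.mlcfa <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$stats$N,
            class = "logLik")
}

#' @export
fitted.mlcfa <- function(object, ...) {
  if (is.null(object$estimates)) return(NULL)
  list(within = implied_within(object$estimates),
       between = implied_between(object$estimates))
}

#' Covariance residuals of a fitted model
#'
#' Differences between the empirical and the model-implied covariance
#' matrices: `within` is \eqn{S_{PW} - \hat\Sigma_W} and `between` is the
#' method-of-moments between estimate \eqn{(S_B - S_{PW})/n} minus
#' \eqn{\hat\Sigma_B}.
#'
#' @param object an [mlcfa()] fit.
#' @param ... unused.
#' @return list of two p x p matrices, or `NULL` for a non-converged fit.
#' @export
residuals.mlcfa <- function(object, ...) {
  if (is.null(object$estimates)) return(NULL)
  s <- object$stats
  list(within = s$s_pw - implied_within(object$estimates),
       between = (s$s_b - s$s_pw) / s$n - implied_between(object$estimates))
}

#' @export
summary.mlcfa <- function(object, ...) {
  structure(list(fit = object, coef = coef(object),
                 resid = residuals(object)),
            class = "summary.mlcfa")
}

#' @export
print.summary.mlcfa <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$coef)) {
    cat("\nEstimates:\n")
    print(round(x$coef, 4))
    cat("\nMax |covariance residual| (within, between): ",
        format(max(abs(x$resid$within)), digits = 3), ", ",
        format(max(abs(x$resid$between)), digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.mlcfa <- function(x, ...) {
  if (is.null(x$estimates)) stop("fit did not converge; nothing to plot")
  f <- fitted(x)
  s <- x$stats
  obs <- c(s$s_pw[lower.tri(s$s_pw, diag = TRUE)],
           ((s$s_b - s$s_pw) / s$n)[lower.tri(s$s_pw, diag = TRUE)])
  imp <- c(f$within[lower.tri(f$within, diag = TRUE)],
           f$between[lower.tri(f$between, diag = TRUE)])
  lev <- rep(c("within", "between"), each = length(obs) / 2)
  graphics::plot(imp, obs, pch = ifelse(lev == "within", 1, 17),
                 xlab = "model-implied covariance",
                 ylab = "sample covariance", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(1, 17), bty = "n",
                   legend = c("within level", "between level"))
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws balanced two-level datasets from the fitted parameter values,
#' with the design (number of clusters and cluster size) of the original
#' data.
#'
#' @param object a converged [mlcfa()] fit.
#' @param nsim number of datasets.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return a list of [two_level_data()] objects.
#' @export
simulate.mlcfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$estimates)) stop("fit did not converge")
  if (!is.null(seed)) set.seed(seed)
  e <- object$estimates
  s <- object$stats
  replicate(nsim, simplify = FALSE,
            draw_two_level(e, G = s$G, n = s$n))
}

#' Serialize a fit to JSON
#'
#' @param fit an [mlcfa()] fit.
#' @param path optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mlcfa"))
  x <- list(spec = jsonlite::fromJSON(spec_to_json(fit$spec)),
            estimates = if (is.null(fit$estimates)) NULL else
              as.list(coef(fit)),
            loglik = fit$loglik, n_free = fit$n_free,
            converged = fit$converged, admissible = fit$admissible,
            n_starts_used = fit$n_starts_used,
            gradient_norm = fit$gradient_norm)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
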