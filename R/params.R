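#' Parameter set of the two-level one-factor model
#'
#' Numeric values for every model parameter: within- and between-level
#' loading vectors, the two scalar factor variances, the diagonal residual
#' variances at each level, and the item means. During data generation all
#' variances are non-negative; during estimation negative variance estimates
#' (Heywood cases) are representable and flagged by [is_admissible()].
#'
#' @param lambda_w,lambda_b numeric p-vectors of within/between loadings.
#' @param phi_w,phi_b scalar factor variances.
#' @param theta_w,theta_b numeric p-vectors of residual variances.
#' @param mu numeric p-vector of item means (default 0).
#' @return An object of class `"mlcfa_params"`.
#' @export
#' @examples
#' mlcfa_params(rep(1, 5), rep(1, 5), 1, 0.375, rep(0.5, 5), rep(0, 5))
mlcfa_params <- function(lambda_w, lambda_b, phi_w, phi_b,
                         theta_w, theta_b, mu = NULL) {
  p <- length(lambda_w)
  if (is.null(mu)) mu <- numeric(p)
  if (length(lambda_b) != p || length(theta_w) != p ||
      length(theta_b) != p || length(mu) != p)
    stop("parameter vectors have inconsistent lengths")
  if (length(phi_w) != 1L || length(phi_b) != 1L)
    stop("factor variances must be scalar (one factor per level)")
  structure(
    list(lambda_w = as.numeric(lambda_w), lambda_b = as.numeric(lambda_b),
         phi_w = as.numeric(phi_w), phi_b = as.numeric(phi_b),
         theta_w = as.numeric(theta_w), theta_b = as.numeric(theta_b),
         mu = as.numeric(mu)),
    class = "mlcfa_params")
}

#' Model-implied covariance matrices
#'
#' The within-level implied covariance is
#' \eqn{\Sigma_W = \Lambda_W \phi_W \Lambda_W' + \Theta_W} and the
#' between-level implied covariance is
#' \eqn{\Sigma_B = \Lambda_B \phi_B \Lambda_B' + \Theta_B}, with diagonal
#' residual matrices. The total covariance decomposes as
#' \eqn{\Sigma_T = \Sigma_W + \Sigma_B}.
#'
#' @param params an [mlcfa_params()] object.
#' @return a symmetric p x p matrix.
#' @export
implied_within <- function(params) {
  lam <- params$lambda_w
  lam %o% lam * params$phi_w + diag(params$theta_w, length(lam))
}

#' @rdname implied_within
#' @export
implied_between <- function(params) {
  lam <- params$lambda_b
  lam %o% lam * params$phi_b + diag(params$theta_b, length(lam))
}

#' @rdname implied_within
#' @export
implied_total <- function(params) {
  implied_within(params) + implied_between(params)
}

#' @export
print.mlcfa_params <- function(x, ...) {
  p <- length(x$lambda_w)
  m <- rbind(lambda_within = x$lambda_w, lambda_between = x$lambda_b,
             theta_within = x$theta_w, theta_between = x$theta_b,
             mu = x$mu)
  colnames(m) <- paste0("y", seq_len(p))
  cat("Two-level one-factor parameter set (p =", p, ")\n")
  print(round(m, 4), ...)
  cat("phi_within =", format(x$phi_w, digits = 4),
      "  phi_between =", format(x$phi_b, digits = 4), "\n")
  invisible(x)
}

# Internal layout of the free-parameter vector for a given spec:
#   1. loadings, non-referent items in increasing index order:
#      equated item -> one shared loading; otherwise lambda_w then lambda_b
#   2. phi_w, phi_b
#   3. theta_w, items 1..p
#   4. theta_b for items not fixed at zero, increasing index order
# Means are saturated and profiled out; they never enter the vector.
free_param_names <- function(spec) {
  p <- spec$n_items
  nm <- character(0)
  for (i in setdiff(seq_len(p), spec$referent)) {
    if (i %in% spec$equal_loadings) nm <- c(nm, sprintf("lambda%d", i))
    else nm <- c(nm, sprintf("lambda_w%d", i), sprintf("lambda_b%d", i))
  }
  nm <- c(nm, "phi_w", "phi_b", sprintf("theta_w%d", seq_len(p)))
  c(nm, sprintf("theta_b%d", setdiff(seq_len(p), spec$zero_between_resid)))
}

#' Pack and unpack free parameters
#'
#' `pack_params()` maps a full parameter set to the vector of free
#' parameters implied by a specification; `unpack_params()` is its inverse.
#' The round trip is exact on the free coordinates. Packing checks that the
#' parameter set honours the specification's fixed entries (referent
#' loadings at 1 on both levels, equated loadings actually equal, zeroed
#' between residual variances actually 0).
#'
#' @param spec an [mlcfa_spec()] object.
#' @param params an [mlcfa_params()] object consistent with `spec`.
#' @param x numeric vector of free parameters in the canonical layout.
#' @param mu item means to attach on unpacking (default zeros; means are
#'   profiled out of the likelihood and carried only for simulation).
#' @return `pack_params()`: a named numeric vector of length
#'   [n_free_params()]; `unpack_params()`: an `mlcfa_params`.
#' @export
pack_params <- function(spec, params) {
  stopifnot(inherits(spec, "mlcfa_spec"), inherits(params, "mlcfa_params"))
  p <- spec$n_items
  if (length(params$lambda_w) != p)
    stop("parameter set has ", length(params$lambda_w),
         " items but spec has ", p)
  r <- spec$referent
  tol <- 0
  if (params$lambda_w[r] != spec$referent_fixed_value ||
      params$lambda_b[r] != spec$referent_fixed_value)
    stop("referent loading must equal its fixed value at both levels")
  x <- numeric(0)
  for (i in setdiff(seq_len(p), r)) {
    if (i %in% spec$equal_loadings) {
      if (params$lambda_w[i] != params$lambda_b[i])
        stop("item ", i, " is constrained to equal loadings across levels")
      x <- c(x, params$lambda_w[i])
    } else {
      x <- c(x, params$lambda_w[i], params$lambda_b[i])
    }
  }
  if (any(params$theta_b[spec$zero_between_resid] != 0))
    stop("between residual variances fixed at zero must be exactly 0")
  x <- c(x, params$phi_w, params$phi_b, params$theta_w,
         params$theta_b[setdiff(seq_len(p), spec$zero_between_resid)])
  names(x) <- free_param_names(spec)
  x
}

#' @rdname pack_params
#' @export
unpack_params <- function(spec, x, mu = NULL) {
  stopifnot(inherits(spec, "mlcfa_spec"))
  p <- spec$n_items
  if (length(x) != n_free_params(spec))
    stop("free-parameter vector has length ", length(x),
         " but spec implies ", n_free_params(spec))
  lam_w <- lam_b <- numeric(p)
  r <- spec$referent
  lam_w[r] <- lam_b[r] <- spec$referent_fixed_value
  k <- 1L
  for (i in setdiff(seq_len(p), r)) {
    if (i %in% spec$equal_loadings) {
      lam_w[i] <- lam_b[i] <- x[k]; k <- k + 1L
    } else {
      lam_w[i] <- x[k]; lam_b[i] <- x[k + 1L]; k <- k + 2L
    }
  }
  phi_w <- x[k]; phi_b <- x[k + 1L]; k <- k + 2L
  theta_w <- x[k:(k + p - 1L)]; k <- k + p
  theta_b <- numeric(p)
  free_b <- setdiff(seq_len(p), spec$zero_between_resid)
  if (length(free_b)) theta_b[free_b] <- x[k:(k + length(free_b) - 1L)]
  mlcfa_params(lam_w, lam_b, phi_w, phi_b, theta_w, theta_b, mu = mu)
}
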