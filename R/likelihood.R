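#' Minus twice the log-likelihood of a balanced two-level normal model
#'
#' Evaluates the exact \eqn{-2\log L} of balanced two-level data under a
#' two-level normal model with within covariance \eqn{\Sigma_W} and between
#' covariance \eqn{\Sigma_B}. The stacked np-vector of a cluster has
#' covariance \eqn{I_n \otimes \Sigma_W + J_n \otimes \Sigma_B}, which gives
#' \deqn{-2\log L = Np\log(2\pi) + (N-G)\log|\Sigma_W| +
#'   \mathrm{tr}(\Sigma_W^{-1} A) + G\log|\Sigma_W + n\Sigma_B| +
#'   n\sum_g (\bar y_g-\mu)'(\Sigma_W + n\Sigma_B)^{-1}(\bar y_g-\mu)}
#' with \eqn{A} the pooled within-cluster SSCP. With saturated means the
#' MLE of \eqn{\mu} is the grand mean, and by default it is profiled out
#' at that value.
#'
#' @param params an [mlcfa_params()] object; its implied matrices are used.
#' @param stats an [suff_stats()] object.
#' @param mu optional fixed mean vector; `NULL` profiles the means at the
#'   grand mean.
#' @return a scalar; `Inf` if either \eqn{\Sigma_W} or
#'   \eqn{\Sigma_W + n\Sigma_B} is not positive definite (the optimizer
#'   treats such points as infinitely bad).
#' @export
#' @examples
#' d <- two_level_data(matrix(rnorm(100), 50, 2), rep(1:10, each = 5))
#' s <- suff_stats(d)
#' p <- mlcfa_params(c(1, 1), c(1, 1), 1, 0.2, c(0.5, 0.5), c(0, 0),
#'                   mu = s$grand_mean)
#' neg2loglik(p, s)
neg2loglik <- function(params, stats, mu = NULL) {
  stopifnot(inherits(params, "mlcfa_params"), inherits(stats, "mlcfa_stats"))
  if (length(params$lambda_w) != stats$p)
    stop("parameter set has ", length(params$lambda_w),
         " items but data have ", stats$p)
  SW <- implied_within(params)
  SB <- implied_between(params)
  if (is.null(mu)) {
    B <- stats$b_sscp
  } else {
    d <- sweep(stats$cluster_means, 2L, mu)
    B <- stats$n * crossprod(d)
  }
  n2ll_core(SW, SB, stats$pooled_within_sscp, B, stats$N, stats$G, stats$n)
}

# Core evaluation from implied matrices and SSCPs; returns Inf when a
# covariance matrix is not PD so callers can treat the point as infeasible.
n2ll_core <- function(SW, SB, A, B, N, G, n) {
  p <- nrow(SW)
  cw <- tryCatch(chol(SW), error = function(e) NULL)
  if (is.null(cw)) return(Inf)
  ST <- SW + n * SB
  ct <- tryCatch(chol(ST), error = function(e) NULL)
  if (is.null(ct)) return(Inf)
  ldW <- 2 * sum(log(diag(cw)))
  ldT <- 2 * sum(log(diag(ct)))
  iW <- chol2inv(cw)
  iT <- chol2inv(ct)
  N * p * log(2 * pi) + (N - G) * ldW + sum(iW * A) + G * ldT + sum(iT * B)
}

# Analytic gradient machinery -------------------------------------------

# Precompute the mapping from the free-parameter vector layout (see
# free_param_names) to loading/variance slots, so the objective and
# gradient avoid list construction in the hot loop.
spec_index_map <- function(spec) {
  p <- spec$n_items
  r <- spec$referent
  iw_items <- integer(0); iw_pos <- integer(0)
  ib_items <- integer(0); ib_pos <- integer(0)
  k <- 1L
  for (i in setdiff(seq_len(p), r)) {
    if (i %in% spec$equal_loadings) {
      iw_items <- c(iw_items, i); iw_pos <- c(iw_pos, k)
      ib_items <- c(ib_items, i); ib_pos <- c(ib_pos, k)
      k <- k + 1L
    } else {
      iw_items <- c(iw_items, i); iw_pos <- c(iw_pos, k)
      ib_items <- c(ib_items, i); ib_pos <- c(ib_pos, k + 1L)
      k <- k + 2L
    }
  }
  kp <- k
  tw_pos <- (kp + 2L):(kp + 1L + p)
  tb_items <- setdiff(seq_len(p), spec$zero_between_resid)
  tb_pos <- if (length(tb_items))
    (kp + 1L + p + 1L):(kp + 1L + p + length(tb_items)) else integer(0)
  base_lam <- numeric(p); base_lam[r] <- spec$referent_fixed_value
  list(p = p, len = n_free_params(spec), base_lam = base_lam,
       iw_items = iw_items, iw_pos = iw_pos,
       ib_items = ib_items, ib_pos = ib_pos,
       kpw = kp, kpb = kp + 1L, tw_pos = tw_pos,
       tb_items = tb_items, tb_pos = tb_pos)
}

# Build implied matrices directly from the free vector.
implied_from_x <- function(map, x) {
  lam_w <- map$base_lam; lam_w[map$iw_items] <- x[map$iw_pos]
  lam_b <- map$base_lam; lam_b[map$ib_items] <- x[map$ib_pos]
  SW <- tcrossprod(lam_w) * x[map$kpw]
  diag(SW) <- diag(SW) + x[map$tw_pos]
  SB <- tcrossprod(lam_b) * x[map$kpb]
  if (length(map$tb_items)) {
    d <- diag(SB)
    d[map$tb_items] <- d[map$tb_items] + x[map$tb_pos]
    diag(SB) <- d
  }
  list(SW = SW, SB = SB, lam_w = lam_w, lam_b = lam_b)
}

# Gradient of the -2 log-likelihood with respect to the free vector.
# With F = (N-G)log|SW| + tr(SW^-1 A) + G log|ST| + tr(ST^-1 B),
# ST = SW + n SB:
#   dF/dSW = W1 + T1,  dF/dSB = n T1, where
#   W1 = (N-G) SW^-1 - SW^-1 A SW^-1,  T1 = G ST^-1 - ST^-1 B ST^-1.
n2ll_grad <- function(map, x, A, B, N, G, n) {
  im <- implied_from_x(map, x)
  cw <- tryCatch(chol(im$SW), error = function(e) NULL)
  ct <- tryCatch(chol(im$SW + n * im$SB), error = function(e) NULL)
  g <- numeric(map$len)
  if (is.null(cw) || is.null(ct)) return(g)
  iW <- chol2inv(cw); iT <- chol2inv(ct)
  W1 <- (N - G) * iW - iW %*% A %*% iW
  T1 <- G * iT - iT %*% B %*% iT
  D <- W1 + T1
  gw <- 2 * x[map$kpw] * drop(D %*% im$lam_w)
  gb <- 2 * n * x[map$kpb] * drop(T1 %*% im$lam_b)
  g[map$iw_pos] <- gw[map$iw_items]
  g[map$ib_pos] <- g[map$ib_pos] + gb[map$ib_items]
  g[map$kpw] <- drop(crossprod(im$lam_w, D %*% im$lam_w))
  g[map$kpb] <- n * drop(crossprod(im$lam_b, T1 %*% im$lam_b))
  g[map$tw_pos] <- diag(D)
  if (length(map$tb_items)) g[map$tb_pos] <- n * diag(T1)[map$tb_items]
  g
}

# Data-driven starting values on the free-parameter scale.
start_values <- function(spec, stats) {
  p <- spec$n_items
  s_pw <- stats$s_pw
  off <- s_pw[upper.tri(s_pw)]
  phi_w0 <- if (length(off)) max(mean(off) / 2, 0.05) else 0.05
  theta_w0 <- diag(s_pw) / 2
  phi_b0 <- max(mean(diag((stats$s_b - s_pw) / stats$n)), 0.01)
  lam_w <- rep(1, p); lam_b <- rep(1, p)
  theta_b <- rep(0.01, p)
  theta_b[spec$zero_between_resid] <- 0
  pars <- mlcfa_params(lam_w, lam_b, phi_w0, phi_b0, theta_w0, theta_b)
  pack_params(spec, pars)
}
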