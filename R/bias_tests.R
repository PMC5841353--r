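#' Model pairs for the item-level cluster-bias test
#'
#' Both testing strategies compare two nested two-level one-factor models
#' differing by exactly two parameters for the tested item: the cross-level
#' equality of its factor loading and its between-level residual variance.
#'
#' `free_baseline_pair()` follows the free-baseline strategy: the
#' unrestricted model is minimally identified (referent loading fixed at 1
#' at both levels, everything else free, all between residual variances
#' free — including the referent's own, which carries only identification
#' constraints); the restricted model additionally equates the tested
#' item's loadings across levels and fixes its between residual variance
#' at 0.
#'
#' `constrained_baseline_pair()` follows the constrained-baseline
#' strategy: the baseline (restricted) model equates every item's loadings
#' across levels and fixes every between residual variance at 0 (the
#' cluster-invariance model); the unrestricted model frees the tested
#' item's cross-level loading equality and its between residual variance,
#' reverting all other items to the baseline constraints.
#'
#' The referent item cannot be tested: its cross-level equality is an
#' identification constraint, not a testable one.
#'
#' @param p number of items.
#' @param referent referent item index.
#' @param item tested item index (different from `referent`).
#' @param referent_theta_b should the referent's between residual variance
#'   be `"free"` (default) or fixed to `"zero"` in the free-baseline
#'   models? Provided as a sensitivity switch.
#' @return list with elements `unrestricted` and `restricted`, both
#'   [mlcfa_spec()] objects whose free-parameter counts differ by exactly 2.
#' @export
#' @examples
#' pr <- free_baseline_pair(5, referent = 1, item = 2)
#' n_free_params(pr$unrestricted) - n_free_params(pr$restricted)  # 2
#' pc <- constrained_baseline_pair(5, referent = 1, item = 2)
#' c(n_free_params(pc$restricted), n_free_params(pc$unrestricted)) # 11 13
free_baseline_pair <- function(p, referent, item,
                               referent_theta_b = c("free", "zero")) {
  referent_theta_b <- match.arg(referent_theta_b)
  check_tested_item(p, referent, item)
  zero0 <- if (referent_theta_b == "zero") referent else integer(0)
  list(
    unrestricted = mlcfa_spec(p, referent, zero_between_resid = zero0),
    restricted = mlcfa_spec(p, referent, equal_loadings = item,
                            zero_between_resid = sort(c(zero0, item))))
}

#' @rdname free_baseline_pair
#' @export
constrained_baseline_pair <- function(p, referent, item) {
  check_tested_item(p, referent, item)
  others <- setdiff(seq_len(p), referent)
  list(
    unrestricted = mlcfa_spec(p, referent,
                              equal_loadings = setdiff(others, item),
                              zero_between_resid = setdiff(seq_len(p), item)),
    restricted = mlcfa_spec(p, referent, equal_loadings = others,
                            zero_between_resid = seq_len(p)))
}

check_tested_item <- function(p, referent, item) {
  if (length(item) != 1L || item < 1L || item > p)
    stop("'item' must be a single index in 1..", p)
  if (length(referent) != 1L || referent < 1L || referent > p)
    stop("'referent' must be a single index in 1..", p)
  if (item == referent)
    stop("the referent item cannot be tested: its cross-level equality ",
         "is an identification constraint")
  invisible(TRUE)
}

#' Unscaled 2-df likelihood-ratio test for cluster bias
#'
#' Computes the unscaled likelihood-ratio statistic
#' \eqn{LRT = -2(\ell_1 - \ell_0) = 2(\ell_0 - \ell_1)} from the fitted
#' unrestricted (\eqn{\ell_0}) and restricted (\eqn{\ell_1}) models and
#' refers it to \eqn{\chi^2_2}. Outcome taxonomy:
#' * `"significant"` / `"non_significant"`: both fits converged and the
#'   statistic is non-negative; compared against `alpha`;
#' * `"inconclusive_negative"`: both fits converged but the statistic is
#'   negative (a negative log-likelihood difference; never clipped to 0,
#'   and counted neither as a positive nor as a negative finding);
#' * `"non_converged"`: either fit failed; no p-value is produced.
#'
#' For df = 2 the upper-tail p-value has the closed form
#' \eqn{p = \exp(-LRT/2)}, used as a numerical cross-check in the tests.
#'
#' @param unrestricted,restricted [mlcfa()] fits of a nested pair differing
#'   by 2 free parameters.
#' @param alpha significance level (0.05 throughout the study).
#' @return An object of class `"mlcfa_lrt"`: list with `loglik_unrestricted`,
#'   `loglik_restricted`, `statistic`, `df = 2`, `p_value`, `status`,
#'   `alpha`.
#' @export
#' @examples
#' # from stored log-likelihoods:
#' # statistic 7.0 -> p = exp(-3.5) ~ 0.0302
lr_test <- function(unrestricted, restricted, alpha = 0.05) {
  stopifnot(inherits(unrestricted, "mlcfa"), inherits(restricted, "mlcfa"))
  df <- unrestricted$n_free - restricted$n_free
  if (df != 2L)
    stop("the nested pair must differ by exactly 2 free parameters, got ",
         df)
  out <- list(loglik_unrestricted = unrestricted$loglik,
              loglik_restricted = restricted$loglik,
              statistic = NA_real_, df = 2L, p_value = NA_real_,
              status = "non_converged", alpha = alpha)
  if (isTRUE(unrestricted$converged) && isTRUE(restricted$converged)) {
    stat <- 2 * (unrestricted$loglik - restricted$loglik)
    out$statistic <- stat
    if (stat < 0) {
      out$status <- "inconclusive_negative"
    } else {
      out$p_value <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
      out$status <- if (out$p_value < alpha) "significant"
                    else "non_significant"
    }
  }
  structure(out, class = "mlcfa_lrt")
}

#' @export
print.mlcfa_lrt <- function(x, ...) {
  cat("Cluster-bias likelihood-ratio test (df = 2)\n")
  cat("  logLik unrestricted:", format(x$loglik_unrestricted, digits = 8),
      " restricted:", format(x$loglik_restricted, digits = 8), "\n")
  cat("  LRT =", format(x$statistic, digits = 5),
      " p =", format(x$p_value, digits = 4),
      " status:", x$status, "\n")
  invisible(x)
}

#' Test one item for cluster bias
#'
#' Builds the model pair for the chosen strategy, fits both models by
#' maximum likelihood and runs the 2-df unscaled likelihood-ratio test.
#' An item is flagged as biased when the test is significant at `alpha`.
#' Deterministic given the data and fitting options; fitting failures
#' propagate into the outcome status rather than raising errors.
#'
#' @param data a [two_level_data()] object (or `stats`, precomputed
#'   sufficient statistics, may be supplied instead).
#' @param item tested item index.
#' @param strategy `"free"` or `"constrained"` baseline strategy.
#' @param referent referent item index.
#' @param alpha significance level.
#' @param stats optional precomputed [suff_stats()].
#' @param baseline_fit optional already-fitted baseline model for the
#'   strategy (the unrestricted model under `"free"`, the restricted
#'   cluster-invariance model under `"constrained"`); reused across items
#'   by the Monte Carlo driver.
#' @param referent_theta_b sensitivity switch for the free-baseline
#'   models, see [free_baseline_pair()].
#' @param ... further arguments passed to [mlcfa()].
#' @return An object of class `"item_test"`: list with `item`, `strategy`,
#'   `referent`, `lrt` (an `"mlcfa_lrt"`), `flagged_biased`, and the two
#'   fits (`fit_unrestricted`, `fit_restricted`).
#' @export
#' @examples
#' set.seed(42)
#' d <- simulate_condition(bias_condition(25, 50, 0.1, 1, 0.05), 1)
#' cluster_bias_test(d, item = 2, strategy = "free")$flagged_biased
cluster_bias_test <- function(data = NULL, item, strategy = c("free",
                              "constrained"), referent = 1L, alpha = 0.05,
                              stats = NULL, baseline_fit = NULL,
                              referent_theta_b = "free", ...) {
  strategy <- match.arg(strategy)
  if (is.null(stats)) stats <- suff_stats(data)
  p <- stats$p
  pair <- if (strategy == "free")
    free_baseline_pair(p, referent, item, referent_theta_b)
  else constrained_baseline_pair(p, referent, item)

  if (strategy == "free") {
    fit0 <- if (is.null(baseline_fit)) mlcfa(pair$unrestricted,
                                             stats = stats, ...)
            else baseline_fit
    start1 <- if (isTRUE(fit0$converged))
      restrict_start(pair$restricted, fit0$estimates) else NULL
    fit1 <- mlcfa(pair$restricted, stats = stats, start = start1, ...)
  } else {
    fit1 <- if (is.null(baseline_fit)) mlcfa(pair$restricted,
                                             stats = stats, ...)
            else baseline_fit
    start0 <- if (isTRUE(fit1$converged))
      relax_start(pair$unrestricted, fit1$estimates) else NULL
    fit0 <- mlcfa(pair$unrestricted, stats = stats, start = start0, ...)
  }
  lrt <- lr_test(fit0, fit1, alpha = alpha)
  structure(list(item = item, strategy = strategy, referent = referent,
                 lrt = lrt,
                 flagged_biased = identical(lrt$status, "significant"),
                 fit_unrestricted = fit0, fit_restricted = fit1),
            class = "item_test")
}

#' @export
print.item_test <- function(x, ...) {
  cat("Item", x$item, "cluster-bias test,", x$strategy,
      "baseline (referent", paste0(x$referent, ")"), "\n")
  print(x$lrt)
  cat("  flagged biased:", x$flagged_biased, "\n")
  invisible(x)
}

#' @export
as.data.frame.item_test <- function(x, ...) {
  data.frame(item = x$item, strategy = x$strategy, referent = x$referent,
             statistic = x$lrt$statistic, df = x$lrt$df,
             p_value = x$lrt$p_value, status = x$lrt$status,
             flagged_biased = x$flagged_biased)
}

# Map a fitted parameter set onto a more restricted spec as a warm start:
# equated loadings start at the average of the two level loadings, zeroed
# between residual variances are dropped.
restrict_start <- function(spec, params) {
  lam_w <- params$lambda_w; lam_b <- params$lambda_b
  sh <- spec$equal_loadings
  if (length(sh)) {
    m <- (lam_w[sh] + lam_b[sh]) / 2
    lam_w[sh] <- m; lam_b[sh] <- m
  }
  tb <- params$theta_b
  tb[spec$zero_between_resid] <- 0
  pack_params(spec, mlcfa_params(lam_w, lam_b, params$phi_w, params$phi_b,
                                 params$theta_w, tb))
}

# Map a restricted fit onto a less restricted spec: freed between residual
# variances start just off the boundary.
relax_start <- function(spec, params) {
  tb <- params$theta_b
  free_b <- setdiff(seq_along(tb), spec$zero_between_resid)
  tb[setdiff(free_b, which(tb != 0))] <- 0.01
  tb[spec$zero_between_resid] <- 0
  pack_params(spec, mlcfa_params(params$lambda_w, params$lambda_b,
                                 params$phi_w, params$phi_b,
                                 params$theta_w, tb))
}
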