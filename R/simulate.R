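#' Define a simulation condition
#'
#' A condition fixes one cell of the factorial design of the decision
#' accuracy study: cluster size, number of clusters, intraclass
#' correlation, how many items are biased and by how much, and whether the
#' referent (anchor) item is itself biased. Biased item sets follow the
#' study layout for five items:
#' * unbiased anchor (referent 1): biased items `2` or `c(2, 4)`;
#' * biased anchor (referent 2): biased items `c(2, 4)` or `c(2, 4, 5)`
#'   (`n_biased` counts the biased items *in addition to* the anchor).
#'
#' @param L1N common cluster size n (2, 5 or 25 in the study design).
#' @param L2N number of clusters G (50 or 100 in the study design).
#' @param icc target intraclass correlation of unbiased items (0 < icc < 1).
#' @param n_biased number of biased items (0, 1 or 2), in addition to the
#'   anchor when `anchor_biased = TRUE`.
#' @param bias_pct bias magnitude as a fraction of total item variance
#'   (0, 0.01 or 0.05); must be 0 exactly when `n_biased = 0`.
#' @param anchor_biased logical; biased referent design.
#' @param replications intended Monte Carlo replications for this cell.
#' @param cell optional integer cell id used for seeding streams.
#' @return An object of class `"bias_condition"` with fields above plus
#'   `p = 5`, `referent` and `biased_items`.
#' @export
#' @examples
#' bias_condition(L1N = 25, L2N = 50, icc = 0.1, n_biased = 1,
#'                bias_pct = 0.05)
bias_condition <- function(L1N, L2N, icc, n_biased = 0L, bias_pct = 0,
                           anchor_biased = FALSE, replications = 500L,
                           cell = NULL) {
  stopifnot(L1N >= 2, L2N >= 2, icc > 0, icc < 1,
            n_biased %in% 0:2, bias_pct >= 0, bias_pct < 1)
  if ((n_biased == 0) != (bias_pct == 0))
    stop("'n_biased' is 0 if and only if 'bias_pct' is 0")
  if (anchor_biased && n_biased == 0)
    stop("a biased-anchor condition needs at least one biased item")
  referent <- if (anchor_biased) 2L else 1L
  biased_items <-
    if (n_biased == 0) integer(0)
    else if (!anchor_biased) list(2L, c(2L, 4L))[[n_biased]]
    else list(c(2L, 4L), c(2L, 4L, 5L))[[n_biased]]
  if (is.null(cell))
    cell <- as.integer(
      L1N + 100L * L2N + round(1e4 * icc) + 1000L * n_biased +
      round(1e6 * bias_pct) + 500000L * anchor_biased)
  structure(list(p = 5L, L1N = as.integer(L1N), L2N = as.integer(L2N),
                 icc = icc, n_biased = as.integer(n_biased),
                 bias_pct = bias_pct, anchor_biased = anchor_biased,
                 referent = referent, biased_items = biased_items,
                 replications = as.integer(replications),
                 cell = as.integer(cell)),
            class = "bias_condition")
}

#' @export
print.bias_condition <- function(x, ...) {
  cat("Simulation condition: G =", x$L2N, ", n =", x$L1N,
      ", ICC =", x$icc, "\n")
  cat("  biased items:",
      if (length(x$biased_items)) paste(x$biased_items, collapse = ", ")
      else "none",
      " bias:", sprintf("%g%% of total variance", 100 * x$bias_pct),
      " referent:", x$referent,
      if (x$anchor_biased) "(biased)" else "(unbiased)", "\n")
  invisible(x)
}

#' Closed-form generation parameters for a condition
#'
#' The generating model has one within factor with variance 1, one between
#' factor, all loadings 1 at both levels, zero between residual variances,
#' and a standard-normal level-2 violator V with a direct effect c on each
#' biased item. For unbiased items the between-factor variance that yields
#' a target intraclass correlation is
#' \deqn{\phi_B = \mathrm{icc}\,(\phi_W + \theta_W) / (1 - \mathrm{icc})}
#' and the violator effect is sized against the *base* total variance
#' (without V's own contribution), so the realized variance inflation of a
#' biased item is exactly `bias_pct`:
#' \deqn{c = \sqrt{\mathrm{bias\_pct}\,(\phi_B + \phi_W + \theta_W)}.}
#'
#' @param condition a [bias_condition()].
#' @param theta_w within-level residual variance per item (scalar).
#' @return list with `p`, `phi_w = 1`, `phi_b`, `theta_w` (p-vector),
#'   `c` (p-vector of violator effects) and `params` (an [mlcfa_params()]
#'   holding the non-violator part).
#' @export
#' @examples
#' generation_params(bias_condition(25, 50, icc = 0.1))$phi_b  # 0.1666667
generation_params <- function(condition, theta_w = 0.5) {
  stopifnot(inherits(condition, "bias_condition"), theta_w > 0)
  p <- condition$p
  phi_w <- 1
  phi_b <- condition$icc * (phi_w + theta_w) / (1 - condition$icc)
  total_base <- phi_b + phi_w + theta_w
  cc <- numeric(p)
  cc[condition$biased_items] <- sqrt(condition$bias_pct * total_base)
  list(p = p, phi_w = phi_w, phi_b = phi_b,
       theta_w = rep(theta_w, p), c = cc,
       params = mlcfa_params(rep(1, p), rep(1, p), phi_w, phi_b,
                             rep(theta_w, p), numeric(p)))
}

# Core balanced two-level draw from an explicit parameter set, optionally
# with a single shared level-2 violator V ~ N(0,1) loading c on each item.
draw_two_level <- function(params, G, n, c = NULL) {
  p <- length(params$lambda_w)
  N <- G * n
  eta_b <- stats::rnorm(G, 0, sqrt(max(params$phi_b, 0)))
  between <- eta_b %o% params$lambda_b
  if (!is.null(c) && any(c != 0)) {
    V <- stats::rnorm(G)
    between <- between + V %o% c
  }
  tb <- sqrt(pmax(params$theta_b, 0))
  if (any(tb > 0))
    between <- between +
      matrix(stats::rnorm(G * p), G, p) * rep(tb, each = G)
  eta_w <- stats::rnorm(N, 0, sqrt(max(params$phi_w, 0)))
  y <- eta_w %o% params$lambda_w +
    matrix(stats::rnorm(N * p), N, p) * rep(sqrt(params$theta_w), each = N)
  g <- rep(seq_len(G), each = n)
  y <- y + between[g, , drop = FALSE]
  y <- sweep(y, 2L, params$mu, `+`)
  colnames(y) <- paste0("y", seq_len(p))
  two_level_data(y, g)
}

# Deterministic per-replication seed from (master seed, cell id, rep);
# rep indices stay below 1009 collisions-free for any fixed master seed.
stream_seed <- function(master, cell, rep_index) {
  as.integer((as.double(master %% 65521L) * 32749 +
              as.double(cell) * 1009 + rep_index) %% 2147483629)
}

#' Generate one balanced two-level dataset for a condition
#'
#' Draws cluster-level between factor scores and a standard-normal level-2
#' violator, member-level within factor scores and residuals, and forms
#' item scores \eqn{y_{gji} = \eta_{B,g} + c_i V_g + \eta_{W,gj} +
#' \epsilon_{gji}} (all loadings 1, zero means). Reproducible streams:
#' the RNG is seeded from `(master_seed, cell, rep_index)`, so any cell
#' and replication can be regenerated independently.
#'
#' @param condition a [bias_condition()].
#' @param rep_index replication number (1-based).
#' @param theta_w within residual variance used by [generation_params()].
#' @param master_seed integer master seed.
#' @return a [two_level_data()] with attribute `"truth"`: list of the
#'   generation parameters, biased items and violator effects.
#' @export
#' @examples
#' d <- simulate_condition(bias_condition(5, 50, 0.2, 1, 0.05), 1)
#' attr(d, "truth")$biased_items
simulate_condition <- function(condition, rep_index, theta_w = 0.5,
                               master_seed = 1L) {
  gp <- generation_params(condition, theta_w)
  set.seed(stream_seed(master_seed, condition$cell, rep_index))
  d <- draw_two_level(gp$params, G = condition$L2N, n = condition$L1N,
                      c = gp$c)
  attr(d, "truth") <- list(condition = condition, phi_b = gp$phi_b,
                           theta_w = theta_w, c = gp$c,
                           biased_items = condition$biased_items,
                           referent = condition$referent)
  d
}

#' Read a condition from a JSON or YAML configuration file
#'
#' Recognized fields: `L1N`, `L2N`, `icc`, `n_biased`, `bias_pct`,
#' `anchor_biased`, `replications`, `cell`.
#'
#' @param path configuration file; `.json` parsed with jsonlite,
#'   `.yaml`/`.yml` with the yaml package.
#' @return a [bias_condition()].
#' @export
read_condition <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path)
  bias_condition(L1N = x$L1N, L2N = x$L2N, icc = x$icc,
                 n_biased = if (is.null(x$n_biased)) 0L else x$n_biased,
                 bias_pct = if (is.null(x$bias_pct)) 0 else x$bias_pct,
                 anchor_biased = isTRUE(x$anchor_biased),
                 replications = if (is.null(x$replications)) 500L
                                else x$replications,
                 cell = x$cell)
}
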