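#' Balanced two-level item-score data
#'
#' Validates and wraps a long-format table of continuous item scores with a
#' cluster identifier: one row per level-1 unit, `G` clusters of a common
#' size `n` (balanced designs only; unbalanced data are rejected, not
#' approximated).
#'
#' @param scores numeric matrix or data frame, N x p, of item scores.
#' @param cluster vector of cluster labels, length N.
#' @return An object of class `"two_level_data"`: a list with elements
#'   `scores` (N x p matrix), `cluster` (factor), `G`, `n`, `N`, `p`.
#' @export
#' @examples
#' d <- two_level_data(matrix(rnorm(40), 20, 2), rep(1:5, each = 4))
#' d$G; d$n
two_level_data <- function(scores, cluster) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (anyNA(scores)) stop("missing item scores are not supported")
  N <- nrow(scores); p <- ncol(scores)
  if (length(cluster) != N)
    stop("'cluster' must have one entry per row of 'scores'")
  cluster <- factor(cluster)
  sizes <- tabulate(cluster)
  G <- nlevels(cluster)
  if (G < 2L) stop("at least 2 clusters are required")
  if (any(sizes < 2L))
    stop("every cluster needs at least 2 members")
  if (length(unique(sizes)) != 1L)
    stop("unbalanced clusters are not supported: sizes ",
         paste(sort(unique(sizes)), collapse = ", "))
  if (is.null(colnames(scores))) colnames(scores) <- paste0("y", seq_len(p))
  structure(list(scores = scores, cluster = cluster,
                 G = G, n = sizes[1L], N = N, p = p),
            class = "two_level_data")
}

#' @export
print.two_level_data <- function(x, ...) {
  cat("Balanced two-level data:", x$G, "clusters x", x$n,
      "members,", x$p, "items\n")
  invisible(x)
}

#' @export
as.data.frame.two_level_data <- function(x, ...) {
  data.frame(cluster = x$cluster, x$scores)
}

#' Read and write two-level data as CSV
#'
#' The CSV layout has a header row, one cluster-id column named `cluster`,
#' and item columns `y1..yp` (any other non-cluster columns are taken as
#' items, in file order).
#'
#' @param path file path.
#' @param data a [two_level_data()] object.
#' @return `read_two_level_csv()` a `two_level_data`;
#'   `write_two_level_csv()` the path, invisibly.
#' @export
read_two_level_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"cluster" %in% names(df))
    stop("CSV must contain a 'cluster' column")
  two_level_data(df[setdiff(names(df), "cluster")], df$cluster)
}

#' @rdname read_two_level_csv
#' @export
write_two_level_csv <- function(data, path) {
  stopifnot(inherits(data, "two_level_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Sufficient statistics for the balanced two-level normal likelihood
#'
#' Computes everything the likelihood needs: the grand mean, cluster means,
#' the pooled within-cluster SSCP matrix
#' \eqn{A = \sum_g \sum_j (y_{gj}-\bar y_g)(y_{gj}-\bar y_g)'},
#' the pooled within-cluster covariance \eqn{S_{PW} = A/(N-G)}, and the
#' scaled between-cluster covariance
#' \eqn{S_B = \frac{n}{G-1}\sum_g (\bar y_g-\bar y)(\bar y_g-\bar y)'}.
#' Under the model, \eqn{E[S_{PW}] = \Sigma_W} and
#' \eqn{E[S_B] = \Sigma_W + n\,\Sigma_B}.
#'
#' @param data a [two_level_data()] object (or anything [two_level_data()]
#'   accepts via `scores`/`cluster`).
#' @param cluster cluster labels when `data` is a plain matrix/data frame.
#' @return An object of class `"mlcfa_stats"`: list with `G`, `n`, `N`,
#'   `p`, `grand_mean`, `cluster_means` (G x p), `pooled_within_sscp`,
#'   `s_pw`, `s_b`, and `b_sscp` (the between SSCP about the grand mean,
#'   scaled by n: \eqn{(G-1) S_B}).
#' @export
#' @examples
#' d <- two_level_data(matrix(c(1, 3, 5, 7), 4, 1), c(1, 1, 2, 2))
#' s <- suff_stats(d)
#' s$s_pw   # 2
#' s$s_b    # 16
suff_stats <- function(data, cluster = NULL) {
  if (!inherits(data, "two_level_data"))
    data <- two_level_data(data, cluster)
  y <- data$scores
  g <- as.integer(data$cluster)
  G <- data$G; n <- data$n; N <- data$N; p <- data$p
  cm <- rowsum(y, g, reorder = TRUE) / n
  grand <- colMeans(y)
  dev <- y - cm[g, , drop = FALSE]
  A <- crossprod(dev)
  cmd <- sweep(cm, 2L, grand)
  B <- n * crossprod(cmd)            # = (G-1) * s_b
  dimnames(A) <- dimnames(B) <- list(colnames(y), colnames(y))
  structure(list(G = G, n = n, N = N, p = p,
                 grand_mean = grand, cluster_means = cm,
                 pooled_within_sscp = A,
                 s_pw = A / (N - G),
                 s_b = B / (G - 1),
                 b_sscp = B),
            class = "mlcfa_stats")
}

#' @export
print.mlcfa_stats <- function(x, ...) {
  cat("Two-level sufficient statistics: G =", x$G, ", n =", x$n,
      ", p =", x$p, "\n")
  cat("pooled within covariance (S_PW):\n")
  print(round(x$s_pw, 4))
  cat("scaled between covariance (S_B, E[S_B] = Sigma_W + n Sigma_B):\n")
  print(round(x$s_b, 4))
  invisible(x)
}
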