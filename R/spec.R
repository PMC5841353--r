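#' Specify a two-level one-factor measurement model
#'
#' A model specification records which parameters of the balanced two-level
#' one-factor model are free, which are fixed, and which are constrained,
#' encoding the identification strategy. The referent (anchor) item's factor
#' loading is fixed at 1 at both the within and the between level, which
#' identifies the latent metric and implicitly imposes cross-level equality
#' for that item. Further constraints are expressed as two index sets:
#' items whose within- and between-level loadings are equated to a single
#' shared free loading, and items whose between-level residual variance is
#' fixed at zero. Item means are always saturated (one free mean per item)
#' and are profiled out of the likelihood analytically.
#'
#' @param n_items number of observed items \eqn{p} (at least 3 for an
#'   identified between-level factor with free residual variances).
#' @param referent 1-based index of the referent item.
#' @param equal_loadings integer vector of item indices whose within- and
#'   between-level loadings are constrained equal (a single shared free
#'   parameter per item). Must not contain the referent, whose equality is
#'   already implied by the fixed value.
#' @param zero_between_resid integer vector of item indices whose
#'   between-level residual variance is fixed at 0.
#'
#' @return An object of class `"mlcfa_spec"`.
#' @seealso [free_baseline_pair()], [constrained_baseline_pair()],
#'   [n_free_params()], [mlcfa()]
#' @export
#' @examples
#' # minimally identified ("free baseline") model for 5 items, referent 1
#' mlcfa_spec(5, referent = 1)
#' # fully constrained ("cluster invariance") model
#' mlcfa_spec(5, referent = 1, equal_loadings = 2:5, zero_between_resid = 1:5)
mlcfa_spec <- function(n_items, referent = 1L,
                       equal_loadings = integer(),
                       zero_between_resid = integer()) {
  n_items <- as.integer(n_items)
  referent <- as.integer(referent)
  equal_loadings <- sort(unique(as.integer(equal_loadings)))
  zero_between_resid <- sort(unique(as.integer(zero_between_resid)))
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1L)
    stop("'n_items' must be a single positive integer")
  if (length(referent) != 1L || is.na(referent) ||
      referent < 1L || referent > n_items)
    stop("'referent' must be an item index in 1..", n_items)
  if (any(equal_loadings < 1L | equal_loadings > n_items))
    stop("'equal_loadings' must be a subset of 1..", n_items)
  if (any(zero_between_resid < 1L | zero_between_resid > n_items))
    stop("'zero_between_resid' must be a subset of 1..", n_items)
  if (referent %in% equal_loadings)
    stop("the referent's cross-level equality is implied by its fixed ",
         "loading; do not list it in 'equal_loadings'")
  structure(
    list(n_items = n_items,
         referent = referent,
         equal_loadings = equal_loadings,
         zero_between_resid = zero_between_resid,
         referent_fixed_value = 1,
         means_saturated = TRUE),
    class = "mlcfa_spec")
}

#' Count the free parameters of a model specification
#'
#' Item means are saturated but profiled out analytically, so they are not
#' counted. The count is: 2 loadings for every non-referent item not under a
#' cross-level equality constraint, 1 for every equated item, plus the two
#' factor variances, plus p within residual variances, plus one between
#' residual variance for every item not fixed at zero.
#'
#' @param spec an [mlcfa_spec()] object.
#' @return integer free-parameter count.
#' @export
#' @examples
#' n_free_params(mlcfa_spec(5))                                   # 20
#' n_free_params(mlcfa_spec(5, equal_loadings = 2:5,
#'                          zero_between_resid = 1:5))            # 11
n_free_params <- function(spec) {
  stopifnot(inherits(spec, "mlcfa_spec"))
  p <- spec$n_items
  n_lam <- 2L * (p - 1L) - length(spec$equal_loadings)
  n_lam + 2L + p + (p - length(spec$zero_between_resid))
}

#' @export
print.mlcfa_spec <- function(x, ...) {
  cat("Two-level one-factor model specification\n")
  cat("  items:", x$n_items,
      " referent:", x$referent, "(loading fixed at 1, both levels)\n")
  cat("  cross-level equal loadings:",
      if (length(x$equal_loadings)) paste(x$equal_loadings, collapse = ", ")
      else "none", "\n")
  cat("  between residual variances fixed at 0:",
      if (length(x$zero_between_resid))
        paste(x$zero_between_resid, collapse = ", ")
      else "none", "\n")
  cat("  free parameters:", n_free_params(x), "\n")
  invisible(x)
}

#' Serialize / deserialize a model specification
#'
#' JSON round-tripping so that command-line runs are reproducible from
#' configuration alone.
#'
#' @param spec an [mlcfa_spec()] object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `spec_to_json()` a JSON string (invisibly, if written to a file);
#'   `spec_from_json()` an `mlcfa_spec`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "mlcfa_spec"))
  x <- list(n_items = spec$n_items, referent = spec$referent,
            equal_loadings = spec$equal_loadings,
            zero_between_resid = spec$zero_between_resid)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname spec_to_json
#' @param json a JSON string or a path to a JSON file.
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  mlcfa_spec(x$n_items, x$referent,
             equal_loadings = unlist(x$equal_loadings),
             zero_between_resid = unlist(x$zero_between_resid))
}
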