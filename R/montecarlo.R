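#' Run all replications of one design cell
#'
#' For every replication: generate a dataset for the condition, test one
#' biased target item (the true-positive target) and one unbiased
#' non-referent item (the false-positive target) for cluster bias under
#' the requested strategies, and tally the outcomes. Tested items follow
#' the study's reporting layout: the TP target is item 2 in
#' unbiased-anchor conditions and item 4 in biased-anchor conditions
#' (item 2 is the referent there and cannot be tested); the FP target is
#' item 3 everywhere. In zero-bias baseline cells both targets measure the
#' false-positive rate.
#'
#' All failure modes become tallies, never errors: a replication where
#' either model of a pair fails to converge counts as non-converged, a
#' negative likelihood-ratio statistic counts as inconclusive (NLD), and
#' neither contributes to the flag counts. Rates are expressed against the
#' intended number of replications, lost runs included.
#'
#' The same simulated datasets are analyzed under both strategies, and the
#' baseline model of each strategy is fitted once per replication and
#' reused for both tested items.
#'
#' @param condition a [bias_condition()].
#' @param strategies character subset of `c("free", "constrained")`.
#' @param reps intended replications (defaults to the condition's).
#' @param seed master seed for the cell's reproducible streams.
#' @param theta_w generating within residual variance.
#' @param alpha significance level.
#' @param ... passed to [mlcfa()].
#' @return A data frame of class `"cell_result"`, one row per strategy,
#'   with the condition fields, tested item indices, intended
#'   replications, counts (`tp_flagged`, `tp_nonsig`, `nld_tp`,
#'   `nonconv_tp`, and the `fp_*` analogues) and `tp_rate`, `fp_rate`.
#' @export
#' @examples
#' cond <- bias_condition(25, 50, icc = 0.1, n_biased = 1, bias_pct = 0.05)
#' run_cell(cond, reps = 5, seed = 7)
run_cell <- function(condition, strategies = c("free", "constrained"),
                     reps = condition$replications, seed = 1L,
                     theta_w = 0.5, alpha = 0.05, ...) {
  stopifnot(inherits(condition, "bias_condition"))
  reps <- as.integer(reps)
  strategies <- match.arg(strategies, several.ok = TRUE)
  p <- condition$p
  referent <- condition$referent
  tp_item <- if (condition$anchor_biased) 4L else 2L
  fp_item <- 3L

  zero <- c(flagged = 0L, nonsig = 0L, nld = 0L, nonconv = 0L)
  tallies <- list()
  for (s in strategies)
    tallies[[s]] <- list(tp = zero, fp = zero)

  classify <- function(status) switch(status,
    significant = "flagged", non_significant = "nonsig",
    inconclusive_negative = "nld", non_converged = "nonconv")

  for (r in seq_len(reps)) {
    d <- simulate_condition(condition, r, theta_w = theta_w,
                            master_seed = seed)
    stats <- suff_stats(d)
    for (s in strategies) {
      base_spec <- if (s == "free")
        free_baseline_pair(p, referent, tp_item)$unrestricted
      else constrained_baseline_pair(p, referent, tp_item)$restricted
      base_fit <- mlcfa(base_spec, stats = stats, ...)
      for (target in c("tp", "fp")) {
        item <- if (target == "tp") tp_item else fp_item
        out <- cluster_bias_test(stats = stats, item = item, strategy = s,
                                 referent = referent, alpha = alpha,
                                 baseline_fit = base_fit, ...)
        k <- classify(out$lrt$status)
        tallies[[s]][[target]][k] <- tallies[[s]][[target]][k] + 1L
      }
    }
  }

  rows <- lapply(strategies, function(s) {
    tt <- tallies[[s]]$tp; ff <- tallies[[s]]$fp
    data.frame(cell = condition$cell, L2N = condition$L2N,
               L1N = condition$L1N, icc = condition$icc,
               n_biased = condition$n_biased, bias_pct = condition$bias_pct,
               anchor_biased = condition$anchor_biased,
               strategy = s, tested_tp_item = tp_item,
               tested_fp_item = fp_item, reps_intended = reps,
               tp_flagged = tt[["flagged"]], tp_nonsig = tt[["nonsig"]],
               nld_tp = tt[["nld"]], nonconv_tp = tt[["nonconv"]],
               fp_flagged = ff[["flagged"]], fp_nonsig = ff[["nonsig"]],
               nld_fp = ff[["nld"]], nonconv_fp = ff[["nonconv"]],
               tp_rate = tt[["flagged"]] / reps,
               fp_rate = ff[["flagged"]] / reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cell_result", class(out))
  out
}

#' Enumerate the factorial study design
#'
#' The full design comprises 18 zero-bias baseline-check conditions
#' (3 cluster sizes x 2 cluster counts x 3 ICCs) and 144 bias conditions
#' (the same 18 crossed with 1 or 2 biased items, 1% or 5% bias, and a
#' biased or unbiased anchor). Cell ids are assigned sequentially in
#' enumeration order and seed the per-cell random streams.
#'
#' @param which `"all"`, `"baseline"` (zero-bias cells only),
#'   `"unbiased_anchor"` or `"biased_anchor"` (bias cells only).
#' @param replications intended replications recorded on each condition.
#' @return list of [bias_condition()] objects.
#' @export
#' @examples
#' length(study_design())                   # 162
#' length(study_design("unbiased_anchor"))  # 72
study_design <- function(which = c("all", "baseline", "unbiased_anchor",
                                   "biased_anchor"),
                         replications = 500L) {
  which <- match.arg(which)
  L1 <- c(2L, 5L, 25L); L2 <- c(50L, 100L); ICC <- c(0.10, 0.20, 0.30)
  out <- list()
  cell <- 0L
  add <- function(lst, cond) { lst[[length(lst) + 1L]] <- cond; lst }
  if (which %in% c("all", "baseline"))
    for (g in L2) for (n in L1) for (i in ICC) {
      cell <- cell + 1L
      out <- add(out, bias_condition(n, g, i, 0L, 0,
                                     replications = replications,
                                     cell = cell))
    }
  else cell <- 18L
  if (which != "baseline")
    for (anchor in c(FALSE, TRUE))
      for (nb in 1:2) for (b in c(0.01, 0.05))
        for (g in L2) for (n in L1) for (i in ICC) {
          cell <- cell + 1L
          if (which == "unbiased_anchor" && anchor) next
          if (which == "biased_anchor" && !anchor) next
          out <- add(out, bias_condition(n, g, i, nb, b,
                                         anchor_biased = anchor,
                                         replications = replications,
                                         cell = cell))
        }
  out
}

#' Run a grid of design cells
#'
#' Runs [run_cell()] for every condition in a design (the full factorial
#' study or any subset) and stacks the per-cell results. Optionally writes
#' one JSON file per cell under `out_dir`, in which case already-present
#' cells are loaded instead of re-run, making long grids resumable.
#'
#' @param design list of [bias_condition()]s, e.g. from [study_design()].
#' @param strategies strategies to run.
#' @param reps intended replications per cell (`NULL` uses each
#'   condition's own).
#' @param seed master seed.
#' @param theta_w generating within residual variance.
#' @param out_dir optional directory for per-cell JSON results.
#' @param verbose print a line per cell.
#' @param ... passed to [mlcfa()] via [run_cell()].
#' @return data frame of class `"mlcfa_study"`: stacked cell results.
#' @export
run_grid <- function(design, strategies = c("free", "constrained"),
                     reps = NULL, seed = 1L, theta_w = 0.5,
                     out_dir = NULL, verbose = FALSE, ...) {
  rows <- vector("list", length(design))
  for (k in seq_along(design)) {
    cond <- design[[k]]
    f <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("cell_%03d.json", cond$cell)) else NULL
    if (!is.null(f) && file.exists(f)) {
      rows[[k]] <- as.data.frame(jsonlite::fromJSON(f))
    } else {
      r <- run_cell(cond, strategies = strategies,
                    reps = if (is.null(reps)) cond$replications else reps,
                    seed = seed, theta_w = theta_w, ...)
      if (!is.null(f)) {
        dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(r, f, digits = NA)
      }
      rows[[k]] <- r
    }
    if (verbose)
      message(sprintf("cell %d/%d (id %d) done", k, length(design),
                      cond$cell))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mlcfa_study", "data.frame")
  out
}

#' Overall decision-accuracy aggregates
#'
#' Unweighted means of the per-cell true-positive and false-positive rates
#' over the bias cells with the requested anchor status, by strategy (the
#' design is balanced, so the unweighted cell mean matches any reasonable
#' pooling).
#'
#' @param cells a `"mlcfa_study"` data frame from [run_grid()].
#' @param anchor_biased which bias cells to aggregate.
#' @return data frame with one row per strategy: `tp_rate`, `fp_rate`,
#'   `n_cells`.
#' @export
aggregate_overall <- function(cells, anchor_biased = FALSE) {
  sub <- cells[cells$n_biased > 0 &
               cells$anchor_biased == anchor_biased, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no bias cells with anchor_biased = ", anchor_biased,
         " in the summary")
  strategies <- unique(sub$strategy)
  do.call(rbind, lapply(strategies, function(s) {
    x <- sub[sub$strategy == s, ]
    data.frame(strategy = s, anchor_biased = anchor_biased,
               tp_rate = mean(x$tp_rate), fp_rate = mean(x$fp_rate),
               n_cells = nrow(x), stringsAsFactors = FALSE)
  }))
}

#' Eta-squared effect sizes over cell outcomes
#'
#' Fixed-effects ANOVA decomposition with design cells as observations:
#' \eqn{\eta^2 = SS_{effect}/SS_{total}} for each named factor (and,
#' optionally, all pairwise interactions among them). Factors with a
#' single observed level are dropped and reported as absent.
#'
#' @param cells a cell-result data frame (rows = cells x strategies).
#' @param outcome `"tp_rate"` or `"fp_rate"`.
#' @param factors column names treated as crossed factors.
#' @param interactions include all two-way interactions?
#' @return data frame with `term`, `df`, `sum_sq`, `eta_sq`, `F`,
#'   `p_value`; the residual row carries `eta_sq` as its share of total SS,
#'   so the `eta_sq` column sums to 1.
#' @export
#' @examples
#' # a factor that perfectly determines the outcome has eta^2 = 1
#' toy <- data.frame(y = c(0, 0, 1, 1), f = c("a", "a", "b", "b"),
#'                   g = c("u", "v", "u", "v"))
#' eta_squared(toy, "y", c("f", "g"))
eta_squared <- function(cells, outcome = c("tp_rate", "fp_rate"),
                        factors = c("L2N", "L1N", "icc", "n_biased",
                                    "bias_pct", "strategy"),
                        interactions = FALSE) {
  outcome <- if (outcome[1L] %in% names(cells)) outcome[1L]
             else match.arg(outcome)
  keep <- factors[vapply(factors, function(f)
    length(unique(cells[[f]])) > 1L, logical(1))]
  dropped <- setdiff(factors, keep)
  if (length(keep) == 0L) stop("no factor with more than one level")
  df <- data.frame(.y = cells[[outcome]])
  for (f in keep) df[[f]] <- factor(cells[[f]])
  rhs <- paste(keep, collapse = " + ")
  if (interactions && length(keep) > 1L)
    rhs <- paste(rhs, "+", paste(utils::combn(keep, 2, paste,
                                              collapse = ":"),
                                 collapse = " + "))
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  an <- stats::anova(fit)
  ss_total <- sum(an[["Sum Sq"]])
  out <- data.frame(term = rownames(an), df = an$Df, sum_sq = an[["Sum Sq"]],
                    eta_sq = an[["Sum Sq"]] / ss_total,
                    F = an[["F value"]], p_value = an[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}
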