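#' Predict logic phenotypes for a set of arrangements
#'
#' Runs [truth_table()] and [classify_model()] for each arrangement at a
#' fixed parameter point. Deterministic; solver non-convergence is carried
#' through in the `converged` column.
#'
#' @param arrangements List of [arrangement()] objects.
#' @param params A [model_params()].
#' @param method Steady-state solver route, see [steady_state()].
#' @return Data frame with one row per arrangement: `label`, `phenotype`,
#'   the four raw cI values (`cI_none`, `cI_IPTG`, `cI_aTc`, `cI_both`) and
#'   `converged`.
#' @export
predict_all <- function(arrangements, params = model_params(),
                        method = "newton") {
  rows <- lapply(arrangements, function(a) {
    tt <- truth_table(a, params, method = method)
    data.frame(label = a$label,
               phenotype = classify_model(tt$cI, params$tau),
               cI_none = tt$cI[["none"]], cI_IPTG = tt$cI[["IPTG"]],
               cI_aTc = tt$cI[["aTc"]], cI_both = tt$cI[["both"]],
               converged = all(tt$table$converged),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default parameter grids for the (K, mu) search
#'
#' `K` is logarithmic over \[1e-3, 10\] (25 points) and `mu` linear over
#' \[0, 1\] (21 points). These are package defaults (the search resolution is
#' configurable); results are reported as admissible regions, never a single
#' best point.
#'
#' @return List with numeric vectors `K` and `mu`.
#' @export
default_grids <- function() {
  list(K = 10^seq(-3, 1, length.out = 25),
       mu = seq(0, 1, length.out = 21))
}

#' Grid search for the admissible (K, mu) region
#'
#' For every grid cell, predicts the logic phenotype of each arrangement in
#' the observed table and counts agreements with the observed labels. The
#' admissible region is the set of cells attaining the maximum agreement
#' (the model is fit to logic classes, and the paper-scale data leave some
#' networks unexplained, so admissibility is defined by maximal rather than
#' perfect agreement).
#'
#' @param observed Data frame with columns `label` (arrangement labels) and
#'   `phenotype` (observed logic labels), one row per arrangement.
#' @param K_grid,mu_grid Grid axis values; defaults from [default_grids()].
#' @param tau Classification threshold.
#' @param params Base [model_params()]; `K` and `mu` are overridden cell by
#'   cell.
#' @param predictions Optional precomputed prediction array (from
#'   [grid_predictions()]) to reuse across repeated searches on the same
#'   grid.
#' @return An object of class `grid_result`: list with `K_grid`, `mu_grid`,
#'   `agreement` (K x mu matrix of counts), `admissible` (logical matrix),
#'   `max_agreement`, `n_observed`, and `argmax` (data frame of admissible
#'   cells in deterministic K-major order).
#' @export
grid_search <- function(observed, K_grid = default_grids()$K,
                        mu_grid = default_grids()$mu, tau = 2 / 5,
                        params = model_params(), predictions = NULL) {
  stopifnot(is.data.frame(observed),
            all(c("label", "phenotype") %in% names(observed)))
  if (nrow(observed) == 0L) stop("observed table is empty")
  if (anyDuplicated(observed$label)) {
    stop("duplicate arrangement labels in observed table")
  }
  stopifnot(length(K_grid) > 0, length(mu_grid) > 0, all(K_grid > 0))
  if (is.null(predictions)) {
    predictions <- grid_predictions(observed$label, K_grid, mu_grid, tau,
                                    params)
  }
  stopifnot(identical(dimnames(predictions)[[1]], observed$label))
  agreement <- matrix(0L, length(K_grid), length(mu_grid))
  for (i in seq_along(K_grid)) {
    for (j in seq_along(mu_grid)) {
      agreement[i, j] <- sum(predictions[, i, j] == observed$phenotype)
    }
  }
  max_agree <- max(agreement)
  admissible <- agreement == max_agree
  idx <- which(admissible, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  argmax <- data.frame(K = K_grid[idx[, 1]], mu = mu_grid[idx[, 2]],
                       agreement = agreement[idx])
  structure(list(K_grid = K_grid, mu_grid = mu_grid, agreement = agreement,
                 admissible = admissible, max_agreement = max_agree,
                 n_observed = nrow(observed), argmax = argmax),
            class = "grid_result")
}

#' Predicted labels for a label set over a (K, mu) grid
#'
#' Computes the model phenotype of each arrangement at every grid cell.
#' Useful on its own and as a cache for repeated [grid_search()] calls
#' against different observed tables on the same grid.
#'
#' @param labels Character vector of arrangement labels.
#' @inheritParams grid_search
#' @return A 3-d character array \[label, K, mu\] with dimnames.
#' @export
grid_predictions <- function(labels, K_grid = default_grids()$K,
                             mu_grid = default_grids()$mu, tau = 2 / 5,
                             params = model_params()) {
  arrs <- lapply(labels, parse_label)
  cmps <- lapply(arrs, compile_arrangement)
  out <- array(NA_character_,
               dim = c(length(labels), length(K_grid), length(mu_grid)),
               dimnames = list(labels, signif(K_grid, 10),
                               signif(mu_grid, 10)))
  for (i in seq_along(K_grid)) {
    for (j in seq_along(mu_grid)) {
      p <- params
      p$K <- K_grid[i]
      p$mu <- mu_grid[j]
      p$tau <- tau
      for (k in seq_along(arrs)) {
        cI <- fast_cI(cmps[[k]], p, a = arrs[[k]])
        out[k, i, j] <- classify_model(cI, tau)
      }
    }
  }
  out
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<grid_result> %d x %d grid; max agreement %d/%d in %d cell(s)\n",
    length(x$K_grid), length(x$mu_grid), x$max_agreement, x$n_observed,
    nrow(x$argmax)))
  invisible(x)
}

#' Compare predicted and observed phenotype tables
#'
#' Joins predictions to observations by arrangement label and summarizes
#' agreement overall and per orientation pair (both members agree, both
#' disagree, or the pair is split).
#'
#' @param predicted Data frame with columns `label`, `phenotype` (e.g. from
#'   [predict_all()]).
#' @param observed Data frame with columns `label`, `phenotype`.
#' @return List with `n`, `n_agree`, `n_disagree`, `per_arrangement` (data
#'   frame `label`, `predicted`, `observed`, `agree`, `pair`), and `pairs`
#'   (data frame `pair`, `n_members`, `concordance`) for pairs with both
#'   members present.
#' @export
compare_predictions <- function(predicted, observed) {
  stopifnot(all(c("label", "phenotype") %in% names(predicted)),
            all(c("label", "phenotype") %in% names(observed)))
  missing_pred <- setdiff(observed$label, predicted$label)
  if (length(missing_pred)) {
    stop("no prediction for observed label(s): ",
         paste(missing_pred, collapse = ", "))
  }
  m <- merge(observed[, c("label", "phenotype")],
             predicted[, c("label", "phenotype")],
             by = "label", suffixes = c(".obs", ".pred"), sort = TRUE)
  per <- data.frame(label = m$label, predicted = m$phenotype.pred,
                    observed = m$phenotype.obs,
                    agree = m$phenotype.pred == m$phenotype.obs,
                    pair = vapply(m$label,
                                  function(l) pair_id(parse_label(l)),
                                  character(1)),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  pair_rows <- lapply(split(per, per$pair), function(d) {
    conc <- if (nrow(d) < 2L) "incomplete"
            else if (all(d$agree)) "both_agree"
            else if (!any(d$agree)) "both_disagree"
            else "split"
    data.frame(pair = d$pair[1], n_members = nrow(d), concordance = conc,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  list(n = nrow(per), n_agree = sum(per$agree),
       n_disagree = sum(!per$agree), per_arrangement = per, pairs = pairs)
}
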