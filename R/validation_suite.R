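#' Activity-ranked train/test partitioning
#'
#' Molecules carrying the tied minimal score form the "inactive" block;
#' the rest are actives. Actives are sorted by descending score (ties
#' keep input order) and chunked into groups of `ranked_group_size`; the
#' top `ranked_group_size - 1` of each group go to training and the
#' remainder to test. `n_random_inactive_test` inactives are drawn
#' (seeded) for the test set unless an explicit choice is supplied; the
#' remaining inactives train.
#'
#' @param activities named numeric score vector.
#' @param ranked_group_size actives per ranked group (default 4).
#' @param n_random_inactive_test inactives placed in the test set
#'   (default 3).
#' @param seed seed for the random inactive draw.
#' @param test_inactive_ids explicit inactive test ids (overrides the
#'   random draw; use this to reproduce a published partition).
#' @param test_ids fully explicit test set (overrides everything).
#' @return object of class `Partition`: list with `training_ids`,
#'   `test_ids`. A test set smaller than 5 molecules triggers a warning
#'   (external-test size guideline).
#' @export
partition_by_activity <- function(activities, ranked_group_size = 4,
                                  n_random_inactive_test = 3, seed = 1,
                                  test_inactive_ids = NULL,
                                  test_ids = NULL) {
  ids <- names(activities)
  if (is.null(ids)) stop("activities must be named by molecule id")
  # external-test guideline (at least 5 test compounds)
  check_size <- function(part) {
    if (length(part$test_ids) < 5L) {
      warning("external test set has fewer than 5 molecules; ",
              "test statistics may be unreliable")
    }
    part
  }
  if (!is.null(test_ids)) {
    test_ids <- as.character(test_ids)
    if (!all(test_ids %in% ids)) stop("unknown test ids")
    return(check_size(structure(list(training_ids = setdiff(ids, test_ids),
                                     test_ids = test_ids),
                                class = "Partition")))
  }
  lo <- min(activities)
  inactive <- ids[activities == lo]
  if (length(inactive) < 2L) inactive <- character(0)  # no tied block
  active <- setdiff(ids, inactive)
  if (length(active) < ranked_group_size) {
    stop("not enough scored actives for ranked partitioning")
  }
  # stable descending sort: ties keep their input order
  act_ord <- active[order(-activities[active])]
  grp <- ceiling(seq_along(act_ord) / ranked_group_size)
  test_act <- unlist(lapply(split(act_ord, grp), function(g) {
    if (length(g) >= ranked_group_size) g[ranked_group_size:length(g)]
    else character(0)
  }), use.names = FALSE)
  if (is.null(test_inactive_ids)) {
    n_draw <- min(n_random_inactive_test, length(inactive))
    test_inact <- if (n_draw > 0) {
      withr::with_seed(as.integer(seed), sample(inactive, n_draw))
    } else character(0)
  } else {
    test_inactive_ids <- as.character(test_inactive_ids)
    if (!all(test_inactive_ids %in% inactive)) {
      stop("test_inactive_ids must come from the tied-minimal-score block")
    }
    test_inact <- test_inactive_ids
  }
  test <- c(test_act, test_inact)
  check_size(structure(list(training_ids = setdiff(ids, test),
                            test_ids = test), class = "Partition"))
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("<Partition: %d training / %d test>\n",
              length(x$training_ids), length(x$test_ids)))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper: at least 3 pairs and nonzero variance on both
#' sides are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) stop("zero variance")
  stats::cor(x, y)
}

#' External-test statistics of trained models
#'
#' Consensus-predicts every test molecule and reports the Pearson r and
#' the least-squares line of predicted (y) on experimental (x). The
#' models must have been trained on the training molecules only; test
#' activities are consulted exclusively here.
#'
#' @param models list of `QsarModel`s (trained on `partition$training_ids`).
#' @param partition a `Partition`.
#' @param sim the full `SimilarityMatrix` (training + test molecules).
#' @param activities named score vector for at least the test molecules.
#' @return list with `r`, `slope`, `intercept`, `predicted`,
#'   `experimental`.
#' @export
external_test_stats <- function(models, partition, sim, activities) {
  test <- partition$test_ids
  if (length(test) < 3) stop("test set must contain at least 3 molecules")
  for (m in models) {
    if (any(test %in% m$training_ids)) {
      stop("model was trained on test molecule(s); invalid external test")
    }
  }
  pred <- vapply(test, function(id) {
    consensus_predict(models, descriptor_row(sim, id))
  }, numeric(1))
  expm <- activities[test]
  fit <- stats::lm(pred ~ expm)
  list(r = pearson_r(expm, pred),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       predicted = pred, experimental = expm)
}

#' Functional dependence of a model on one descriptor
#'
#' Scans one descriptor over its observed range (default 50 evenly
#' spaced points) while pinning the other three at their training-set
#' average similarity, and records the predicted activity. A physically
#' sensible model shows increasing curves for descriptors referencing
#' cross-reactive molecules and decreasing curves for descriptors
#' referencing inert ones.
#'
#' @param model a `QsarModel`.
#' @param descriptor one of the model's descriptor ids (or index 1-4).
#' @param pool descriptor pool the model was trained on.
#' @param n_points scan resolution (default 50).
#' @param scan_range optional `c(lo, hi)` override; default is the
#'   descriptor's observed min/max in the pool.
#' @return data frame with columns `similarity`, `predicted`.
#' @export
functional_dependence <- function(model, descriptor, pool, n_points = 50,
                                  scan_range = NULL) {
  if (is.numeric(descriptor)) descriptor <- model$descriptor_ids[descriptor]
  if (!descriptor %in% model$descriptor_ids) {
    stop("descriptor is not part of the model")
  }
  cols <- pool[, model$descriptor_ids, drop = FALSE]
  avg <- colMeans(cols)
  if (is.null(scan_range)) scan_range <- range(cols[, descriptor])
  xs <- seq(scan_range[1], scan_range[2], length.out = n_points)
  preds <- vapply(xs, function(v) {
    q <- avg
    q[descriptor] <- v
    predict(model, q)
  }, numeric(1))
  data.frame(similarity = xs, predicted = preds)
}

#' y-randomization (activity scrambling) robustness check
#'
#' Re-runs the whole GNN procedure with randomly shuffled activities.
#' Per shuffle the best `keep_best` models with non-negative q2 are
#' retained together with their training-set r2 (squared Pearson of
#' fitted vs experimental). The separation flag is true iff every real
#' model's q2 strictly exceeds every retained randomized q2.
#'
#' @inheritParams run_ensemble
#' @param n_shuffles activity randomizations (100 at full scale).
#' @param runs_per_shuffle GA runs per shuffle (50 at full scale).
#' @param keep_best randomized models retained per shuffle (default 10).
#' @param seed master seed for shuffling and GA runs.
#' @param real_models models fit to the true activities (e.g. the top 3
#'   from [run_ensemble()]); needed for the separation flag.
#' @return object of class `RandomizationReport`: list with `random`
#'   (data frame shuffle/q2/r2), `real` (data frame q2/r2), `separated`.
#' @export
y_randomize <- function(pool, activities, n_shuffles = 100,
                        runs_per_shuffle = 50, keep_best = 10, seed = 1,
                        real_models = NULL, population = 250,
                        generations = 75, subset_size = 4, max_iter = 500,
                        tol = 1e-6) {
  y <- align_activities(pool, activities)
  train_r2 <- function(model, yy) {
    fitted <- vapply(seq_len(nrow(pool)), function(i) {
      predict(model, pool[i, model$descriptor_ids])
    }, numeric(1))
    pearson_r(yy, fitted)^2
  }
  shuffles <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_shuffles), function(s) sample(y))
  })
  rows <- list()
  for (s in seq_len(n_shuffles)) {
    ys <- shuffles[[s]]
    stopifnot(identical(sort(ys), sort(y)))  # multiset preserved
    names(ys) <- rownames(pool)
    models <- tryCatch(
      run_ensemble(pool, ys, n_runs = runs_per_shuffle,
                   base_seed = seed + 1000L * s, population = population,
                   generations = generations, subset_size = subset_size,
                   n_models = keep_best, max_iter = max_iter, tol = tol),
      error = function(e) list())
    models <- Filter(function(m) m$q2 >= 0, models)
    models <- models[seq_len(min(keep_best, length(models)))]
    for (m in models) {
      rows[[length(rows) + 1L]] <-
        data.frame(shuffle = s, q2 = m$q2, r2 = train_r2(m, ys))
    }
  }
  random <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(shuffle = integer(0), q2 = numeric(0), r2 = numeric(0))
  real <- NULL
  separated <- NA
  if (!is.null(real_models)) {
    real <- data.frame(
      q2 = vapply(real_models, function(m) m$q2, numeric(1)),
      r2 = vapply(real_models, function(m) train_r2(m, y), numeric(1)))
    separated <- if (nrow(random) == 0) TRUE else
      min(real$q2) > max(random$q2)
  }
  structure(list(random = random, real = real, separated = separated),
            class = "RandomizationReport")
}

#' @export
print.RandomizationReport <- function(x, ...) {
  cat(sprintf("<RandomizationReport: %d randomized models kept", nrow(x$random)))
  if (nrow(x$random) > 0) cat(sprintf(", max q2 %.3f", max(x$random$q2)))
  if (!is.null(x$real)) cat(sprintf("; real min q2 %.3f; separated: %s",
                                    min(x$real$q2), x$separated))
  cat(">\n")
  invisible(x)
}
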