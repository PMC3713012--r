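#' Affine activity scaling onto the sigmoid output range
#'
#' Maps `[min(scores), max(scores)]` onto `[0.1, 0.9]` (required because
#' the network output unit is a logistic sigmoid) and records the inverse
#' for prediction read-out.
#'
#' @param scores numeric activities with at least 2 distinct values.
#' @return list with `forward`, `inverse`, `min`, `max`.
#' @export
scale_activities <- function(scores) {
  lo <- min(scores); hi <- max(scores)
  if (hi - lo <= 0) stop("activities are constant; cannot scale")
  list(
    forward = function(y) 0.1 + 0.8 * (y - lo) / (hi - lo),
    inverse = function(t) lo + (t - 0.1) / 0.8 * (hi - lo),
    min = lo, max = hi
  )
}

initial_weights <- function(seed) {
  withr::with_seed(as.integer(seed), stats::runif(7, -0.5, 0.5))
}

#' Train the 4-1-1 neural network
#'
#' One logistic hidden unit and one logistic output unit: 5 weights plus
#' 2 thresholds, 7 adjustable parameters in all. Trained by scaled
#' conjugate gradient on the sum-of-squares error; bit-reproducible for a
#' fixed seed (the seed only sets the initial weights).
#'
#' @param inputs numeric matrix, one row per molecule, 4 columns.
#' @param targets scaled targets in (0, 1).
#' @param seed integer; determines the initial weights.
#' @param max_iter,tol optimizer budget (weight updates; gradient-norm
#'   stopping tolerance).
#' @return object of class `NeuralNet411`: list with `weights` (7),
#'   `sse`, `iterations`, `grad_norm`.
#' @export
train_net <- function(inputs, targets, seed = 1, max_iter = 500,
                      tol = 1e-6) {
  inputs <- as.matrix(inputs)
  if (!all(is.finite(inputs)) || !all(is.finite(targets))) {
    stop("inputs and targets must be finite")
  }
  if (nrow(inputs) < 5) {
    stop("need at least 5 training rows for 7 parameters")
  } else if (nrow(inputs) < 8) {
    warning("fewer than 8 rows for 7 adjustable parameters; fit may be underdetermined")
  }
  fit <- cpp_train_net(inputs, as.numeric(targets), initial_weights(seed),
                       as.integer(max_iter), tol)
  structure(list(weights = fit$par, sse = fit$sse,
                 iterations = fit$iterations, grad_norm = fit$grad_norm),
            class = "NeuralNet411")
}

#' Forward pass of a 4-1-1 network
#' @param net a `NeuralNet411` (or 7-vector of weights).
#' @param inputs matrix (or 4-vector) of descriptor values.
#' @return sigmoid outputs in (0, 1).
#' @export
forward_net <- function(net, inputs) {
  w <- if (inherits(net, "NeuralNet411")) net$weights else as.numeric(net)
  if (is.null(dim(inputs))) inputs <- matrix(inputs, ncol = 4)
  cpp_forward_net(w, as.matrix(inputs))
}

#' Build the similarity-descriptor pool
#'
#' One column per (reference molecule, field) pair, i.e. 2N columns for N
#' training molecules, named `shape|<id>` and `elec|<id>`. Row i, column
#' `shape|r` holds the shape similarity of molecule i to reference r;
#' self-similarity columns are included.
#'
#' @param sim a `SimilarityMatrix`.
#' @param ids molecules to use (default: all in `sim`).
#' @return numeric matrix with molecule ids as row names.
#' @export
build_descriptor_pool <- function(sim, ids = NULL) {
  if (is.null(ids)) ids <- sim$ids
  ids <- as.character(ids)
  S <- sim$shape[ids, ids, drop = FALSE]
  E <- sim$electrostatic[ids, ids, drop = FALSE]
  pool <- cbind(S, E)
  colnames(pool) <- c(paste0("shape|", ids), paste0("elec|", ids))
  rownames(pool) <- ids
  pool
}

#' Descriptor values of one molecule against a reference set
#'
#' Extracts a query molecule's similarity to every reference molecule in
#' both fields, named like the columns of [build_descriptor_pool()], for
#' use with [predict.QsarModel()] and [consensus_predict()].
#'
#' @param sim a `SimilarityMatrix` containing both the query and the
#'   reference molecules.
#' @param query_id molecule id of the query.
#' @param reference_ids reference (training) molecule ids; default all.
#' @return named numeric vector.
#' @export
descriptor_row <- function(sim, query_id, reference_ids = NULL) {
  if (is.null(reference_ids)) reference_ids <- sim$ids
  reference_ids <- as.character(reference_ids)
  out <- c(sim$shape[query_id, reference_ids],
           sim$electrostatic[query_id, reference_ids])
  names(out) <- c(paste0("shape|", reference_ids),
                  paste0("elec|", reference_ids))
  out
}

check_subset <- function(pool, subset) {
  if (is.character(subset)) {
    idx <- match(subset, colnames(pool))
    if (any(is.na(idx))) stop("unknown descriptor(s): ",
                              paste(subset[is.na(idx)], collapse = ", "))
    subset <- idx
  }
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("descriptor subset contains duplicates")
  subset
}

align_activities <- function(pool, activities) {
  if (is.null(names(activities))) {
    if (length(activities) != nrow(pool)) stop("activities do not match pool rows")
    return(as.numeric(activities))
  }
  idx <- match(rownames(pool), names(activities))
  if (any(is.na(idx))) {
    stop("missing activity for molecule(s): ",
         paste(rownames(pool)[is.na(idx)], collapse = ", "))
  }
  as.numeric(activities[idx])
}

#' Leave-one-out cross-validated q2 of a descriptor subset
#'
#' For each molecule the 4-1-1 net is retrained on the other N-1 rows
#' (from the same seed-derived initial weights) and the held-out activity
#' is predicted and back-transformed;
#' `q2 = 1 - sum(y_pred - y_exp)^2 / sum(y_exp - mean(y_exp))^2`.
#' `q2 = 1` for perfect prediction; 0 means no better than the mean.
#'
#' @param pool descriptor pool from [build_descriptor_pool()].
#' @param subset 4 column names or indices.
#' @param activities named numeric vector (names = molecule ids) or
#'   unnamed vector aligned with pool rows.
#' @param seed integer; initial-weight seed shared by all folds.
#' @param max_iter,tol optimizer budget per fold.
#' @return q2 (at most 1).
#' @export
loo_q2 <- function(pool, subset, activities, seed = 1, max_iter = 500,
                   tol = 1e-6) {
  subset <- check_subset(pool, subset)
  y <- align_activities(pool, activities)
  if (stats::var(y) <= 0) stop("degenerate activity variance")
  cpp_loo_q2(pool[, subset, drop = FALSE], y, initial_weights(seed),
             as.integer(max_iter), tol)
}

#' Cross-validated correlation coefficient q2
#'
#' `q2 = 1 - sum(y_pred - y_exp)^2 / sum(y_exp - mean(y_exp))^2`. Equals
#' 1 for perfect prediction and 0 when predictions are no better than
#' the experimental mean.
#'
#' @param y_exp experimental activities.
#' @param y_pred predicted activities (e.g. from cross-validation).
#' @return q2 value (at most 1 only when predictions beat the mean; can
#'   be arbitrarily negative).
#' @export
q_squared <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred)) stop("length mismatch")
  ss <- sum((y_exp - mean(y_exp))^2)
  if (ss <= 0) stop("degenerate activity variance")
  1 - sum((y_pred - y_exp)^2) / ss
}

subset_key <- function(idx) paste(sort(idx), collapse = "-")

make_fitness <- function(pool, y, nn_seed, max_iter, tol, cache) {
  w0 <- initial_weights(nn_seed)
  function(idx) {
    key <- subset_key(idx)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- cpp_loo_q2(pool[, idx, drop = FALSE], y, w0,
                        max_iter, tol)
      cache[[key]] <- val
    }
    val
  }
}

random_subset <- function(p, k) sort(sample.int(p, k))

finalize_model <- function(pool, y, idx, q2, nn_seed, max_iter, tol,
                           seed, run_index) {
  sc <- scale_activities(y)
  fit <- cpp_train_net(pool[, idx, drop = FALSE], sc$forward(y),
                       initial_weights(nn_seed), max_iter, tol)
  structure(list(
    descriptor_ids = colnames(pool)[idx],
    descriptor_index = idx,
    net = structure(list(weights = fit$par, sse = fit$sse,
                         iterations = fit$iterations,
                         grad_norm = fit$grad_norm),
                    class = "NeuralNet411"),
    q2 = q2,
    scaling = c(min = sc$min, max = sc$max),
    training_ids = rownames(pool),
    seed = seed, nn_seed = nn_seed, run_index = run_index
  ), class = "QsarModel")
}

#' @export
print.QsarModel <- function(x, ...) {
  cat(sprintf("<QsarModel q2 = %.3f: %s>\n", x$q2,
              paste(x$descriptor_ids, collapse = ", ")))
  invisible(x)
}

#' Genetic-algorithm descriptor selection
#'
#' Evolves fixed-size subsets of descriptor-pool columns with LOO q2 of
#' the 4-1-1 net as fitness. Chromosomes are sets of 4 distinct column
#' indices; tournament selection (size 2), uniform crossover with
#' duplicate repair, per-gene mutation (rate 0.05, resampling an unused
#' column) and elitism of 1, so best-fitness is non-decreasing across
#' generations. Deterministic for a fixed seed.
#'
#' @inheritParams loo_q2
#' @param population number of individuals (default 250).
#' @param generations evolutionary cycles (default 75).
#' @param subset_size descriptors per model (default 4).
#' @param seed GA random seed.
#' @param nn_seed seed for the net's initial weights (default `seed`);
#'   kept separate so repeated GA runs share one fitness landscape.
#' @param n_models unique-subset models to return (default 10).
#' @param cache optional environment memoizing subset fitness across
#'   calls with identical `pool`/`activities`/`nn_seed`.
#' @return list of `QsarModel`, unique subsets sorted by q2 descending.
#' @export
ga_select <- function(pool, activities, population = 250, generations = 75,
                      subset_size = 4, seed = 1, nn_seed = seed,
                      n_models = 10, max_iter = 500, tol = 1e-6,
                      cache = NULL) {
  p <- ncol(pool)
  if (p < subset_size) stop("pool has fewer columns than subset_size")
  y <- align_activities(pool, activities)
  if (stats::var(y) <= 0) stop("degenerate activity variance")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  fitness <- make_fitness(pool, y, nn_seed, as.integer(max_iter), tol, cache)

  if (p == subset_size) {
    idx <- seq_len(p)
    return(list(finalize_model(pool, y, idx, fitness(idx), nn_seed,
                               as.integer(max_iter), tol, seed, 1L)))
  }

  result <- withr::with_seed(as.integer(seed), {
    pop <- replicate(population, random_subset(p, subset_size),
                     simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
    trajectory <- numeric(generations + 1L)
    trajectory[1L] <- max(fit)
    for (gen in seq_len(generations)) {
      elite <- which.max(fit)
      newpop <- vector("list", population)
      newpop[[1L]] <- pop[[elite]]
      for (i in 2:population) {
        # tournament selection, size 2
        pick <- function() {
          c2 <- sample.int(population, 2L)
          pop[[c2[if (fit[c2[1]] >= fit[c2[2]]) 1L else 2L]]]
        }
        pa <- pick(); pb <- pick()
        # uniform crossover with duplicate repair
        take <- stats::runif(subset_size) < 0.5
        child <- ifelse(take, pa, pb)
        child <- unique(child)
        while (length(child) < subset_size) {
          child <- unique(c(child, sample.int(p, 1L)))
        }
        # per-gene mutation: resample a random unused column
        mut <- which(stats::runif(subset_size) < 0.05)
        for (m in mut) {
          free <- setdiff(seq_len(p), child)
          child[m] <- free[sample.int(length(free), 1L)]
        }
        newpop[[i]] <- sort(child)
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
      trajectory[gen + 1L] <- max(fit)
    }
    list(pop = pop, fit = fit, trajectory = trajectory)
  })

  keys <- vapply(result$pop, subset_key, character(1))
  keep <- !duplicated(keys)
  pop <- result$pop[keep]; fit <- result$fit[keep]
  ord <- order(fit, decreasing = TRUE)
  ord <- ord[seq_len(min(n_models, length(ord)))]
  models <- lapply(seq_along(ord), function(i) {
    finalize_model(pool, y, pop[[ord[i]]], fit[ord[i]], nn_seed,
                   as.integer(max_iter), tol, seed, 1L)
  })
  # best-so-far fitness per generation; non-decreasing under elitism
  attr(models, "trajectory") <- result$trajectory
  models
}

#' Repeated GNN runs with model deduplication
#'
#' Runs [ga_select()] `n_runs` times with distinct GA seeds derived from
#' `base_seed` (the fitness landscape itself is pinned to `base_seed` via
#' `nn_seed`, so fitness values are comparable and cacheable across
#' runs). Per-run best models are merged and deduplicated by descriptor
#' set, keeping the entry with the higher q2.
#'
#' @inheritParams ga_select
#' @param n_runs GA repetitions (10 for a train/test split, 50 for an
#'   entire-set analysis, by convention).
#' @param base_seed first GA seed; run r uses `base_seed + r - 1`.
#' @return list of unique `QsarModel`s sorted by q2 descending.
#' @export
run_ensemble <- function(pool, activities, n_runs = 10, base_seed = 1,
                         population = 250, generations = 75,
                         subset_size = 4, n_models = 10, max_iter = 500,
                         tol = 1e-6, cache = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  all_models <- list()
  for (r in seq_len(n_runs)) {
    models <- ga_select(pool, activities, population, generations,
                        subset_size, seed = base_seed + r - 1L,
                        nn_seed = base_seed, n_models = n_models,
                        max_iter = max_iter, tol = tol, cache = cache)
    for (m in models) m$run_index <- r
    all_models <- c(all_models, models)
  }
  keys <- vapply(all_models, function(m) subset_key(m$descriptor_index),
                 character(1))
  q2s <- vapply(all_models, function(m) m$q2, numeric(1))
  best <- tapply(seq_along(keys), keys, function(i) i[which.max(q2s[i])])
  kept <- all_models[as.integer(best)]
  kept[order(vapply(kept, function(m) m$q2, numeric(1)), decreasing = TRUE)]
}

#' Predict activity for a query molecule
#'
#' Forward pass of the model's net on the query's 4 descriptor values,
#' back-transformed to the original activity scale. Similarity values
#' outside \[-1, 1\] trigger a warning but are still evaluated.
#'
#' @param object a `QsarModel`.
#' @param newdata numeric vector: either exactly 4 values in the model's
#'   descriptor order, or a longer named vector (e.g. from
#'   [descriptor_row()]) from which the model's descriptors are pulled.
#' @param ... unused.
#' @return predicted activity on the original score scale.
#' @export
predict.QsarModel <- function(object, newdata, ...) {
  x <- newdata
  if (!is.null(names(x)) && length(x) != 4) {
    miss <- setdiff(object$descriptor_ids, names(x))
    if (length(miss) > 0L) stop("query lacks descriptor(s): ",
                                paste(miss, collapse = ", "))
    x <- x[object$descriptor_ids]
  }
  if (length(x) != 4) stop("query must provide 4 descriptor values")
  if (any(abs(x) > 1 + 1e-9)) {
    warning("similarity value outside [-1, 1]; prediction computed anyway")
  }
  o <- forward_net(object$net, as.numeric(x))
  lo <- object$scaling[["min"]]; hi <- object$scaling[["max"]]
  unname(lo + (o - 0.1) / 0.8 * (hi - lo))
}

#' Consensus prediction over several models
#'
#' Arithmetic mean of the per-model predictions for one query.
#'
#' @param models list of `QsarModel`s.
#' @param query named descriptor vector covering every model's
#'   descriptors (see [descriptor_row()]).
#' @return consensus-predicted activity.
#' @export
consensus_predict <- function(models, query) {
  if (length(models) == 0L) stop("need at least one model")
  mean(vapply(models, function(m) predict(m, query), numeric(1)))
}

#' Serialize models to JSON
#'
#' @param models list of `QsarModel`s.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(descriptor_ids = m$descriptor_ids, weights = m$net$weights,
         q2 = m$q2, scaling = as.list(m$scaling),
         training_ids = m$training_ids, seed = m$seed,
         run_index = m$run_index)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read models serialized by [write_models_json()]
#' @param path JSON file.
#' @return list of `QsarModel`s.
#' @export
read_models_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    row <- payload[i, ]
    structure(list(
      descriptor_ids = unlist(row$descriptor_ids),
      descriptor_index = NULL,
      net = structure(list(weights = unlist(row$weights)),
                      class = "NeuralNet411"),
      q2 = row$q2,
      scaling = c(min = row$scaling$min, max = row$scaling$max),
      training_ids = unlist(row$training_ids),
      seed = row$seed, run_index = row$run_index
    ), class = "QsarModel")
  })
}
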