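test_that("activity scaling maps endpoints and round-trips", {
  sc <- scale_activities(c(-17, 56))
  expect_equal(sc$forward(-17), 0.1)
  expect_equal(sc$forward(56), 0.9)
  expect_equal(sc$forward((-17 + 56) / 2), 0.5)
  xs <- c(-17, -3, 0, 12.5, 56)
  expect_equal(sc$inverse(sc$forward(xs)), xs, tolerance = 1e-12)
  expect_error(scale_activities(rep(4, 5)), "constant")
})

test_that("q_squared reproduces the worked toy values", {
  expect_equal(q_squared(c(0, 2, 4), c(0, 2, 4)), 1)
  y <- c(1, 5, 9, 2)
  expect_equal(q_squared(y, rep(mean(y), 4)), 0)
  expect_equal(q_squared(c(0, 2, 4), c(1, 2, 3)), 0.75)
  expect_error(q_squared(rep(1, 3), c(1, 2, 3)), "degenerate")
})

test_that("net training fits constants and monotone toys deterministically", {
  X <- matrix(runif(32, 0.9, 1), 8, 4)
  fit <- train_net(X, rep(0.5, 8), seed = 1)
  expect_lt(fit$sse, 1e-6)
  expect_equal(forward_net(fit, X), rep(0.5, 8), tolerance = 1e-3)

  # monotone toy: target = row mean mapped onto [0.1, 0.9]; at 5 rows the
  # 7-parameter net interpolates
  withr::with_seed(4, X5 <- matrix(runif(20), 5, 4))
  m5 <- rowMeans(X5)
  t5 <- 0.1 + 0.8 * (m5 - min(m5)) / (max(m5) - min(m5))
  fit5 <- suppressWarnings(train_net(X5, t5, seed = 2))
  expect_lt(fit5$sse, 1e-3)

  # at 8 rows the net cannot interpolate a linear map; SCG must reach the
  # representational floor found by an independent optimizer (BFGS)
  withr::with_seed(4, X2 <- matrix(runif(32), 8, 4))
  m <- rowMeans(X2)
  t2 <- 0.1 + 0.8 * (m - min(m)) / (max(m) - min(m))
  fit2 <- train_net(X2, t2, seed = 2)
  obj <- function(w) {
    h <- plogis(X2 %*% w[1:4] + w[5])
    sum((plogis(w[6] * h + w[7]) - t2)^2)
  }
  oracle <- stats::optim(crossreact3d:::initial_weights(2), obj,
                         method = "BFGS",
                         control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(fit2$sse, oracle$value * 1.2 + 1e-8)

  fit3 <- train_net(X2, t2, seed = 2)
  expect_identical(fit2$weights, fit3$weights)  # bit-identical per seed
  fit4 <- train_net(X2, t2, seed = 99)
  expect_false(identical(fit2$weights, fit4$weights))
  expect_error(train_net(X2[1:4, ], t2[1:4], seed = 1), "at least 5")
  expect_error(train_net(X2 * NA, t2, seed = 1), "finite")
})

test_that("loo_q2 rewards the planted descriptor and stays below 1", {
  p <- planted_pool()
  q_good <- loo_q2(p$pool, c(1, 2, 3, 4), p$activities, seed = 1)
  q_bad <- loo_q2(p$pool, c(5, 6, 7, 8), p$activities, seed = 1)
  expect_gt(q_good, 0.8)
  expect_lt(q_bad, q_good)
  expect_lte(q_good, 1)
  expect_error(loo_q2(p$pool, c(1, 1, 2, 3), p$activities), "duplicates")
  expect_error(loo_q2(p$pool, c(1, 2, 3, 4),
                      setNames(rep(1, 12), rownames(p$pool))), "degenerate")
  # named subsets resolve to the same value
  expect_equal(loo_q2(p$pool, colnames(p$pool)[1:4], p$activities, seed = 1),
               q_good)
})

test_that("ga_select honours its contracts on a tiny pool", {
  p <- planted_pool()
  # pool of exactly 4 columns: the only subset, fitness = its loo_q2
  sub <- p$pool[, 1:4]
  m <- ga_select(sub, p$activities, seed = 3)
  expect_length(m, 1L)
  expect_setequal(m[[1]]$descriptor_ids, colnames(sub))
  expect_equal(m[[1]]$q2, loo_q2(sub, 1:4, p$activities, seed = 3))

  ms1 <- ga_select(p$pool, p$activities, population = 30, generations = 10,
                   seed = 5)
  ms2 <- ga_select(p$pool, p$activities, population = 30, generations = 10,
                   seed = 5)
  expect_identical(ms1[[1]]$descriptor_ids, ms2[[1]]$descriptor_ids)
  expect_identical(ms1[[1]]$q2, ms2[[1]]$q2)
  for (m in ms1) expect_false(anyDuplicated(m$descriptor_ids) > 0)
  # elitism: best-so-far fitness never decreases
  expect_true(all(diff(attr(ms1, "trajectory")) >= -1e-12))
})

test_that("GA matches exhaustive enumeration on a small pool", {
  p <- planted_pool(n = 12, p = 10, seed = 21)
  combos <- utils::combn(10, 4)
  qs <- apply(combos, 2, function(ss) loo_q2(p$pool, ss, p$activities,
                                             seed = 7))
  best_exh <- max(qs)
  ms <- ga_select(p$pool, p$activities, population = 40, generations = 20,
                  seed = 7, nn_seed = 7)
  expect_gte(ms[[1]]$q2, best_exh - 0.02)
})

test_that("run_ensemble merges and deduplicates across runs", {
  p <- planted_pool()
  one <- ga_select(p$pool, p$activities, population = 20, generations = 5,
                   seed = 9, nn_seed = 9, n_models = 5)
  ens1 <- run_ensemble(p$pool, p$activities, n_runs = 1, base_seed = 9,
                       population = 20, generations = 5, n_models = 5)
  expect_equal(ens1[[1]]$descriptor_ids, one[[1]]$descriptor_ids)
  expect_equal(ens1[[1]]$q2, one[[1]]$q2)

  ens <- run_ensemble(p$pool, p$activities, n_runs = 3, base_seed = 9,
                      population = 20, generations = 5, n_models = 5)
  keys <- vapply(ens, function(m) paste(sort(m$descriptor_ids),
                                        collapse = "-"), character(1))
  expect_false(any(duplicated(keys)))
  expect_true(all(diff(vapply(ens, function(m) m$q2, numeric(1))) <= 1e-12))
})

test_that("prediction is consistent with the fitted net and its scaling", {
  p <- planted_pool()
  m <- ga_select(p$pool[, 1:4], p$activities, seed = 2)[[1]]
  # query identical to a training molecule = the LOO-free fitted value
  i <- 5L
  pred <- predict(m, p$pool[i, m$descriptor_ids])
  o <- forward_net(m$net, unname(p$pool[i, m$descriptor_ids]))
  lo <- m$scaling[["min"]]; hi <- m$scaling[["max"]]
  expect_equal(pred, lo + (o - 0.1) / 0.8 * (hi - lo))
  expect_error(predict(m, c(0.9, 0.9)), "4 descriptor")
  expect_warning(predict(m, c(2, 0.9, 0.9, 0.9)), "outside")
  # named query longer than 4 gets subset by descriptor id
  q <- c(p$pool[i, ], extra = 0.5)
  expect_equal(predict(m, q), pred)
})

test_that("consensus prediction averages and ignores model order", {
  fake <- function(v) {
    structure(list(descriptor_ids = paste0("d", 1:4),
                   net = structure(list(weights = c(0, 0, 0, 0, 0, 0, 0)),
                                   class = "NeuralNet411"),
                   q2 = 0.9, scaling = c(min = v * 2 - 10, max = v * 2 - 10 + 16),
                   training_ids = "x", seed = 1, run_index = 1),
              class = "QsarModel")
  }
  # with all weights 0 the net outputs sigmoid(0) = 0.5, i.e. the scaled
  # midpoint, so prediction = midpoint of [min, max] = v*2 - 2
  ms <- lapply(c(6, 11, 16), fake)   # predictions 10, 20, 30
  q <- c(d1 = 0.9, d2 = 0.9, d3 = 0.9, d4 = 0.9)
  expect_equal(predict(ms[[1]], q), 10)
  expect_equal(consensus_predict(ms, q), 20)
  expect_equal(consensus_predict(rev(ms), q), 20)
  expect_equal(consensus_predict(ms[2], q), 20)
  expect_error(consensus_predict(list(), q), "at least one")
})

test_that("model JSON serialization round-trips predictions", {
  p <- planted_pool()
  ms <- ga_select(p$pool, p$activities, population = 20, generations = 5,
                  seed = 4, n_models = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_models_json(ms, f)
  back <- read_models_json(f)
  expect_length(back, length(ms))
  q <- p$pool[3, ]
  for (i in seq_along(ms)) {
    expect_equal(predict(back[[i]], q), predict(ms[[i]], q), tolerance = 1e-12)
    expect_equal(back[[i]]$q2, ms[[i]]$q2)
  }
})
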