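test_that("the published activity table partitions into the published sets", {
  act <- melanA_activity_table()
  part <- partition_by_activity(act, test_inactive_ids = melanA_test_inactives())
  expect_length(part$training_ids, 17L)
  expect_length(part$test_ids, 6L)
  expect_setequal(part$test_ids, c("10", "56", "58", "100", "104", "108"))
  expect_setequal(c(part$training_ids, part$test_ids), names(act))
})

test_that("ranked grouping sends one active per full group to test", {
  scores <- setNames(c(48:37), paste0("a", 1:12))  # 12 distinct actives
  scores <- c(scores, setNames(rep(-5, 4), paste0("i", 1:4)))
  part <- partition_by_activity(scores, seed = 3)
  expect_length(intersect(part$test_ids, paste0("a", 1:12)), 3L)
  # the 4th, 8th and 12th ranked actives are the test actives
  expect_setequal(grep("^a", part$test_ids, value = TRUE),
                  c("a4", "a8", "a12"))
  # deterministic given the seed
  part2 <- partition_by_activity(scores, seed = 3)
  expect_identical(part, part2)
  part3 <- partition_by_activity(scores, seed = 4)
  expect_setequal(grep("^a", part3$test_ids, value = TRUE),
                  c("a4", "a8", "a12"))

  expect_error(partition_by_activity(setNames(c(5, 4, 3, -1, -1), letters[1:5])),
               "not enough")
  # explicit override works but an undersized test set is flagged
  expect_warning(
    explicit <- partition_by_activity(scores, test_ids = c("a1", "a2", "i1")),
    "fewer than 5")
  expect_setequal(explicit$test_ids, c("a1", "a2", "i1"))
})

test_that("pearson_r matches hand computations and validates input", {
  x <- c(0.2, 1.7, 2.4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 2)), 3), 0.866)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("external test statistics recover a planted relationship", {
  p <- planted_pool(n = 18, p = 12, seed = 31)
  ids <- rownames(p$pool)
  part <- structure(list(training_ids = ids[1:12], test_ids = ids[13:18]),
                    class = "Partition")
  # similarity container exposing the pool columns for all molecules
  sim <- structure(list(
    ids = ids,
    shape = matrix(0, 18, 18, dimnames = list(ids, ids)),
    electrostatic = matrix(0, 18, 18, dimnames = list(ids, ids))),
    class = "SimilarityMatrix")
  sim$shape[, ids[1:12]] <- p$pool[, 1:12]
  colnames(sim$shape) <- ids
  train_pool <- build_descriptor_pool(sim, ids[1:12])[part$training_ids, ]
  train_pool[, paste0("shape|", ids[1:12])] <- p$pool[1:12, 1:12]
  # keep it simple: model on the planted descriptor column set
  pool_tr <- p$pool[part$training_ids, ]
  m <- ga_select(pool_tr[, 1:4], p$activities[part$training_ids], seed = 2)[[1]]
  # descriptor_row-compatible query: name the pool columns directly
  preds <- vapply(part$test_ids, function(id) {
    predict(m, p$pool[id, m$descriptor_ids])
  }, numeric(1))
  r <- pearson_r(p$activities[part$test_ids], preds)
  expect_gt(r, 0.8)

  # the full function wires the same pieces together
  sim2 <- structure(list(
    ids = ids,
    shape = outer(p$pool[, 1], p$pool[, 1], pmin),
    electrostatic = outer(p$pool[, 2], p$pool[, 2], pmin)),
    class = "SimilarityMatrix")
  dimnames(sim2$shape) <- dimnames(sim2$electrostatic) <- list(ids, ids)
  pool2 <- build_descriptor_pool(sim2, ids[1:12])[part$training_ids, ]
  m2 <- ga_select(pool2, p$activities[part$training_ids],
                  population = 20, generations = 8, seed = 5)[[1]]
  st <- external_test_stats(list(m2), part, sim2, p$activities)
  expect_named(st, c("r", "slope", "intercept", "predicted", "experimental"),
               ignore.order = TRUE)
  expect_length(st$predicted, 6L)
  # perfect-prediction degenerate check of the regression arithmetic
  fit <- lm(c(1, 3, 5) ~ c(0, 1, 2))
  expect_equal(unname(coef(fit)), c(1, 2))

  m_leaky <- m2; m_leaky$training_ids <- ids
  expect_error(external_test_stats(list(m_leaky), part, sim2, p$activities),
               "trained on test")
})

test_that("functional dependence scans behave per the model weights", {
  # hand-built model: only input 1 carries weight
  m <- structure(list(
    descriptor_ids = c("shape|r", "d2", "d3", "d4"),
    net = structure(list(weights = c(6, 0, 0, 0, -5.7, 4, -2)),
                    class = "NeuralNet411"),
    q2 = 0.9, scaling = c(min = -17, max = 56),
    training_ids = paste0("m", 1:8), seed = 1, run_index = 1),
    class = "QsarModel")
  pool <- matrix(runif(32, 0.9, 1), 8, 4,
                 dimnames = list(paste0("m", 1:8),
                                 c("shape|r", "d2", "d3", "d4")))
  flat <- functional_dependence(m, "d2", pool)
  expect_equal(diff(range(flat$predicted)), 0)
  rising <- functional_dependence(m, "shape|r", pool, n_points = 25)
  expect_equal(nrow(rising), 25L)
  expect_true(all(diff(rising$predicted) > 0))  # positive path weights
  expect_equal(range(rising$similarity), range(pool[, "shape|r"]))

  # curve at the descriptor's training average = all-average prediction
  avg <- colMeans(pool[, m$descriptor_ids])
  base <- predict(m, avg)
  curve <- functional_dependence(m, "shape|r", pool,
                                 scan_range = rep(avg["shape|r"], 2))
  expect_equal(unique(curve$predicted), base)
  expect_error(functional_dependence(m, "nope", pool), "not part")
})

test_that("y-randomization preserves the activity multiset and flags separation", {
  p <- planted_pool(n = 10, p = 8, seed = 13)
  real <- ga_select(p$pool, p$activities, population = 25, generations = 8,
                    seed = 2, n_models = 3)
  rep <- y_randomize(p$pool, p$activities, n_shuffles = 3,
                     runs_per_shuffle = 1, keep_best = 3, seed = 11,
                     real_models = real[1:min(3, length(real))],
                     population = 25, generations = 8)
  expect_s3_class(rep, "RandomizationReport")
  expect_true(all(rep$random$q2 >= 0))
  expect_true(all(rep$random$shuffle %in% 1:3))
  expect_false(is.na(rep$separated))
  # separation flag is strict dominance in q2
  if (nrow(rep$random) > 0) {
    expect_equal(rep$separated, min(rep$real$q2) > max(rep$random$q2))
  }
})
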