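linear_table <- function(n = 120, noise = 0, seed = 61) {
  withr::with_seed(seed, {
    t <- as.data.frame(matrix(runif(n * 4, 0, 100), n, 4))
    names(t) <- c("f1", "f2", "f3", "f4")
    t$score <- 2 * t$f1 - 0.5 * t$f2 + 10 + rnorm(n, 0, noise)
    t
  })
}

test_that("split sizes follow the fraction exactly and are seed-stable", {
  t416 <- linear_table(416)
  sp <- split_data(t416, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 333)
  expect_equal(nrow(sp$test), 83)
  t10 <- linear_table(10)
  sp10 <- split_data(t10, 0.8, seed = 4)
  expect_equal(nrow(sp10$train), 8)
  expect_equal(nrow(sp10$test), 2)
  expect_identical(split_data(t416, seed = 9)$train_idx,
                   split_data(t416, seed = 9)$train_idx)
  expect_error(split_data(t416, 1.2), "train_fraction")
  expect_error(split_data(t416[1:3, ]), "at least 5")
})

test_that("glm recovers a noiseless linear target with ~zero CV error", {
  t <- linear_table(100, noise = 0)
  m <- train_model(t, family = "glm", features = c("f1", "f2"), seed = 5)
  expect_lt(m$cv_rmse, 1e-6)
  co <- stats::coef(m$fit$finalModel)
  expect_equal(unname(co[c("f1", "f2")]), c(2, -0.5), tolerance = 1e-6)
  ev <- evaluate(m, linear_table(50, noise = 0, seed = 62))
  expect_lt(ev$rmse, 1e-6)
  expect_equal(ev$r_squared, 1, tolerance = 1e-9)
})

test_that("evaluate matches hand-rolled RMSE and R-squared formulas", {
  for (noise in c(3, 15, 40)) {
    t <- linear_table(150, noise = noise, seed = 63 + noise)
    sp <- split_data(t, seed = 1)
    m <- train_model(sp$train, family = "glm", features = c("f1", "f3"),
                     seed = 1)
    obs <- sp$test$score
    pred <- predict(m, sp$test)
    ev <- evaluate(m, sp$test)
    expect_equal(ev$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-9)
    expect_equal(ev$r_squared, cor(pred, obs)^2, tolerance = 1e-9)
    expect_equal(ev$r_squared_ss,
                 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
                 tolerance = 1e-9)
  }
})

test_that("degenerate evaluations are refused or downgraded with a warning", {
  t <- linear_table(60)
  t$score <- 50  # constant target -> refuse to train
  expect_error(train_model(t, family = "glm", features = "f1"), "variance")
  t2 <- linear_table(60, seed = 66)
  m <- train_model(t2, family = "glm", features = "f1", seed = 1)
  expect_error(evaluate(m, t2[0, ]), "empty")
  # a single test row leaves the correlation undefined
  expect_warning(ev1 <- evaluate(m, t2[1, ]), "constant")
  expect_equal(ev1$r_squared, 0)
})

test_that("select_best picks minimum RMSE with documented tie-breaks", {
  r <- list(glm = list(rmse = 16.4, r_squared = 0.77),
            rf = list(rmse = 12.7, r_squared = 0.86),
            knn = list(rmse = 13.6, r_squared = 0.84))
  expect_equal(select_best(r), "rf")
  expect_equal(select_best(r["glm"]), "glm")
  tie <- list(glm = list(rmse = 10, r_squared = 0.8),
              rf = list(rmse = 10, r_squared = 0.9))
  expect_equal(select_best(tie), "rf")
  expect_error(select_best(list()), "no results")
})

test_that("rf predictions are invariant to feature column order", {
  tab <- fx_table()
  m <- train_model(tab, family = "rf", features = c("normN50", "gap_perc",
                                                    "error_free_bases"),
                   seed = 6)
  shuffled <- tab[, rev(colnames(tab))]
  expect_equal(predict(m, tab), predict(m, shuffled), tolerance = 1e-12)
  expect_error(predict(m, tab[, c("normN50", "gap_perc")]),
               "error_free_bases")
})

test_that("model persistence round-trips predictions exactly", {
  tab <- fx_table()
  m <- train_model(tab, family = "rf", seed = 8)
  dir <- file.path(tempdir(), "qm-roundtrip")
  save_model(m, dir)
  m2 <- load_model(dir)
  withr::with_seed(64, {
    newdata <- as.data.frame(matrix(runif(100 * 13, 0, 100), 100, 13))
    names(newdata) <- METRIC_NAMES
  })
  expect_identical(predict(m, newdata), predict(m2, newdata))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$family, "rf")
  expect_error(load_model(tempfile()), "no model")
})

test_that("training is deterministic under a fixed seed", {
  tab <- fx_table()
  m1 <- train_model(tab, family = "rf", seed = 10)
  m2 <- train_model(tab, family = "rf", seed = 10)
  expect_identical(predict(m1, tab), predict(m2, tab))
  expect_identical(m1$tuned, m2$tuned)
})

test_that("rf beats glm on a nonlinear synthetic target", {
  withr::with_seed(65, {
    n <- 300
    t <- data.frame(f1 = runif(n, 0, 100), f2 = runif(n, 0, 100),
                    f3 = runif(n, 0, 100))
    t$score <- 80 / (1 + exp(-(t$f1 - 50) / 8)) + 0.1 * t$f2 + rnorm(n, 0, 2)
  })
  sp <- split_data(t, seed = 11)
  feats <- c("f1", "f2", "f3")
  m_rf <- train_model(sp$train, family = "rf", features = feats, seed = 11)
  m_glm <- train_model(sp$train, family = "glm", features = feats, seed = 11)
  expect_lt(evaluate(m_rf, sp$test)$rmse, evaluate(m_glm, sp$test)$rmse)
})

test_that("zero-variance training targets are refused for every family", {
  t <- fx_table()
  t$score <- 42
  expect_error(train_model(t, family = "rf"), "variance")
  expect_error(train_model(t, family = "unknown_family"), "arg")
})

test_that("finalize_and_predict scores perfect metrics near the top of scale", {
  tab <- fx_table()
  perfect <- as.data.frame(as.list(ideal_vector()))
  perfect$norm_contig_number <- min(tab$norm_contig_number)
  out <- finalize_and_predict("rf", tab, perfect, seed = 12)
  top <- max(tab$score)
  expect_gt(out$scores, 0.9 * top)
  expect_error(predict(out$model, perfect[, 1:3]), "missing feature")
})
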