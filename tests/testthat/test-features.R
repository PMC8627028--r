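# random table with controlled relationships to the target
toy_table <- function(n = 400, seed = 51) {
  withr::with_seed(seed, {
    y <- runif(n, 0, 100)
    data.frame(
      score = y,
      strong = y + rnorm(n, 0, 5),
      weak = rnorm(n),
      dup = y + rnorm(n, 0, 5),
      neg = -y + rnorm(n, 0, 10)
    )
  })
}

test_that("pearson filter keeps correlated features, drops noise", {
  t <- toy_table(10000)
  pf <- pearson_filter(t, features = c("strong", "weak", "neg"))
  expect_true(all(c("strong", "neg") %in% pf$retained))
  expect_equal(pf$removed, "weak")
  expect_gt(pf$r[["strong"]], 0.9)
  # a feature equal to the target has r exactly 1
  t$self <- t$score
  pf2 <- pearson_filter(t, features = "self")
  expect_equal(unname(pf2$r), 1)
  expect_equal(pf2$retained, "self")
})

test_that("pearson filter is invariant to row order and affine rescaling", {
  t <- toy_table(500)
  pf <- pearson_filter(t, features = c("strong", "weak", "neg"))
  t2 <- t[sample(nrow(t)), ]
  t2$strong <- 1000 + 0.01 * t2$strong
  pf2 <- pearson_filter(t2, features = c("strong", "weak", "neg"))
  expect_equal(pf$r, pf2$r, tolerance = 1e-12)
  expect_identical(pf$retained, pf2$retained)
})

test_that("zero-variance features are removed with a warning", {
  t <- toy_table(100)
  t$flat <- 5
  expect_warning(pf <- pearson_filter(t, features = c("strong", "flat")),
                 "zero-variance")
  expect_false("flat" %in% pf$retained)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  t <- toy_table(300)
  cm <- correlation_matrix(t, features = c("strong", "weak", "dup", "neg"))
  expect_equal(cm$matrix, t(cm$matrix))
  expect_equal(unname(diag(cm$matrix)), rep(1, 4))
  # duplicated-ish columns are flagged collinear
  expect_true(nrow(cm$collinear_pairs) >= 1)
  t$copy <- t$strong
  cm2 <- correlation_matrix(t, features = c("strong", "copy"))
  expect_equal(cm2$matrix["strong", "copy"], 1)
})

test_that("jmim agrees with brute-force joint-MI maximisation on tiny tables", {
  # brute force over all selection orders, replicating the greedy objective
  brute_jmim <- function(t, features, target) {
    dx <- lapply(t[features], function(x) match(x, sort(unique(x))))
    dy <- match(t[[target]], sort(unique(t[[target]])))
    mi <- function(x, y) {
      tab <- table(x, y); p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p); nz <- p > 0
      sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
    }
    jm <- function(f, s) mi(interaction(dx[[f]], dx[[s]], drop = TRUE), dy)
    sel <- character(0); cand <- features
    while (length(cand)) {
      sc <- if (!length(sel)) vapply(cand, function(f) mi(dx[[f]], dy), 0)
      else vapply(cand, function(f) min(vapply(sel, function(s) jm(f, s), 0)), 0)
      pick <- cand[which.max(sc)]
      sel <- c(sel, pick); cand <- setdiff(cand, pick)
    }
    sel
  }
  set.seed(52)
  for (i in 1:25) {
    nf <- sample(2:4, 1)
    nr <- sample(8:16, 1)
    t <- as.data.frame(matrix(sample(0:2, nr * nf, replace = TRUE), nr, nf))
    names(t) <- paste0("f", seq_len(nf))
    t$score <- sample(0:1, nr, replace = TRUE)
    expect_identical(as.character(jmim_rank(t, features = names(t)[1:nf], bins = 10L)),
                     brute_jmim(t, names(t)[1:nf], "score"))
  }
})

test_that("jmim puts XOR partners first and noise last", {
  g <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1)
  g$score <- xor(g$x1, g$x2) * 1L
  r <- jmim_rank(g, features = c("x1", "x2", "x3"))
  expect_setequal(as.character(r[1:2]), c("x1", "x2"))
  expect_equal(as.character(r[3]), "x3")
})

test_that("a duplicated feature ranks below an informative partner", {
  t <- toy_table(800)
  t$dup_exact <- t$strong
  r <- as.character(jmim_rank(t, features = c("strong", "dup_exact", "neg")))
  expect_equal(r[1], "strong")
  expect_equal(r[2], "neg")       # adds joint information the duplicate cannot
  expect_equal(r[3], "dup_exact")
  expect_error(jmim_rank(t, features = "strong", k = 5), "exceeds")
})

test_that("permutation importance singles out the generating feature", {
  t <- toy_table(300)
  imp <- permutation_importance(t, features = c("strong", "weak"), seed = 2,
                                n_trees = 200L)
  expect_gt(imp[["strong"]], imp[["weak"]])
  expect_equal(names(which.max(imp)), "strong")
  expect_error(permutation_importance(t, features = c("strong", "weak"),
                                      reps = 0L), "reps")
})

test_that("exhaustive subset search: exact fit, noise floor, nested R2", {
  t <- toy_table(300)
  t$self <- t$score
  ss <- exhaustive_subset_search(t, candidates = "self")
  expect_equal(ss$final, "self")
  expect_equal(ss$final_r_squared, 1)

  withr::with_seed(53, {
    noise <- data.frame(score = runif(1000),
                        a = rnorm(1000), b = rnorm(1000), c = rnorm(1000))
  })
  ssn <- exhaustive_subset_search(noise, candidates = c("a", "b", "c"))
  expect_lt(max(ssn$by_size$r_squared), 0.05)

  ss3 <- exhaustive_subset_search(t, candidates = c("strong", "dup", "neg"))
  best_r2 <- ss3$best_per_size$r_squared
  expect_true(all(diff(best_r2) >= -1e-12))
  expect_error(exhaustive_subset_search(t, candidates = letters), "too many")
})

test_that("sign-contradiction rule bars collinearity-flipped features", {
  # z correlates positively with y only through x; conditional on x its
  # weight flips negative, so subsets holding z are reported but not chosen
  withr::with_seed(54, {
    n <- 2000
    x <- rnorm(n)
    z <- x + rnorm(n, 0, 0.2)
    y <- 3 * x - 2 * z + rnorm(n, 0, 0.1)
    t <- data.frame(score = y, x = x, z = z)
  })
  expect_gt(cor(t$z, t$score), 0.1)  # marginally positive
  ss <- exhaustive_subset_search(t, candidates = c("x", "z"))
  expect_false("z" %in% ss$final)
  expect_true("z" %in% ss$excluded_by_sign)
})

test_that("the full cascade runs on a synthetic metrics table", {
  tab <- fx_table()
  # this small table has no fragment-coverage dropouts over gaps at all, so
  # the cascade warns while removing the zero-variance column
  expect_warning(rep <- select_features(tab, seed = 3), "zero-variance")
  expect_s3_class(rep, "FeatureReport")
  expect_true(all(rep$final %in% rep$pearson$retained))
  expect_lte(length(rep$final), 6)
  expect_true("error_free_bases" %in% rep$pearson$retained)
  p <- tempfile(fileext = ".json")
  write_feature_report(rep, p)
  j <- jsonlite::read_json(p)
  expect_identical(unlist(j$final), rep$final)
})
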