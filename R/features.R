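#' Validate a metrics table
#'
#' Checks that a training table carries the 13 metric columns
#' ([METRIC_NAMES]) and the target score column, with no missing values.
#'
#' @param t data.frame.
#' @param target name of the target score column.
#' @return `t` invisibly; errors list unexpected/missing columns.
#' @export
validate_metrics_table <- function(t, target = "score") {
  missing <- setdiff(c(METRIC_NAMES, target), colnames(t))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  cols <- c(METRIC_NAMES, target)
  bad <- cols[vapply(t[cols], function(x) anyNA(x) || !is.numeric(x), TRUE)]
  if (length(bad)) stop("non-numeric or missing values in: ",
                        paste(bad, collapse = ", "))
  invisible(t)
}

#' Pearson correlation filter
#'
#' Computes the sample Pearson correlation of every feature with the target
#' and retains features whose correlation falls outside (`lo`, `hi`): features with only a
#' very weak linear relationship to the target (|r| < 0.1 by default) are
#' removed. Zero-variance features have undefined correlation and are
#' removed with a warning.
#'
#' @param t metrics table.
#' @param features feature columns to test (defaults to [METRIC_NAMES]).
#' @param target target column name.
#' @param lo,hi exclusion band; a feature is removed when `lo < r < hi`.
#' @return list with `r` (named vector over `features`), `retained`,
#'   `removed`.
#' @export
pearson_filter <- function(t, features = intersect(METRIC_NAMES, colnames(t)),
                           target = "score", lo = -0.1, hi = 0.1) {
  if (nrow(t) < 3L) stop("need >= 3 rows")
  y <- t[[target]]
  if (stats::sd(y) == 0) stop("target has zero variance")
  r <- vapply(features, function(f) {
    x <- t[[f]]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  if (anyNA(r)) {
    warning("zero-variance feature(s) removed: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  keep <- !is.na(r) & (r <= lo | r >= hi)
  list(r = r, retained = names(r)[keep], removed = names(r)[!keep])
}

#' Pairwise feature correlation matrix
#'
#' @param t metrics table.
#' @param features feature columns.
#' @param collinear_threshold |r| above which a pair is flagged collinear.
#' @return list with `matrix` (symmetric, unit diagonal) and
#'   `collinear_pairs` (data.frame `a`, `b`, `r`).
#' @export
correlation_matrix <- function(t, features = intersect(METRIC_NAMES, colnames(t)),
                               collinear_threshold = 0.8) {
  if (nrow(t) < 3L) stop("need >= 3 rows")
  m <- stats::cor(t[features])
  ut <- which(upper.tri(m) & abs(m) > collinear_threshold, arr.ind = TRUE)
  pairs <- data.frame(a = rownames(m)[ut[, 1]], b = colnames(m)[ut[, 2]],
                      r = m[ut])
  list(matrix = m, collinear_pairs = pairs)
}

# equal-frequency discretisation into <= bins levels
discretize_ef <- function(x, bins = 10L) {
  if (length(unique(x)) <= bins) return(match(x, sort(unique(x))))
  q <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                              type = 7))
  findInterval(x, q, rightmost.closed = TRUE, all.inside = TRUE)
}

# plug-in (empirical) mutual information of discrete vectors, in nats
mi_discrete <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

# joint MI I((X, Xs); Y) with X, Xs, Y discrete
joint_mi <- function(x, xs, y) {
  mi_discrete(interaction(x, xs, drop = TRUE), y)
}

#' JMIM feature ranking
#'
#' Greedy joint-mutual-information-maximisation ranking: the first feature
#' maximises I(X; Y); each subsequent pick maximises
#' `min over selected s of I(X, X_s; Y)`, so a candidate that is redundant
#' with any already-selected feature is down-weighted. Continuous columns
#' are discretised by equal-frequency binning. Ties break by column order,
#' making the ranking deterministic.
#'
#' @param t metrics table.
#' @param features candidate feature columns.
#' @param k how many features to rank (<= number of candidates).
#' @param target target column.
#' @param bins equal-frequency bin count for discretisation.
#' @return character vector: the first `k` features in selection order,
#'   with attribute `"criterion"` holding the JMIM objective at each pick.
#' @export
jmim_rank <- function(t, features = intersect(METRIC_NAMES, colnames(t)),
                      k = length(features), target = "score", bins = 10L) {
  if (k > length(features)) stop("k exceeds the number of candidate features")
  if (k < 1L) stop("k must be >= 1")
  dx <- lapply(t[features], discretize_ef, bins = bins)
  dy <- discretize_ef(t[[target]], bins = bins)

  selected <- character(0)
  crit <- numeric(0)
  candidates <- features
  mi0 <- vapply(candidates, function(f) mi_discrete(dx[[f]], dy), 0)
  while (length(selected) < k) {
    if (length(selected) == 0L) {
      score <- mi0[candidates]
    } else {
      score <- vapply(candidates, function(f) {
        min(vapply(selected, function(s) joint_mi(dx[[f]], dx[[s]], dy), 0))
      }, 0)
    }
    best <- candidates[which.max(score)]  # which.max: first max -> column order
    crit <- c(crit, max(score))
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  structure(selected, criterion = crit)
}

#' Permutation importance from a random forest
#'
#' Percent increase in out-of-bag MSE when each feature column is randomly
#' permuted, averaged over `reps` permutations per tree (the forest's own
#' out-of-bag permutation importance).
#'
#' @param t metrics table.
#' @param features feature columns to use.
#' @param target target column.
#' @param reps permutations per tree (>= 1).
#' @param seed integer seed.
#' @param n_trees forest size.
#' @return named numeric vector of %IncMSE per feature.
#' @export
permutation_importance <- function(t, features = intersect(METRIC_NAMES, colnames(t)),
                                   target = "score", reps = 5L, seed = 1L,
                                   n_trees = 500L) {
  if (reps < 1L) stop("reps must be >= 1")
  withr_seed(seed, {
    rf <- randomForest::randomForest(x = t[features], y = t[[target]],
                                     ntree = n_trees, importance = TRUE,
                                     nPerm = reps)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)
    stats::setNames(imp[, 1], rownames(imp))
  })
}

#' Exhaustive best-subset linear regression
#'
#' Fits ordinary least squares for every subset of the candidate features
#' up to `max_size` and reports R^2 and residual sum of squares per subset
#' size. The chosen final set is the best subset after excluding any
#' feature whose fitted coefficient sign contradicts the sign of its
#' marginal correlation with the target: such a sign flip indicates that
#' the feature's weight is driven by collinearity rather than its own
#' relationship to the score, so subsets containing it are reported but not
#' selected.
#'
#' @param t metrics table.
#' @param candidates candidate feature columns (at most 20).
#' @param target target column.
#' @param max_size largest subset size to consider.
#' @return list with `by_size` (data.frame: size, features, r_squared,
#'   rss), `best_per_size`, `final` (character vector of selected
#'   features), and `excluded_by_sign` (features barred by the
#'   sign-contradiction rule in the winning subset search).
#' @export
exhaustive_subset_search <- function(t, candidates, target = "score",
                                     max_size = 6L) {
  if (length(candidates) > 20L) stop("too many candidates for exhaustive search")
  y <- t[[target]]
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  marg <- vapply(candidates, function(f) stats::cor(t[[f]], y), 0)

  rows <- list()
  for (size in seq_len(min(max_size, length(candidates)))) {
    subsets <- utils::combn(candidates, size, simplify = FALSE)
    for (ss in subsets) {
      if (n <= size + 1L) {
        warning("subset of size ", size, " skipped: too few rows")
        next
      }
      X <- cbind(1, as.matrix(t[ss]))
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      coefs <- fit$coefficients[-1]
      contradiction <- any(sign(coefs) * sign(marg[ss]) < 0, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, features = paste(ss, collapse = "+"),
        r_squared = 1 - rss / tss, rss = rss,
        sign_contradiction = contradiction)
    }
  }
  by_size <- do.call(rbind, rows)
  best_per_size <- do.call(rbind, lapply(split(by_size, by_size$size), function(d) {
    d[which.min(d$rss), ]
  }))

  ok <- by_size[!by_size$sign_contradiction, ]
  if (nrow(ok) == 0L) stop("every candidate subset has a sign contradiction")
  winner <- ok[which.min(ok$rss), ]
  final <- strsplit(winner$features, "+", fixed = TRUE)[[1]]

  overall_best <- by_size[which.min(by_size$rss), ]
  excluded <- setdiff(strsplit(overall_best$features, "+", fixed = TRUE)[[1]], final)

  list(by_size = by_size, best_per_size = best_per_size, final = final,
       final_r_squared = winner$r_squared, excluded_by_sign = excluded,
       marginal_r = marg)
}

#' Full feature-selection cascade
#'
#' Runs, in order: the Pearson filter (drop |r| < 0.1 features), the
#' pairwise correlation report, JMIM ranking (drop the `drop_jmim`
#' lowest-ranked), random-forest permutation importance (drop the
#' `drop_incmse` smallest), and the exhaustive subset regression with the
#' sign-contradiction exclusion. The union of the JMIM and %IncMSE drops is
#' removed before the subset search.
#'
#' @param t metrics table (validated against the 13-metric schema).
#' @param target target column.
#' @param drop_jmim how many lowest-JMIM features to drop.
#' @param drop_incmse how many lowest-%IncMSE features to drop.
#' @param max_size largest subset size for the exhaustive search.
#' @param seed integer seed (forest + permutation).
#' @return a `FeatureReport` list: `pearson`, `correlations`, `jmim`,
#'   `incmse`, `dropped_redundant`, `subset_search`, `final`.
#' @export
select_features <- function(t, target = "score", drop_jmim = 2L,
                            drop_incmse = 2L, max_size = 6L, seed = 1L) {
  validate_metrics_table(t, target)
  pf <- pearson_filter(t, target = target)
  cm <- correlation_matrix(t, features = pf$retained)
  jm <- jmim_rank(t, features = pf$retained, target = target)
  im <- permutation_importance(t, features = pf$retained, target = target,
                               seed = seed)
  drop1 <- utils::tail(jm, drop_jmim)
  drop2 <- names(sort(im))[seq_len(min(drop_incmse, length(im)))]
  dropped <- union(drop1, drop2)
  candidates <- setdiff(pf$retained, dropped)
  ss <- exhaustive_subset_search(t, candidates, target = target,
                                 max_size = max_size)
  structure(list(pearson = pf, correlations = cm, jmim = jm, incmse = im,
                 dropped_redundant = dropped, subset_search = ss,
                 final = ss$final),
            class = "FeatureReport")
}

#' @exportS3Method base::print
print.FeatureReport <- function(x, ...) {
  cat("FeatureReport\n")
  cat("  retained after Pearson filter:", paste(x$pearson$retained, collapse = ", "), "\n")
  cat("  dropped as redundant (JMIM / %IncMSE):",
      paste(x$dropped_redundant, collapse = ", "), "\n")
  cat("  final set:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a FeatureReport to JSON
#'
#' @param report a `FeatureReport` from [select_features()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(report, path) {
  out <- list(
    pearson_r = as.list(report$pearson$r),
    retained = report$pearson$retained,
    jmim_order = as.character(report$jmim),
    incmse = as.list(report$incmse),
    dropped_redundant = report$dropped_redundant,
    final = report$final,
    final_r_squared = report$subset_search$final_r_squared)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
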