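make_table <- function(n, k = 3, seed = 1, response = NULL,
                       feat_names = LETTERS[seq_len(k)]) {
  set.seed(seed)
  tab <- as.data.frame(matrix(runif(n * k), n,
                              dimnames = list(NULL, feat_names)))
  tab$intensity <- if (is.null(response)) rnorm(n) else response(tab)
  attr(tab, "categorical") <- character(0)
  class(tab) <- c("feature_table", class(tab))
  tab
}

fast_params <- function(...) boost_params(nrounds = 120, max_depth = 4,
                                          eta = 0.1, seed = 1, ...)

test_that("feature tables honour masks, counts and sampling seeds", {
  series <- small_series()
  es <- small_es()
  im <- rmsd_map(es, c("WY", "HQ"))
  tab <- build_feature_table(series[[6]], im)
  n_valid <- sum(!is.na(im$rmsd$values))
  expect_equal(nrow(tab), n_valid)
  expect_named(tab, c("Dem", "Slope", "NDVI", "Pre", "Tem", "Soil",
                      "Landforms", "Land", "Pop", "GDP", "intensity"))
  expect_false(anyNA(tab))
  # reproducible random sampling
  t1 <- build_feature_table(series[[6]], im, "random", n = 100, seed = 4)
  t2 <- build_feature_table(series[[6]], im, "random", n = 100, seed = 4)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100)
  # masking one driver shrinks rows to the mask intersection
  s2 <- series[[6]]
  extra_na <- which(!is.na(s2$rasters$Pop$values))[1:50]
  s2$rasters$Pop$values[extra_na] <- NA
  t3 <- build_feature_table(s2, im)
  expect_equal(nrow(t3), n_valid - 50)
})

test_that("a constant response is reproduced exactly", {
  tab <- make_table(200, response = function(t) rep(2.5, nrow(t)))
  m <- fit_tradeoff_model(tab, fast_params())
  expect_equal(unique(round(predict(m, tab), 9)), 2.5, tolerance = 1e-9)
})

test_that("a planted step function is recovered with high held-out R^2", {
  tab <- make_table(2000, response = function(t)
    1 * (t$A > 0.5) + rnorm(nrow(t), sd = 0.01))
  m <- fit_tradeoff_model(tab, fast_params())
  expect_gt(m$metrics["r_squared"], 0.9)
})

test_that("predictions are additive in the per-tree contributions", {
  tab <- make_table(300, response = function(t) t$A + sin(3 * t$B))
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  expect_lt(att$max_local_accuracy_residual, 1e-6)
  expect_equal(att$base_value + rowSums(att$contributions),
               att$predictions, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("local accuracy holds on a 2000-row table", {
  tab <- make_table(2000, k = 5, response = function(t)
    0.3 * t$A - 0.2 * t$B^2 + 0.1 * t$C * t$D + rnorm(nrow(t), sd = 0.05))
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  expect_lt(att$max_local_accuracy_residual, 1e-6)
})

test_that("features absent from the trees receive zero attribution", {
  # B and C are constant, so no split can use them
  set.seed(6)
  tab <- data.frame(A = runif(300), B = 1, C = 2)
  tab$intensity <- 2 * tab$A + rnorm(300, sd = 0.05)
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  expect_true(all(att$contributions[, c("B", "C")] == 0))
  expect_true(any(att$contributions[, "A"] != 0))
})

test_that("attributions match brute-force Shapley enumeration", {
  # small ensemble: 3 features, shallow trees, so 2^3 coalitions enumerate
  tab <- make_table(50, k = 3, seed = 9, response = function(t)
    t$A + 0.5 * t$B - 0.25 * t$C)
  m <- fit_tradeoff_model(tab, boost_params(nrounds = 6, max_depth = 2,
                                            eta = 0.5, seed = 1))
  att <- shapley_attributions(m, tab)
  for (i in c(1, 17, 42)) {
    phi <- shapley_enumerate(m, tab[i, ])
    expect_equal(unname(att$contributions[i, ]), unname(phi),
                 tolerance = 1e-6)
  }
})

test_that("column mismatches are reported by name", {
  tab <- make_table(100)
  m <- fit_tradeoff_model(tab, fast_params())
  expect_error(shapley_attributions(m, tab[, c("A", "B", "intensity")]),
               "C")
})

test_that("a planted dominant driver ranks first across seeded runs", {
  wins <- 0L
  for (s in 1:20) {
    tab <- make_table(800, k = 3, seed = s, response = function(t)
      5 * t$A + 0.1 * t$C + rnorm(nrow(t), sd = 0.2))
    m <- fit_tradeoff_model(tab, boost_params(nrounds = 80, max_depth = 3,
                                              eta = 0.2, seed = s))
    rk <- rank_drivers(shapley_attributions(m, tab))
    wins <- wins + (rk$feature[1] == "A")
  }
  expect_gte(wins, 19L)
})

test_that("an irrelevant feature never dominates the ranking", {
  for (s in 1:20) {
    tab <- make_table(500, k = 3, seed = 100 + s, response = function(t)
      2 * t$A + t$C + rnorm(nrow(t), sd = 0.1))
    m <- fit_tradeoff_model(tab, boost_params(nrounds = 60, max_depth = 3,
                                              eta = 0.2, seed = s))
    rk <- rank_drivers(shapley_attributions(m, tab))
    expect_false(rk$feature[1] == "B")
  }
})

test_that("ranking is invariant to row order", {
  tab <- make_table(400, k = 3, seed = 77, response = function(t)
    3 * t$A - t$B)
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  perm <- sample(nrow(tab))
  att2 <- att
  att2$contributions <- att$contributions[perm, ]
  att2$table <- att$table[perm, ]
  expect_identical(rank_drivers(att), rank_drivers(att2))
})

test_that("monotone positive effects yield no crossings", {
  tab <- make_table(1500, k = 2, seed = 15, response = function(t)
    2 * t$A + rnorm(nrow(t), sd = 0.05))
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  # attribution of A rises through zero once (centred at the base value),
  # so the raw-curve check targets B, which contributes nothing but noise
  thrB <- detect_thresholds(att, tab, "B", bins = 12)
  expect_s3_class(thrB, "threshold_report")
  # a feature with uniformly positive contributions: shift A's curve
  att_pos <- att
  att_pos$contributions[, "A"] <-
    abs(att_pos$contributions[, "A"]) + 0.01
  thrA <- detect_thresholds(att_pos, tab, "A")
  expect_length(thrA$crossings, 0)
  expect_equal(thrA$intervals$effect, "promoting")
})

test_that("a hinge response yields one crossing at the analytic location", {
  # response ramps above x = 17; the attribution's sign change sits where
  # the curve crosses its mean, i.e. at 17 + E[(x - 17)+]
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 5000
    x <- runif(n, 0, 34)
    tab <- data.frame(x = x, z = runif(n))
    tab$intensity <- pmax(x - 17, 0) + rnorm(n, sd = 0.3)
    expected_cross <- 17 + mean(pmax(x - 17, 0))
    m <- fit_tradeoff_model(tab, boost_params(nrounds = 150, max_depth = 3,
                                              eta = 0.1, seed = s))
    att <- shapley_attributions(m, tab)
    thr <- detect_thresholds(att, tab, "x", bins = 50)
    bin_width <- 34 / 50
    hits <- hits + any(abs(thr$crossings - expected_cross) <= bin_width)
  }
  expect_gte(hits, 9L)
})

test_that("a V-shaped response yields two ordered crossings", {
  # |x - 17| on x ~ U(0, 34): attribution crosses zero at 8.5 and 25.5
  set.seed(52)
  n <- 6000
  x <- runif(n, 0, 34)
  tab <- data.frame(x = x, z = runif(n))
  tab$intensity <- abs(x - 17) + rnorm(n, sd = 0.3)
  m <- fit_tradeoff_model(tab, boost_params(nrounds = 150, max_depth = 3,
                                            eta = 0.1, seed = 1))
  att <- shapley_attributions(m, tab)
  thr <- detect_thresholds(att, tab, "x", bins = 50)
  expect_length(thr$crossings, 2)
  expect_true(all(diff(thr$crossings) > 0))
  bin_width <- 34 / 50
  expect_equal(thr$crossings[1], 8.5, tolerance = 2 * bin_width / 8.5)
  expect_equal(thr$crossings[2], 25.5, tolerance = 2 * bin_width / 25.5)
  # interval effects alternate: promoting, suppressing, promoting
  expect_equal(thr$intervals$effect,
               c("promoting", "suppressing", "promoting"))
})

test_that("categorical drivers are summarized per category", {
  set.seed(71)
  n <- 1000
  tab <- data.frame(Land = sample(1:4, n, TRUE), A = runif(n))
  tab$intensity <- c(-0.5, -0.2, 0.3, 0.6)[tab$Land] +
    rnorm(n, sd = 0.05)
  attr(tab, "categorical") <- "Land"
  class(tab) <- c("feature_table", class(tab))
  m <- fit_tradeoff_model(tab, fast_params())
  att <- shapley_attributions(m, tab)
  thr <- detect_thresholds(att, tab, "Land")
  expect_equal(thr$type, "categorical")
  expect_equal(thr$categories$effect,
               c("suppressing", "suppressing", "promoting", "promoting"))
})
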