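test_that("min-max standardization is the declared linear map", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_standardize(5, 5, 10), 0)
  expect_equal(minmax_standardize(10, 5, 10), 1)
  expect_error(minmax_standardize(c(1, 1, 1)), "degenerate")
})

test_that("partial correlation reduces correctly in analytic cases", {
  set.seed(2)
  # controls uncorrelated with a and b leave r unchanged (construct r13 =
  # r23 = 0 exactly by residualizing the control)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  z <- rnorm(40)
  z_perp <- residuals(lm(z ~ a + b))
  expect_equal(partial_correlation(a, b, list(z_perp)), cor(a, b),
               tolerance = 1e-10)
  # fully mediated: r12 = r13 * r23 gives zero partial correlation
  z2 <- rnorm(60)
  a2 <- 0.8 * z2 + rnorm(60)
  b2 <- 0.6 * z2 + rnorm(60)
  a2r <- 0.8 * z2 + residuals(lm((a2 - 0.8 * z2) ~ z2 + b2))
  # direct construction: a2r correlates with b2 only through z2
  expect_lt(abs(partial_correlation(a2r, b2, list(z2))), 1e-8)
})

test_that("partial correlation equals the residual-regression oracle", {
  set.seed(33)
  for (rep in 1:100) {
    g <- sample(1:2, 1)
    X <- matrix(rnorm(50 * (2 + g)), 50)
    a <- X[, 1]; b <- X[, 2]
    ctrl <- lapply(seq_len(g), function(j) X[, 2 + j])
    Z <- do.call(cbind, ctrl)
    oracle <- cor(residuals(lm(a ~ Z)), residuals(lm(b ~ Z)))
    expect_equal(partial_correlation(a, b, ctrl), oracle,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and underdetermined inputs are flagged", {
  expect_warning(r <- partial_correlation(rep(1, 10), rnorm(10)),
                 "zero-variance")
  expect_true(is.na(r))
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   list(rnorm(4), rnorm(4))),
               "insufficient")
})

test_that("p-values follow the t reference distribution", {
  # r = 0 is exactly null
  expect_equal(correlation_pvalue(0, 20, 0), 1)
  # worked example: r = 0.5, n = 22, g = 2 -> t = 2.449, p ~ 0.0248
  t_oracle <- 0.5 * sqrt(18 / (1 - 0.25))
  expect_equal(t_oracle, 2.449, tolerance = 1e-3)
  p <- correlation_pvalue(0.5, 22, 2)
  expect_equal(p, 2 * pt(-t_oracle, 18), tolerance = 1e-12)
  expect_equal(p, 0.0248, tolerance = 2e-3)
  # p decreases monotonically as r -> 1
  rs <- seq(0.1, 0.95, by = 0.05)
  ps <- correlation_pvalue(rs, 20, 2)
  expect_true(all(diff(ps) < 0))
  expect_warning(p1 <- correlation_pvalue(1, 20, 0), "degenerate")
  expect_equal(p1, 0)
})

test_that("the classification rule follows sign and significance", {
  expect_equal(classify_relationship(0.6, 0.01), 1L)
  expect_equal(classify_relationship(-0.6, 0.01), -1L)
  expect_equal(classify_relationship(0.9, 0.2), 0L)
  expect_equal(classify_relationship(c(0.5, -0.5, 0.1),
                                     c(0.001, 0.04, 0.9)),
               c(1L, -1L, 0L))
  expect_equal(significance_stars(c(0.2, 0.07, 0.03)),
               c("*", "**", "***"))
})

test_that("RMSD closed forms hold", {
  expect_equal(rmsd(c(0.4, 0.4)), 0)
  expect_equal(rmsd(c(0, 1)), sqrt(0.5), tolerance = 1e-9)
  expect_equal(rmsd(c(0.2, 0.5, 0.8)), 0.3, tolerance = 1e-9)
  # permutation invariance
  set.seed(3)
  v <- runif(4)
  expect_equal(rmsd(v), rmsd(rev(v)))
  expect_error(rmsd(0.3), "two services")
})

test_that("pairwise RMSD maps equal |v1 - v2| / sqrt(2) pointwise", {
  set.seed(14)
  A <- matrix(runif(100, 10, 50), 10, 10)
  B <- matrix(runif(100, -5, 5), 10, 10)
  es <- fake_es_list(list(WY = list(A), SC = list(B)))
  im <- rmsd_map(es, c("WY", "SC"), year = 0)
  sa <- (A - min(A)) / (max(A) - min(A))
  sb <- (B - min(B)) / (max(B) - min(B))
  expect_equal(im$rmsd$values, abs(sa - sb) / sqrt(2), tolerance = 1e-12)
  # identical services -> zero map
  es2 <- fake_es_list(list(WY = list(A), SC = list(A)))
  expect_true(all(rmsd_map(es2, c("WY", "SC"), 0)$rmsd$values == 0))
  # endpoint pixel: one service at its min where the other peaks
  C <- A; C[3, 3] <- min(A) - 1e-9
  D <- B; D[3, 3] <- max(B)
  es3 <- fake_es_list(list(WY = list(C), SC = list(D)))
  expect_equal(rmsd_map(es3, c("WY", "SC"), 0)$rmsd$values[3, 3],
               sqrt(0.5), tolerance = 1e-6)
})

test_that("category maps ignore affine rescaling of raw service units", {
  set.seed(7)
  mats <- function(f) lapply(1:8, function(t) f(matrix(rnorm(64), 8, 8)))
  base <- list(WY = mats(identity), SC = mats(identity),
               WS = mats(identity), HQ = mats(identity))
  es <- fake_es_list(base)
  tm1 <- tradeoff_map(es, c("WY", "SC"))
  scaled <- base
  scaled$WY <- lapply(base$WY, function(m) 100 + 3 * m)
  scaled$SC <- lapply(base$SC, function(m) 0.01 * m - 7)
  tm2 <- tradeoff_map(fake_es_list(scaled), c("WY", "SC"))
  expect_equal(tm1$r$values, tm2$r$values, tolerance = 1e-12)
  expect_identical(tm1$category$values, tm2$category$values)
})

test_that("a self-pair is pure synergy; planted anti-correlation is a
           trade-off", {
  set.seed(23)
  n_years <- 20
  base <- lapply(1:n_years, function(t) matrix(rnorm(144), 12, 12))
  anti <- lapply(base, function(m) -m + matrix(rnorm(144, sd = 0.05),
                                               12, 12))
  noise <- function() lapply(1:n_years, function(t)
    matrix(rnorm(144), 12, 12))
  es <- fake_es_list(list(WY = base, SC = base, WS = noise(),
                          HQ = noise()))
  tm <- tradeoff_map(es, c("WY", "SC"))
  # identical series: r = 1 wherever defined, synergy where significant
  expect_true(all(abs(tm$r$values - 1) < 1e-6, na.rm = TRUE))
  expect_true(all(tm$category$values[!is.na(tm$category$values)] %in%
                    c(0, 1)))
  es2 <- fake_es_list(list(WY = base, SC = anti, WS = noise(),
                           HQ = noise()))
  tm2 <- tradeoff_map(es2, c("WY", "SC"))
  expect_gt(tm2$fractions["tradeoff"], 0.95)
})

test_that("independent services reject at close to the nominal rate", {
  set.seed(61)
  n_years <- 20
  noise <- function() lapply(1:n_years, function(t)
    matrix(rnorm(2000), 40, 50))
  es <- fake_es_list(list(WY = noise(), SC = noise(), WS = noise(),
                          HQ = noise()))
  tm <- tradeoff_map(es, c("WY", "SC"), alpha = 0.05)
  sig_rate <- 1 - tm$fractions["nonsignificant"]
  expect_gt(sig_rate, 0.04)
  expect_lt(sig_rate, 0.06)
})

test_that("temporal mode enforces its degrees-of-freedom requirement", {
  set.seed(9)
  mats <- function() lapply(1:4, function(t) matrix(rnorm(16), 4, 4))
  es <- fake_es_list(list(WY = mats(), SC = mats(), WS = mats(),
                          HQ = mats()))
  expect_error(tradeoff_map(es, c("WY", "SC")), "degrees of freedom")
  # with g = 0 controls 4 years suffice
  expect_s3_class(tradeoff_map(es, c("WY", "SC"), controls = character(0)),
                  "tradeoff_maps")
})

test_that("spatial mode returns one classified row per year", {
  es <- small_es()
  sp <- tradeoff_map(es, c("WY", "HQ"), mode = "spatial")
  expect_equal(nrow(sp), 6)
  expect_true(all(sp$g == 2))
  expect_true(all(sp$category %in% c("tradeoff", "synergy",
                                     "nonsignificant")))
  expect_true(all(abs(sp$r) <= 1))
})
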