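test_that("square-root transform is monotone and guards double application", {
  m <- matrix(c(0, 100, 25, 4), 2, 2)
  s <- sqrt_transform(m)
  expect_equal(as.numeric(s), c(0, 10, 5, 2))
  expect_error(sqrt_transform(s), "already")
  expect_error(sqrt_transform(-m), "non-negative")
  expect_true(all(diff(sqrt_transform(matrix(c(1, 4, 9, 16), 4, 1))) > 0))
})

test_that("PCA axis 1 captures rank-1 structure and rejects degenerate input", {
  g <- seq(-2, 2, length.out = 10)
  m <- cbind(a = 5 + g, b = 5 - g)   # perfect negative covariation
  p <- pca_axis1(m)
  expect_equal(p$axis1_variance_fraction, 1)
  expect_error(pca_axis1(matrix(3, 5, 4)), "zero variance")
  expect_error(pca_axis1(m[1:2, ]), "at least 3")
})

test_that("PCA recovers a latent gradient's variance share", {
  set.seed(21)
  fr <- replicate(50, {
    n <- 60; p <- 8
    grad <- rnorm(n); grad <- grad - mean(grad)
    load <- rnorm(p); load <- load / sqrt(sum(load^2))
    signal <- outer(grad, load)
    noise <- matrix(rnorm(n * p), n, p)
    # noise orthogonal to the gradient (samples) and its loading (taxa), so
    # the construction's variance split is what PCA should report
    noise <- noise - outer(grad, drop(crossprod(noise, grad))) / sum(grad^2)
    noise <- noise - (noise %*% load) %*% t(load)
    # scale so the gradient contributes 60% of total variance
    noise <- noise * sqrt(sum(signal^2) * 0.4 / 0.6) / sqrt(sum(noise^2))
    pca_axis1(signal + noise)$axis1_variance_fraction
  })
  expect_lt(abs(median(fr) - 0.60), 0.05)
})

test_that("PCA scores are invariant to taxon order and oriented by time", {
  cm <- make_community(community_config(), seed = 2)
  sq <- sqrt_transform(cm$abundance)
  p1 <- pca_axis1(sq, ages = cm$ages)
  perm <- sample(ncol(sq))
  sq2 <- sq[, perm]
  attr(sq2, "sqrt_transformed") <- TRUE
  p2 <- pca_axis1(sq2, ages = cm$ages)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
  expect_gte(cor(p1$scores, cm$ages), 0)
})

test_that("partial RDA recovers the prescribed variance fraction", {
  fr <- vapply(1:50, function(s) {
    cc <- make_community(community_config(), seed = s)
    partial_rda(sqrt_transform(cc$abundance), cc$supply,
                cc$ages)$rda_variance_fraction
  }, numeric(1))
  expect_lt(abs(median(fr) - 0.25), 0.05)
})

test_that("partial RDA agrees with vegan's conditioned RDA", {
  skip_if_not_installed("vegan")
  cc <- make_community(community_config(), seed = 3)
  sq <- sqrt_transform(cc$abundance)
  ours <- partial_rda(sq, cc$supply, cc$ages)$rda_variance_fraction
  x <- cc$supply; z <- cc$ages
  v <- vegan::rda(sq ~ x + Condition(z))
  theirs <- v$CCA$tot.chi / (v$tot.chi - v$pCCA$tot.chi)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("partial RDA nulls out orthogonal or collinear predictors", {
  set.seed(22)
  cc <- make_community(community_config(), seed = 4)
  sq <- sqrt_transform(cc$abundance)
  # random predictor unrelated to the community
  rnd <- rnorm(length(cc$ages))
  expect_lt(partial_rda(sq, rnd, cc$ages)$rda_variance_fraction, 0.1)
  # predictor identical to the covariable: fully partialled out
  expect_warning(r <- partial_rda(sq, cc$ages, cc$ages), "collinear")
  expect_identical(r$rda_variance_fraction, 0)
  expect_true(r$collinear_flag)
})

test_that("partial RDA is invariant to affine rescaling of its inputs", {
  cc <- make_community(community_config(), seed = 5)
  sq <- sqrt_transform(cc$abundance)
  f0 <- partial_rda(sq, cc$supply, cc$ages)$rda_variance_fraction
  f1 <- partial_rda(sq, 3 * cc$supply - 40, cc$ages)$rda_variance_fraction
  f2 <- partial_rda(sq, cc$supply, 0.1 * cc$ages + 7)$rda_variance_fraction
  expect_equal(f1, f0, tolerance = 1e-10)
  expect_equal(f2, f0, tolerance = 1e-10)
})

test_that("autumn/spring ratio handles zeros and missing labels", {
  m <- matrix(c(20, 0, 10,
                40, 30, 0), nrow = 3,
              dimnames = list(NULL, c("aut", "spr")))
  seasons <- c(aut = "autumn", spr = "spring")
  r <- autumn_spring_ratio(m, seasons)
  expect_equal(r$ratio[1], 0.5)
  expect_equal(r$ratio[2], 0)
  expect_true(is.na(r$ratio[3]))
  expect_equal(r$flag[3], "undefined")
  expect_error(autumn_spring_ratio(m, c(aut = "other", spr = "other")),
               "labelled")
  expect_error(autumn_spring_ratio(m, c(aut = "autumn")), "spring")
})

test_that("correlation is exact on deterministic series and symmetric", {
  x <- 1:20
  r <- correlate_series(x, -x)
  expect_equal(r$r, -1)
  set.seed(23)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(correlate_series(a, b)$r, correlate_series(b, a)$r)
  expect_error(correlate_series(1:10, rep(1, 10)), "zero variance")
  expect_error(correlate_series(1:3, 1:3), "at least 5")
})

test_that("independent series rarely show |r| > 0.3 at n = 100", {
  set.seed(24)
  big <- replicate(200, abs(correlate_series(rnorm(100), rnorm(100))$r))
  expect_gte(mean(big < 0.3), 0.95)
})
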