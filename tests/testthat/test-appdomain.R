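train_block <- function(seed = 41, n = 18, p = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("t%02d", 1:n),
                                sprintf("d%d", 1:p)))
    X
  })
}

test_that("standardization AD follows the three-branch rule", {
  X <- train_block()
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  at_mean <- matrix(mu, 1, dimnames = list("q", colnames(X)))
  r <- ad_standardization(X, at_mean)
  expect_equal(r$class, "inside")
  expect_equal(r$s_max, 0)

  far <- matrix(mu + c(4, 5, 6) * sdv, 1,
                dimnames = list("q", colnames(X)))
  expect_equal(ad_standardization(X, far)$class, "outlier")

  # mixed profile (1, 1, 4): s_new = 2 + 1.28 * sd(c(1,1,4)) = 4.217...
  mix <- matrix(mu + c(1, 1, 4) * sdv, 1,
                dimnames = list("q", colnames(X)))
  rm <- ad_standardization(X, mix)
  expect_equal(rm$s_new, 2 + 1.28 * sd(c(1, 1, 4)), tolerance = 1e-10)
  expect_equal(round(rm$s_new, 3), 4.217)
  expect_equal(rm$class, "outlier")

  Xc <- X; Xc[, 2] <- 7
  expect_error(ad_standardization(Xc, at_mean), "zero-spread")
})

test_that("standardization AD is invariant to affine column rescaling", {
  X <- train_block(42)
  Q <- X[1:5, ] + 0.5
  base <- ad_standardization(X, Q)
  scale <- c(10, -3, 0.01); shift <- c(-2, 5, 100)
  Xa <- sweep(sweep(X, 2, scale, "*"), 2, shift, "+")
  Qa <- sweep(sweep(Q, 2, scale, "*"), 2, shift, "+")
  resc <- ad_standardization(Xa, Qa)
  expect_equal(resc$s_max, base$s_max)
  expect_equal(resc$class, base$class)
})

test_that("leverages match the brute-force projection and sum to p'", {
  X <- train_block(43)
  res <- rnorm(nrow(X), 0, 0.1)
  lev <- ad_leverage(X, X, res, rmse = 0.1)
  A <- cbind(1, X)
  H <- A %*% solve(t(A) %*% A) %*% t(A)
  expect_equal(lev$h, unname(diag(H)), tolerance = 1e-10)
  expect_equal(sum(lev$h), ncol(X) + 1, tolerance = 1e-10)
  expect_equal(lev$h_star[1], 3 * (ncol(X) + 1) / nrow(X))
  expect_true(all(lev$h >= 0 & lev$h <= 1))
})

test_that("h* follows the printed formula", {
  X <- train_block(44, n = 18, p = 3)
  lev <- ad_leverage(X, X[1, , drop = FALSE], 0, 1)
  expect_equal(lev$h_star, 12 / 18)
})

test_that("duplicating an extreme point lowers its leverage", {
  X <- train_block(45, n = 12, p = 2)
  X[1, ] <- c(6, 6)  # extreme
  h1 <- ad_leverage(X, X[1, , drop = FALSE], 0, 1)$h
  Xdup <- rbind(X, X[1, ])
  h2 <- ad_leverage(Xdup, X[1, , drop = FALSE], 0, 1)$h
  expect_lt(h2, h1)
})

test_that("leverage classes cover the four Williams-plot quadrants", {
  X <- train_block(46, n = 20, p = 2)
  Q <- rbind(inside = c(0, 0), good = c(8, 8),
             resp = c(0.2, -0.1), both = c(7, -9))
  colnames(Q) <- colnames(X)
  res <- c(0.1, 0.2, 5, -4)
  lev <- ad_leverage(X, Q, res, rmse = 1)
  expect_equal(lev$class,
               c("inside", "good_leverage", "response_outlier",
                 "structural_response_outlier"))
})

test_that("compact synthetic designs are fully inside the domain", {
  withr::with_seed(47, {
    X <- matrix(rnorm(60, sd = 1), 20, 3,
                dimnames = list(sprintf("t%02d", 1:20), c("a", "b", "c")))
    y <- drop(1 + X %*% c(1, -1, 0.5)) + rnorm(20, 0, 0.1)
    m <- fit_ols(X, y)
    std <- ad_standardization(X, X)
    expect_true(all(std$class == "inside"))
    lev <- ad_leverage(X, X, m$fit$residuals, m$fit$rmse_c)
    expect_true(all(abs(lev$std_residual) <= 3))
  })
})

test_that("ILs sharing an anion share the anion-block contribution to s", {
  ils <- fixture_ils()
  m <- assemble_separate(ils, fixture_ion_descriptors())
  vals <- dm_values(m)
  acols <- grep("\\^A$", colnames(vals), value = TRUE)[1:2]
  X <- vals[1:18, acols]
  keep <- apply(X, 2, sd) > 0
  X <- X[, keep, drop = FALSE]
  s <- ad_standardization(X, vals[, colnames(X), drop = FALSE])
  scn_rows <- which(ils$anion_id == "SCN")
  expect_length(unique(s$s_max[scn_rows]), 1)
})

test_that("williams_data carries points and both thresholds", {
  X <- train_block(48)
  lev <- ad_leverage(X, X, rnorm(18, 0, 0.1), 0.1)
  w <- williams_data(lev)
  expect_equal(nrow(w$points), 18)
  expect_equal(w$thresholds$sigma_band, 3)
  expect_equal(w$thresholds$h_star, 12 / 18)
  empty <- ad_leverage(X, X[0, , drop = FALSE], numeric(0), 0.1)
  expect_equal(nrow(williams_data(empty)$points), 0)
})

test_that("assess_ad reports both methods over train and validation sets", {
  d <- generate_dataset(generator_spec(seed = 49))
  m <- assemble_pair_additive(d$ils,
                              suppressWarnings(ion_descriptors(d$registry)))
  ids <- d$ils$il_id
  y <- stats::setNames(d$ils$endpoint, ids)
  model <- fit_ols(m[m$il_id %in% ids[1:18], ], y[1:18])
  ad <- assess_ad(model, m, y, ids[1:18], ids[19:24])
  expect_equal(nrow(ad), 24)
  expect_setequal(unique(ad$set), c("train", "valid"))
  expect_true(all(ad$std_class %in% c("inside", "outlier")))
  expect_gt(attr(ad, "h_star"), 0)
})
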