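test_that("fit_ols solves exact and degenerate cases", {
  X <- matrix(c(0, 1, 2), dimnames = list(NULL, "x"))
  m <- fit_ols(X, c(1, 3, 5))
  expect_equal(unname(m$coefficients), 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$fit$residuals, rep(0, 3), tolerance = 1e-12)

  X2 <- matrix(rnorm(10), dimnames = list(NULL, "x"))
  mc <- fit_ols(X2, rep(3, 10))
  expect_equal(unname(mc$coefficients), 0, tolerance = 1e-10)
  expect_equal(mc$intercept, 3, tolerance = 1e-10)

  withr::with_seed(5, {
    X3 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    beta <- c(1.5, -2, 0.5)
    m3 <- fit_ols(X3, drop(2 + X3 %*% beta))
    expect_equal(unname(m3$coefficients), beta, tolerance = 1e-10)
  })

  Xs <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12))
  expect_error(fit_ols(Xs, rnorm(6)), "collinear column\\(s\\): b")
})

test_that("predict applies fixed equations exactly", {
  mods <- load_fixture_models()
  m4 <- mods[["M4"]]
  row <- data.frame(GMTI = 1000, MDDD = 5, AMW = 10, check.names = FALSE)
  expect_equal(unname(predict(m4, row)), 4.15 - 1.0 - 0.45 - 1.6,
               tolerance = 1e-12)
  m2 <- mods[["M2"]]
  row2 <- data.frame(`L1m^C` = 4.48, `L1i^A` = 0.00, check.names = FALSE)
  expect_equal(unname(predict(m2, row2)), 2.52 - 0.12 * 4.48,
               tolerance = 1e-12)
  zero <- data.frame(GMTI = 0, MDDD = 0, AMW = 0, check.names = FALSE)
  expect_equal(unname(predict(m4, zero)), m4$intercept)
  expect_error(predict(m4, data.frame(GMTI = 1)), "MDDD, AMW")
})

test_that("fitted values are reproduced by predict on training data", {
  withr::with_seed(8, {
    X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(1 + X %*% c(1, 0.5, -1)) + rnorm(15, 0, 0.3)
    m <- fit_ols(X, y)
    expect_equal(unname(predict(m, X)), m$fit$fitted, tolerance = 1e-12)
  })
})

test_that("fixture models carry the printed coefficients", {
  mods <- load_fixture_models()
  expect_length(mods, 6)
  expect_equal(mods[["M1"]]$intercept, 2.49)
  expect_equal(unname(mods[["M1"]]$coefficients), c(-0.14, -0.001))
  expect_equal(mods[["M1"]]$descriptor_names, c("Psi_i_0^A", "SMTIV^C"))
  expect_equal(mods[["M5"]]$intercept, 6.91)
  expect_equal(unname(mods[["M5"]]$coefficients), c(-0.24, -1.05, 0.53))
  expect_equal(mods[["M6"]]$intercept, 3.49)
  expect_equal(mods[["M3"]]$intercept, 2.304)
})

test_that("stepwise finds the informative descriptor among noise", {
  withr::with_seed(21, {
    X <- matrix(rnorm(24 * 11), 24, 11,
                dimnames = list(NULL, c(sprintf("N%02d", 1:10), "true")))
    y <- drop(2 + 3 * X[, "true"])
    sw <- stepwise_select(X, y, criterion = "press", max_features = 3)
    expect_equal(sw$trace$candidate[sw$trace$accepted][1], "true")
    expect_equal(sw$model$descriptor_names, "true")
  })
})

test_that("duplicate informative columns: exactly one enters", {
  withr::with_seed(22, {
    x <- rnorm(24)
    X <- cbind(a = x, b = x, c = rnorm(24))
    y <- 1 + 2 * x + rnorm(24, 0, 0.1)
    sw <- stepwise_select(X, y, max_features = 3, corr_max = 0.7)
    expect_length(intersect(sw$model$descriptor_names, c("a", "b")), 1)
  })
})

test_that("stepwise recovers exact support in the noiseless orthogonal case", {
  withr::with_seed(23, {
    Q <- qr.Q(qr(matrix(rnorm(24 * 8), 24, 8)))
    colnames(Q) <- sprintf("v%d", 1:8)
    y <- drop(Q %*% c(2, 0, -1.5, 0, 0, 1, 0, 0))
    sw <- stepwise_select(Q, y, criterion = "press", max_features = 8)
    expect_setequal(sw$model$descriptor_names, c("v1", "v3", "v6"))
  })
})

test_that("the final model's criterion beats every visited candidate", {
  withr::with_seed(24, {
    X <- matrix(rnorm(24 * 8), 24, 8,
                dimnames = list(NULL, sprintf("v%d", 1:8)))
    y <- drop(1 + X %*% c(1, -1, 0.5, rep(0, 5))) + rnorm(24, 0, 0.3)
    sw <- stepwise_select(X, y, criterion = "press", max_features = 4)
    final <- min(sw$trace$criterion_value[sw$trace$accepted])
    expect_true(all(sw$trace$criterion_value >= final - 1e-12))
  })
})

test_that("replaying a trace reproduces the selected descriptors", {
  withr::with_seed(25, {
    X <- matrix(rnorm(24 * 6), 24, 6,
                dimnames = list(NULL, sprintf("v%d", 1:6)))
    y <- drop(X %*% c(2, -2, rep(0, 4))) + rnorm(24, 0, 0.2)
    sw <- stepwise_select(X, y)
    expect_setequal(replay_trace(sw$trace), sw$model$descriptor_names)
  })
})

test_that("model JSON round-trips to identical predictions", {
  m <- load_fixture_models()[["M4"]]
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, tmp)
  m2 <- read_model_json(tmp)
  row <- data.frame(GMTI = 1234, MDDD = 5.5, AMW = 9.1, check.names = FALSE)
  expect_identical(predict(m, row), predict(m2, row))
  expect_identical(m2$descriptor_names, m$descriptor_names)
})
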