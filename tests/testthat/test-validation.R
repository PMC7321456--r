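test_that("calibration statistics match hand arithmetic", {
  perfect <- calibration_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE_C, 0)
  expect_equal(perfect$MAE, 0)

  s <- calibration_stats(c(0, 1, 2), c(0, 0, 0))
  expect_equal(s$R2, -1.5)
  expect_equal(s$RMSE_C, sqrt(5 / 3))
  expect_equal(s$MAE, 1)

  m <- calibration_stats(c(0, 1, 2), rep(1, 3))
  expect_equal(m$R2, 0)
  expect_error(calibration_stats(c(1, 1), c(1, 2)), "undefined")
})

test_that("LOO shortcut equals explicit refits", {
  withr::with_seed(31, {
    X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(1 + X %*% c(1, -0.5, 2)) + rnorm(15, 0, 0.4)
    cv <- loo_cv(X, y)
    brute <- vapply(1:15, function(i) {
      f <- stats::lsfit(X[-i, ], y[-i])
      y[i] - sum(c(1, X[i, ]) * f$coefficients)
    }, numeric(1))
    expect_equal(cv$press_residuals, brute, tolerance = 1e-10)
    expect_equal(cv$Q2_CV, 1 - sum(brute^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  })
})

test_that("LOO on noiseless linear data gives Q2 = 1", {
  X <- matrix(seq_len(12), dimnames = list(NULL, "x"))
  y <- 2 * seq_len(12) + 1
  expect_equal(loo_cv(X, y)$Q2_CV, 1, tolerance = 1e-10)
})

test_that("uninformative predictors give negative expected Q2", {
  q2 <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
      loo_cv(X, rnorm(30))$Q2_CV
    })
  }, numeric(1))
  expect_lt(mean(q2), 0)
})

test_that("external validation statistics match hand arithmetic", {
  p <- external_stats(c(1, 2), c(1, 2), 5)
  expect_equal(p$Q2_EXT, 1)
  expect_equal(p$RMSE_EXT, 0)
  expect_equal(external_stats(c(1, 2), c(1.5, 1.5), 1.5)$Q2_EXT, 0)
  e <- external_stats(c(1, 2), c(1.1, 1.9), 0)
  expect_equal(e$Q2_EXT, 1 - 0.02 / 5)
})

test_that("Q2_EXT is invariant only under a shared constant shift", {
  y <- c(1.2, 0.8, 2.1); yh <- c(1.0, 1.1, 1.8); mu <- 1.4
  base <- external_stats(y, yh, mu)$Q2_EXT
  expect_equal(external_stats(y + 3, yh + 3, mu + 3)$Q2_EXT, base)
  expect_false(isTRUE(all.equal(external_stats(y + 3, yh + 3, mu)$Q2_EXT,
                                base)))
})

test_that("concordance correlation matches hand cases and attenuation", {
  expect_equal(ccc(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(ccc(c(0, 1, 2), c(1, 2, 3)), 4 / 7)
  expect_equal(ccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_error(ccc(c(1, 1), c(2, 2)), "undefined")
  withr::with_seed(33, {
    for (i in 1:25) {
      x <- rnorm(20); y <- rnorm(20, x, 0.5)
      expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
    }
  })
})

test_that("modified r2 penalizes scale divergence", {
  r <- r2m(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r2m, 1)
  expect_equal(r$delta, 0)

  obs <- c(1, 2, 3); pred <- 2 * obs
  rs <- r2m(obs, pred)
  expect_equal(cor(obs, pred)^2, 1)
  expect_lt(rs$r2m, 1)
  # hand oracle (through-origin slope of obs on pred, r0^2 comparing the
  # predictions with their k-scaled selves)
  k <- sum(obs * pred) / sum(pred^2)
  r0 <- 1 - sum((pred - k * pred)^2) / sum((pred - mean(pred))^2)
  expect_equal(rs$r2m, 1 * (1 - sqrt(abs(1 - r0))))

  withr::with_seed(34, {
    vals <- vapply(1:20, function(i)
      r2m(rnorm(50), rnorm(50))$r2m, numeric(1))
    expect_lt(mean(abs(vals)), 0.1)
  })
})

test_that("Tropsha checklist evaluates values and inclusive bounds", {
  y <- c(0.5, 1.1, 1.9, 2.4, 3.2); q2 <- 0.8
  perfect <- tropsha_checklist(y, y, q2)
  expect_true(all(perfect$pass))
  expect_equal(perfect$value[perfect$criterion == "0.85 <= k <= 1.15"], 1)

  shifted <- tropsha_checklist(y, y + 10, q2)
  expect_false(all(shifted$pass))
  kfail <- shifted[grepl("<= k", shifted$criterion), ]
  expect_false(all(kfail$pass))

  # boundary k = 0.85 passes (inclusive)
  yb <- c(1, 2, 3, 4)
  pred <- yb / 0.85   # through-origin slope of obs on pred = 0.85
  chk <- tropsha_checklist(yb, pred, q2)
  expect_equal(chk$value[chk$criterion == "0.85 <= k <= 1.15"], 0.85,
               tolerance = 1e-12)
  expect_true(chk$pass[chk$criterion == "0.85 <= k <= 1.15"])
})

test_that("Toth F ratio and critical comparison behave as printed", {
  r <- toth_f(0.8, 0.9, 20, 3)
  expect_equal(r$F, 2)
  expect_equal(toth_f(0.7, 0.7, 20, 3)$F, 1)
  expect_error(toth_f(0.9, 1, 20, 3), "undefined")
  # near-noiseless synthetic data: no influential points, so F sits
  # modestly above 1 (PRESS residuals carry the 1/(1-h) inflation) and
  # well below the critical value
  withr::with_seed(35, {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(1 + X %*% c(1, 1, 1)) + rnorm(20, 0, 1e-6)
    cal <- calibration_stats(y, fit_ols(X, y)$fit$fitted)
    cv <- loo_cv(X, y)
    ft <- toth_f(cv$Q2_CV, cal$R2, 20, 3)
    expect_gte(ft$F, 1)
    expect_lt(ft$F, 2)
    expect_true(ft$pass)
  })
})

test_that("full validation report is internally consistent", {
  withr::with_seed(36, {
    d <- generate_dataset(generator_spec(seed = 36))
    m <- assemble_pair_additive(d$ils,
                                suppressWarnings(
                                  ion_descriptors(d$registry)))
    ids <- d$ils$il_id
    rep <- validate_model(fit_ols(m[m$il_id %in% ids[1:18], ],
                                  d$ils$endpoint[1:18]),
                          m, stats::setNames(d$ils$endpoint, ids),
                          ids[1:18], ids[19:24])
    expect_lte(rep$R2, 1)
    expect_gte(rep$RMSE_C, 0)
    expect_gte(rep$RMSE_EXT, 0)
    expect_true(abs(rep$CCC) <= 1)
    expect_true(all(is.finite(c(rep$Q2_CV, rep$Q2_EXT, rep$toth$F))))
    expect_equal(nrow(rep$predictions), 24)
  })
})
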