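test_that("full-model OLS matches the normal-equations oracle", {
  withr::with_seed(11, {
    for (k in 1:20) {
      n <- sample(20:50, 1)
      p <- sample(2:6, 1)
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("x", seq_len(p))))
      y <- rnorm(n)
      df <- data.frame(y = y, X)
      ord <- chain_ordering(boxes = list("y", colnames(X)))
      fit <- fit_full_model("y", ord, df)
      oracle <- ols_oracle(cbind(1, X), y)
      expect_equal(unname(coef(fit$lm)), oracle$beta, tolerance = 1e-10)
      sm <- summary(fit$lm)$coefficients
      expect_equal(unname(sm[, 2]), oracle$se, tolerance = 1e-10)
      expect_equal(unname(sm[, 4]), oracle$p, tolerance = 1e-10)
    }
  })
})

test_that("a single standardized covariate gives slope cov/var", {
  withr::with_seed(3, {
    x <- rnorm(10); y <- 2 * x + rnorm(10)
    df <- data.frame(y = y, x = x, z = rnorm(10))
    ord <- chain_ordering(boxes = list("y", "x"))
    fit <- fit_full_model("y", ord, df)
    # closed-form simple-regression slope
    expect_equal(unname(coef(fit$lm)["x"]),
                 sum((x - mean(x)) * (y - mean(y))) /
                   sum((x - mean(x))^2))
  })
})

test_that("response identical to a covariate yields an exact fit", {
  df <- data.frame(y = c(1, 2, 3, 4, 5), m = c(1, 2, 3, 4, 5),
                   x = c(2, 1, 4, 3, 5))
  ord <- chain_ordering(boxes = list("y", "m"))
  # summary.lm warns on an essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_full_model("y", ord, df))
  expect_equal(unname(coef(fit$lm)["m"]), 1)
  expect_lt(sum(residuals(fit$lm)^2), 1e-20)
  expect_equal(variance_explained(fit), 1)
})

test_that("a pure-noise response shows no signal at large n", {
  withr::with_seed(99, {
    n <- 1000
    df <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                     c = rnorm(n))
    ord <- chain_ordering(boxes = list("y", c("a", "b", "c")))
    fit <- fit_full_model("y", ord, df)
    tv <- summary(fit$lm)$coefficients[-1, 3]
    expect_true(all(abs(tv) < 4))
    expect_lt(variance_explained(fit), 0.02)
  })
})

test_that("rank deficiency raises a collinearity error naming the column", {
  withr::with_seed(4, {
    x <- rnorm(30)
    df <- data.frame(y = rnorm(30), a = x, b = 2 * x)
    ord <- chain_ordering(boxes = list("y", c("a", "b")))
    expect_error(fit_full_model("y", ord, df), "aliased.*b")
  })
})

test_that("partial F-test matches the explicit RSS-ratio oracle", {
  withr::with_seed(21, {
    for (k in 1:10) {
      n <- 40
      X <- matrix(rnorm(n * 4), n, 4)
      y <- X[, 1] + rnorm(n)
      full <- lm(y ~ X)
      reduced <- lm(y ~ X[, 1:2])
      ft <- partial_f_test(reduced, full)
      orc <- partial_f_oracle(cbind(1, X[, 1:2]), cbind(1, X), y)
      expect_equal(ft$statistic, orc$statistic, tolerance = 1e-10)
      expect_equal(ft$p_value, orc$p, tolerance = 1e-10)
    }
  })
  expect_error(partial_f_test(lm(rnorm(10) ~ 1), lm(rnorm(12) ~ 1)),
               "same rows")
})

test_that("backward elimination keeps real signals and drops noise", {
  withr::with_seed(31, {
    n <- 500
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- 2 * x1 + rnorm(n)
    df <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
    ord <- chain_ordering(boxes = list("y", c("x1", "x2", "x3")))
    sel <- select_model(fit_full_model("y", ord, df))
    expect_equal(sel$terms, "x1")
    expect_equal(unname(coef(sel$lm)["x1"]), 2, tolerance = 0.2)
    expect_s3_class(sel$trace, "data.frame")
  })
})

test_that("selection returns intercept-only under the null at roughly (1-alpha)^k", {
  withr::with_seed(77, {
    k <- 3; reps <- 200; alpha <- 0.05
    hits <- 0
    for (r in seq_len(reps)) {
      n <- 60
      df <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                       c = rnorm(n))
      ord <- chain_ordering(boxes = list("y", c("a", "b", "c")))
      sel <- select_model(fit_full_model("y", ord, df), alpha)
      if (length(sel$terms) == 0) hits <- hits + 1
    }
    # expected approximately (1 - alpha)^k = 0.857; allow generous slack
    expect_gt(hits / reps, 0.75)
  })
})

test_that("an already-minimal model is a fixed point of selection", {
  withr::with_seed(8, {
    n <- 300
    x <- rnorm(n)
    df <- data.frame(y = 3 * x + rnorm(n), x = x)
    ord <- chain_ordering(boxes = list("y", "x"))
    full <- fit_full_model("y", ord, df)
    sel <- select_model(full)
    expect_equal(sel$terms, full$terms)
    expect_equal(coef(sel$lm), coef(full$lm))
  })
})

test_that("selected model is nested in the full model with no larger R^2", {
  withr::with_seed(55, {
    for (k in 1:5) {
      n <- 150
      df <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                       c = rnorm(n), d = rnorm(n))
      df$y <- df$y + 0.5 * df$a
      ord <- chain_ordering(boxes = list("y", c("a", "b", "c", "d")))
      full <- fit_full_model("y", ord, df)
      sel <- select_model(full)
      expect_true(all(sel$terms %in% full$terms))
      expect_lte(variance_explained(sel), variance_explained(full) + 1e-12)
    }
  })
})

test_that("categorical blocks are dropped or kept whole", {
  withr::with_seed(13, {
    n <- 300
    grp <- sample(c("UK", "DE", "AU"), n, replace = TRUE)
    x <- rnorm(n)
    y <- 2 * (grp == "DE") - 1.5 * (grp == "AU") + rnorm(n)
    df <- data.frame(y = y, x = x, grp = grp, stringsAsFactors = FALSE)
    ord <- chain_ordering(boxes = list("y", c("x", "grp")),
                          categorical = c(grp = "UK"))
    sel <- select_model(fit_full_model("y", ord, df))
    expect_equal(sel$terms, "grp")
    # block term reports a partial-F p with NA coefficient
    expect_true(is.na(sel$coef_table$coefficient))
    expect_equal(sel$coef_table$df, 2L)
  })
})

test_that("interaction screening adds planted products and forces hierarchy", {
  withr::with_seed(41, {
    n <- 500
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- x1 + x2 + 1.5 * x1 * x2 + rnorm(n)
    df <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
    ord <- chain_ordering(boxes = list("y", c("x1", "x2", "x3")))
    sel <- select_model(fit_full_model("y", ord, df))
    aug <- screen_interactions(sel, list(c("x1", "x2")))
    expect_true("x1:x2" %in% aug$terms)
    expect_true(all(c("x1", "x2") %in% aug$terms))
    # coefficient close to the planted value
    row <- aug$coef_table[aug$coef_table$term == "x1:x2", ]
    expect_equal(row$coefficient, 1.5, tolerance = 0.2)

    # empty candidate list is the identity
    same <- screen_interactions(sel, list())
    expect_equal(same$terms, sel$terms)
    expect_error(screen_interactions(sel, list(c("y", "x1"))),
                 "references the response")
  })
})

test_that("null interactions are added at about the screening level", {
  withr::with_seed(61, {
    reps <- 200; added <- 0
    for (r in seq_len(reps)) {
      n <- 80
      x1 <- rnorm(n); x2 <- rnorm(n)
      df <- data.frame(y = x1 + rnorm(n), x1 = x1, x2 = x2)
      ord <- chain_ordering(boxes = list("y", c("x1", "x2")))
      sel <- select_model(fit_full_model("y", ord, df))
      aug <- screen_interactions(sel, list(c("x1", "x2")))
      if ("x1:x2" %in% aug$terms) added <- added + 1
    }
    rate <- added / reps   # nominal 0.05
    expect_lt(rate, 0.12)
  })
})

test_that("variance explained handles the degenerate boundary", {
  df <- data.frame(y = rnorm(50), x = rnorm(50))
  ord <- chain_ordering(boxes = list("y", "x"))
  fit <- fit_full_model("y", ord, df)
  sel <- select_model(fit, selection_alpha = 1e-9)  # forces intercept-only
  expect_equal(length(sel$terms), 0)
  expect_equal(variance_explained(sel), 0)
  const <- data.frame(y = rep(1, 20), x = rnorm(20))
  cfit <- suppressWarnings(fit_full_model("y", ord, const))
  expect_error(variance_explained(cfit), "zero total variance")
})

test_that("intrinsic continuous covariates are centred with stored constants", {
  withr::with_seed(17, {
    n <- 200
    gps <- rnorm(n, 22, 3)
    df <- data.frame(y = 0.1 * gps + rnorm(n), m = rnorm(n), gps = gps)
    ord <- chain_ordering(boxes = list("y", "m", "gps"), center = "gps")
    fit <- fit_full_model("y", ord, df)
    expect_equal(unname(fit$centers["gps"]), mean(gps))
    # slopes are invariant to centring
    expect_equal(unname(coef(fit$lm)["gps"]),
                 unname(coef(lm(y ~ m + gps, df))["gps"]))
  })
})
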