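test_that("symmetric associations pick the right test per variable pair", {
  withr::with_seed(12, {
    n <- 300
    df <- data.frame(
      a = rnorm(n),
      b = rnorm(n),
      g = sample(c("f", "m"), n, replace = TRUE),
      h = sample(c("x", "y", "z"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    df$b2 <- df$a  # identical continuous pair -> certain edge
    res <- symmetric_associations(c("a", "b2", "g", "h"), df,
                                  categorical = c(g = "f", h = "x"))
    row <- res[res$a == "a" & res$b == "b2", ]
    expect_equal(row$test, "pearson")
    expect_true(row$significant)
    expect_equal(res$test[res$a == "a" & res$b == "g"], "oneway_f")
    expect_equal(res$test[res$a == "g" & res$b == "h"], "chisq")
    # a single variable has no pairs
    expect_equal(nrow(symmetric_associations("a", df)), 0)
  })
})

test_that("independent intrinsic variables connect at about the nominal rate", {
  withr::with_seed(314, {
    reps <- 200; hits <- 0
    for (r in seq_len(reps)) {
      df <- data.frame(u = rnorm(100), v = rnorm(100))
      res <- symmetric_associations(c("u", "v"), df, edge_alpha = 0.10)
      if (res$significant) hits <- hits + 1
    }
    expect_gt(hits / reps, 0.04)
    expect_lt(hits / reps, 0.18)
  })
})

test_that("graph assembly turns retained significant terms into edges", {
  withr::with_seed(7, {
    n <- 400
    m <- rnorm(n); x1 <- rnorm(n); x2 <- rnorm(n)
    df <- data.frame(y = 2 * m + rnorm(n), m = m, x1 = x1, x2 = x2)
    ord <- chain_ordering(boxes = list("y", "m", c("x1", "x2")))
    fit <- select_model(fit_full_model("y", ord, df))
    g <- build_chain_graph(list(fit), ord)
    expect_s3_class(g, "chain_graph")
    expect_equal(nrow(g$edges), 1)
    expect_equal(g$edges$source, "m")
    expect_equal(g$edges$target, "y")
    expect_equal(g$edges$type, "directed")

    # intercept-only fits everywhere -> empty graph
    noise <- df; noise$y <- rnorm(n)
    null_fit <- select_model(fit_full_model("y", ord, noise),
                             selection_alpha = 1e-12)
    g0 <- build_chain_graph(list(null_fit), ord)
    expect_equal(nrow(g0$edges), 0)

    # a fit referencing variables outside the ordering is rejected
    small_ord <- chain_ordering(boxes = list("y", "x1"))
    expect_error(build_chain_graph(list(fit), small_ord),
                 "outside the ordering")
  })
})

test_that("directed edges always point leftward in the ordering", {
  withr::with_seed(20, {
    sim <- generate_cohort(synthetic_config(seed = 20, n_enrolled = 800,
                                            retention = 1))
    ord <- default_ordering()
    g <- fit_chain_graph(sim$cohort, ord,
                         interactions = list(c("d_weight", "d_satfat_pct")))
    box_of <- function(v) which(vapply(ord$boxes, function(b) v %in% b,
                                       logical(1)))
    dir_edges <- g$edges[g$edges$type != "undirected", ]
    for (k in seq_len(nrow(dir_edges))) {
      src_boxes <- vapply(strsplit(dir_edges$source[k], ":")[[1]], box_of,
                          numeric(1))
      expect_true(all(src_boxes > box_of(dir_edges$target[k])))
    }
  })
})

test_that("outcome-ratio predictions exponentiate the linear predictor", {
  withr::with_seed(23, {
    n <- 250
    d <- data.frame(lr = rnorm(n, -0.1, 0.2), w = rnorm(n, -4, 5),
                    s = rnorm(n, -1, 2), gps = rnorm(n, 22, 3))
    d$lr <- d$lr + 0.02 * d$w - 0.02 * (d$gps - 22)
    ord <- chain_ordering(boxes = list("lr", c("w", "s"), "gps"),
                          center = "gps")
    fit <- select_model(fit_full_model("lr", ord, d))
    q <- predict_outcome_ratio(fit, at = list(w = -5, gps = 20))
    # hand-computed linear predictor with explicit centring
    cf <- coef(fit$lm)
    lp <- unname(cf["(Intercept)"]) +
      (if ("w" %in% names(cf)) cf[["w"]] * -5 else 0) +
      (if ("gps" %in% names(cf)) cf[["gps"]] * (20 - fit$centers[["gps"]])
       else 0)
    expect_equal(q$log_ratio, unname(lp), tolerance = 1e-12)
    expect_equal(q$ratio, exp(lp), tolerance = 1e-12)
    expect_equal(q$pct_change, 100 * (exp(lp) - 1), tolerance = 1e-12)

    # unsupplied covariates sit at no-change / sample mean: difference of
    # two queries depends only on the covariate difference
    qa <- predict_outcome_ratio(fit, at = list(w = -2))
    qb <- predict_outcome_ratio(fit, at = list(w = -7))
    qc <- predict_outcome_ratio(fit, at = list(w = 3))
    qd <- predict_outcome_ratio(fit, at = list(w = -2))
    expect_equal(qa$ratio / qb$ratio, qc$ratio / qd$ratio,
                 tolerance = 1e-12)

    expect_error(predict_outcome_ratio(fit, at = list(zz = 1)),
                 "not in the fitted model")
    expect_warning(predict_outcome_ratio(fit, at = list(w = 1e6)),
                   "outside the observed range")
  })
})

test_that("a null model predicts no change", {
  df <- data.frame(y = c(0, 0, 0, 0), x = c(1, 2, 3, 4))
  ord <- chain_ordering(boxes = list("y", "x"))
  fit <- suppressWarnings(select_model(fit_full_model("y", ord, df),
                                       selection_alpha = 1e-9))
  q <- predict_outcome_ratio(fit)
  expect_equal(q$ratio, 1)
  expect_equal(q$pct_change, 0)
})

test_that("DOT export is deterministic and round-trips the edge set", {
  withr::with_seed(29, {
    sim <- generate_cohort(synthetic_config(seed = 29, n_enrolled = 600,
                                            retention = 1))
    g <- fit_chain_graph(sim$cohort,
                         interactions = list(c("d_weight", "d_satfat_pct"),
                                             c("arm", "d_weight")))
    dot1 <- export_graph_dot(g)
    dot2 <- export_graph_dot(g)
    expect_identical(dot1, dot2)

    parsed <- parse_graph_dot(dot1)
    want <- g$edges
    # undirected edges appear once in either orientation
    key <- function(s, t, ty) {
      und <- ty == "undirected"
      paste(ifelse(und, pmin(s, t), s), ifelse(und, pmax(s, t), t), ty)
    }
    expect_setequal(key(parsed$source, parsed$target, parsed$type),
                    key(want$source, want$target, want$type))

    # empty graph still yields a valid document with node statements
    ord <- chain_ordering(boxes = list("y", "x"))
    empty <- build_chain_graph(list(), ord)
    dot0 <- export_graph_dot(empty)
    expect_match(dot0, "digraph chain_graph")
    expect_match(dot0, "\"y\";")
    expect_equal(nrow(parse_graph_dot(dot0)), 0)
  })
})

test_that("JSON export carries nodes, threshold and edges", {
  ord <- chain_ordering(boxes = list("y", "x"))
  df <- data.frame(y = rnorm(50), x = rnorm(50))
  g <- fit_chain_graph(df, ord)
  js <- jsonlite::fromJSON(export_graph_json(g))
  expect_setequal(js$nodes, c("y", "x"))
  expect_equal(js$edge_alpha, 0.10)
})
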