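#' @keywords internal
# Assemble the model data for one response: complete cases on the response
# and every eligible explanatory variable, with categorical variables as
# factors whose first level is the declared reference. Variables named in
# `center_vars` (intrinsic continuous covariates such as a genetic score
# or age, which have no natural zero) are mean-centred so that main
# effects stay interpretable when product terms are added; change scores
# keep their natural zero ("no change").
prep_model_data <- function(response, vars, data, categorical = NULL,
                            center_vars = character(0)) {
  cols <- c(response, vars)
  df <- data[, cols, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (v in intersect(names(categorical), cols)) {
    f <- factor(as.character(df[[v]]))
    df[[v]] <- stats::relevel(f, ref = categorical[[v]])
  }
  centers <- numeric(0)
  for (v in intersect(center_vars, vars)) {
    if (is.numeric(df[[v]])) {
      centers[v] <- mean(df[[v]])
      df[[v]] <- df[[v]] - centers[v]
    }
  }
  attr(df, "centers") <- centers
  df
}

# fit an OLS model for `response` on the given term labels (possibly
# including interaction labels "a:b"); empty term set = intercept only
fit_terms <- function(response, terms, data) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  stats::lm(fml, data = data)
}

#' Partial F-test between two nested OLS fits
#'
#' The nested-model comparison statistic: the residual-sum-of-squares
#' reduction from the reduced to the full model, per dropped parameter,
#' scaled by the full model's residual variance,
#' \deqn{F = \frac{(RSS_r - RSS_f) / (df_r - df_f)}{RSS_f / df_f}.}
#'
#' @param reduced,full `lm` fits on the same rows, reduced nested in full.
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
partial_f_test <- function(reduced, full) {
  if (length(stats::residuals(reduced)) != length(stats::residuals(full))) {
    stop("nested comparison requires fits on the same rows", call. = FALSE)
  }
  rss_r <- sum(stats::residuals(reduced)^2)
  rss_f <- sum(stats::residuals(full)^2)
  df_r <- stats::df.residual(reduced)
  df_f <- stats::df.residual(full)
  df1 <- df_r - df_f
  if (df1 <= 0) stop("models are not strictly nested", call. = FALSE)
  if (rss_f == 0) {
    # exact fit: dropped terms either cost nothing (stat 0) or everything
    stat <- if (rss_r > 0) Inf else 0
  } else {
    stat <- max(((rss_r - rss_f) / df1) / (rss_f / df_f), 0)
  }
  list(statistic = stat, df1 = df1, df2 = df_f,
       p_value = stats::pf(stat, df1, df_f, lower.tail = FALSE))
}

# variables referenced by a term label ("a" -> a; "a:b" -> a, b)
term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# per-term summary of a fitted model: single-coefficient terms report the
# coefficient, its SE and t-test p-value; multi-coefficient (factor block
# or factor interaction) terms report the partial-F p with NA coefficient
term_table <- function(object) {
  lm_fit <- object$lm
  terms <- object$terms
  if (!length(terms)) {
    return(data.frame(term = character(0), coefficient = numeric(0),
                      se = numeric(0), p_value = numeric(0),
                      df = integer(0), stringsAsFactors = FALSE))
  }
  sm <- summary(lm_fit)$coefficients
  asgn <- attr(stats::model.matrix(lm_fit), "assign")
  labels <- attr(stats::terms(lm_fit), "term.labels")
  canon <- function(x) vapply(x, function(t)
    paste(sort(term_vars(t)), collapse = ":"), character(1))
  rows <- lapply(terms, function(tm) {
    k <- match(canon(tm), canon(labels))
    idx <- which(asgn == k)
    if (length(idx) == 1L) {
      data.frame(term = tm, coefficient = sm[idx, 1], se = sm[idx, 2],
                 p_value = sm[idx, 4], df = 1L, stringsAsFactors = FALSE)
    } else {
      reduced <- drop_term_fit(object, tm)
      ft <- partial_f_test(reduced, lm_fit)
      data.frame(term = tm, coefficient = NA_real_, se = NA_real_,
                 p_value = ft$p_value, df = ft$df1, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# refit with one term removed (interaction removal keeps its main effects)
drop_term_fit <- function(object, term) {
  fit_terms(object$response, setdiff(object$terms, term), object$data)
}

new_chain_fit <- function(response, terms, data, trace = NULL) {
  lm_fit <- fit_terms(response, terms, data)
  if (anyNA(stats::coef(lm_fit))) {
    aliased <- names(stats::coef(lm_fit))[is.na(stats::coef(lm_fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  out <- list(response = response, terms = terms, data = data,
              centers = attr(data, "centers") %||% numeric(0),
              lm = lm_fit, n = nrow(data), trace = trace)
  out$coef_table <- term_table(out)
  class(out) <- "chain_fit"
  out
}

#' @export
print.chain_fit <- function(x, ...) {
  cat(sprintf("chain_fit: %s ~ %s  (n = %d, R^2 = %.4f)\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$n, variance_explained(x)))
  if (nrow(x$coef_table)) print(x$coef_table, digits = 4)
  invisible(x)
}

#' Fit the full (saturated) regression for one response
#'
#' The first step of the sequences-of-regressions construction: ordinary
#' least squares of the response on every variable in the boxes strictly
#' to its right, with categorical variables dummy-coded against their
#' declared reference level. Analysis is complete-case over the response
#' and all eligible explanatory variables. Variables the ordering declares
#' for centring (intrinsic covariates with no natural zero, such as a
#' genetic score or age) are mean-centred; slopes are unchanged, and the
#' centring constants are stored in the fit.
#'
#' @param response Name of a variable in a non-rightmost box.
#' @param ordering A `chain_ordering`.
#' @param data The analysis data frame.
#' @return A `chain_fit` with per-term coefficients, standard errors (from
#'   the unbiased residual-variance estimate) and two-sided t-test
#'   p-values.
#' @export
fit_full_model <- function(response, ordering, data) {
  validate_ordering(ordering, data)
  vars <- rhs_variables(ordering, response)
  df <- prep_model_data(response, vars, data, ordering$categorical,
                        intersect(ordering$center %||% character(0), vars))
  # parameters: intercept + one per continuous + levels-1 per factor
  n_par <- 1L + sum(vapply(vars, function(v) {
    if (is.factor(df[[v]])) nlevels(df[[v]]) - 1L else 1L
  }, integer(1)))
  if (nrow(df) < n_par + 2L) {
    stop(sprintf("too few complete cases (%d) for %d parameters",
                 nrow(df), n_par), call. = FALSE)
  }
  new_chain_fit(response, vars, df)
}

#' Backward elimination by nested-model comparison
#'
#' Starting from a full fit, repeatedly removes the term whose removal is
#' least damaging: at each step every droppable term (one not participating
#' in a retained interaction) is tested by a partial F-test of the reduced
#' against the current model, and the term with the largest p-value above
#' `selection_alpha` is dropped. Categorical variables are dropped or kept
#' as whole dummy blocks. Ties on the p-value are broken by the smaller
#' absolute t-statistic, then lexicographically by term name, so the
#' search is deterministic. The selected model is refitted on the same
#' rows as the full model.
#'
#' @param fit A `chain_fit` from [fit_full_model()].
#' @param selection_alpha Retention threshold for the partial-F p-value;
#'   default 0.05.
#' @return A `chain_fit` for the selected model, with a `trace` listing
#'   each elimination step. An empty selected set yields the
#'   intercept-only fit.
#' @export
select_model <- function(fit, selection_alpha = 0.05) {
  stopifnot(inherits(fit, "chain_fit"))
  terms <- fit$terms
  trace <- list()
  repeat {
    in_interaction <- unique(unlist(lapply(
      terms[grepl(":", terms, fixed = TRUE)], term_vars)))
    droppable <- setdiff(terms, in_interaction)
    if (!length(droppable)) break
    current <- fit_terms(fit$response, terms, fit$data)
    cand <- lapply(droppable, function(tm) {
      reduced <- fit_terms(fit$response, setdiff(terms, tm), fit$data)
      ft <- partial_f_test(reduced, current)
      list(term = tm, p = ft$p_value, t_abs = sqrt(ft$statistic * ft$df1))
    })
    p <- vapply(cand, `[[`, numeric(1), "p")
    if (max(p) <= selection_alpha) break
    worst <- which(p >= max(p) - 1e-12)
    if (length(worst) > 1L) {
      t_abs <- vapply(cand[worst], `[[`, numeric(1), "t_abs")
      worst <- worst[t_abs <= min(t_abs) + 1e-12]
      if (length(worst) > 1L) {
        nm <- vapply(cand[worst], `[[`, character(1), "term")
        worst <- worst[order(nm)[1]]
      }
    }
    dropped <- cand[[worst[1]]]
    trace[[length(trace) + 1L]] <-
      data.frame(step = length(trace) + 1L, dropped = dropped$term,
                 p_value = dropped$p, stringsAsFactors = FALSE)
    terms <- setdiff(terms, dropped$term)
  }
  new_chain_fit(fit$response, terms, fit$data,
                trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Screen prespecified, clinically motivated interactions
#'
#' Each candidate pair of explanatory variables is tested by a nested
#' comparison: the current model augmented with both main effects is
#' compared against the same model plus the product term. A significant
#' product term (partial-F p below `selection_alpha`) is added with its
#' main effects forced in (hierarchy principle); candidates are processed
#' in the order given, each tested against the model as augmented so far.
#' Only prespecified pairs are screened — the search space is deliberately
#' not exhaustive, because an interaction must be interpretable to earn a
#' place in the graph.
#'
#' @param fit A selected `chain_fit`.
#' @param candidate_pairs List of length-2 character vectors of variable
#'   names, each drawn from the response's right-hand side.
#' @param selection_alpha Threshold for adding a product term; default
#'   0.05.
#' @return The augmented `chain_fit` (identical terms when nothing is
#'   significant).
#' @export
screen_interactions <- function(fit, candidate_pairs,
                                selection_alpha = 0.05) {
  stopifnot(inherits(fit, "chain_fit"))
  terms <- fit$terms
  for (pair in candidate_pairs) {
    if (length(pair) != 2L) {
      stop("each candidate must be a pair of variable names", call. = FALSE)
    }
    if (fit$response %in% pair) {
      stop("interaction candidate references the response: ",
           fit$response, call. = FALSE)
    }
    if (!all(pair %in% names(fit$data))) {
      stop("interaction candidate outside the model data: ",
           paste(pair, collapse = ":"), call. = FALSE)
    }
    pair <- sort(pair)
    prod_term <- paste(pair, collapse = ":")
    if (prod_term %in% terms) next
    base_terms <- union(terms, pair)
    base <- fit_terms(fit$response, base_terms, fit$data)
    aug <- fit_terms(fit$response, c(base_terms, prod_term), fit$data)
    ft <- partial_f_test(base, aug)
    if (ft$p_value < selection_alpha) {
      terms <- c(base_terms, prod_term)
    }
  }
  new_chain_fit(fit$response, terms, fit$data, trace = fit$trace)
}

#' Unadjusted variance explained by a fitted model
#'
#' @param fit A `chain_fit`.
#' @return R-squared, `1 - RSS/TSS`, of the selected model.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "chain_fit"))
  y <- stats::model.response(stats::model.frame(fit$lm))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero total variance: R^2 undefined", call. = FALSE)
  1 - sum(stats::residuals(fit$lm)^2) / tss
}
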