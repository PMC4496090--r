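#' Symmetric associations within the rightmost (intrinsic) box
#'
#' Variables sharing the rightmost box have no exposure ordering between
#' them, so associations are symmetric: each pair is tested marginally —
#' Pearson correlation t-test for two continuous variables, one-way F for
#' a continuous/categorical pair, chi-square for two categorical
#' variables — and significant pairs receive an undirected edge.
#'
#' @param vars Character vector of rightmost-box variable names (>= 2 for
#'   any edge to exist; fewer returns an empty set).
#' @param data The analysis data frame.
#' @param categorical Named character vector of reference levels
#'   identifying which variables are categorical.
#' @param edge_alpha Significance level for declaring an edge; default
#'   0.10.
#' @return Data frame with columns `a`, `b`, `test`, `statistic`,
#'   `p_value`, `significant`.
#' @export
symmetric_associations <- function(vars, data, categorical = NULL,
                                   edge_alpha = 0.10) {
  empty <- data.frame(a = character(0), b = character(0),
                      test = character(0), statistic = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (length(vars) < 2) return(empty)
  is_cat <- vars %in% names(categorical)
  names(is_cat) <- vars
  rows <- list()
  for (i in seq_len(length(vars) - 1)) {
    for (j in seq((i + 1), length(vars))) {
      a <- vars[i]; b <- vars[j]
      x <- data[[a]]; y <- data[[b]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (!is_cat[a] && !is_cat[b]) {
        ct <- stats::cor.test(x, y)
        test <- "pearson"; stat <- unname(ct$statistic); p <- ct$p.value
      } else if (xor(is_cat[a], is_cat[b])) {
        g <- factor(if (is_cat[a]) x else y)
        v <- if (is_cat[a]) y else x
        av <- stats::anova(stats::lm(v ~ g))
        test <- "oneway_f"; stat <- av$`F value`[1]; p <- av$`Pr(>F)`[1]
      } else {
        ct <- suppressWarnings(stats::chisq.test(factor(x), factor(y)))
        test <- "chisq"; stat <- unname(ct$statistic); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(a = a, b = b, test = test, statistic = stat,
                   p_value = p, significant = p < edge_alpha,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the chain graph from the selected regressions
#'
#' Reads the graph off the fitted sequence of regressions: every retained
#' term of every selected model whose p-value is below `edge_alpha`
#' becomes a directed edge into the response (main effects) or an
#' interaction edge (product terms, rendered distinctly), annotated with
#' the partial regression coefficient, its SE and p-value. Undirected
#' edges come from [symmetric_associations()]. The absence of an edge
#' between two variables encodes that they are conditionally independent
#' given the selected explanatory sets.
#'
#' @param fits List of selected `chain_fit` objects, one per modelled
#'   response.
#' @param ordering The `chain_ordering` the fits were built from.
#' @param undirected Optional data frame from [symmetric_associations()].
#' @param edge_alpha Display threshold on each edge's p-value; default
#'   0.10 — looser than the selection threshold so moderate associations
#'   remain visible.
#' @return A `chain_graph` object: `nodes`, `edges` (columns `source`,
#'   `target`, `type` in directed/undirected/interaction, `coefficient`,
#'   `se`, `p_value`), the fits, and the thresholds used.
#' @export
build_chain_graph <- function(fits, ordering, undirected = NULL,
                              edge_alpha = 0.10) {
  stopifnot(inherits(ordering, "chain_ordering"))
  nodes <- unlist(ordering$boxes)
  rows <- list()
  for (fit in fits) {
    stopifnot(inherits(fit, "chain_fit"))
    bad <- setdiff(unique(unlist(lapply(fit$terms, term_vars))), nodes)
    if (length(bad)) {
      stop("fit for '", fit$response,
           "' references variables outside the ordering: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tt <- fit$coef_table
    for (k in seq_len(nrow(tt))) {
      if (tt$p_value[k] >= edge_alpha) next
      rows[[length(rows) + 1L]] <- data.frame(
        source = tt$term[k], target = fit$response,
        type = if (grepl(":", tt$term[k], fixed = TRUE)) "interaction"
               else "directed",
        coefficient = tt$coefficient[k], se = tt$se[k],
        p_value = tt$p_value[k], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(undirected) && nrow(undirected)) {
    sig <- undirected[undirected$significant, , drop = FALSE]
    for (k in seq_len(nrow(sig))) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = sig$a[k], target = sig$b[k], type = "undirected",
        coefficient = NA_real_, se = NA_real_, p_value = sig$p_value[k],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               type = character(0), coefficient = numeric(0),
               se = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, fits = fits,
                 ordering = ordering, edge_alpha = edge_alpha),
            class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("chain_graph: %d nodes, %d edge(s) at alpha = %g\n",
              length(x$nodes), nrow(x$edges), x$edge_alpha))
  if (nrow(x$edges)) print(x$edges, digits = 4)
  invisible(x)
}

#' Path-based prediction of an outcome ratio
#'
#' Evaluates a selected model's linear predictor at a query point on the
#' log scale and exponentiates, giving the predicted final/baseline ratio
#' of the outcome and the corresponding percent change. Query values are
#' given on the raw scale; mean-centred intrinsic covariates are
#' translated through the fit's stored centring constants. Covariates not
#' named in the query sit at 0 for change scores ("no change"), at their
#' sample mean for centred intrinsic covariates, or at their reference
#' level (categorical), so a query can fix mean lifestyle changes and
#' sweep, say, a genetic score between its quartiles.
#'
#' @param fit A selected `chain_fit` whose response is a log-ratio
#'   outcome.
#' @param at Named list of covariate values (numbers for continuous
#'   variables, level names for categorical ones). Every name must be a
#'   variable in the fitted model.
#' @return List with `log_ratio` (the linear predictor), `ratio`
#'   (`exp(log_ratio)`) and `pct_change` (`100 * (ratio - 1)`). A
#'   continuous value outside the model's observed range triggers an
#'   extrapolation warning, not an error.
#' @export
predict_outcome_ratio <- function(fit, at = list()) {
  stopifnot(inherits(fit, "chain_fit"))
  model_vars <- setdiff(names(fit$data), fit$response)
  unknown <- setdiff(names(at), model_vars)
  if (length(unknown)) {
    stop("query covariate(s) not in the fitted model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  newdata <- fit$data[1, model_vars, drop = FALSE]
  for (v in model_vars) {
    col <- fit$data[[v]]
    if (is.factor(col)) {
      lev <- if (v %in% names(at)) as.character(at[[v]]) else levels(col)[1]
      if (!lev %in% levels(col)) {
        stop(sprintf("level '%s' unknown for variable '%s'", lev, v),
             call. = FALSE)
      }
      newdata[[v]] <- factor(lev, levels = levels(col))
    } else {
      ctr <- if (v %in% names(fit$centers)) fit$centers[[v]] else 0
      val <- if (v %in% names(at)) as.numeric(at[[v]]) - ctr else 0
      lo <- min(col, na.rm = TRUE); hi <- max(col, na.rm = TRUE)
      if (v %in% names(at) && (val < lo || val > hi)) {
        warning(sprintf("query value %g for '%s' lies outside the observed range [%g, %g]",
                        val + ctr, v, lo + ctr, hi + ctr), call. = FALSE)
      }
      newdata[[v]] <- val
    }
  }
  lp <- unname(stats::predict(fit$lm, newdata = newdata))
  list(log_ratio = lp, ratio = exp(lp), pct_change = 100 * (exp(lp) - 1))
}

# deterministic DOT identifier quoting
dot_q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

dot_label <- function(coefficient, se, p_value) {
  if (is.na(coefficient)) {
    sprintf("p=%s", fmt_num(p_value))
  } else {
    sprintf("%s (%s), p=%s", fmt_num(coefficient), fmt_num(se),
            fmt_num(p_value))
  }
}

#' Export a chain graph as a DOT document
#'
#' Deterministic Graphviz output: directed edges as arrows labelled
#' "coefficient (SE), p"; symmetric associations as undirected (`dir=none`)
#' solid lines; interaction terms as a distinct dashed diamond node
#' `"a:b"` with dashed feeds from its two sources and a dashed edge into
#' the target. Output is byte-identical across runs for identical input.
#'
#' @param graph A `chain_graph`.
#' @param path Optional file to write to.
#' @return The DOT document as a character scalar (invisibly when `path`
#'   is given).
#' @export
export_graph_dot <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "chain_graph"))
  e <- graph$edges
  lines <- c("digraph chain_graph {", "  rankdir=RL;",
             "  node [shape=box];")
  for (n in graph$nodes) lines <- c(lines, paste0("  ", dot_q(n), ";"))
  inter <- e[e$type == "interaction", , drop = FALSE]
  for (k in seq_len(nrow(inter))) {
    lines <- c(lines, sprintf("  %s [shape=diamond, style=dashed];",
                              dot_q(inter$source[k])))
  }
  for (k in seq_len(nrow(e))) {
    lab <- dot_label(e$coefficient[k], e$se[k], e$p_value[k])
    lines <- c(lines, switch(
      e$type[k],
      directed = sprintf("  %s -> %s [label=\"%s\"];",
                         dot_q(e$source[k]), dot_q(e$target[k]), lab),
      interaction = {
        src <- term_vars(e$source[k])
        c(sprintf("  %s -> %s [style=dashed, arrowhead=none];",
                  dot_q(src[1]), dot_q(e$source[k])),
          sprintf("  %s -> %s [style=dashed, arrowhead=none];",
                  dot_q(src[2]), dot_q(e$source[k])),
          sprintf("  %s -> %s [style=dashed, label=\"%s\"];",
                  dot_q(e$source[k]), dot_q(e$target[k]), lab))
      },
      undirected = sprintf("  %s -> %s [dir=none, label=\"%s\"];",
                           dot_q(e$source[k]), dot_q(e$target[k]), lab)))
  }
  lines <- c(lines, "}")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Parse the edge set back out of an exported DOT document
#'
#' A minimal reader for the documents produced by [export_graph_dot()],
#' used to verify round-tripping; not a general DOT parser.
#'
#' @param dot A DOT document string (or lines).
#' @return Data frame with `source`, `target`, `type`.
#' @export
parse_graph_dot <- function(dot) {
  lines <- unlist(strsplit(paste(dot, collapse = "\n"), "\n"))
  edge_re <- '^\\s*"([^"]+)"\\s*->\\s*"([^"]+)"\\s*\\[([^]]*)\\];\\s*$'
  hits <- grepl(edge_re, lines)
  src <- sub(edge_re, "\\1", lines[hits])
  tgt <- sub(edge_re, "\\2", lines[hits])
  attrs <- sub(edge_re, "\\3", lines[hits])
  type <- ifelse(grepl("dir=none", attrs), "undirected",
                 ifelse(grepl(":", src, fixed = TRUE) &
                          !grepl("arrowhead=none", attrs), "interaction",
                        "directed"))
  # the two dashed feeds into an interaction junction are rendering
  # detail, not edges of the statistical graph
  keep <- !grepl("arrowhead=none", attrs)
  data.frame(source = src[keep], target = tgt[keep], type = type[keep],
             stringsAsFactors = FALSE)
}

#' Export a chain graph's edge list as JSON
#'
#' @param graph A `chain_graph`.
#' @param path Optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @export
export_graph_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "chain_graph"))
  payload <- list(nodes = graph$nodes, edge_alpha = graph$edge_alpha,
                  edges = graph$edges)
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Fit a full chain-graph model in one call
#'
#' Runs the complete sequences-of-regressions construction: for every
#' modelled response, fit the full model on everything to its right,
#' backward-eliminate at `selection_alpha`, screen the prespecified
#' interaction candidates applicable to that response, then assemble the
#' graph together with the rightmost-box symmetric associations.
#'
#' @param data The analysis data frame.
#' @param ordering A `chain_ordering`; default [default_ordering()].
#' @param interactions List of length-2 character vectors — candidate
#'   interaction pairs; a pair is screened for every response that has
#'   both members on its right-hand side.
#' @param selection_alpha Nested-comparison threshold; default 0.05.
#' @param edge_alpha Edge-display threshold; default 0.10.
#' @return A `chain_graph`.
#' @export
fit_chain_graph <- function(data, ordering = default_ordering(),
                            interactions = list(),
                            selection_alpha = 0.05, edge_alpha = 0.10) {
  validate_ordering(ordering, data)
  fits <- list()
  for (response in ordering$modelled) {
    rhs <- rhs_variables(ordering, response)
    full <- fit_full_model(response, ordering, data)
    sel <- select_model(full, selection_alpha)
    cands <- Filter(function(p) all(p %in% rhs), interactions)
    if (length(cands)) {
      sel <- screen_interactions(sel, cands, selection_alpha)
    }
    fits[[response]] <- sel
  }
  intrinsic <- ordering$boxes[[length(ordering$boxes)]]
  undirected <- symmetric_associations(intrinsic, data,
                                       ordering$categorical, edge_alpha)
  build_chain_graph(fits, ordering, undirected, edge_alpha)
}
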