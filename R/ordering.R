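#' Define a variable ordering for a chain-graph model
#'
#' A chain graph orders variables into boxes by order of exposure: the
#' leftmost box holds the final responses, the rightmost box the intrinsic
#' characteristics (age, sex, genetic score, ...), and each variable is a
#' potential response to everything strictly to its right. Variables
#' sharing a box are treated as stacked — playing a similar role but not
#' modelled on each other.
#'
#' @param boxes A list of character vectors, leftmost box first.
#' @param categorical Named character vector mapping categorical variable
#'   names to their reference level (e.g. `c(sex = "female")`); all other
#'   variables are treated as continuous.
#' @param modelled Character vector of variables to fit a regression for.
#'   Defaults to every continuous variable outside the rightmost box;
#'   randomised treatment indicators are typically left unmodelled since
#'   their independence of intrinsic factors holds by design.
#' @param center Character vector of continuous variables to mean-centre
#'   before fitting — typically intrinsic covariates with no natural zero
#'   (a genetic score, age), so that main effects stay interpretable when
#'   product terms involving them are screened. Change scores should not
#'   be listed: their zero ("no change") is meaningful.
#' @return A `chain_ordering` object.
#' @export
#' @examples
#' ord <- chain_ordering(
#'   boxes = list(c("y1", "y2"), "m", "x"),
#'   categorical = NULL)
chain_ordering <- function(boxes, categorical = NULL, modelled = NULL,
                           center = NULL) {
  stopifnot(is.list(boxes), length(boxes) >= 2)
  boxes <- lapply(boxes, as.character)
  vars <- unlist(boxes)
  if (anyDuplicated(vars)) {
    stop("variable(s) appear in more than one box: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(categorical)) {
    unknown <- setdiff(names(categorical), vars)
    if (length(unknown)) {
      stop("categorical reference given for unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(modelled)) {
    non_rightmost <- unlist(boxes[-length(boxes)])
    modelled <- setdiff(non_rightmost, names(categorical))
  } else {
    modelled <- as.character(modelled)
    if (length(setdiff(modelled, unlist(boxes[-length(boxes)])))) {
      stop("modelled variables must lie outside the rightmost box",
           call. = FALSE)
    }
  }
  if (length(boxes[[length(boxes)]]) == 0L) {
    warning("rightmost (intrinsic) box is empty", call. = FALSE)
  }
  center <- as.character(center %||% character(0))
  bad_center <- setdiff(center, setdiff(vars, names(categorical)))
  if (length(bad_center)) {
    stop("center lists unknown or categorical variable(s): ",
         paste(bad_center, collapse = ", "), call. = FALSE)
  }
  structure(list(boxes = boxes, categorical = categorical,
                 modelled = modelled, center = center),
            class = "chain_ordering")
}

#' @export
print.chain_ordering <- function(x, ...) {
  cat("chain_ordering with", length(x$boxes), "boxes (responses first):\n")
  for (i in seq_along(x$boxes)) {
    cat(sprintf("  [%d] %s\n", i, paste(x$boxes[[i]], collapse = ", ")))
  }
  if (length(x$categorical)) {
    cat("  categorical (reference):",
        paste(sprintf("%s (%s)", names(x$categorical), x$categorical),
              collapse = ", "), "\n")
  }
  cat("  modelled:", paste(x$modelled, collapse = ", "), "\n")
  invisible(x)
}

#' Validate an ordering against a data table
#'
#' Confirms every ordering variable maps to a data column, declared
#' categorical variables contain their reference level, and continuous
#' variables are numeric.
#'
#' @param ordering A `chain_ordering`.
#' @param data The analysis data frame (or its column names).
#' @return `ordering`, invisibly usable, with factors checked.
#' @export
validate_ordering <- function(ordering, data) {
  stopifnot(inherits(ordering, "chain_ordering"))
  cols <- if (is.data.frame(data)) names(data) else as.character(data)
  vars <- unlist(ordering$boxes)
  absent <- setdiff(vars, cols)
  if (length(absent)) {
    stop("ordering variable(s) not found in data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(data)) {
    for (v in names(ordering$categorical)) {
      lv <- unique(as.character(stats::na.omit(data[[v]])))
      if (!ordering$categorical[[v]] %in% lv) {
        stop(sprintf("reference level '%s' absent from variable '%s'",
                     ordering$categorical[[v]], v), call. = FALSE)
      }
    }
    for (v in setdiff(vars, names(ordering$categorical))) {
      if (!is.numeric(data[[v]])) {
        stop("continuous ordering variable is not numeric: ", v,
             call. = FALSE)
      }
    }
  }
  ordering
}

#' Variables strictly to the right of a response's box
#'
#' @param ordering A `chain_ordering`.
#' @param response A variable name in a non-rightmost box.
#' @return Character vector of eligible explanatory variables.
#' @export
rhs_variables <- function(ordering, response) {
  stopifnot(inherits(ordering, "chain_ordering"))
  box <- which(vapply(ordering$boxes, function(b) response %in% b,
                      logical(1)))
  if (length(box) != 1L) {
    stop("response not found in ordering: ", response, call. = FALSE)
  }
  if (box == length(ordering$boxes)) {
    stop("rightmost-box variables cannot be responses: ", response,
         call. = FALSE)
  }
  unlist(ordering$boxes[(box + 1):length(ordering$boxes)])
}

#' The default trial ordering
#'
#' The variable ordering used throughout the package's worked examples:
#' log-ratio glycaemic outcomes (HOMA-IR, HOMA-B, glucose, HbA1c) as
#' stacked final responses, then weight change, then the stacked lifestyle
#' changes (dietary saturated fat as percent of energy, daily steps in
#' thousands), then treatment arm, and intrinsic characteristics (genetic
#' predisposition score, age, sex, country) in the rightmost box. The
#' genetic score and age are declared for mean-centring.
#'
#' @return A `chain_ordering`.
#' @export
default_ordering <- function() {
  chain_ordering(
    boxes = list(
      c("lr_homa_ir", "lr_homa_b", "lr_glucose", "lr_hba1c"),
      "d_weight",
      c("d_satfat_pct", "d_steps_k"),
      "arm",
      c("gps", "age", "sex", "country")
    ),
    categorical = c(arm = "SC", sex = "female", country = "UK"),
    center = c("gps", "age")
  )
}
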