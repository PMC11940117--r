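# Cohort statistics: decade grouping, group summaries, independent t-tests,
# standardized backward-elimination stepwise regression, trend-shape
# classification.

#' Assign an age to its decade group
#'
#' Bins by the integer part of age: 18-20, 21-30, ..., 71-80, 81-88. A
#' boundary age such as 21.0 belongs to the group whose printed range starts
#' at 21.
#'
#' @param age Numeric vector of ages in years, within [18, 89).
#' @return Character vector of group labels, ordered factor levels as in
#'   [age_group_bins()].
#' @export
#' @examples
#' assign_age_group(c(19.38, 20.99, 21.0, 88.92))
assign_age_group <- function(age) {
  if (any(age < 18 | age >= 89)) stop("age must be within [18, 89)")
  bins <- age_group_bins()
  ia <- floor(age)
  idx <- vapply(ia, function(a) which(a >= bins$lo & a <= bins$hi), integer(1L))
  factor(bins$group[idx], levels = bins$group)
}

#' Per-group mean, standard error and 95% confidence interval
#'
#' Normal-approximation summaries per group: mean, `SE = SD / sqrt(n)`, and
#' `mean +/- 1.96 SE`. Groups with fewer than two subjects get a missing SE
#' (with a warning).
#'
#' @param data A data frame.
#' @param value Column with the per-subject outcome (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A tibble: `group`, `n`, `mean`, `se`, `ci_lo`, `ci_hi`, ordered by
#'   group level.
#' @export
group_summary <- function(data, value, group) {
  out <- data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      se = stats::sd({{ value }}) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(group) |>
    dplyr::mutate(
      se = ifelse(n < 2L, NA_real_, se),
      ci_lo = mean - 1.96 * se,
      ci_hi = mean + 1.96 * se
    )
  if (any(out$n < 2L)) {
    warning("group(s) with n < 2: standard error reported as missing")
  }
  out
}

#' Independent two-sample t-test
#'
#' Pooled-variance two-sided t-test by default (Welch's correction by flag).
#' Degenerate inputs follow fixed conventions: zero variance in both groups
#' with equal means gives `p = 1`; with unequal means, `p = 0`.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param welch Use Welch's unequal-variance test.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
ttest_independent <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      t = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
      df = length(a) + length(b) - 2,
      p = if (equal) 1 else 0,
      mean_a = mean(a), mean_b = mean(b)
    ))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

#' Backward-elimination stepwise regression with standardized coefficients
#'
#' Z-scores the outcome and every predictor, drops linearly dependent
#' predictor columns by pivoted QR (tolerance `collinear_tol`), fits ordinary
#' least squares with an intercept, then repeatedly removes the single
#' predictor with the largest p-value above `alpha` and refits, until every
#' retained predictor is significant. Ties in p-value break by column order;
#' a non-finite p-value (e.g. under a numerically perfect fit) is treated as
#' least significant. The procedure is deterministic in its inputs; all
#' predictors may be eliminated, in which case an empty model is returned.
#'
#' @param data A data frame containing outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names; defaults to
#'   every other numeric column.
#' @param alpha Retention significance threshold.
#' @param collinear_tol Pivoted-QR tolerance for dropping dependent columns.
#' @return Object of class `tes_stepwise`: retained terms with standardized
#'   coefficients and p-values, `r_squared`, the eliminated-predictor
#'   `trace`, `dropped_collinear`, and the call parameters. Use
#'   [generics::tidy()] / [generics::glance()] for tabular views.
#' @export
stepwise_backward <- function(data, outcome, predictors = NULL, alpha = 0.05,
                              collinear_tol = 1e-10) {
  data <- as.data.frame(data)
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, logical(1L))]
    predictors <- setdiff(num, outcome)
  }
  if (!outcome %in% names(data)) stop("outcome column not found")
  miss <- setdiff(predictors, names(data))
  if (length(miss) > 0L) stop("missing predictor(s): ", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    stop("need n > number of predictors + 1")
  }

  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  y <- zscore(data[[outcome]])
  X <- vapply(predictors, function(p) zscore(data[[p]]), numeric(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, predictors))

  # constant columns carry no information: drop with the collinear set
  const <- predictors[apply(X, 2L, function(col) all(col == 0))]
  dropped <- const
  Xw <- X[, setdiff(predictors, const), drop = FALSE]
  if (ncol(Xw) > 0L) {
    qr_ <- qr(Xw, tol = collinear_tol)
    if (qr_$rank < ncol(Xw)) {
      keep <- sort(qr_$pivot[seq_len(qr_$rank)])
      dropped <- c(dropped, colnames(Xw)[-keep])
      Xw <- Xw[, keep, drop = FALSE]
    }
  }

  active <- colnames(Xw)
  trace <- tibble::tibble(
    step = integer(), removed = character(), p_at_removal = numeric(),
    r_squared = numeric()
  )
  step <- 0L
  repeat {
    if (length(active) == 0L) {
      fit <- NULL
      coefs <- tibble::tibble(
        term = character(), estimate = numeric(), p.value = numeric()
      )
      r2 <- 0
      break
    }
    df_fit <- data.frame(.y = y, Xw[, active, drop = FALSE], check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = df_fit)
    sm <- suppressWarnings(summary(fit))
    ct <- sm$coefficients
    rows <- match(active, rownames(ct))
    pvals <- ct[rows, "Pr(>|t|)"]
    est <- ct[rows, "Estimate"]
    r2 <- sm$r.squared
    pworst <- ifelse(is.finite(pvals), pvals, Inf)
    if (all(pworst <= alpha)) {
      coefs <- tibble::tibble(
        term = active, estimate = unname(est), p.value = unname(pvals)
      )
      break
    }
    worst <- which.max(pworst) # ties and non-finite break by column order
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, removed = active[worst],
      p_at_removal = unname(pvals[worst]), r_squared = r2
    ))
    active <- active[-worst]
  }

  structure(
    list(
      terms = coefs, r_squared = r2, trace = trace,
      dropped_collinear = dropped, alpha = alpha,
      n = n, outcome = outcome, predictors = predictors,
      collinear_tol = collinear_tol
    ),
    class = "tes_stepwise"
  )
}

#' @export
print.tes_stepwise <- function(x, ...) {
  cat(sprintf(
    "<tes_stepwise> outcome %s, n = %d, R^2 = %.3f\n", x$outcome, x$n,
    x$r_squared
  ))
  if (nrow(x$terms) == 0L) {
    cat("  (empty model: all predictors eliminated)\n")
  } else {
    print(x$terms)
  }
  if (length(x$dropped_collinear) > 0L) {
    cat("  dropped collinear:", paste(x$dropped_collinear, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stepwise fit
#'
#' @param x A [stepwise_backward()] result.
#' @param ... Unused.
#' @return Tibble with one row per original predictor: `term`, standardized
#'   `estimate`, `p.value`, and `status`
#'   (`"retained"`, `"eliminated"`, `"collinear"`).
#' @export
tidy.tes_stepwise <- function(x, ...) {
  tibble::tibble(term = x$predictors) |>
    dplyr::left_join(x$terms, by = "term") |>
    dplyr::mutate(status = dplyr::case_when(
      term %in% x$terms$term ~ "retained",
      term %in% x$dropped_collinear ~ "collinear",
      TRUE ~ "eliminated"
    ))
}

#' Glance at a stepwise fit
#'
#' @param x A [stepwise_backward()] result.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `n`, `n.retained`, `n.eliminated`,
#'   `n.collinear`, `alpha`.
#' @export
glance.tes_stepwise <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, n = x$n,
    n.retained = nrow(x$terms),
    n.eliminated = nrow(x$trace),
    n.collinear = length(x$dropped_collinear),
    alpha = x$alpha
  )
}

#' Classify the shape of an age trend
#'
#' Given group means ordered by age, returns `"U_SHAPED"` when the minimum
#' sits at an interior (including penultimate) position and both the first
#' and last means strictly exceed it (relative tolerance `1e-9`);
#' `"MONOTONE_DECREASING"` / `"MONOTONE_INCREASING"` for strict chains; and
#' `"OTHER"` otherwise.
#'
#' @param means Numeric vector of group means ordered by increasing age
#'   (`>= 4` groups).
#' @return A list: `shape` and `argmin` (index of the minimum).
#' @export
#' @examples
#' detect_trend_shape(c(5, 4, 3, 2, 3))
detect_trend_shape <- function(means) {
  k <- length(means)
  if (k < 4L) stop("need at least 4 group means")
  tol <- 1e-9 * max(abs(means), 1e-300)
  argmin <- which.min(means)
  d <- diff(means)
  shape <- if (all(d < -tol)) {
    "MONOTONE_DECREASING"
  } else if (all(d > tol)) {
    "MONOTONE_INCREASING"
  } else if (argmin > 1L && argmin < k &&
    means[1L] > means[argmin] + tol &&
    means[k] > means[argmin] + tol) {
    "U_SHAPED"
  } else {
    "OTHER"
  }
  list(shape = shape, argmin = argmin)
}
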