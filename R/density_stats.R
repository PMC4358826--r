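# Volume-density relationship: log-log Pearson correlations and power-law
# fits per dataset class.

#' Pearson correlation between log volume and log density
#'
#' Natural logs throughout; p from the exact t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 df, two-sided. For a perfect
#' log-linear relation (|r| = 1) the p-value underflows and is clamped to
#' the smallest positive double.
#'
#' @param table An `object_table` with at least 3 records.
#' @return A list of class `correlation_result`: `r`, `n`, `p`, `variables`.
#' @export
log_log_correlation <- function(table) {
  stopifnot(inherits(table, "object_table"))
  x <- log(table$volume_cm3)
  y <- log(table$density_g_cm3)
  correlation_result(x, y, variables = "ln V vs ln d")
}

# shared core, also used on arbitrary log pairs
correlation_result <- function(x, y, variables = "x vs y") {
  n <- length(x)
  if (n < 3) stop("need at least 3 records for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  structure(list(r = r, n = n, p = p, variables = variables),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, n = %d, p = %.4g\n", x$variables, x$r, x$n, x$p))
  invisible(x)
}

#' Fit a power law density = c * V^gamma
#'
#' Ordinary least squares of `ln d` on `ln V`; `gamma` is the slope, `c`
#' the exponentiated intercept (density at V = 1 cm^3), `residual_sd` the
#' root mean squared residual in log space (divisor n, so it is exactly 0
#' for a noiseless power-law population).
#'
#' @param table An `object_table` with at least 3 records.
#' @return A list of class `power_law_fit`: `c`, `gamma`, `residual_sd`, `n`.
#' @export
fit_power_law <- function(table) {
  stopifnot(inherits(table, "object_table"))
  x <- log(table$volume_cm3)
  y <- log(table$density_g_cm3)
  n <- length(x)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in log volume", call. = FALSE)
  fit <- .ols(x, y)
  res <- y - (fit$intercept + fit$slope * x)
  structure(list(c = exp(fit$intercept), gamma = fit$slope,
                 residual_sd = sqrt(mean(res^2)), n = n),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("d = %.4g * V^%.4f  (residual sd %.3f in log space, n = %d)\n",
              x$c, x$gamma, x$residual_sd, x$n))
  invisible(x)
}

# closed-form simple OLS
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

#' Per-class correlation report across several datasets
#'
#' One log-log correlation per supplied table, plus a pooled result over
#' the tables named in `pool` (default: all artificial + liftable tables).
#' Flags which classes reach p < alpha.
#'
#' @param tables Named list of `object_table`s.
#' @param pool Names of tables pooled into the extra `pooled` row; `NULL`
#'   pools every table whose records are all artificial and liftable.
#' @param alpha Significance level for the flag column (default 0.05).
#' @return A data.frame of class `dataset_contrast`: one row per table plus
#'   a `pooled` row, with columns `class, r, n, p, significant`.
#' @export
dataset_contrast <- function(tables, pool = NULL, alpha = 0.05) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  res <- lapply(tables, log_log_correlation)
  if (is.null(pool)) {
    pool <- names(tables)[vapply(tables, function(t)
      all(t$category == "artificial" & t$liftable), TRUE)]
  }
  rows <- data.frame(
    class = names(tables),
    r = vapply(res, `[[`, 0, "r"),
    n = vapply(res, `[[`, 0L, "n"),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
  if (length(pool) >= 1) {
    pooled <- pool_object_tables(tables[pool])
    pr <- log_log_correlation(pooled)
    rows <- rbind(rows, data.frame(class = "pooled", r = pr$r, n = pr$n,
                                   p = pr$p, stringsAsFactors = FALSE))
  }
  rows$significant <- rows$p < alpha
  rownames(rows) <- NULL
  structure(rows, class = c("dataset_contrast", "data.frame"),
            pooled_over = pool, alpha = alpha)
}
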