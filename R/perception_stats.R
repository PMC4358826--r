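# Ratio-report psychophysics analysis: Expected-Weight vs Perceived-Volume
# groups reporting pair ratios against a reference of 10 units.
#
# All analysis happens on canonical small/large natural-log ratios, so an
# expectation that the smaller object is relatively denser appears as an EW
# log ratio above the PV log ratio.

#' Normalize a raw ratio report to a canonical small/large log ratio
#'
#' The left object carries the reference value 10; the report concerns the
#' right object. With the small object on the left (order `"S-L"`) the
#' canonical small/large log ratio is `ln(10 / report)`; with the large
#' object on the left (`"L-S"`) it is `ln(report / 10)`. A report of 10
#' maps to 0 (indifference); saying "20" in S-L order and "5" in L-S order
#' both mean "the larger is twice the smaller" and map to ln(1/2).
#'
#' @param report Positive report in reference-10 units. Vectorized.
#' @param order `"S-L"` or `"L-S"` per trial.
#' @param reference Reference value assigned to the left object (default 10).
#' @return Canonical log small/large ratio.
#' @export
normalize_response <- function(report, order, reference = 10) {
  if (any(!is.finite(report)) || any(report <= 0)) {
    stop("reports must be positive", call. = FALSE)
  }
  order <- as.character(order)
  if (!all(order %in% c("S-L", "L-S"))) {
    stop('order must be "S-L" or "L-S"', call. = FALSE)
  }
  ifelse(order == "S-L", log(reference / report), log(report / reference))
}

.trial_cols <- c("subject", "group", "object_set", "pair", "order", "report")

.check_trials <- function(trials) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing)) {
    stop(sprintf("trial data missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!all(trials$group %in% c("EW", "PV"))) {
    stop('group must be "EW" or "PV"', call. = FALSE)
  }
  invisible(trials)
}

#' Collapse trials to per-subject pair means
#'
#' Normalizes every report and averages the canonical log ratios per
#' subject x object set x pair, pooling the two presentation orders.
#'
#' @param trials Data.frame with columns
#'   `subject, group, object_set, pair, order, report`.
#' @return Data.frame of class `subject_pair_summary` with columns
#'   `subject, group, object_set, pair, mean_log_ratio, n_trials`.
#' @export
subject_pair_means <- function(trials) {
  .check_trials(trials)
  trials$log_ratio <- normalize_response(trials$report, trials$order)
  agg <- stats::aggregate(log_ratio ~ subject + group + object_set + pair,
                          data = trials, FUN = mean)
  cnt <- stats::aggregate(log_ratio ~ subject + group + object_set + pair,
                          data = trials, FUN = length)
  agg$n_trials <- cnt$log_ratio
  names(agg)[names(agg) == "log_ratio"] <- "mean_log_ratio"
  agg <- agg[order(agg$group, agg$subject, agg$object_set, agg$pair), ]
  rownames(agg) <- NULL
  structure(agg, class = c("subject_pair_summary", "data.frame"))
}

#' Lilliefors normality test with a seeded Monte-Carlo null
#'
#' Kolmogorov-Smirnov-type statistic against a normal distribution whose
#' mean and (n-1 denominator) standard deviation are estimated from the
#' sample: `D = sup |empirical CDF - fitted normal CDF|`. Because the
#' parameters are estimated, the classic KS null is invalid; the p-value is
#' instead taken from `n_mc` resampled standard-normal datasets of the same
#' size (estimation is scale/location invariant, so the standard-normal
#' null is exact).
#'
#' @param sample Numeric vector, n >= 5.
#' @param n_mc Monte-Carlo replicates for the null (default 10000).
#' @param seed RNG seed for the null resampling.
#' @return A list of class `test_result`: `statistic` (D), `df` (`NA`),
#'   `p`, `label`.
#' @export
lilliefors_test <- function(sample, n_mc = 10000, seed = 1) {
  n <- length(sample)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(sample) == 0) stop("constant sample", call. = FALSE)
  D <- .lilliefors_D(sample)
  null <- with_seed(seed, replicate(n_mc, .lilliefors_D(stats::rnorm(n))))
  p <- (1 + sum(null >= D)) / (n_mc + 1)
  test_result(D, NA_real_, p, sprintf("Lilliefors D, n = %d", n))
}

.lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Phi <- stats::pnorm(z)
  max(seq_len(n) / n - Phi, Phi - (seq_len(n) - 1) / n)
}

#' One-sample t-test
#'
#' Classic t on n - 1 df, two-sided.
#'
#' @param sample Numeric vector, n >= 2, nonzero variance.
#' @param mu0 Null mean (default 0).
#' @return A `test_result` with `statistic` = t, `df` = n - 1, `p`.
#' @export
one_sample_t <- function(sample, mu0 = 0) {
  n <- length(sample)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(sample)
  if (s == 0) stop("zero variance", call. = FALSE)
  tval <- (mean(sample) - mu0) / (s / sqrt(n))
  test_result(tval, n - 1, 2 * stats::pt(-abs(tval), df = n - 1),
              sprintf("one-sample t vs %g", mu0))
}

#' Construct a scalar test result
#'
#' @param statistic Test statistic (t, D, d, ... as labeled).
#' @param df Degrees of freedom or `NA`.
#' @param p Two-sided p-value in (0, 1].
#' @param label Description of the test.
#' @return A list of class `test_result`.
#' @export
test_result <- function(statistic, df, p, label) {
  stopifnot(p > 0, p <= 1)
  structure(list(statistic = statistic, df = df, p = p, label = label),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$label,
              x$statistic, if (is.na(x$df)) "-" else format(x$df), x$p))
  invisible(x)
}

#' Volume-underestimation t-tests per object set
#'
#' For the Perceived-Volume group, tests whether per-subject mean log report
#' errors (mean log PV ratio minus true log volume ratio, averaged over the
#' six pairs) differ from 0 per object set.
#'
#' @param summaries A `subject_pair_summary`.
#' @param volumes Named list of stimulus volumes as [stimulus_volumes()].
#' @return Named list of `test_result`, one per object set.
#' @export
volume_underestimation_tests <- function(summaries, volumes = stimulus_volumes()) {
  pv <- summaries[summaries$group == "PV", ]
  if (nrow(pv) == 0) stop("no PV-group data", call. = FALSE)
  out <- list()
  for (set in unique(pv$object_set)) {
    st <- stimulus_pair_table(volumes[[set]])
    sub <- pv[pv$object_set == set, ]
    sub$err <- sub$mean_log_ratio - st$VR[match(sub$pair, st$pair)]
    per_subj <- tapply(sub$err, sub$subject, mean)
    out[[set]] <- one_sample_t(as.numeric(per_subj))
  }
  out
}

# ---- split-plot (mixed-design) ANOVA -------------------------------------

# Balanced split-plot decomposition: one between-subjects factor, one or two
# within-subjects factors, exactly one observation per subject x within-cell.
# Each fixed effect is tested against its own subject-interaction stratum.
.split_plot_anova <- function(data, dv, between, within, subject) {
  y <- data[[dv]]
  A <- factor(data[[between]])
  S <- factor(data[[subject]])
  W <- lapply(within, function(w) factor(data[[w]]))
  names(W) <- within
  a <- nlevels(A)
  subj_group <- tapply(as.character(A), S, unique)
  if (any(lengths(subj_group) != 1)) {
    stop("each subject must belong to exactly one group", call. = FALSE)
  }
  n_per <- table(unlist(subj_group))
  if (length(unique(n_per)) != 1) {
    stop("unbalanced design: unequal subjects per group", call. = FALSE)
  }
  n <- unique(n_per)
  cell_sizes <- table(S, interaction(W, drop = FALSE))
  if (any(cell_sizes != 1)) {
    stop("incomplete design: need exactly one value per subject x within-cell",
         call. = FALSE)
  }
  N <- a * n
  ws <- vapply(W, nlevels, 0L)
  m <- mean(y)
  dev2 <- function(f) {            # SS of centered means over factor combo f
    mm <- tapply(y, f, mean)
    list(means = mm)
  }
  eff <- function(...) {
    # marginal-mean table over the listed factors
    fs <- list(...)
    if (!length(fs)) return(m)
    tapply(y, fs, mean)
  }
  ss <- list(); df <- list()
  mA <- eff(A); mS <- eff(A, S)    # subject means nested in group
  b <- ws[1]; B <- W[[1]]
  mB <- eff(B); mAB <- eff(A, B); mSB <- eff(A, S, B)
  reps_per_wcell <- length(y) / (N * prod(ws))  # always 1 by the check above
  cmult <- if (length(W) == 2) ws[2] else 1
  ss$A <- n * b * cmult * sum((mA - m)^2)
  df$A <- a - 1
  subj_dev <- sweep(mS, 1, mA, `-`)             # m_ij - m_i, NA for foreign cells
  ss$`S(A)` <- b * cmult * sum(subj_dev^2, na.rm = TRUE)
  df$`S(A)` <- a * (n - 1)
  ss$B <- N * cmult * sum((mB - m)^2)
  df$B <- b - 1
  ab_dev <- mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + m
  ss$AB <- n * cmult * sum(ab_dev^2)
  df$AB <- (a - 1) * (b - 1)
  # B x subject(A): m_ijk - m_ij - m_ik + m_i
  sb_dev <- mSB
  for (ia in seq_len(a)) for (is in seq_len(dim(mSB)[2])) for (ib in seq_len(b)) {
    if (!is.na(mSB[ia, is, ib])) {
      sb_dev[ia, is, ib] <- mSB[ia, is, ib] - mS[ia, is] - mAB[ia, ib] + mA[ia]
    }
  }
  ss$`BxS(A)` <- cmult * sum(sb_dev^2, na.rm = TRUE)
  df$`BxS(A)` <- a * (n - 1) * (b - 1)
  if (length(W) == 2) {
    cc <- ws[2]; C <- W[[2]]
    mC <- eff(C); mAC <- eff(A, C); mSC <- eff(A, S, C)
    mBC <- eff(B, C); mABC <- eff(A, B, C)
    ss$C <- N * b * sum((mC - m)^2)
    df$C <- cc - 1
    ac_dev <- mAC - outer(mA, rep(1, cc)) - outer(rep(1, a), mC) + m
    ss$AC <- n * b * sum(ac_dev^2)
    df$AC <- (a - 1) * (cc - 1)
    sc_dev <- mSC
    for (ia in seq_len(a)) for (is in seq_len(dim(mSC)[2])) for (ic in seq_len(cc)) {
      if (!is.na(mSC[ia, is, ic])) {
        sc_dev[ia, is, ic] <- mSC[ia, is, ic] - mS[ia, is] - mAC[ia, ic] + mA[ia]
      }
    }
    ss$`CxS(A)` <- b * sum(sc_dev^2, na.rm = TRUE)
    df$`CxS(A)` <- a * (n - 1) * (cc - 1)
    bc_dev <- mBC - outer(mB, rep(1, cc)) - outer(rep(1, b), mC) + m
    ss$BC <- N * sum(bc_dev^2)
    df$BC <- (b - 1) * (cc - 1)
    abc_dev <- mABC
    for (ia in seq_len(a)) for (ib in seq_len(b)) for (ic in seq_len(cc)) {
      abc_dev[ia, ib, ic] <- mABC[ia, ib, ic] - mAB[ia, ib] - mAC[ia, ic] -
        mBC[ib, ic] + mA[ia] + mB[ib] + mC[ic] - m
    }
    ss$ABC <- n * sum(abc_dev^2)
    df$ABC <- (a - 1) * (b - 1) * (cc - 1)
    ss_total <- sum((y - m)^2)
    ss$`BxCxS(A)` <- ss_total - sum(unlist(ss))
    if (ss$`BxCxS(A)` < 0 && ss$`BxCxS(A)` > -1e-8) ss$`BxCxS(A)` <- 0
    df$`BxCxS(A)` <- a * (n - 1) * (b - 1) * (cc - 1)
    error_of <- c(A = "S(A)", B = "BxS(A)", AB = "BxS(A)",
                  C = "CxS(A)", AC = "CxS(A)",
                  BC = "BxCxS(A)", ABC = "BxCxS(A)")
  } else {
    error_of <- c(A = "S(A)", B = "BxS(A)", AB = "BxS(A)")
  }
  effects <- names(error_of)
  rows <- lapply(effects, function(e) {
    err <- error_of[[e]]
    ms_e <- ss[[e]] / df[[e]]
    ms_err <- ss[[err]] / df[[err]]
    Fv <- if (ms_err > 0) ms_e / ms_err else NaN
    data.frame(effect = e, ss = ss[[e]], df_num = df[[e]],
               df_den = df[[err]], F = Fv,
               p = if (is.nan(Fv)) NA_real_ else
                 stats::pf(Fv, df[[e]], df[[err]], lower.tail = FALSE),
               error_stratum = err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            strata_ss = ss, strata_df = df,
            factors = c(between = between, within = paste(within, collapse = ",")))
}

#' Mixed-design (split-plot) ANOVA on subject pair summaries
#'
#' The 2 (condition: EW vs PV, between subjects) x 3 (object set) x 6
#' (pair) design: between-subjects effect tested against subjects within
#' groups; each within-subject effect and its interaction with condition
#' tested against the corresponding subject-interaction stratum. Classical
#' uncorrected degrees of freedom (no sphericity correction). The design
#' must be complete and balanced; anything else is an error.
#'
#' @param summaries A `subject_pair_summary` (or any data.frame with the
#'   named columns).
#' @param dv,between,within,subject Column names; defaults match
#'   [subject_pair_means()] output.
#' @return An `anova_table` data.frame: one row per effect with
#'   `effect, ss, df_num, df_den, F, p, error_stratum`. Effect names use
#'   `A` = between factor, `B`/`C` = within factors in the order given.
#' @export
mixed_anova <- function(summaries, dv = "mean_log_ratio", between = "group",
                        within = c("object_set", "pair"), subject = "subject") {
  stopifnot(length(within) %in% 1:2)
  .split_plot_anova(as.data.frame(summaries), dv, between, within, subject)
}

#' Post-hoc per-pair mixed ANOVAs
#'
#' One 2 (condition) x 3 (object set) split-plot ANOVA per object pair.
#'
#' @param summaries A `subject_pair_summary`.
#' @return Named list of `anova_table`s, one per pair (in pair order).
#' @export
posthoc_pair_anovas <- function(summaries) {
  pairs <- sort(unique(as.character(summaries$pair)))
  out <- lapply(pairs, function(p) {
    mixed_anova(summaries[summaries$pair == p, , drop = FALSE],
                within = "object_set")
  })
  names(out) <- pairs
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with sorted p-values p_(1) <= ... <= p_(m), the
#' adjusted value is `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1
#' and mapped back to input order. Monotone and never below the raw p.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values in input order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  q_sorted <- cummin(m / seq(m, 1) * p_values[o])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Cohen's d between two groups
#'
#' Mean difference over the pooled standard deviation (n - 1 denominators
#' pooled over both groups).
#'
#' @param groupA,groupB Numeric vectors of per-subject means (n >= 2 each).
#' @return A `test_result` with `statistic` = d, `df`/`p` = `NA`-free:
#'   df is the pooled df; p is not defined for an effect size and set to 1.
#' @export
cohens_d <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  if (na < 2 || nb < 2) stop("need n >= 2 per group", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(groupA) - mean(groupB)) / sqrt(sp2)
  test_result(d, na + nb - 2, 1, "Cohen's d")
}

#' Condition-effect report per pair (post-hoc table layout)
#'
#' Assembles, per object pair: the post-hoc condition F and p, the
#' Benjamini-Hochberg q over the six tests, and Cohen's d for EW vs PV
#' per-subject means collapsed across object sets.
#'
#' @param summaries A `subject_pair_summary`.
#' @return Data.frame `pair, F_condition, df_num, df_den, p, q, cohens_d`.
#' @export
condition_effect_table <- function(summaries) {
  anovas <- posthoc_pair_anovas(summaries)
  rows <- lapply(names(anovas), function(pr) {
    at <- anovas[[pr]]
    cond <- at[at$effect == "A", ]
    sub <- summaries[summaries$pair == pr, ]
    subj_means <- stats::aggregate(mean_log_ratio ~ subject + group,
                                   data = sub, FUN = mean)
    dres <- cohens_d(subj_means$mean_log_ratio[subj_means$group == "EW"],
                     subj_means$mean_log_ratio[subj_means$group == "PV"])
    data.frame(pair = pr, F_condition = cond$F, df_num = cond$df_num,
               df_den = cond$df_den, p = cond$p, cohens_d = dres$statistic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_correct(out$p)
  out[, c("pair", "F_condition", "df_num", "df_den", "p", "q", "cohens_d")]
}

#' Perceptual ratio lines per object set
#'
#' For the Expected-Weight group: OLS of the across-subject mean log EW
#' ratio (one point per pair) on the true log volume ratio, per object set.
#' The matching density line follows from the weight-to-density transform:
#' slope minus 1, identical intercept.
#'
#' @param summaries A `subject_pair_summary` containing EW-group rows.
#' @param volumes Named list of stimulus volumes as [stimulus_volumes()].
#' @param group Which group's reports to fit (default `"EW"`).
#' @return Named list per object set, each with `weight` and `density`
#'   `ratio_line`s.
#' @export
fit_perceptual_lines <- function(summaries, volumes = stimulus_volumes(),
                                 group = "EW") {
  ew <- summaries[summaries$group == group, ]
  if (nrow(ew) == 0) stop(sprintf("no %s-group data", group), call. = FALSE)
  out <- list()
  for (set in unique(as.character(ew$object_set))) {
    st <- stimulus_pair_table(volumes[[set]])
    sub <- ew[ew$object_set == set, ]
    pair_means <- tapply(sub$mean_log_ratio, as.character(sub$pair), mean)
    missing <- setdiff(st$pair, names(pair_means))
    if (length(missing)) {
      stop(sprintf("missing pair(s) %s for set %s",
                   paste(missing, collapse = ", "), set), call. = FALSE)
    }
    x <- st$VR
    y <- as.numeric(pair_means[st$pair])
    fit <- .ols(x, y)
    out[[set]] <- list(
      weight = ratio_line(fit$slope, fit$intercept, "weight", n_pairs = length(x)),
      density = ratio_line(fit$slope - 1, fit$intercept, "density",
                           n_pairs = length(x)))
  }
  out
}

#' Read a trial CSV in the canonical schema
#'
#' Columns: `subject, group, object_set, pair, order, report`. This is the
#' schema a converter for deposited SPSS-format trial data should target.
#'
#' @param path CSV path.
#' @return Validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  .check_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}
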