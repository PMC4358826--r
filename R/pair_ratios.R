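# Full-factorial small/large pair ratios and the weight/density ratio lines.
#
# Conventions: every pair is oriented small/large, so the log volume ratio
# VR = ln(V_S/V_L) is strictly negative and "smaller is denser" shows up as
# a positive log density ratio. DR = WR - VR holds identically because
# d = w/V.

#' Build all small/large object pairs
#'
#' Full factorial combination of the table's objects, keeping the half with
#' V_small < V_large: n(n-1)/2 pairs minus pairs with exactly equal volumes,
#' which have no small/large orientation and are dropped (with a warning).
#'
#' @param table An `object_table` with at least 2 records.
#' @return A data.frame of class `pair_ratios` with columns
#'   `small_id, large_id, VR, WR, DR` (natural-log small/large ratios).
#' @export
build_pairs <- function(table) {
  stopifnot(inherits(table, "object_table"))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 objects to form pairs", call. = FALSE)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  Vi <- table$volume_cm3[i]; Vj <- table$volume_cm3[j]
  ties <- Vi == Vj
  if (any(ties)) {
    warning(sprintf("dropping %d equal-volume pair(s)", sum(ties)), call. = FALSE)
    i <- i[!ties]; j <- j[!ties]; Vi <- Vi[!ties]; Vj <- Vj[!ties]
  }
  swap <- Vi > Vj
  s <- ifelse(swap, j, i)
  l <- ifelse(swap, i, j)
  VR <- log(table$volume_cm3[s] / table$volume_cm3[l])
  WR <- log(table$weight_g[s] / table$weight_g[l])
  out <- data.frame(small_id = table$id[s], large_id = table$id[l],
                    VR = VR, WR = WR, DR = WR - VR,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pair_ratios", "data.frame"))
}

#' Construct a ratio line from known coefficients
#'
#' A line through log-ratio space: `log_ratio = slope * VR + intercept`,
#' e.g. the pooled environmental weight line (slope .613, intercept .114).
#'
#' @param slope,intercept Line coefficients (log-ratio units).
#' @param kind `"weight"` or `"density"`.
#' @param n_pairs Number of pairs behind the fit (`NA` for a printed line).
#' @return A list of class `ratio_line`.
#' @export
ratio_line <- function(slope, intercept, kind = c("weight", "density"),
                       n_pairs = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, kind = kind,
                 n_pairs = n_pairs), class = "ratio_line")
}

#' @export
print.ratio_line <- function(x, ...) {
  cat(sprintf("%sR = %.3fVR %s %.3f  (n_pairs = %s)\n",
              if (x$kind == "weight") "W" else "D", x$slope,
              if (x$intercept < 0) "-" else "+", abs(x$intercept),
              if (is.na(x$n_pairs)) "?" else format(x$n_pairs)))
  invisible(x)
}

#' Fit the weight- or density-ratio line over a pair set
#'
#' OLS of WR (or DR) on VR. Because DR = WR - VR exactly, the density line
#' always equals the weight line minus the identity: slope_density =
#' slope_weight - 1 with identical intercepts.
#'
#' @param pairs A `pair_ratios` data.frame.
#' @param kind `"weight"` or `"density"`.
#' @return A `ratio_line`.
#' @export
fit_ratio_line <- function(pairs, kind = c("weight", "density")) {
  kind <- match.arg(kind)
  stopifnot(inherits(pairs, "pair_ratios"))
  if (nrow(pairs) < 2) stop("need at least 2 pairs", call. = FALSE)
  x <- pairs$VR
  if (stats::var(x) == 0) stop("degenerate design: constant VR", call. = FALSE)
  y <- if (kind == "weight") pairs$WR else pairs$DR
  fit <- .ols(x, y)
  ratio_line(fit$slope, fit$intercept, kind, n_pairs = nrow(pairs))
}

#' Predict a small/large ratio from a ratio line
#'
#' Evaluates the line at `ln(volume_ratio)` and exponentiates back to ratio
#' space.
#'
#' @param line A `ratio_line`.
#' @param volume_ratio Small/large volume ratio in (0, 1]. Vectorized.
#' @return Predicted small/large weight (or density) ratio.
#' @export
predict_ratio <- function(line, volume_ratio) {
  stopifnot(inherits(line, "ratio_line"))
  if (any(!is.finite(volume_ratio)) || any(volume_ratio <= 0) ||
      any(volume_ratio > 1)) {
    stop("volume_ratio must lie in (0, 1]", call. = FALSE)
  }
  exp(line$slope * log(volume_ratio) + line$intercept)
}

#' Convert a weight ratio to a density ratio given the volume ratio
#'
#' From d = w/V: `d_S/d_L = (w_S/w_L) * (V_L/V_S) = weight_ratio / volume_ratio`.
#'
#' @param weight_ratio Small/large weight ratio (> 0). Vectorized.
#' @param volume_ratio Small/large volume ratio (> 0).
#' @return Small/large density ratio.
#' @export
density_ratio_from_weight <- function(weight_ratio, volume_ratio) {
  if (any(!is.finite(weight_ratio)) || any(weight_ratio <= 0) ||
      any(!is.finite(volume_ratio)) || any(volume_ratio <= 0)) {
    stop("ratios must be positive", call. = FALSE)
  }
  weight_ratio / volume_ratio
}

#' Pair volume ratios for a four-object stimulus set
#'
#' Takes the four strictly increasing stimulus volumes (objects A < B < C <
#' D) and returns the six small/large pair volume ratios in the fixed pair
#' order A:B, A:C, A:D, B:C, B:D, C:D. For the nominal 1 : 3.375 : 8 : 27
#' design these are 1/3.375, 1/8, 1/27, 3.375/8, 3.375/27 (= 1/8), 8/27.
#'
#' @param volumes Numeric vector of 4 strictly increasing volumes (cm^3).
#' @return A data.frame with columns `pair`, `volume_ratio`, `VR`.
#' @export
stimulus_pair_table <- function(volumes) {
  if (length(volumes) != 4 || any(diff(volumes) <= 0)) {
    stop("need 4 strictly increasing volumes", call. = FALSE)
  }
  names(volumes) <- c("A", "B", "C", "D")
  combos <- utils::combn(4, 2)
  pair <- paste0(names(volumes)[combos[1, ]], ":", names(volumes)[combos[2, ]])
  vr <- volumes[combos[1, ]] / volumes[combos[2, ]]
  data.frame(pair = pair, volume_ratio = as.numeric(vr), VR = log(as.numeric(vr)),
             stringsAsFactors = FALSE)
}

#' Printed stimulus volumes of the three experimental object sets
#'
#' Four volumes (cm^3) per set, small to large, nominally in the ratio
#' 1 : 3.375 : 8 : 27.
#'
#' @return Named list with elements `Blobs`, `Greebles`, `Cubes`.
#' @export
stimulus_volumes <- function() {
  list(
    Blobs    = c(111.63, 376.75, 893.03, 3013.98),
    Greebles = c(65.72, 221.80, 525.75, 1774.41),
    Cubes    = c(131.10, 442.45, 1048.77, 3539.61)
  )
}

#' Predicted environmental ratio table for a stimulus set
#'
#' The Table-2/Table-3 layout: for each of the six pairs, the weight line's
#' predicted small/large weight ratio and the density ratio implied by the
#' weight-to-density transform.
#'
#' @param weight_line A `ratio_line` of kind `"weight"`.
#' @param volumes Four strictly increasing stimulus volumes.
#' @return A data.frame `pair, volume_ratio, predicted_weight_ratio,
#'   predicted_density_ratio`.
#' @export
predicted_ratio_table <- function(weight_line, volumes) {
  stopifnot(inherits(weight_line, "ratio_line"), weight_line$kind == "weight")
  st <- stimulus_pair_table(volumes)
  wr <- predict_ratio(weight_line, st$volume_ratio)
  data.frame(pair = st$pair, volume_ratio = st$volume_ratio,
             predicted_weight_ratio = wr,
             predicted_density_ratio = density_ratio_from_weight(wr, st$volume_ratio),
             stringsAsFactors = FALSE)
}
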