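# Validation layer: tolerance-based strut matching, PPV/TPR, Bland-Altman
# agreement, thickness distribution comparison.

#' Match detected struts against a reference set
#'
#' Greedy nearest-first one-to-one matching under Euclidean distance:
#' repeatedly pair the globally closest unmatched detected/reference pair
#' while its distance is within `tol_um`. Matched pairs are true positives;
#' unmatched detections are false positives; unmatched references are false
#' negatives.
#'
#' @param detected,reference data.frames (or matrices) with `x_px`, `y_px`
#'   columns in a shared pixel coordinate frame.
#' @param tol_um matching tolerance in micrometres (default 150, roughly a
#'   strut-plus-bloom footprint).
#' @param calibration_mm_per_px calibration converting pixels to
#'   micrometres.
#' @return object of class `oct_match`: list with `tp`, `fp`, `fn`, `ppv`,
#'   `tpr` (`NA` when the denominator is 0) and `pairs`
#'   (detected index, reference index, distance in um).
#' @export
match_struts <- function(detected, reference, tol_um = 150,
                         calibration_mm_per_px = 0.01) {
  if (tol_um <= 0) stop("parameter error: tol_um must be positive")
  get_xy <- function(z) {
    if (is.null(z) || (is.data.frame(z) && !nrow(z)) ||
        (is.matrix(z) && !nrow(z)))
      return(matrix(numeric(0), 0, 2))
    if (is.data.frame(z)) cbind(z$x_px, z$y_px) else z[, 1:2, drop = FALSE]
  }
  d_xy <- get_xy(detected); r_xy <- get_xy(reference)
  nd <- nrow(d_xy); nr <- nrow(r_xy)
  pairs <- data.frame(detected = integer(0), reference = integer(0),
                      distance_um = numeric(0))
  if (nd && nr) {
    um <- calibration_mm_per_px * 1000
    dist <- outer(seq_len(nd), seq_len(nr), function(i, j)
      sqrt((d_xy[i, 1] - r_xy[j, 1])^2 + (d_xy[i, 2] - r_xy[j, 2])^2) * um)
    free_d <- rep(TRUE, nd); free_r <- rep(TRUE, nr)
    repeat {
      dd <- dist
      dd[!free_d, ] <- Inf; dd[, !free_r] <- Inf
      m <- which.min(dd)
      if (!length(m) || dd[m] > tol_um || !is.finite(dd[m])) break
      i <- (m - 1) %% nd + 1; j <- (m - 1) %/% nd + 1
      pairs <- rbind(pairs, data.frame(detected = i, reference = j,
                                       distance_um = dist[i, j]))
      free_d[i] <- FALSE; free_r[j] <- FALSE
      if (!any(free_d) || !any(free_r)) break
    }
  }
  tp <- nrow(pairs); fp <- nd - tp; fn <- nr - tp
  rates <- ppv_tpr(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 ppv = rates$ppv, tpr = rates$tpr, pairs = pairs),
            class = "oct_match")
}

#' @export
print.oct_match <- function(x, ...) {
  cat(sprintf("<oct_match> tp %d, fp %d, fn %d | PPV %s, TPR %s\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$ppv), "undefined", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$tpr), "undefined", sprintf("%.3f", x$tpr))))
  invisible(x)
}

#' Positive predictive value and true positive rate
#'
#' PPV = TP / (TP + FP), TPR = TP / (TP + FN). A zero denominator yields
#' `NA` (undefined), never a division error.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `ppv` and `tpr`.
#' @export
ppv_tpr <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("parameter error: counts must be >= 0")
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Bland-Altman agreement between two measurement series
#'
#' Differences are `a - b`; limits of agreement are
#' mean +/- 1.96 * sample SD (n-1 denominator). The Pearson correlation of
#' the raw series is included; it is `NA` when either series is constant.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2).
#' @return object of class `oct_agreement`: `mean_difference`, `loa_low`,
#'   `loa_high`, `sd_difference`, `pearson_r`, `n`, and the `differences`
#'   and `means` used for plotting.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("parameter error: series must have equal length")
  if (length(values_a) < 2L) stop("parameter error: need n >= 2")
  d <- values_a - values_b
  m <- mean(d); s <- sd(d)
  r <- if (sd(values_a) == 0 || sd(values_b) == 0) NA_real_
       else cor(values_a, values_b)
  structure(list(mean_difference = m, sd_difference = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 pearson_r = r, n = length(d), differences = d,
                 means = (values_a + values_b) / 2),
            class = "oct_agreement")
}

#' @export
print.oct_agreement <- function(x, ...) {
  cat(sprintf(
    "<oct_agreement> n %d | mean diff %+.3g, LoA [%+.3g, %+.3g], r %s\n",
    x$n, x$mean_difference, x$loa_low, x$loa_high,
    ifelse(is.na(x$pearson_r), "undefined", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x an `oct_agreement`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oct_agreement <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of methods",
       ylab = "difference (a - b)", ...)
  abline(h = x$mean_difference, lty = 1)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Compare two thickness distributions
#'
#' Median and quartiles per sample (linear-interpolation quantile
#' convention, R type 7) plus a two-sided Mann-Whitney-Wilcoxon p-value
#' (normal approximation with tie correction for larger samples, exact
#' otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param sample_a,sample_b non-empty numeric vectors (micrometres).
#' @return list with `summary_a`, `summary_b` (median, q1, q3, n) and
#'   `p_value`.
#' @export
thickness_distribution_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("parameter error: samples must be non-empty")
  qs <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
  }
  p <- suppressWarnings(
    wilcox.test(sample_a, sample_b, alternative = "two.sided")$p.value)
  list(summary_a = qs(sample_a), summary_b = qs(sample_b), p_value = p,
       test = "Mann-Whitney-Wilcoxon")
}
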