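# Predictive-potential criteria for one (observed, predicted) pairing.
# Conventions: `observed` is x / y, `predicted` is y-tilde in the usual
# external-validation notation; statistics that need the training set
# (Q2F1, Q2F3) take a `training_context`.

check_pair <- function(observed, predicted, min_n = 3L) {
  x <- as.numeric(observed); y <- as.numeric(predicted)
  if (length(x) != length(y)) stop("observed/predicted length mismatch")
  if (anyNA(x) || anyNA(y)) stop("missing values in observed/predicted")
  if (length(x) < min_n) stop("need at least ", min_n, " observations")
  list(x = x, y = y, n = length(x))
}

#' Pearson product-moment correlation
#'
#' @param observed,predicted numeric vectors of equal length (n >= 3).
#' @return correlation coefficient, or NA if either variance is zero.
#' @export
pearson_r <- function(observed, predicted) {
  p <- check_pair(observed, predicted)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) return(NA_real_)
  stats::cor(p$x, p$y)
}

#' Concordance correlation coefficient
#'
#' Lin's agreement measure: \deqn{CCC = 2\sum(x-\bar x)(y-\bar y) /
#' [\sum(x-\bar x)^2 + \sum(y-\bar y)^2 + n(\bar x-\bar y)^2]}
#' The location/scale penalty guarantees \code{|CCC| <= |r|}.
#'
#' @inheritParams pearson_r
#' @return the CCC, or NA when both variances are zero.
#' @export
ccc <- function(observed, predicted) {
  p <- check_pair(observed, predicted)
  sxy <- sum((p$x - mean(p$x)) * (p$y - mean(p$y)))
  den <- sum((p$x - mean(p$x))^2) + sum((p$y - mean(p$y))^2) +
    p$n * (mean(p$x) - mean(p$y))^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

#' Through-origin regression statistics (Golbraikh-Tropsha)
#'
#' Slopes of the least-squares fits through the origin in both directions
#' and the corresponding determination coefficients:
#' \code{k = sum(y * yt) / sum(yt^2)}, \code{k' = sum(y * yt) / sum(y^2)},
#' \code{r0^2 = 1 - sum((yt - k*yt)^2) / sum((yt - mean(yt))^2)} and the
#' primed analogue with roles swapped (\code{y} observed, \code{yt}
#' predicted).
#'
#' @inheritParams pearson_r
#' @return list with \code{k}, \code{k_primed}, \code{r0_sq},
#'   \code{r0_sq_primed} (NA where a denominator vanishes).
#' @export
through_origin <- function(observed, predicted) {
  p <- check_pair(observed, predicted)
  y <- p$x; yt <- p$y
  s_yyt <- sum(y * yt)
  k  <- if (sum(yt^2) > 0) s_yyt / sum(yt^2) else NA_real_
  kp <- if (sum(y^2) > 0)  s_yyt / sum(y^2)  else NA_real_
  den1 <- sum((yt - mean(yt))^2)
  den2 <- sum((y - mean(y))^2)
  r0 <- if (!is.na(k) && den1 > 0) 1 - sum((yt - k * yt)^2) / den1 else NA_real_
  r0p <- if (!is.na(kp) && den2 > 0) 1 - sum((y - kp * y)^2) / den2 else NA_real_
  list(k = k, k_primed = kp, r0_sq = r0, r0_sq_primed = r0p)
}

#' Training-set context for the Q2 family
#'
#' @param endpoints numeric vector of training-set endpoint values.
#' @return list with \code{mean}, \code{n} and the centred sum of squares
#'   \code{ss}, as needed by Q2F1 and Q2F3.
#' @export
training_context <- function(endpoints) {
  y <- as.numeric(endpoints)
  if (length(y) < 1L || anyNA(y)) stop("invalid training endpoints")
  list(mean = mean(y), n = length(y), ss = sum((y - mean(y))^2))
}

#' External predictivity: Q2 and the F1/F2/F3 variants
#'
#' All four share the prediction error sum \code{PRESS =
#' sum((predicted - observed)^2)} over the external set and differ in the
#' reference: \code{q2} and \code{q2_f2} scale by the external-set
#' variance about the external mean; \code{q2_f1} scales by deviations of
#' the external observations from the training mean; \code{q2_f3} divides
#' the per-molecule external error by the per-molecule training variance.
#'
#' @inheritParams pearson_r
#' @param context a [training_context()]; without it F1 and F3 are NA.
#' @return list with \code{q2}, \code{q2_f1}, \code{q2_f2}, \code{q2_f3}.
#' @export
q2_family <- function(observed, predicted, context = NULL) {
  p <- check_pair(observed, predicted)
  press <- sum((p$y - p$x)^2)
  ss_ext <- sum((p$x - mean(p$x))^2)
  q2 <- if (ss_ext > 0) 1 - press / ss_ext else NA_real_
  f1 <- f3 <- NA_real_
  if (!is.null(context)) {
    ss_tr_ext <- sum((p$x - context$mean)^2)
    f1 <- if (ss_tr_ext > 0) 1 - press / ss_tr_ext else NA_real_
    if (context$n >= 2L && context$ss > 0) {
      f3 <- 1 - (press / p$n) / (context$ss / context$n)
    }
  }
  list(q2 = q2, q2_f1 = f1, q2_f2 = q2, q2_f3 = f3)
}

#' Leave-one-out Q2 of the one-variable calibration
#'
#' Cheap exact LOO for the two-parameter linear model
#' \code{endpoint = C0 + C1 * DCW}, using the hat-matrix identity for the
#' deleted residuals.
#'
#' @param dcw_values descriptor values of the training molecules.
#' @param endpoints their endpoint values.
#' @return the LOO cross-validated Q2.
#' @export
q2_loo <- function(dcw_values, endpoints) {
  x <- as.numeric(dcw_values); y <- as.numeric(endpoints)
  if (length(x) != length(y) || length(x) < 4L) {
    stop("need at least 4 aligned points for LOO")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  h <- stats::hat(cbind(1, x))
  press <- sum((fit$residuals / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' rm2 metrics
#'
#' Directional \code{rm2 = r^2 * (1 - sqrt(|r^2 - r0^2|))} computed with
#' the through-origin determination coefficient in each regression
#' direction; reported as the average of the two directions and their
#' absolute difference.  \code{variant = "literal"} drops the square root
#' (the form some sources print).
#'
#' @inheritParams pearson_r
#' @param variant \code{"sqrt"} (default, the literature form) or
#'   \code{"literal"}.
#' @return list with \code{rm2}, \code{rm2_reverse}, \code{rm2_avg},
#'   \code{rm2_delta}.
#' @export
rm2_metrics <- function(observed, predicted, variant = c("sqrt", "literal")) {
  variant <- match.arg(variant)
  r <- pearson_r(observed, predicted)
  if (is.na(r)) {
    return(list(rm2 = NA_real_, rm2_reverse = NA_real_,
                rm2_avg = NA_real_, rm2_delta = NA_real_))
  }
  to <- through_origin(observed, predicted)
  r2 <- r^2
  gap <- function(r0sq) {
    if (is.na(r0sq)) return(NA_real_)
    d <- abs(r2 - r0sq)
    if (variant == "sqrt") sqrt(d) else d
  }
  rm2 <- r2 * (1 - gap(to$r0_sq))
  rm2_rev <- r2 * (1 - gap(to$r0_sq_primed))
  list(rm2 = rm2, rm2_reverse = rm2_rev,
       rm2_avg = mean(c(rm2, rm2_rev)),
       rm2_delta = abs(rm2 - rm2_rev))
}

#' Index of ideality of correlation
#'
#' Splits the residuals \code{observed - predicted} into negative and
#' non-negative classes, takes the mean absolute error of each, and
#' scales the correlation coefficient by the ratio of the smaller to the
#' larger.  If either class is empty the index is 0 by definition.
#'
#' @inheritParams pearson_r
#' @param r_calibration the correlation coefficient to scale (by
#'   convention that of the calibration set); defaults to the Pearson r
#'   of the pairing itself.
#' @return the IIC value.
#' @export
iic <- function(observed, predicted, r_calibration = NULL) {
  p <- check_pair(observed, predicted)
  if (is.null(r_calibration)) r_calibration <- pearson_r(observed, predicted)
  delta <- p$x - p$y
  neg <- delta < 0
  pos <- delta >= 0
  if (!any(neg) || !any(pos)) return(0)
  mae_neg <- mean(abs(delta[neg]))
  mae_pos <- mean(abs(delta[pos]))
  hi <- max(mae_neg, mae_pos)
  ratio <- if (hi == 0) 1 else min(mae_neg, mae_pos) / hi
  r_calibration * ratio
}

#' Full predictive-potential criteria report
#'
#' Assembles every criterion — Pearson r and r^2, CCC, through-origin
#' slopes and determination coefficients, the Q2 family, rm2 metrics and
#' IIC — plus the Golbraikh-Tropsha acceptability flags for one
#' (observed, predicted) pairing.  Individually undefined statistics are
#' reported as NA rather than aborting the report.
#'
#' @inheritParams q2_family
#' @param r_calibration passed to [iic()].
#' @param rm2_variant passed to [rm2_metrics()].
#' @param gt_thresholds Golbraikh-Tropsha thresholds, overridable:
#'   \code{list(k_lo = 0.85, k_hi = 1.15, r2_min = 0.6, q2_min = 0.5,
#'   r0_gap_max = 0.1)}.
#' @return object of class \code{"criteria_report"}.
#' @examples
#' criteria_report(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
#' @export
criteria_report <- function(observed, predicted, context = NULL,
                            r_calibration = NULL,
                            rm2_variant = c("sqrt", "literal"),
                            gt_thresholds = list()) {
  rm2_variant <- match.arg(rm2_variant)
  p <- check_pair(observed, predicted)
  gt <- utils::modifyList(list(k_lo = 0.85, k_hi = 1.15, r2_min = 0.6,
                               q2_min = 0.5, r0_gap_max = 0.1),
                          gt_thresholds)
  r <- pearson_r(observed, predicted)
  to <- through_origin(observed, predicted)
  q2 <- q2_family(observed, predicted, context)
  rm2 <- rm2_metrics(observed, predicted, variant = rm2_variant)
  vals <- list(
    n = p$n, r = r, r_squared = if (is.na(r)) NA_real_ else r^2,
    ccc = ccc(observed, predicted),
    k = to$k, k_primed = to$k_primed,
    r0_sq = to$r0_sq, r0_sq_primed = to$r0_sq_primed,
    q2 = q2$q2, q2_f1 = q2$q2_f1, q2_f2 = q2$q2_f2, q2_f3 = q2$q2_f3,
    rm2 = rm2$rm2, rm2_reverse = rm2$rm2_reverse,
    rm2_avg = rm2$rm2_avg, rm2_delta = rm2$rm2_delta,
    iic = iic(observed, predicted, r_calibration),
    rmse = sqrt(mean((p$x - p$y)^2)),
    mae = mean(abs(p$x - p$y))
  )
  r2 <- vals$r_squared
  flag <- function(x) !is.na(x) && x
  flags <- list(
    gt_r2 = flag(r2 > gt$r2_min),
    gt_q2 = flag(vals$q2 > gt$q2_min),
    gt_slope = flag((to$k >= gt$k_lo && to$k <= gt$k_hi) ||
                      (to$k_primed >= gt$k_lo && to$k_primed <= gt$k_hi)),
    gt_r0_gap = flag(!is.na(r2) && r2 > 0 &&
                       ((!is.na(to$r0_sq) &&
                           (r2 - to$r0_sq) / r2 < gt$r0_gap_max) ||
                          (!is.na(to$r0_sq_primed) &&
                             (r2 - to$r0_sq_primed) / r2 < gt$r0_gap_max)))
  )
  flags$gt_pass <- all(unlist(flags))
  structure(c(vals, list(flags = flags, rm2_variant = rm2_variant)),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, digits = 4L, ...) {
  nums <- x[!(names(x) %in% c("flags", "rm2_variant", "n"))]
  cat("Predictive-potential criteria (n = ", x$n, ")\n", sep = "")
  for (nm in names(nums)) {
    v <- nums[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is.na(v)) "NA" else formatC(v, digits = digits,
                                                format = "g")))
  }
  f <- x$flags
  cat("  Golbraikh-Tropsha:",
      if (f$gt_pass) "pass" else "fail",
      sprintf("(r2 %s, q2 %s, slope %s, r0 gap %s)\n",
              ifelse(f$gt_r2, "ok", "low"), ifelse(f$gt_q2, "ok", "low"),
              ifelse(f$gt_slope, "ok", "off"),
              ifelse(f$gt_r0_gap, "ok", "wide")))
  invisible(x)
}

#' @export
as.data.frame.criteria_report <- function(x, ...) {
  nums <- x[!(names(x) %in% c("flags", "rm2_variant"))]
  data.frame(criterion = names(nums), value = as.numeric(unlist(nums)),
             stringsAsFactors = FALSE)
}
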