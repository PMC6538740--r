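#' Tumour volume from caliper diameters
#'
#' The standard ellipsoid approximation `volume = length * width^2 * 0.5`,
#' in mm^3. By caliper convention the length is the larger diameter; pairs
#' with width > length are swapped with a warning.
#'
#' @param length,width caliper diameters in mm (vectorised).
#' @return Volumes in mm^3.
#' @examples
#' tumour_volume(10, 10)  # 500
#' @export
tumour_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sum(swap), " measurement(s) with width > length swapped")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 * 0.5
}

#' Tumour growth inhibition (TGI)
#'
#' `TGI (%) = [1 - treated/control] * 100` on mean tumour volumes. Negative
#' values (treated arm larger than control) are legitimate. The ratio is
#' unit-free, so both volumes may be in mm^3 or cm^3 as long as they agree.
#'
#' @param v_treated treated-arm mean volume (vectorised over arms).
#' @param v_control control-arm mean volume (> 0).
#' @return TGI in percent.
#' @examples
#' tgi(6.216, 8.496)  # 26.836...
#' @export
tgi <- function(v_treated, v_control) {
  if (length(v_control) != 1L || !is.finite(v_control) || v_control <= 0)
    stop("control volume must be a single positive number")
  if (any(!is.finite(v_treated)) || any(v_treated < 0))
    stop("treated volumes must be nonnegative")
  (1 - v_treated / v_control) * 100
}

measurement_volumes <- function(measurements, day = NULL) {
  req <- c("mouse_id", "arm", "day", "length_mm", "width_mm")
  if (!is.data.frame(measurements) || nrow(measurements) == 0L)
    stop("measurement table has no rows")
  if (!all(req %in% names(measurements)))
    stop("measurement table needs columns: ", paste(req, collapse = ", "))
  if (!is.null(day)) {
    measurements <- measurements[measurements$day == day, , drop = FALSE]
    if (!nrow(measurements)) stop("no measurements on day ", day)
  }
  measurements$volume_mm3 <- tumour_volume(measurements$length_mm,
                                           measurements$width_mm)
  measurements
}

#' Per-arm volume summaries
#'
#' @param measurements data frame `mouse_id, arm, day, length_mm, width_mm`.
#' @param day optional single day to restrict to.
#' @param units `"mm3"` (default) or `"cm3"` for display on the cm^3 scale.
#' @return Data frame `arm, day, mean_volume, sd_volume, n` (n = mice).
#' @export
arm_summary <- function(measurements, day = NULL, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  m <- measurement_volumes(measurements, day)
  # one volume per mouse x day (mean over any replicate calipers)
  per_mouse <- aggregate(volume_mm3 ~ arm + day + mouse_id, data = m, FUN = mean)
  agg <- aggregate(volume_mm3 ~ arm + day, data = per_mouse,
                   FUN = function(v) c(mean(v), stats::sd(v), length(v)))
  out <- data.frame(arm = agg$arm, day = agg$day,
                    mean_volume = agg$volume_mm3[, 1],
                    sd_volume = agg$volume_mm3[, 2],
                    n = as.integer(agg$volume_mm3[, 3]),
                    stringsAsFactors = FALSE)
  if (units == "cm3") {
    out$mean_volume <- out$mean_volume / 1000
    out$sd_volume <- out$sd_volume / 1000
  }
  out[order(out$day, out$arm), , drop = FALSE]
}

#' TGI per arm against a control arm
#'
#' Default convention is the ratio of arm mean volumes (`ratio_of_means`).
#' `mean_of_ratios` instead averages `1 - Vt_i/Vc_j` over all treated x
#' control mouse pairs, i.e. uses the mean of the inverse control volumes;
#' the two conventions differ when control volumes vary.
#'
#' @param measurements caliper table (see [arm_summary()]).
#' @param day day at which to compute TGI.
#' @param control name of the control arm.
#' @param convention `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return Data frame `arm, day, mean_volume, n, tgi_percent` (control row
#'   excluded).
#' @export
tgi_table <- function(measurements, day, control = "control",
                      convention = c("ratio_of_means", "mean_of_ratios")) {
  convention <- match.arg(convention)
  m <- measurement_volumes(measurements, day)
  per_mouse <- aggregate(volume_mm3 ~ arm + mouse_id, data = m, FUN = mean)
  if (!(control %in% per_mouse$arm))
    stop("control arm '", control, "' absent on day ", day)
  vc <- per_mouse$volume_mm3[per_mouse$arm == control]
  arms <- setdiff(unique(per_mouse$arm), control)
  rows <- lapply(arms, function(a) {
    vt <- per_mouse$volume_mm3[per_mouse$arm == a]
    val <- if (convention == "ratio_of_means") {
      tgi(mean(vt), mean(vc))
    } else {
      mean(outer(vt, vc, function(t, c) (1 - t / c) * 100))
    }
    data.frame(arm = a, day = day, mean_volume = mean(vt),
               n = length(vt), tgi_percent = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$arm), , drop = FALSE]
}

#' Between-arm statistics on tumour volumes
#'
#' `t_test`: pairwise two-sided unpaired t-tests on per-mouse volumes at
#' the stated day (equal-variance Student by default; Welch via
#' `var_equal = FALSE`). `anova_bh`: one-way ANOVA F-test across all arms
#' followed by the pairwise t-tests with Benjamini-Hochberg adjusted
#' q-values. Significance is flagged at p (or q) < 0.05.
#'
#' @param measurements caliper table (see [arm_summary()]).
#' @param day day of comparison.
#' @param method `"t_test"` or `"anova_bh"`.
#' @param var_equal logical; pooled-variance t-test (default) or Welch.
#' @return For `t_test`, a data frame `arm_a, arm_b, statistic, p,
#'   significant`; for `anova_bh` a list with `anova` (`F`, `df1`, `df2`,
#'   `p`) and `pairwise` (the pairwise table with a `q` column).
#' @export
compare_arms <- function(measurements, day, method = c("t_test", "anova_bh"),
                         var_equal = TRUE) {
  method <- match.arg(method)
  m <- measurement_volumes(measurements, day)
  per_mouse <- aggregate(volume_mm3 ~ arm + mouse_id, data = m, FUN = mean)
  sizes <- table(per_mouse$arm)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("arm(s) with fewer than 2 mice on day ", day, ": ",
         paste(small, collapse = ", "))

  arms <- sort(unique(per_mouse$arm))
  pairs <- utils::combn(arms, 2L)
  pw <- apply(pairs, 2L, function(pr) {
    x <- per_mouse$volume_mm3[per_mouse$arm == pr[1]]
    y <- per_mouse$volume_mm3[per_mouse$arm == pr[2]]
    tt <- stats::t.test(x, y, var.equal = var_equal)
    c(statistic = unname(tt$statistic), p = tt$p.value)
  })
  pairwise <- data.frame(arm_a = pairs[1, ], arm_b = pairs[2, ],
                         statistic = pw["statistic", ], p = pw["p", ],
                         stringsAsFactors = FALSE)

  if (method == "t_test") {
    pairwise$significant <- pairwise$p < 0.05
    rownames(pairwise) <- NULL
    return(pairwise)
  }
  fit <- stats::aov(volume_mm3 ~ arm, data = per_mouse)
  an <- summary(fit)[[1]]
  pairwise$q <- bh_adjust(pairwise$p)
  pairwise$significant <- pairwise$q < 0.05
  rownames(pairwise) <- NULL
  list(anova = list(F = an[["F value"]][1], df1 = an[["Df"]][1],
                    df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1]),
       pairwise = pairwise)
}

#' Read a caliper measurement CSV
#'
#' Expects columns `mouse_id,arm,day,length_mm,width_mm`.
#'
#' @param path file path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mouse_id", "arm", "day", "length_mm", "width_mm")
  if (!all(req %in% names(x)))
    stop("measurement file ", path, " needs columns: ",
         paste(req, collapse = ", "))
  if (nrow(x) == 0L) stop("measurement file ", path, " has no rows")
  x
}
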