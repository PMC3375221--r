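# Centered moving average; returns NA at the edges where the window does
# not fit.
movingAverage <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

#' Time of maximum growth rate
#'
#' Smooths log(OD) with a centered moving average, takes central-difference
#' derivatives, smooths the derivative with the same window (plate-reader OD
#' noise is strongly amplified by differentiation, so both stages are
#' smoothed), and locates the maximum; ties are broken to the earliest time.
#' A curve whose smoothed log(OD) never rises by at least one doubling
#' (log 2) is flagged as a non-grower and returns `NA` with attribute
#' `reason = "non_grower"` (strains can grow in water but not in sulfite).
#'
#' @param times hours, strictly increasing
#' @param od optical density readings, all positive
#' @param smooth_window moving-average window in points; odd, >= 3
#' @return time (hours) of maximum smoothed d log(OD)/dt, or flagged `NA`
#' @export
maxGrowthRateTime <- function(times, od, smooth_window = 5) {
  if (length(times) != length(od)) stop("times and od must match in length")
  if (length(times) < 10) stop("need at least 10 points")
  if (any(diff(times) <= 0)) stop("time vector must be strictly increasing")
  if (any(od <= 0)) stop("OD must be positive where the log is taken")
  if (smooth_window < 3 || smooth_window %% 2 != 1)
    stop("smooth_window must be odd and >= 3")
  sm <- movingAverage(log(od), smooth_window)
  ok <- !is.na(sm)
  if (max(sm[ok]) - min(sm[ok]) < log(2)) {
    out <- NA_real_
    attr(out, "reason") <- "non_grower"
    return(out)
  }
  n <- length(sm)
  i <- 2:(n - 1)
  rate <- (sm[i + 1] - sm[i - 1]) / (times[i + 1] - times[i - 1])
  rate <- movingAverage(rate, smooth_window)
  times[i][which.max(rate)]                # which.max takes the earliest tie
}

#' Sulfite-dependent growth delay
#'
#' The resistance phenotype: the difference in time-of-maximum-growth-rate
#' between a sulfite-treated culture and its water-treated control from the
#' same strain and day.  May be negative.  If either curve is a non-grower
#' the delay is a missing value with a reason code (`"control_failed"` or
#' `"sulfite_failed"`).
#'
#' @param sulfite,control lists or data.frames with elements/columns
#'   `times` (or `time_h`) and `od`
#' @param construct,day,batch annotation labels carried into the output
#' @param smooth_window passed to [maxGrowthRateTime()]
#' @return one-row data.frame: construct, day, batch, delay_hours, reason
#' @export
sulfiteDelay <- function(sulfite, control, construct = "construct",
                         day = "day1", batch = "batch1", smooth_window = 5) {
  getcol <- function(x, nm, alt) x[[nm]] %||% x[[alt]]
  ts <- getcol(sulfite, "times", "time_h")
  os <- sulfite$od
  tc <- getcol(control, "times", "time_h")
  oc <- control$od
  mc <- maxGrowthRateTime(tc, oc, smooth_window)
  ms <- maxGrowthRateTime(ts, os, smooth_window)
  reason <- ""
  delay <- NA_real_
  if (is.na(mc)) reason <- "control_failed"
  else if (is.na(ms)) reason <- "sulfite_failed"
  else delay <- ms - mc
  data.frame(construct = construct, day = day, batch = batch,
             delay_hours = delay, reason = reason,
             stringsAsFactors = FALSE)
}

#' Growth delays from a long-format plate-reader table
#'
#' Computes one delay per (strain, day, batch) from paired sulfite/control
#' curves in a long table with columns `strain`, `treatment`
#' ("sulfite"/"control"), `day`, `batch`, `time_h`, `od`.
#'
#' @param tab long-format data.frame
#' @param smooth_window passed to [maxGrowthRateTime()]
#' @return data.frame of [sulfiteDelay()] rows
#' @export
delayTable <- function(tab, smooth_window = 5) {
  need <- c("strain", "treatment", "day", "batch", "time_h", "od")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  keys <- unique(tab[, c("strain", "day", "batch")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(tab, keys[i, , drop = FALSE])
    s <- sub[sub$treatment == "sulfite", ]
    w <- sub[sub$treatment == "control", ]
    s <- s[order(s$time_h), ]
    w <- w[order(w$time_h), ]
    sulfiteDelay(list(times = s$time_h, od = s$od),
                 list(times = w$time_h, od = w$od),
                 construct = keys$strain[i], day = keys$day[i],
                 batch = keys$batch[i], smooth_window = smooth_window)
  })
  do.call(rbind, out)
}

#' Z-score standardization within day
#'
#' Centers and scales values day by day (sample standard deviation, n-1),
#' so measurements from different days are comparable.  Idempotent within
#' numerical tolerance.
#'
#' @param values numeric vector
#' @param day grouping labels, same length
#' @return standardized vector (per-day mean 0, sd 1)
#' @export
zscoreByDay <- function(values, day) {
  if (length(values) != length(day)) stop("values and day must match")
  out <- numeric(length(values))
  for (d in unique(day)) {
    i <- day == d
    if (sum(i) < 2) stop("day '", d, "' has fewer than 2 values")
    s <- stats::sd(values[i])
    if (s == 0) stop("day '", d, "' has zero variance")
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric comparison of two or more groups of delay phenotypes, with
#' tie correction and a chi-square(k-1) reference distribution.
#'
#' @param groups list of two or more numeric vectors
#' @return list with `statistic` (H), `df`, `p_value`
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  v <- unlist(groups)
  if (length(v) < 2) stop("need at least 2 observations")
  if (length(unique(v)) == 1)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(v, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Exact rank-sum p-values for small samples (both groups <= 10, no ties),
#' normal approximation with continuity and tie correction otherwise;
#' adjusted p = min(1, m * p_raw).
#'
#' @param pairs list of two-element lists/vectors `(groupA, groupB)`
#' @param m number of comparisons in the family (>= number of pairs)
#' @return data.frame with `W`, `p_raw`, `p_adjusted` per pair
#' @export
wilcoxonBonferroni <- function(pairs, m = length(pairs)) {
  if (m < length(pairs)) stop("m must be >= the number of pairs tested")
  rows <- lapply(pairs, function(pr) {
    a <- pr[[1]]
    b <- pr[[2]]
    if (!length(a) || !length(b)) stop("empty group in a pair")
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(W = unname(wt$statistic), p_raw = wt$p.value,
               p_adjusted = min(1, m * wt$p.value))
  })
  do.call(rbind, rows)
}
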