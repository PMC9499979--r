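#' Assemble hourly beaked whale detections under noise conditions
#'
#' Builds one record per UTC hour of recording coverage: the cumulative
#' number of minutes with beaked whale acoustic presence (`bw_minutes`,
#' 0-60), presence flags for the three anthropogenic signal classes, and
#' the resulting noise condition. Conditions enumerate the presence/
#' absence combinations: 1 = all absent; 2 = vessel noise; 3 =
#' echosounders; 4 = vessel + echosounders; 5 = UA devices; 6 = UA +
#' vessel; 7 = UA + echosounders; 8 = all present.
#'
#' An hour is flagged for a class if any encounter of that class overlaps
#' it (any-overlap semantics); a minute counts as beaked-whale-positive
#' if any encounter touches its UTC-aligned half-open minute bin.
#' Overlapping duplicate encounters within a class are merged with a
#' warning. Hours without recording coverage are excluded.
#'
#' @param bw_log beaked whale encounter log ([log_bw_presence()]).
#' @param anthro_log anthropogenic encounter log ([detect_anthro()]);
#'   classes `ua`, `echosounder_*` and `vessel` are recognised.
#' @param coverage data.frame with `start_utc`, `end_utc` (POSIXct)
#'   recording coverage intervals.
#' @return data.frame of class `hourly_records`: `hour_utc`,
#'   `bw_minutes`, `ua_present`, `echo_present`, `vessel_present`,
#'   `condition`.
#' @export
hourly_assemble <- function(bw_log, anthro_log, coverage) {
  stopifnot(all(c("start_utc", "end_utc") %in% names(coverage)))
  get_iv <- function(log, classes) {
    if (is.null(log) || nrow(log) == 0L)
      return(data.frame(start = numeric(0), end = numeric(0)))
    sel <- log$signal_class %in% classes
    s <- as.numeric(log$start_utc[sel]); e <- as.numeric(log$end_utc[sel])
    if (length(s) > 1L) {
      o <- order(s)
      if (any(s[o][-1] < e[o][-length(e)]))
        warning("overlapping encounters within one class; merging")
    }
    merge_intervals(s, e)
  }
  bw <- get_iv(bw_log, "beaked_whale")
  ua <- get_iv(anthro_log, "ua")
  echo <- get_iv(anthro_log, c("echosounder_28", "echosounder_50"))
  ves <- get_iv(anthro_log, "vessel")

  cov_s <- as.numeric(coverage$start_utc); cov_e <- as.numeric(coverage$end_utc)
  hours <- unique(unlist(lapply(seq_along(cov_s), function(i)
    seq(floor(cov_s[i] / 3600), ceiling(cov_e[i] / 3600) - 1))))
  hours <- sort(hours)
  # keep only hours with any coverage
  hours <- hours[vapply(hours, function(h)
    any(.overlaps(cov_s, cov_e, h * 3600, (h + 1) * 3600)), logical(1))]

  any_overlap <- function(iv, lo, hi)
    nrow(iv) > 0L && any(.overlaps(iv$start, iv$end, lo, hi))
  rows <- lapply(hours, function(h) {
    lo <- h * 3600; hi <- lo + 3600
    mins <- lo + 0:59 * 60
    bw_min <- sum(vapply(mins, function(m)
      any_overlap(bw, m, m + 60), logical(1)))
    uaf <- any_overlap(ua, lo, hi)
    ecf <- any_overlap(echo, lo, hi)
    vef <- any_overlap(ves, lo, hi)
    data.frame(hour_utc = as.POSIXct(lo, origin = "1970-01-01", tz = "UTC"),
               bw_minutes = bw_min, ua_present = uaf, echo_present = ecf,
               vessel_present = vef,
               condition = 1L + vef + 2L * ecf + 4L * uaf)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hourly_records", "data.frame")
  out
}

#' Kruskal-Wallis test of hourly detections across noise conditions
#'
#' Rank-based one-way analysis of variance (with tie correction) of
#' hourly beaked whale detection sums across the noise-condition groups;
#' degrees of freedom are the number of non-empty groups minus one.
#'
#' @param records an [hourly_assemble()] table (or any data.frame with
#'   `bw_minutes` and `condition`).
#' @return list: `chi2`, `df`, `p`, `group_sizes`.
#' @export
kruskal_wallis <- function(records) {
  g <- factor(records$condition)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  kt <- stats::kruskal.test(records$bw_minutes, g)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, group_sizes = table(g))
}

#' Post hoc pairwise rank comparisons with Bonferroni correction
#'
#' Dunn-type z tests on group mean ranks for all pairs of non-empty
#' groups, with tie-corrected standard errors and Bonferroni-adjusted
#' p values, plus per-group mean-rank comparison intervals for plotting:
#' two groups whose intervals do not overlap differ significantly at the
#' adjusted level.
#'
#' @param records an [hourly_assemble()] table.
#' @param alpha family significance level.
#' @return list: `pairwise` (data.frame: `group_i`, `group_j`, `z`,
#'   `p_raw`, `adjusted_p`, `significant`), `intervals` (data.frame:
#'   `condition`, `n`, `mean_rank`, `lower`, `upper`), `excluded`
#'   (condition labels absent from the data).
#' @export
posthoc_pairwise <- function(records, alpha = 0.05) {
  g <- droplevels(factor(records$condition))
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  x <- records$bw_minutes
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  k <- nlevels(g)
  npairs <- k * (k - 1) / 2
  pr <- t(utils::combn(k, 2))
  z <- (mr[pr[, 1]] - mr[pr[, 2]]) /
    sqrt(v0 * (1 / n[pr[, 1]] + 1 / n[pr[, 2]]))
  p_raw <- 2 * stats::pnorm(-abs(z))
  adj <- pmin(1, p_raw * npairs)
  pairwise <- data.frame(group_i = lev[pr[, 1]], group_j = lev[pr[, 2]],
                         z = as.numeric(z), p_raw = as.numeric(p_raw),
                         adjusted_p = as.numeric(adj),
                         significant = as.numeric(adj) < alpha)
  zc <- stats::qnorm(1 - alpha / (k * (k - 1)))
  hw <- zc * sqrt(v0 / n) / sqrt(2)
  intervals <- data.frame(condition = lev, n = as.numeric(n),
                          mean_rank = as.numeric(mr),
                          lower = as.numeric(mr - hw),
                          upper = as.numeric(mr + hw))
  all_cond <- as.character(1:8)
  list(pairwise = pairwise, intervals = intervals,
       excluded = setdiff(all_cond, lev))
}

#' Compare beaked whale acoustic presence across noise conditions
#'
#' The top-level statistical comparison: a Kruskal-Wallis test of hourly
#' beaked whale detection minutes across the noise-condition groups,
#' followed by Dunn-type pairwise post hoc comparisons with Bonferroni
#' correction and mean-rank comparison intervals.
#'
#' @param records an [hourly_assemble()] table.
#' @param alpha significance level for the post hoc tests.
#' @return object of class `noise_condition_test` with `print`,
#'   `summary` and `plot` methods.
#' @export
noise_condition_test <- function(records, alpha = 0.05) {
  kw <- kruskal_wallis(records)
  ph <- posthoc_pairwise(records, alpha = alpha)
  structure(list(chi2 = kw$chi2, df = kw$df, p = kw$p,
                 group_sizes = kw$group_sizes, pairwise = ph$pairwise,
                 intervals = ph$intervals, excluded = ph$excluded,
                 alpha = alpha, n = nrow(records), call = match.call()),
            class = "noise_condition_test")
}

#' @export
print.noise_condition_test <- function(x, ...) {
  cat("Kruskal-Wallis comparison of hourly detections across noise conditions\n")
  cat(sprintf("  chi-squared = %.2f, df = %d, p = %.3g  (n = %d hours)\n",
              x$chi2, x$df, x$p, x$n))
  ns <- sum(x$pairwise$significant)
  cat(sprintf("  %d of %d Bonferroni-adjusted pairwise comparisons significant at %.2f\n",
              ns, nrow(x$pairwise), x$alpha))
  if (length(x$excluded))
    cat("  empty conditions excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.noise_condition_test <- function(object, ...) {
  print(object)
  cat("\nGroup mean ranks and comparison intervals:\n")
  print(object$intervals, row.names = FALSE, digits = 4)
  cat("\nPairwise comparisons:\n")
  print(object$pairwise, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Plot mean-rank comparison intervals by noise condition
#'
#' Group mean-rank estimates (circles) with comparison intervals
#' (lines); non-overlapping intervals indicate a significant pairwise
#' difference after Bonferroni correction.
#'
#' @param x a [noise_condition_test()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.noise_condition_test <- function(x, ...) {
  iv <- x$intervals
  yy <- rev(seq_len(nrow(iv)))
  graphics::plot(iv$mean_rank, yy, xlim = range(iv$lower, iv$upper),
                 pch = 1, cex = 1.3, yaxt = "n", ylab = "Noise condition",
                 xlab = "Mean rank of hourly detection minutes", ...)
  graphics::axis(2, at = yy, labels = iv$condition, las = 1)
  graphics::segments(iv$lower, yy, iv$upper, yy)
  invisible(x)
}
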