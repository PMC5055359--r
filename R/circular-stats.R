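#' Circular mean and standard deviation of angles
#'
#' Directional statistics via unit-vector resultants: the circular mean is
#' the direction of the summed unit vectors, and the circular SD is
#' `sqrt(-2 log(Rbar))` (in radians, reported in degrees), where `Rbar` is
#' the mean resultant length. When `Rbar` is numerically zero (for example
#' two antipodal angles) the mean is undefined and both entries are `NA`
#' with `undefined = TRUE`.
#'
#' Linear mean and SD are reported alongside, since furcation-angle
#' populations are confined to `[0, 180]` degrees where "mean +/- SD"
#' summaries are conventionally linear.
#'
#' @param angles numeric vector of angles in degrees.
#' @return A list with `mean`, `sd` (circular, degrees), `n`, `Rbar`,
#'   `undefined`, `linear_mean`, `linear_sd`.
#' @examples
#' circular_mean_sd(c(350, 10))$mean  # 0
#' @export
circular_mean_sd <- function(angles) {
  if (length(angles) == 0) stopf("empty angle vector")
  if (!all(is.finite(angles))) stopf("non-finite angles")
  th <- deg2rad(angles)
  S <- mean(sin(th))
  C <- mean(cos(th))
  Rbar <- sqrt(S^2 + C^2)
  if (Rbar < 1e-12) {
    return(list(mean = NA_real_, sd = NA_real_, n = length(angles),
                Rbar = Rbar, undefined = TRUE,
                linear_mean = mean(angles), linear_sd = stats::sd(angles)))
  }
  mu <- rad2deg(atan2(S, C)) %% 360
  if (360 - mu < 1e-9) mu <- 0
  sdc <- rad2deg(sqrt(-2 * log(Rbar)))
  list(mean = mu, sd = sdc, n = length(angles), Rbar = Rbar,
       undefined = FALSE,
       linear_mean = mean(angles), linear_sd = stats::sd(angles))
}

#' Boxplot summary statistics for one angle population
#'
#' Quartiles by linear interpolation (type 7), whiskers at the extremes --
#' the convention used for per-stack angle boxplots.
#'
#' @param x numeric vector.
#' @return Named vector `min`, `q25`, `median`, `q75`, `max`, `n`.
#' @export
boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
    n = length(x))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition across groups, with the p value
#' from the F distribution; significance is declared at `p < 0.05`.
#'
#' @param groups a list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return An object of class `anova_oneway`: list with `F`, `p`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `significant`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stopf("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(values))) stopf("non-finite values")
  g <- factor(rep(seq_along(groups), sizes))
  grand <- mean(values)
  gm <- tapply(values, g, mean)
  ssb <- sum(sizes * (gm - grand)^2)
  ssw <- sum((values - gm[g])^2)
  dfb <- length(groups) - 1
  dfw <- length(values) - length(groups)
  if (ssw == 0) {
    Fstat <- if (ssb == 0) 0 else Inf
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
  }
  p <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, dfb, dfw,
                                                lower.tail = FALSE)
  out <- list(F = Fstat, p = p, df_between = dfb, df_within = dfw,
              ss_between = ssb, ss_within = ssw, significant = p < 0.05)
  class(out) <- "anova_oneway"
  out
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}
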