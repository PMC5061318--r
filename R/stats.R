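#' Raw median absolute deviation
#'
#' `median(|x - median(x)|)`, unscaled: the 1.4826 normal-consistency
#' constant is applied only where a formula places it explicitly (see
#' [ssmd_star()]), not here.
#'
#' @param values numeric vector (at least one value).
#' @return raw MAD.
#' @export
mad_raw <- function(values) {
  if (length(values) == 0) stop("empty input")
  median(abs(values - median(values)))
}

# location/dispersion summaries for one control arm
group_stats <- function(values) {
  tibble::tibble(n = length(values), mean = mean(values), sd = sd(values),
                 median = median(values), mad = mad_raw(values))
}

#' Z'-factor and robust Z'-factor
#'
#' `Z' = 1 - 3 (d+ + d-) / |m+ - m-|` with `(m, d)` the per-arm mean and
#' standard deviation, or — for the robust variant — the median and raw
#' median absolute deviation. Note the robust variant uses MADs directly
#' (no 1.4826 rescaling), so on normal data robust Z' sits below the
#' classical Z' unless the consistency factor is applied externally.
#'
#' @param pos,neg numeric vectors for the positive and negative control arms
#'   (each with at least 2 values).
#' @param robust use medians and MADs instead of means and SDs.
#' @return the Z'-factor (always <= 1 when the locations differ).
#' @export
z_prime <- function(pos, neg, robust = FALSE) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  if (robust) {
    m <- c(median(pos), median(neg)); d <- c(mad_raw(pos), mad_raw(neg))
  } else {
    m <- c(mean(pos), mean(neg)); d <- c(sd(pos), sd(neg))
  }
  if (m[1] == m[2]) stop("zero location difference: Z'-factor undefined")
  1 - 3 * (d[1] + d[2]) / abs(m[1] - m[2])
}

#' Robust strictly standardized mean difference (SSMD*)
#'
#' `SSMD* = (X~+ - X~-) / (1.4826 * sqrt(s~+^2 + s~-^2))` with per-arm
#' medians `X~` and raw median absolute deviations `s~`.
#'
#' @inheritParams z_prime
#' @return SSMD* (sign follows the median difference).
#' @export
ssmd_star <- function(pos, neg) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  s <- c(mad_raw(pos), mad_raw(neg))
  if (all(s == 0)) stop("zero denominator: both MADs are zero")
  (median(pos) - median(neg)) / (1.4826 * sqrt(sum(s^2)))
}

#' Standard normal quantile
#'
#' Inverse CDF of the standard normal; `normal_quantile(0.9975)` is the
#' two-sided 0.5% false-positive quantile 2.81 and `normal_quantile(0.90)`
#' the 10% false-negative quantile 1.28 used in the power analysis.
#'
#' @param p probability in (0, 1).
#' @return z value.
#' @export
normal_quantile <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  qnorm(p)
}

#' Required sample size for a target effect
#'
#' `n = ceiling( 2 (z_alpha + z_beta)^2 sigma^2 / delta^2 )`, the normal
#' two-arm sample-size formula. `z_alpha` defaults to the two-sided 0.5%
#' false-positive quantile and `z_beta` to the 10% false-negative quantile.
#'
#' @param sigma pooled standard deviation of the control arms.
#' @param delta effect size on the score scale (nonzero).
#' @param z_alpha,z_beta standard normal quantiles for the false-positive
#'   and false-negative rates.
#' @return integer sample size per arm (0 when `sigma` is 0).
#' @export
required_sample_size <- function(sigma, delta,
                                 z_alpha = normal_quantile(1 - 0.005 / 2),
                                 z_beta = normal_quantile(0.90)) {
  stopifnot(delta != 0, sigma >= 0)
  as.integer(ceiling(2 * (z_alpha + z_beta)^2 * sigma^2 / delta^2))
}

#' Normalized effect size
#'
#' Expresses an effect `delta` as a fraction of the full control separation
#' `BHS(DMSO) - BHS(Mtz)`.
#'
#' @param delta effect size on the score scale.
#' @param bhs_pos,bhs_neg control levels of the positive (e.g. DMSO) and
#'   negative (e.g. full ablation) arms.
#' @return `delta / (bhs_pos - bhs_neg)`.
#' @export
normalized_effect <- function(delta, bhs_pos, bhs_neg) {
  if (bhs_pos == bhs_neg) stop("zero control separation")
  delta / (bhs_pos - bhs_neg)
}

#' Pooled standard deviation of two arms
#'
#' `sqrt((s+^2 + s-^2) / 2)`.
#'
#' @inheritParams z_prime
#' @return pooled SD.
#' @export
pooled_sd <- function(pos, neg) sqrt((sd(pos)^2 + sd(neg)^2) / 2)

#' Effect of group averaging on screening metrics, by bootstrap
#'
#' For each of `B` bootstrap replicates, each arm is resampled with
#' replacement to its original size, the observations are randomly
#' partitioned into groups of size `g` (remainder dropped), the groups are
#' averaged, and Z', robust Z' and SSMD* are computed on the group means.
#' The across-replicate means are reported per group size.
#'
#' @inheritParams z_prime
#' @param group_sizes group sizes to evaluate.
#' @param B number of bootstrap replicates.
#' @param seed integer seed making the table reproducible.
#' @return tibble with columns `group_size`, `n_groups_pos`, `n_groups_neg`,
#'   `z_prime`, `robust_z_prime`, `ssmd_star`.
#' @export
bootstrap_group_averaging <- function(pos, neg, group_sizes = 1:5, B = 1000,
                                      seed = 1L) {
  stopifnot(length(pos) >= 2, length(neg) >= 2, B >= 1)
  if (max(group_sizes) * 2 > min(length(pos), length(neg)))
    stop("group size too large for arm size")
  group_means <- function(x, g) {
    n <- (length(x) %/% g) * g
    if (n == 0) stop("group size exceeds arm size")
    colMeans(matrix(x[sample.int(length(x), n)], nrow = g))
  }
  metric_or_na <- function(f) tryCatch(f, error = function(e) NA_real_)
  withr::with_seed(as.integer(seed), {
    out <- lapply(group_sizes, function(g) {
      acc <- matrix(NA_real_, B, 3)
      for (b in seq_len(B)) {
        bp <- pos[sample.int(length(pos), replace = TRUE)]
        bn <- neg[sample.int(length(neg), replace = TRUE)]
        gp <- group_means(bp, g); gn <- group_means(bn, g)
        # degenerate replicates (tied resamples giving zero spread or zero
        # location difference) are dropped from the average
        acc[b, ] <- c(metric_or_na(z_prime(gp, gn)),
                      metric_or_na(z_prime(gp, gn, robust = TRUE)),
                      metric_or_na(ssmd_star(gp, gn)))
      }
      tibble::tibble(group_size = g,
                     n_groups_pos = length(pos) %/% g,
                     n_groups_neg = length(neg) %/% g,
                     z_prime = mean(acc[, 1], na.rm = TRUE),
                     robust_z_prime = mean(acc[, 2], na.rm = TRUE),
                     ssmd_star = mean(acc[, 3], na.rm = TRUE))
    })
    dplyr::bind_rows(out)
  })
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction (df = 1, upper-tail p), as used to compare
#' correct-posing proportions between plate designs.
#'
#' @param counts 2x2 matrix of nonnegative counts with positive margins.
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
chi_squared_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ht <- chisq.test(counts, correct = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA across two or more groups, e.g.
#' across the concentrations of a dose-response series.
#'
#' @param groups list of numeric vectors, each with at least 2 values, or a
#'   data frame with columns `value` and `group`.
#' @return tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2, all(vapply(groups, length, integer(1)) >= 2))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
                 p_value = ht$p.value)
}

#' Screening-quality metrics from a score table
#'
#' Computes per-arm summaries (mean, SD, median, raw MAD) and the three
#' separation metrics (Z', robust Z', SSMD*) from a tidy score table.
#'
#' @param scores data frame of per-larva scores.
#' @param score name of the score column (default `"bhs"`).
#' @param condition name of the condition column.
#' @param positive,negative condition labels of the positive (e.g. DMSO) and
#'   negative (e.g. Mtz) control arms.
#' @return a `screen_metrics` object; see [tidy.screen_metrics()] and
#'   [glance.screen_metrics()].
#' @export
screen_metrics <- function(scores, score = "bhs", condition = "condition",
                           positive, negative) {
  stopifnot(is.data.frame(scores), score %in% names(scores),
            condition %in% names(scores))
  v <- scores[[score]]; g <- scores[[condition]]
  pos <- v[g == positive & !is.na(v)]
  neg <- v[g == negative & !is.na(v)]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 usable scores in each control arm")
  arms <- dplyr::bind_rows(
    dplyr::mutate(group_stats(pos), arm = positive, .before = 1),
    dplyr::mutate(group_stats(neg), arm = negative, .before = 1))
  structure(list(
    arms = arms,
    z_prime = z_prime(pos, neg),
    robust_z_prime = z_prime(pos, neg, robust = TRUE),
    ssmd_star = ssmd_star(pos, neg),
    pooled_sd = pooled_sd(pos, neg),
    pos = pos, neg = neg,
    labels = c(positive = positive, negative = negative)),
    class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("Screening metrics (", x$labels["positive"], " vs ",
      x$labels["negative"], ")\n", sep = "")
  cat(sprintf("  Z'-factor        %8.3f\n", x$z_prime))
  cat(sprintf("  robust Z'-factor %8.3f\n", x$robust_z_prime))
  cat(sprintf("  SSMD*            %8.3f\n", x$ssmd_star))
  print(x$arms)
  invisible(x)
}

#' Tidy a screen_metrics object
#'
#' @param x a [screen_metrics()] result.
#' @param ... unused.
#' @return tibble with one row per metric.
#' @export
tidy.screen_metrics <- function(x, ...) {
  tibble::tibble(metric = c("z_prime", "robust_z_prime", "ssmd_star"),
                 value = c(x$z_prime, x$robust_z_prime, x$ssmd_star))
}

#' One-row summary of a screen_metrics object
#'
#' @inheritParams tidy.screen_metrics
#' @return one-row tibble with the metrics, arm sizes and pooled SD.
#' @export
glance.screen_metrics <- function(x, ...) {
  tibble::tibble(z_prime = x$z_prime, robust_z_prime = x$robust_z_prime,
                 ssmd_star = x$ssmd_star, pooled_sd = x$pooled_sd,
                 n_pos = length(x$pos), n_neg = length(x$neg))
}
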