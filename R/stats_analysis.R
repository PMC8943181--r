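# Study-level statistics for the randomized smoke-evacuation design.

# Pull a response vector (one value per operation) out of summaries.
response_values <- function(summaries, response) {
  vapply(summaries, function(s) {
    if (!is.null(s[[response]])) return(as.numeric(s[[response]]))
    i <- match(response, s$channel_stats$channel)
    if (!is.na(i)) return(s$channel_stats$max_ppb[i])
    stop("grouping error: unknown response '", response, "'")
  }, numeric(1))
}

design_field <- function(summaries, field) {
  vapply(summaries, function(s) {
    if (is.null(s$design)) stop("grouping error: summary lacks a design")
    s$design[[field]]
  }, character(1))
}

#' Two-group comparison of an operation-level response
#'
#' Welch's two-sample two-sided t-test of a per-operation response between
#' the two levels of a randomized or observational factor, reported in the
#' field's customary "mean +/- sd, p" style. Welch's unequal-variance form
#' is used because group spreads in this setting are typically unequal.
#'
#' @param summaries List of `operation_summary` objects.
#' @param factor One of `"ses"`, `"approach"`, `"location"`.
#' @param response Name of a summary field (e.g.
#'   `"harmful_total_mean_ppb"`, `"total_voc_max_ppb"`) or a channel name
#'   (its per-operation maximum is used).
#' @return A `comparison_result`: factor, per-group n/mean/sd, mean
#'   difference (first level minus second, levels sorted), two-sided
#'   p-value.
#' @export
compare_groups <- function(summaries, factor = c("ses", "approach", "location"),
                           response = "harmful_total_mean_ppb") {
  factor <- match.arg(factor)
  g <- design_field(summaries, factor)
  y <- response_values(summaries, response)
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    stop("grouping error: factor '", factor, "' needs exactly two levels ",
         "present (found ", length(levels), ")")
  }
  y1 <- y[g == levels[1]]
  y2 <- y[g == levels[2]]
  if (length(y1) < 2 || length(y2) < 2) {
    stop("grouping error: each level needs n >= 2")
  }
  if (stats::sd(y1) == 0 && stats::sd(y2) == 0 && mean(y1) == mean(y2)) {
    tt <- list(p.value = 1)  # degenerate: identical constant groups
  } else {
    tt <- stats::t.test(y1, y2, var.equal = FALSE)
  }
  structure(list(factor = factor, response = response,
                 groups = data.frame(level = levels,
                                     n = c(length(y1), length(y2)),
                                     mean = c(mean(y1), mean(y2)),
                                     sd = c(stats::sd(y1), stats::sd(y2)),
                                     stringsAsFactors = FALSE),
                 mean_difference = mean(y1) - mean(y2),
                 p_value = tt$p.value),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  g <- x$groups
  cat(sprintf("%s, %s: %s %.2f (+/- %.2f, n=%d) vs %s %.2f (+/- %.2f, n=%d), p = %.3g\n",
              x$response, x$factor,
              g$level[1], g$mean[1], g$sd[1], g$n[1],
              g$level[2], g$mean[2], g$sd[2], g$n[2], x$p_value))
  invisible(x)
}

#' Least-squares decomposition of factor effects
#'
#' Ordinary least squares of a per-operation response on one 0/1 indicator
#' per design factor — SES use (`with_ses` = 1), open approach (1), surgeon
#' level (1) — plus an intercept. Coding one indicator per factor (rather
#' than one per level) keeps the design matrix full rank alongside the
#' intercept and gives each coefficient the interpretation "change in
#' response (ppb) attributable to that condition". Factors constant across
#' the supplied operations are dropped from the model.
#'
#' @param summaries List of `operation_summary` objects.
#' @param response Response field name, as in [compare_groups()].
#' @return A `decomposition_result`: coefficients (ppb) per included
#'   indicator, intercept, multiple correlation R, residual sd, n.
#' @export
effect_decomposition <- function(summaries, response = "harmful_total_mean_ppb") {
  y <- response_values(summaries, response)
  X <- data.frame(
    ses = as.numeric(design_field(summaries, "ses") == "with_ses"),
    open = as.numeric(design_field(summaries, "approach") == "open"),
    surgeon_level = as.numeric(design_field(summaries, "location") ==
                                 "surgeon_level"))
  varying <- vapply(X, function(col) length(unique(col)) > 1, TRUE)
  X <- X[varying]
  if (ncol(X) == 0) {
    stop("decomposition error: no factor varies across the operations")
  }
  for (col in names(X)) {
    if (min(table(X[[col]])) < 2) {
      stop("decomposition error: factor '", col,
           "' needs >= 2 operations per level")
    }
  }
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("decomposition error: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(response = response,
                 coefficients = stats::coef(fit)[-1],
                 intercept = unname(stats::coef(fit)[1]),
                 R = sqrt(sm$r.squared),
                 residual_sd = sm$sigma,
                 n = length(y),
                 fit = fit),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("Effect decomposition of", x$response, sprintf("(n = %d)\n", x$n))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-14s %+.2f ppb\n", nm, x$coefficients[[nm]]))
  }
  cat(sprintf("  intercept      %.2f ppb;  R = %.2f;  residual sd = %.2f\n",
              x$intercept, x$R, x$residual_sd))
  invisible(x)
}

#' Distribution of the time of maximum concentration
#'
#' Tests whether concentration maxima cluster early in operations. Per
#' operation, the `K` channels with the largest maximum concentration are
#' selected (all channels when fewer than `K`); their normalised
#' times-of-maximum (`argmax_time_fraction`, in \\[0, 1\\]) are pooled
#' across operations and compared against the uniform distribution — the
#' expected pattern if maxima showed no systematic timing — with a
#' one-sample Kolmogorov-Smirnov test.
#'
#' @param summaries List of `operation_summary` objects.
#' @param K Channels per operation to pool (default 100).
#' @param bins Number of histogram bins reported (default 20).
#' @return A `max_time_result`: pooled fractions, K, histogram counts and
#'   breaks, KS statistic and p-value.
#' @export
max_time_distribution <- function(summaries, K = 100, bins = 20) {
  if (K < 1) stop("parameter error: K must be >= 1")
  fractions <- unlist(lapply(summaries, function(s) {
    cs <- s$channel_stats
    if (nrow(cs) == 0) stop("processing error: operation has no channels")
    top <- order(cs$max_ppb, decreasing = TRUE)[seq_len(min(K, nrow(cs)))]
    cs$argmax_time_fraction[top]
  }))
  ks <- suppressWarnings(stats::ks.test(fractions, "punif", exact = FALSE))
  h <- graphics::hist(fractions, breaks = seq(0, 1, length.out = bins + 1),
                      plot = FALSE)
  structure(list(fractions = fractions, K = K,
                 histogram = data.frame(mid = h$mids, count = h$counts),
                 ks_statistic = unname(ks$statistic),
                 p_value = ks$p.value,
                 n = length(fractions)),
            class = "max_time_result")
}

#' @export
print.max_time_result <- function(x, ...) {
  cat(sprintf("Time-of-maximum uniformity: %d pooled fractions (K = %d), D = %.3f, p = %.3g\n",
              x$n, x$K, x$ks_statistic, x$p_value))
  invisible(x)
}

#' Sample size for a two-group comparison
#'
#' Smallest integer group size `n` at which a two-sided two-sample t-test
#' detects a standardized effect `d = effect_mean_diff / sd` with the stated
#' power, using the normal-approximation power evaluated against the
#' t-distribution critical value:
#' `power(n) = pnorm(d * sqrt(n/2) - qt(1 - alpha/2, 2n - 2))`.
#' The returned n is floored at 2.
#'
#' @param effect_mean_diff Smallest group-mean difference to detect (> 0).
#' @param sd Common within-group standard deviation (> 0). Pass the
#'   standardized effect directly via `sd = 1`.
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param n_max Search ceiling.
#' @return Integer n per group.
#' @examples
#' sample_size_two_group(1.22, 1)  # 15 per group at alpha 0.05, power 0.90
#' @export
sample_size_two_group <- function(effect_mean_diff, sd = 1, alpha = 0.05,
                                  power = 0.90, n_max = 1e5) {
  if (effect_mean_diff <= 0) stop("parameter error: effect must be > 0")
  if (sd <= 0) stop("parameter error: sd must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("parameter error: alpha and power must be in (0, 1)")
  }
  d <- effect_mean_diff / sd
  for (n in 2:n_max) {
    pw <- stats::pnorm(d * sqrt(n / 2) - stats::qt(1 - alpha / 2, 2 * n - 2))
    if (pw >= power) return(n)
  }
  stop("parameter error: no n <= n_max reaches the requested power")
}
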