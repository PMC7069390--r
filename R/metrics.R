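# Diagnostic-validity estimation: 2x2 tables, proportion CIs, likelihood
# ratios, AUROC, and the McNemar paired test.

#' Cross-classification of screen versus reference status
#'
#' `tp` = sustained, `fp` = white-coat, `fn` = masked, `tn` = normotensive.
#' Pairs with either status missing are dropped (and counted in
#' `n_excluded`).
#'
#' @param screen,reference logical vectors of equal length.
#' @return object of class `confusion_table` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n`, `n_excluded`.
#' @export
confusion_table <- function(screen, reference) {
  if (length(screen) != length(reference)) {
    stop("screen and reference must have equal length", call. = FALSE)
  }
  ok <- !is.na(screen) & !is.na(reference)
  s <- screen[ok]
  r <- reference[ok]
  structure(list(tp = sum(s & r), fp = sum(s & !r),
                 fn = sum(!s & r), tn = sum(!s & !r),
                 n = sum(ok), n_excluded = sum(!ok)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(paste0("<confusion_table n=%d>\n",
                     "          ref+  ref-\n",
                     " screen+ %5d %5d\n",
                     " screen- %5d %5d\n"),
              x$n, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Binomial proportion with confidence interval
#'
#' Point estimate `successes / n` with a 95% (by default) interval by the
#' Wilson score method (default), the Wald normal approximation, or the
#' exact Clopper-Pearson method (beta-quantile closed form). Vectorized
#' over `successes` and `n`.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param method `"wilson"`, `"wald"` or `"exact"`.
#' @param conf_level confidence level.
#' @return data frame: `estimate`, `ci_low`, `ci_high`, `ci_method`, `n`.
#' @export
proportion_ci <- function(successes, n, method = c("wilson", "wald",
                                                   "exact"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(successes < 0 | successes > n)) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  p <- successes / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wilson") {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  } else if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- pmax(0, p - half)
    hi <- pmin(1, p + half)
  } else {
    alpha <- 1 - conf_level
    lo <- ifelse(successes == 0, 0,
                 stats::qbeta(alpha / 2, successes, n - successes + 1))
    hi <- ifelse(successes == n, 1,
                 stats::qbeta(1 - alpha / 2, successes + 1, n - successes))
  }
  data.frame(estimate = p, ci_low = lo, ci_high = hi,
             ci_method = method, n = n, stringsAsFactors = FALSE)
}

#' Sensitivity, specificity and predictive values of a 2x2 table
#'
#' Simple proportions with CIs per [proportion_ci()]. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param table a [confusion_table()].
#' @param ci_method passed to [proportion_ci()].
#' @return data frame with rows `sensitivity`, `specificity`, `ppv`,
#'   `npv` and columns `metric`, `estimate`, `ci_low`, `ci_high`,
#'   `ci_method`, `numerator`, `denominator`.
#' @export
validity_metrics <- function(table, ci_method = "wilson") {
  stopifnot(inherits(table, "confusion_table"))
  cells <- list(sensitivity = c(table$tp, table$tp + table$fn),
                specificity = c(table$tn, table$tn + table$fp),
                ppv = c(table$tp, table$tp + table$fp),
                npv = c(table$tn, table$tn + table$fn))
  rows <- lapply(names(cells), function(m) {
    k <- cells[[m]][1]
    d <- cells[[m]][2]
    if (d == 0) {
      data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, ci_method = ci_method,
                 numerator = k, denominator = d, stringsAsFactors = FALSE)
    } else {
      ci <- proportion_ci(k, d, ci_method)
      data.frame(metric = m, estimate = ci$estimate, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, ci_method = ci_method,
                 numerator = k, denominator = d, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Positive and negative likelihood ratios with log-method CIs
#'
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`; CIs via the
#' standard delta-method variance of `log LR`. Degenerate tables (perfect
#' sensitivity or specificity) yield infinite/zero ratios flagged by
#' `degenerate = TRUE`, never silently truncated.
#'
#' @param table a [confusion_table()].
#' @param conf_level confidence level.
#' @return data frame with rows `lr_pos`, `lr_neg`.
#' @export
likelihood_ratios <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lr_row <- function(name, num, den, est, var_terms_ok, se_log) {
    degen <- !is.finite(est) || est == 0 || !var_terms_ok
    if (degen || est <= 0) {
      data.frame(metric = name, estimate = est, ci_low = NA_real_,
                 ci_high = NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metric = name, estimate = est,
                 ci_low = exp(log(est) - z * se_log),
                 ci_high = exp(log(est) + z * se_log),
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }
  lrp <- sens / (1 - spec)
  lrn <- (1 - sens) / spec
  se_p <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  se_n <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  rbind(lr_row("lr_pos", tp, fp, lrp, tp > 0 && fp > 0, se_p),
        lr_row("lr_neg", fn, tn, lrn, fn > 0 && tn > 0, se_n))
}

#' AUROC of a single-cutoff (binary) classifier
#'
#' The trapezoidal area under the two-point ROC curve, `(sens + spec) / 2`.
#'
#' @param table a [confusion_table()].
#' @return area in `[0, 1]`.
#' @export
auc_point <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  sens <- table$tp / (table$tp + table$fn)
  spec <- table$tn / (table$tn + table$fp)
  (sens + spec) / 2
}

#' Empirical (Mann-Whitney) AUROC of a continuous score
#'
#' Probability that a random positive scores above a random negative, ties
#' counted half; computed via mid-ranks. CI by the Hanley-McNeil variance,
#' clipped to `[0, 1]`.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels logical reference labels.
#' @param conf_level confidence level.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
auc_empirical <- function(scores, labels, conf_level = 0.95) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks handle ties as half-wins
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * sqrt(v)),
       ci_high = min(1, auc + z * sqrt(v)),
       n_pos = n1, n_neg = n0)
}

#' McNemar test for paired binary outcomes
#'
#' Tests symmetry of the discordant cells. `mode = "asymptotic"` uses
#' `chi^2 = (b - c)^2 / (b + c)` on 1 df (no continuity correction);
#' `"exact"` uses the two-sided binomial test of `b` successes in `b + c`
#' trials at p = 1/2. `"auto"` picks exact when `b + c < 25`.
#'
#' @param b,c discordant counts.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @return list with `statistic` (chi-square, `NA` for exact), `p_value`,
#'   `mode`, `degenerate` (`TRUE` when `b = c = 0`).
#' @export
mcnemar_test <- function(b, c, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, mode = mode,
                degenerate = TRUE))
  }
  if (mode == "auto") mode <- if (n < 25) "exact" else "asymptotic"
  if (mode == "exact") {
    k <- min(b, c)
    p <- if (b == c) 1 else min(1, 2 * stats::pbinom(k, n, 0.5))
    list(statistic = NA_real_, p_value = p, mode = "exact",
         degenerate = FALSE)
  } else {
    stat <- (b - c)^2 / n
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         mode = "asymptotic", degenerate = FALSE)
  }
}
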