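# Bland-Altman agreement, the Pitman-Morgan test, and the covariate
# regression on between-method differences.

#' Bland-Altman agreement between two paired measurements
#'
#' Differences are `x - y`, means `(x + y) / 2`. Reports the mean
#' difference (bias), SD of differences (n-1 denominator), 95% limits of
#' agreement `bias +/- 1.96 * SD`, and the Pitman-Morgan check for a
#' proportional trend: the correlation `r` between difference and mean
#' (equivalent to testing equality of the two methods' variances), with a
#' p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param x,y paired numeric vectors (mmHg), `n >= 3` complete pairs.
#' @param loa_z multiplier for the limits of agreement (1.96 = 95%).
#' @return object of class `bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pitman_r`, `pitman_p`, `degenerate`
#'   (constant differences collapse the limits and leave Pitman
#'   undefined), plus the `diffs` and `means` vectors for plotting.
#' @export
bland_altman <- function(x, y, loa_z = 1.96) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  md <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0 || stats::sd(m) == 0
  if (degenerate) {
    r <- NA_real_
    p <- NA_real_
  } else {
    r <- stats::cor(d, m)
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(n = n, mean_diff = md, sd_diff = sd_d,
                 loa_low = md - loa_z * sd_d, loa_high = md + loa_z * sd_d,
                 pitman_r = r, pitman_p = p, degenerate = degenerate,
                 diffs = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman n=%d>\n",
                     " bias %.2f mmHg, SD %.2f, 95%% LoA [%.1f, %.1f]\n",
                     " Pitman r = %s, p = %s\n"),
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high,
              format(x$pitman_r, digits = 3),
              format(x$pitman_p, digits = 3)))
  invisible(x)
}

#' Regress between-method differences on subject covariates
#'
#' Ordinary least squares of the (office minus ambulatory) difference on
#' the supplied covariates; used to ask whether age, sex, site, BMI,
#' diabetes or smoking shift the disagreement between devices. A
#' rank-deficient design is rejected with the offending columns named.
#'
#' @param differences numeric response (mmHg).
#' @param covariates data frame of regressors (factors allowed); an
#'   empty/NULL data frame fits the intercept-only model.
#' @return data frame: `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value`, plus attributes `n` and `r_squared`.
#' @export
difference_regression <- function(differences, covariates = NULL) {
  if (is.null(covariates) || length(covariates) == 0) {
    dat <- data.frame(.diff = differences)
    fml <- .diff ~ 1
  } else {
    dat <- cbind(data.frame(.diff = differences), covariates)
    fml <- stats::as.formula(paste(".diff ~",
                                   paste(names(covariates),
                                         collapse = " + ")))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  mm <- stats::model.matrix(fml, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fml, data = dat)
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    estimate = s$coefficients[, 1],
                    std_error = s$coefficients[, 2],
                    t_value = s$coefficients[, 3],
                    p_value = s$coefficients[, 4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(dat)
  attr(out, "r_squared") <- s$r.squared
  out
}
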