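#' Welch two-sample t-test from raw samples or summary statistics
#'
#' Compares two groups with the unequal-variance (Welch) t statistic and
#' Satterthwaite degrees of freedom. Each group may be given either as a raw
#' numeric sample (delegated to [stats::t.test()]) or as published summary
#' statistics `list(mean =, sd =, n =)` — the form needed to test printed
#' cohort tables.
#'
#' @param a,b raw numeric sample vectors, or lists with elements `mean`,
#'   `sd`, `n` (summary form).
#' @return tibble with columns `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(a, b) {
  sumstat <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(mean = x$mean, sd = x$sd, n = x$n, raw = NULL)
    } else {
      if (length(x) < 2) stop("need n >= 2 observations per group",
                              call. = FALSE)
      list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x)
    }
  }
  sa <- sumstat(a); sb <- sumstat(b)
  if (sa$n < 2 || sb$n < 2 || sa$sd <= 0 || sb$sd <= 0)
    stop("degenerate group: need n >= 2 and sd > 0", call. = FALSE)
  if (!is.null(sa$raw) && !is.null(sb$raw)) {
    ht <- stats::t.test(sa$raw, sb$raw, var.equal = FALSE)
    tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  } else {
    se2a <- sa$sd^2 / sa$n
    se2b <- sb$sd^2 / sb$n
    tt <- (sa$mean - sb$mean) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (sa$n - 1) + se2b^2 / (sb$n - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  tibble::tibble(t = tt, df = df, p_value = p, mean_a = sa$mean,
                 mean_b = sb$mean)
}

#' Intraclass correlation from a subjects-by-raters matrix
#'
#' Two-way, single-measurement ICC computed from the two-way ANOVA mean
#' squares: `form = "absolute"` is ICC(A,1) (absolute agreement — penalises
#' systematic rater offsets), `form = "consistency"` is ICC(C,1). 95%
#' confidence bounds use the F-distribution construction of McGraw & Wong
#' (Satterthwaite degrees of freedom for the absolute form), which can yield
#' negative lower bounds on small samples.
#'
#' @param data numeric matrix or data frame, rows = subjects (>= 3),
#'   columns = raters/methods (>= 2), no missing cells.
#' @param form `"absolute"` or `"consistency"`.
#' @param conf_level confidence level for the bounds.
#' @return an `icc_result`: `icc`, `lower`, `upper`, `form`, `n_subjects`,
#'   `n_raters` (also available via [generics::tidy()]).
#' @export
icc <- function(data, form = c("absolute", "consistency"),
                conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(data)
  if (any(!is.finite(x))) stop("missing or non-finite cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  if (msr <= .Machine$double.eps * max(1, mse)) {
    warning("zero between-subject variance; ICC defined as 0", call. = FALSE)
    out <- list(icc = 0, lower = NA_real_, upper = NA_real_, form = form,
                n_subjects = n, n_raters = k,
                msr = msr, msc = msc, mse = mse)
    return(structure(out, class = "icc_result"))
  }

  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) /
      (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fstar_u <- stats::qf(1 - alpha / 2, n - 1, v)
    fstar_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fstar_u * mse) /
      (fstar_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fstar_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fstar_l * msr)
  }
  structure(list(icc = est, lower = lower, upper = upper, form = form,
                 n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(%s) = %.4f, 95%% CI (%.4f, %.4f), n = %d x %d\n",
              x$form, x$icc, x$lower, x$upper, x$n_subjects, x$n_raters))
  invisible(x)
}

#' @rdname icc
#' @param x an `icc_result`.
#' @param ... unused.
#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(form = x$form, icc = x$icc, lower = x$lower,
                 upper = x$upper, n_subjects = x$n_subjects,
                 n_raters = x$n_raters)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences `d = x - y`, their mean and sample SD, and the 95% limits of
#' agreement `mean_diff +/- 1.96 * sd_diff`. The per-pair plot data
#' (pair means vs differences) is kept on the result for [autoplot()].
#'
#' @param x,y equal-length numeric vectors of paired measurements (n >= 2).
#' @param loa_mult limits-of-agreement multiplier (1.96 for 95%).
#' @return a `bland_altman` result: `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `n`, and `data` (tibble `mean`, `diff`).
#' @export
bland_altman <- function(x, y, loa_mult = 1.96) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - loa_mult * s, loa_upper = m + loa_mult * s,
                 n = length(x), loa_mult = loa_mult,
                 data = tibble::tibble(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.4f (95%% LOA: %.4f, %.4f), n = %d\n",
              x$mean_diff, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @rdname bland_altman
#' @param object,x a `bland_altman` result.
#' @param ... unused.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper, n = x$n)
}

#' @rdname bland_altman
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "indianred") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (x - y)",
                  title = sprintf("Bland-Altman: bias %.3f, LOA (%.3f, %.3f)",
                                  object$mean_diff, object$loa_lower,
                                  object$loa_upper))
}

#' Binary classification metrics at a single operating point
#'
#' Confusion counts of predicted against true binary labels, with accuracy,
#' sensitivity, specificity, and the area under the two-point ROC curve
#' `(sensitivity + specificity) / 2` — the AUC of a classifier observed only
#' as thresholded labels.
#'
#' @param truth,pred equal-length binary (0/1) vectors; `truth` must contain
#'   both classes.
#' @return tibble with `tp`, `fn`, `tn`, `fp`, `acc`, `sen`, `spec`, `auc`.
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  if (length(unique(truth)) < 2)
    stop("truth contains a single class; metrics undefined", call. = FALSE)
  tp <- sum(truth == 1 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  sen <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 acc = (tp + tn) / length(truth),
                 sen = sen, spec = spec, auc = (sen + spec) / 2)
}

#' Reconstruct a confusion matrix from printed accuracy/sensitivity/specificity
#'
#' Searches all confusion matrices of total size `n` for those whose
#' accuracy, sensitivity and specificity round (to `digits` decimals) to the
#' printed values — the way published classification tables can be inverted
#' back to integer counts when only rounded metrics are reported.
#'
#' @param acc,sen,spec printed metric values.
#' @param n total number of cases.
#' @param digits decimals the metrics were printed with.
#' @return tibble of all consistent `(tp, fn, tn, fp)` rows (typically one).
#' @export
reconstruct_confusion <- function(acc, sen, spec, n, digits = 4) {
  rnd <- function(v) round(v, digits)
  hits <- list()
  for (pos in 1:(n - 1)) {
    neg <- n - pos
    tp <- 0:pos
    sen_ok <- tp[rnd(tp / pos) == rnd(sen)]
    if (length(sen_ok) == 0) next
    tn <- 0:neg
    spec_ok <- tn[rnd(tn / neg) == rnd(spec)]
    if (length(spec_ok) == 0) next
    grid <- expand.grid(tp = sen_ok, tn = spec_ok)
    grid <- grid[rnd((grid$tp + grid$tn) / n) == rnd(acc), , drop = FALSE]
    if (nrow(grid) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        tp = grid$tp, fn = pos - grid$tp, tn = grid$tn, fp = neg - grid$tn)
    }
  }
  if (length(hits) == 0)
    return(tibble::tibble(tp = integer(), fn = integer(), tn = integer(),
                          fp = integer()))
  dplyr::bind_rows(hits)
}
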