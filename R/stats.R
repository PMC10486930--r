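# Cohort-level statistics: cumulative IOP, normality-gated two-group tests,
# one-way ANOVA with Tukey-Kramer post hoc tests, and least-squares
# regression with pointwise confidence bands.

#' Cumulative IOP (area under the pressure-time curve)
#'
#' Trapezoidal integral of IOP over days, in mmHg*Days. No baseline or
#' contralateral subtraction is applied by default (cumulative IOP is defined
#' simply as the area under the curve); `baseline` subtracts a constant
#' pressure before integrating.
#'
#' @param x an `iop_series` (data.frame with `day`, `iop`) — or a numeric
#'   vector of days, with `iop` supplied separately.
#' @param iop pressures when `x` is a numeric day vector.
#' @param baseline optional constant to subtract (mmHg).
#' @return cumulative IOP in mmHg*Days.
#' @examples
#' cumulative_iop(c(0, 2), c(10, 20))  # 30
#' @export
cumulative_iop <- function(x, iop = NULL, baseline = 0) {
  if (is.data.frame(x)) { day <- x$day; iop <- x$iop } else day <- x
  stopifnot(length(day) == length(iop), length(day) >= 2)
  if (any(diff(day) <= 0)) stop_gq("days must be strictly increasing")
  y <- iop - baseline
  sum(diff(day) * (head(y, -1) + y[-1]) / 2)
}

exact_wilcox_p <- function(a, b) {
  # two-sided exact rank-sum p by full enumeration over C(n, n_a)
  # assignments of the pooled ranks; handles ties via midranks.
  n_a <- length(a); pooled <- c(a, b); n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  combs <- combn(n, n_a)
  w_all <- colSums(matrix(r[combs], nrow = n_a))
  mu <- mean(w_all)
  # two-sided: total probability of rank sums at least as far from the mean
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Normality-gated two-group comparison
#'
#' Each group is first tested for normality (Shapiro-Wilk at alpha 0.05,
#' provided n >= 3); if any group fails — or is too small to test — the
#' comparison uses the Wilcoxon rank sum test, otherwise a two-sided
#' two-sample t-test. The Wilcoxon branch uses the exact null distribution
#' for combined n <= 20 (full permutation enumeration when ties are present)
#' and the tie-corrected normal approximation above that.
#'
#' @param a,b numeric samples.
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @param var_equal pooled-variance t when the t branch is taken.
#' @param method `"auto"` (default: normality gate decides), or force
#'   `"wilcoxon"` / `"t"`.
#' @return a `test_result` list: `method` ("t" or "wilcoxon"), `statistic`,
#'   `p`, `normality_p` (per group, NA when not testable).
#' @export
two_group_test <- function(a, b, gate_alpha = 0.05, var_equal = TRUE,
                           method = c("auto", "wilcoxon", "t")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 1, length(b) >= 1)
  sw <- function(x) {
    if (length(x) < 3 || sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }
  np <- c(a = sw(a), b = sw(b))
  nonpar <- switch(method,
    auto = any(is.na(np)) || any(np < gate_alpha, na.rm = TRUE),
    wilcoxon = TRUE, t = FALSE)
  n <- length(a) + length(b)
  if (all(c(a, b) == c(a, b)[1])) {            # everything tied
    return(structure(list(method = "wilcoxon", statistic = NA_real_, p = 1,
                          normality_p = np), class = "test_result"))
  }
  if (nonpar) {
    ties <- anyDuplicated(c(a, b)) > 0
    if (n <= 20) {
      p <- if (ties) exact_wilcox_p(a, b) else
        wilcox.test(a, b, exact = TRUE)$p.value
      w <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$statistic)
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      p <- ht$p.value; w <- ht$statistic
    }
    structure(list(method = "wilcoxon", statistic = unname(w), p = min(p, 1),
                   normality_p = np), class = "test_result")
  } else {
    ht <- t.test(a, b, var.equal = var_equal)
    structure(list(method = "t", statistic = unname(ht$statistic),
                   p = ht$p.value, normality_p = np), class = "test_result")
  }
}

#' One-way ANOVA with Tukey-Kramer post hoc tests
#'
#' Omnibus one-way ANOVA followed by Tukey's honest significant differences
#' (the Tukey-Kramer form: studentized-range quantiles with unequal group
#' sizes).
#'
#' @param groups named list of numeric samples (>= 3 groups, each n >= 2).
#' @return a `test_result`: `method = "anova"`, `statistic` (F), `p`,
#'   `pairwise` (data.frame: pair, diff, lwr, upr, p_adj),
#'   `normality_p` per group.
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(11, 12, 13)))
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2)) stop_gq("every group needs at least 2 observations")
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), ns), levels = names(groups)))
  if (sd(df$y) == 0)
    return(structure(list(method = "anova", statistic = 0, p = 1,
                          pairwise = NULL,
                          normality_p = setNames(rep(NA_real_, length(groups)),
                                                 names(groups))),
                     class = "test_result"))
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  sw <- vapply(groups, function(x)
    if (length(x) >= 3 && sd(x) > 0) shapiro.test(x)$p.value else NA_real_,
    numeric(1))
  structure(list(method = "anova", statistic = an[["F value"]][1],
                 p = an[["Pr(>F)"]][1], pairwise = pw, normality_p = sw),
            class = "test_result")
}

#' Least-squares regression with a 95 percent mean-prediction band
#'
#' Ordinary least squares of `y` on `x` with the t-based pointwise confidence
#' interval of the conditional mean.
#'
#' @param x,y numeric vectors (>= 3 points; `x` must vary).
#' @param newx abscissae for the band (default: sorted unique `x`).
#' @param conf confidence level (default 0.95).
#' @return list: `slope`, `intercept`, `band` (data.frame `x`, `fit`, `lwr`,
#'   `upr`), and the fitted `lm` object as `fit`.
#' @export
linreg_ci <- function(x, y, newx = NULL, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_gq("regression needs at least 3 points")
  if (sd(x) == 0) stop_gq("x is constant: regression undefined")
  fit <- lm(y ~ x)
  newx <- newx %||% sort(unique(x))
  pr <- predict(fit, newdata = data.frame(x = newx),
                interval = "confidence", level = conf)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       band = data.frame(x = newx, fit = pr[, "fit"], lwr = pr[, "lwr"],
                         upr = pr[, "upr"]),
       fit = fit)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result: method=%s, statistic=%s, p=%.4g\n", x$method,
              format(x$statistic, digits = 4), x$p))
  if (!is.null(x$pairwise)) { cat("pairwise (Tukey-Kramer):\n"); print(x$pairwise) }
  invisible(x)
}

# serialize a test_result for the JSON report
test_result_json <- function(x) {
  out <- list(method = x$method, statistic = x$statistic, p = x$p,
              normality_p = as.list(x$normality_p))
  if (!is.null(x$pairwise)) out$pairwise <- x$pairwise
  out
}
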