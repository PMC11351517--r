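# Statistical layer: covariate-by-oculomotor correlations (Spearman or
# Pearson), the late-error multiple regression with assumption diagnostics,
# and the variance inflation factor.

#' Correlate oculomotor summaries with covariates
#'
#' Computes, for every (covariate, oculomotor parameter) pair, the Spearman
#' rank correlation (average ranks for ties; p via the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n-2 df) or the Pearson
#' correlation. Observations are pairwise complete; pairs with fewer than 3
#' complete observations are omitted with a warning. Raw p-values are flagged
#' at `alpha` with no multiplicity correction by default; Benjamini-Hochberg
#' adjustment is available but off by default.
#'
#' @param summaries A data frame of per-subject oculomotor summaries with a
#'   `subject` column (e.g. the `summaries` element of an [simulate_cohort()]
#'   result).
#' @param covariates A covariate data frame with a `subject` column.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust `"none"` (default) or `"BH"`; when `"BH"`, the flag uses the
#'   adjusted p-values reported in `p_adjusted`.
#' @param oculomotor_cols,covariate_cols Columns to correlate; default: all
#'   numeric columns apart from identifiers and bookkeeping.
#' @return A data frame of class `mgst_correlations`: `covariate`,
#'   `oculomotor`, `method`, `estimate`, `p_value` (and `p_adjusted` for BH),
#'   `n`, `significant`.
#' @export
correlate_all <- function(summaries, covariates,
                          method = c("spearman", "pearson"),
                          alpha = 0.05, adjust = c("none", "BH"),
                          oculomotor_cols = NULL, covariate_cols = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot("subject" %in% names(summaries), "subject" %in% names(covariates))
  merged <- merge(summaries, covariates, by = "subject")
  if (is.null(oculomotor_cols)) {
    skip <- c("subject", "n_trials", "n_valid_trials", "excluded")
    oculomotor_cols <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                                       logical(1))], skip)
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(covariates)[vapply(covariates, is.numeric,
                                                       logical(1))], "subject")
  }
  rows <- vector("list", length(covariate_cols) * length(oculomotor_cols))
  k <- 0
  dropped <- 0
  for (cv in covariate_cols) {
    for (oc in oculomotor_cols) {
      x <- merged[[cv]]
      y <- merged[[oc]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3) {
        dropped <- dropped + 1
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
      )
      k <- k + 1
      rows[[k]] <- data.frame(covariate = cv, oculomotor = oc,
                              method = method,
                              estimate = unname(ct$estimate),
                              p_value = ct$p.value, n = n)
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d pair(s) omitted: fewer than 3 complete observations",
                    dropped))
  }
  res <- do.call(rbind, rows[seq_len(k)])
  if (is.null(res)) {
    res <- data.frame(covariate = character(), oculomotor = character(),
                      method = character(), estimate = numeric(),
                      p_value = numeric(), n = integer())
  }
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
    res$significant <- res$p_adjusted < alpha
  } else {
    res$significant <- res$p_value < alpha
  }
  class(res) <- c("mgst_correlations", "data.frame")
  res
}

#' @export
print.mgst_correlations <- function(x, ...) {
  cat(sprintf("<mgst_correlations> %d pairs (%s), %d significant\n",
              nrow(x), if (nrow(x)) x$method[1] else "", sum(x$significant)))
  if (any(x$significant)) {
    print.data.frame(x[x$significant, , drop = FALSE], digits = 3,
                     row.names = FALSE)
  }
  invisible(x)
}

# Jarque-Bera normality test from sample skewness and kurtosis
jarque_bera <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  stat <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = stat, p_value = stats::pchisq(stat, 2, lower.tail = FALSE))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j on
#' the remaining predictors; computed as the diagonal of the inverse
#' correlation matrix. Perfectly collinear predictors get `Inf` and are named
#' in the `"collinear"` attribute.
#'
#' @param x A numeric matrix or data frame of at least two predictor columns.
#' @return Named numeric vector of VIFs (all >= 1 up to rounding).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("vif requires at least 2 predictors")
  if (!is.numeric(x)) stop("predictors must be numeric")
  r <- stats::cor(x)
  out <- rep(NA_real_, ncol(x))
  names(out) <- colnames(x)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (!is.null(inv) && all(is.finite(inv))) {
    out[] <- diag(inv)
  } else {
    for (j in seq_len(ncol(x))) {
      r2 <- suppressWarnings(summary(stats::lm(x[, j] ~ x[, -j]))$r.squared)
      out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }
  }
  attr(out, "collinear") <- names(out)[is.infinite(out)]
  out
}

#' Multiple regression of the late-error rate
#'
#' Ordinary least squares of `%LateErrorRate` on age, gender and selected
#' neuropsychological scores, with the assumption checks usually reported
#' alongside: Breusch-Pagan for homoscedasticity, Jarque-Bera for residual
#' normality, Durbin-Watson for independence, a residual-versus-fitted
#' curvature check for linearity, and per-predictor VIFs for
#' multicollinearity. Gender is coded 0 = female, 1 = male, so a positive
#' coefficient means a higher male rate. Complete cases only.
#'
#' @param data Data frame containing the dependent variable and predictors
#'   (e.g. merged summaries and covariates).
#' @param dv Name of the dependent variable column.
#' @param predictors Predictor column names; default the seven-variable set
#'   (age, gender, MoCA total, HADS anxiety and depression, Color Trails 1
#'   time and errors).
#' @param alpha Significance level used by the printed flags.
#' @return A list of class `mgst_regression`: `coefficients` (term, B, SE, t,
#'   p), `f_statistic`, `df1`, `df2`, `p_overall`, `r_squared`,
#'   `adj_r_squared`, `vif`, `diagnostics` (named list of test results with
#'   `met` flags), `n`, and the underlying `lm` fit.
#' @export
fit_late_error_regression <- function(data, dv = "pct_late_error",
                                      predictors = c("age", "gender",
                                                     "MOTS-1", "HDTSA-1",
                                                     "HDTSD-1", "CLRES01-1",
                                                     "CLRES02-1"),
                                      alpha = 0.05) {
  missing_cols <- setdiff(c(dv, predictors), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[, c(dv, predictors), drop = FALSE]
  if ("gender" %in% predictors && !is.numeric(d$gender)) {
    g <- tolower(as.character(d$gender))
    if (!all(g %in% c("male", "female", NA))) {
      stop("gender must be numeric (0 = female, 1 = male) or 'male'/'female'")
    }
    d$gender <- as.numeric(g == "male")
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1) {
    stop(sprintf("need more than %d complete cases for %d predictors, got %d",
                 p + 1, p, n))
  }
  X <- as.matrix(d[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    aliased <- predictors[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1]
    stop("design is rank deficient; offending predictor(s): ",
         paste(aliased, collapse = ", "))
  }
  fml <- stats::as.formula(paste0("`", dv, "` ~ ",
                                  paste0("`", predictors, "`",
                                         collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  coefs <- data.frame(term = c("(Intercept)", predictors),
                      B = unname(sm$coefficients[, 1]),
                      SE = unname(sm$coefficients[, 2]),
                      t = unname(sm$coefficients[, 3]),
                      p = unname(sm$coefficients[, 4]))

  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  bp <- lmtest::bptest(fit)
  dw <- lmtest::dwtest(fit, alternative = "two.sided")
  jb <- jarque_bera(res)
  lin_fit <- stats::lm(res ~ fitted + I(fitted^2))
  lin_p <- summary(lin_fit)$coefficients["I(fitted^2)", 4]

  out <- list(
    coefficients = coefs,
    f_statistic = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    p_overall = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                          sm$fstatistic[3], lower.tail = FALSE),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    vif = vif(X),
    diagnostics = list(
      homoscedasticity = list(test = "Breusch-Pagan",
                              statistic = unname(bp$statistic),
                              p_value = bp$p.value, met = bp$p.value > alpha),
      normality = list(test = "Jarque-Bera", statistic = jb$statistic,
                       p_value = jb$p_value, met = jb$p_value > alpha),
      independence = list(test = "Durbin-Watson",
                          statistic = unname(dw$statistic),
                          p_value = dw$p.value, met = dw$p.value > alpha),
      linearity = list(test = "residual-vs-fitted curvature",
                       p_value = lin_p, met = lin_p > alpha)
    ),
    n = n,
    alpha = alpha,
    fit = fit
  )
  out$p_overall <- unname(out$p_overall)
  class(out) <- "mgst_regression"
  out
}

#' @export
print.mgst_regression <- function(x, ...) {
  cat(sprintf("<mgst_regression> n = %d, F(%d,%d) = %.3f, p = %.4f, R2 = %.3f\n",
              x$n, x$df1, x$df2, x$f_statistic, x$p_overall, x$r_squared))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat("VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif), collapse = ", "),
      "\n")
  met <- vapply(x$diagnostics, function(d) d$met, logical(1))
  cat("assumptions met:", paste(names(met)[met], collapse = ", "),
      if (any(!met)) paste0("; violated: ",
                            paste(names(met)[!met], collapse = ", ")) else "",
      "\n")
  invisible(x)
}
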