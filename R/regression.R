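#' Variance inflation factors and collinearity flags
#'
#' For each predictor j, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the
#' ordinary least-squares regression of predictor j on all other predictors;
#' tolerance is `1 / VIF`. Flags follow the usual screening thresholds: any
#' individual VIF > 10, mean VIF > 1, or tolerance < 0.1.
#'
#' @param X Numeric matrix or data frame of predictors (>= 2 columns).
#' @return List: `vif` (named), `tolerance`, `mean_vif`, and logical `flags`.
#' @export
vif_diagnostics <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("vif_diagnostics: need at least 2 predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("vif_diagnostics: constant predictor(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12)
      stop("vif_diagnostics: predictor ", colnames(X)[j],
           " is collinear with the others")
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  tol <- 1 / vif
  list(vif = vif, tolerance = tol, mean_vif = mean(vif),
       flags = list(individual_gt_10 = any(vif > 10),
                    mean_gt_1 = mean(vif) > 1,
                    tolerance_lt_0.1 = any(tol < 0.1)))
}

#' Shapiro-Wilk normality check of model residuals
#'
#' @param fit An `lm` fit (or an object with `$residuals`).
#' @return List: `W`, `p_value`, and advisory `non_normal` flag at
#'   alpha = 0.05.
#' @export
residual_normality <- function(fit) {
  r <- stats::residuals(fit)
  if (length(r) < 3) stop("residual_normality: need at least 3 residuals")
  sw <- stats::shapiro.test(r)
  list(W = unname(sw$statistic), p_value = sw$p.value,
       non_normal = sw$p.value < 0.05)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors (n >= 3, non-zero variance).
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("pearson_r: need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("pearson_r: zero variance")
  stats::cor(x[ok], y[ok])
}

# standardized coefficients: refit on z-scored outcome and predictors
standardized_betas <- function(data, outcome, predictors) {
  zd <- as.data.frame(lapply(data[c(outcome, predictors)], scale))
  f <- stats::reformulate(predictors, response = outcome)
  stats::coef(stats::lm(f, data = zd))[-1]
}

#' Hierarchical regression of a cognitive outcome on an MMN index
#'
#' Fits the reduced model (`outcome ~ age + education` by default) and the
#' full model adding one MMN index, by ordinary least squares on complete
#' cases. Reports delta R-squared, the nested F-test of the added predictor
#' (identical to `anova(reduced, full)`), unstandardized and standardized
#' coefficients with two-sided p-values, collinearity diagnostics of the full
#' design, and the Shapiro-Wilk check of the full model's residuals.
#'
#' @param data Data frame containing all variables.
#' @param outcome Name of the outcome column (a composite score).
#' @param added Name of the MMN index column to add, or `NULL` for the
#'   reduced model only.
#' @param base Names of the covariates entered first.
#' @return Object of class `hier_reg`.
#' @export
fit_hierarchical <- function(data, outcome, added = NULL,
                             base = c("age_years", "education_years")) {
  vars <- c(outcome, base, added)
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v))
    stop("fit_hierarchical: missing column(s): ",
         paste(missing_v, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  k_full <- length(base) + length(added)
  if (nrow(d) <= k_full + 1)
    stop("fit_hierarchical: not enough complete cases")
  reduced <- stats::lm(stats::reformulate(base, response = outcome), data = d)
  if (is.null(added)) {
    full <- reduced
  } else {
    X <- as.matrix(d[c(base, added)])
    if (qr(cbind(1, X))$rank < ncol(X) + 1)
      stop("fit_hierarchical: rank-deficient design among: ",
           paste(c(base, added), collapse = ", "))
    full <- stats::lm(stats::reformulate(c(base, added), response = outcome),
                      data = d)
  }
  r2_red <- summary(reduced)$r.squared
  r2_full <- summary(full)$r.squared
  n <- nrow(d)
  if (!is.null(added)) {
    df2 <- n - k_full - 1
    nested_F <- (r2_full - r2_red) * df2 / (1 - r2_full)
    nested_p <- stats::pf(nested_F, 1, df2, lower.tail = FALSE)
  } else {
    nested_F <- NA_real_; nested_p <- NA_real_; df2 <- n - k_full - 1
  }
  betas <- standardized_betas(d, outcome, c(base, added))
  vif <- if (k_full >= 2) vif_diagnostics(d[c(base, added)]) else NULL
  structure(list(outcome = outcome, base = base, added = added,
                 reduced = reduced, full = full, n = n,
                 r2_reduced = r2_red, r2_full = r2_full,
                 delta_r2 = r2_full - r2_red,
                 nested_F = nested_F, nested_df = c(1, df2),
                 nested_p = nested_p,
                 coefficients = summary(full)$coefficients,
                 beta_std = betas, vif = vif,
                 residual_normality = residual_normality(full)),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("<hier_reg> %s ~ %s%s (n = %d)\n", x$outcome,
              paste(x$base, collapse = " + "),
              if (!is.null(x$added)) paste0(" [+ ", x$added, "]") else "",
              x$n))
  cat(sprintf("  R2 reduced = %.3f, R2 full = %.3f, delta R2 = %.3f\n",
              x$r2_reduced, x$r2_full, x$delta_r2))
  if (!is.null(x$added))
    cat(sprintf("  nested F(%d, %d) = %.2f, p = %.4g; beta[%s] = %.3f\n",
                x$nested_df[1], x$nested_df[2], x$nested_F, x$nested_p,
                x$added, x$beta_std[x$added]))
  invisible(x)
}

#' @export
summary.hier_reg <- function(object, ...) {
  print(object)
  cat("\nFull-model coefficients:\n")
  stats::printCoefmat(object$coefficients)
  cat("\nStandardized coefficients:\n")
  print(round(object$beta_std, 3))
  if (!is.null(object$vif)) {
    cat("\nVIF:\n"); print(round(object$vif$vif, 3))
    cat(sprintf("mean VIF = %.3f\n", object$vif$mean_vif))
  }
  cat(sprintf("\nShapiro-Wilk of residuals: W = %.3f, p = %.3f\n",
              object$residual_normality$W, object$residual_normality$p_value))
  invisible(object)
}

#' @export
coef.hier_reg <- function(object, ...) stats::coef(object$full)

#' Hierarchical model with an MMN x deviant-family interaction block
#'
#' Instead of one model per deviant family, the short-ISI MMN enters the full
#' model as an MMN x family term over the five Optimum-1 families (long
#' format, one row per subject x family); the block of added terms is tested
#' against the reduced covariate-only model with a nested F-test on the block.
#'
#' @param long Long-format data frame with columns for the outcome, the base
#'   covariates, `amplitude_uv` and `family` (all five families present for
#'   each subject).
#' @param outcome Outcome column name.
#' @param base Covariate column names.
#' @return List with the reduced and full `lm` fits, `delta_r2`,
#'   `block_F`, `block_df`, `block_p` and `n_rows`.
#' @export
fit_deviant_interaction <- function(long, outcome,
                                    base = c("age_years", "education_years")) {
  fams <- c("duration", "frequency", "intensity", "location", "gap")
  missing_f <- setdiff(fams, unique(as.character(long$family)))
  if (length(missing_f))
    stop("fit_deviant_interaction: missing family(ies): ",
         paste(missing_f, collapse = ", "))
  d <- long[stats::complete.cases(long[c(outcome, base, "amplitude_uv", "family")]), ]
  d$family <- factor(as.character(d$family), levels = fams)
  reduced <- stats::lm(stats::reformulate(base, response = outcome), data = d)
  full_f <- stats::reformulate(c(base, "amplitude_uv:family"), response = outcome)
  full <- stats::lm(full_f, data = d)
  if (any(is.na(stats::coef(full))))
    stop("fit_deviant_interaction: collinear interaction design")
  an <- stats::anova(reduced, full)
  list(reduced = reduced, full = full,
       delta_r2 = summary(full)$r.squared - summary(reduced)$r.squared,
       block_F = an$F[2], block_df = c(an$Df[2], an$Res.Df[2]),
       block_p = an$`Pr(>F)`[2], n_rows = nrow(d))
}

#' Group contrast on a per-subject score
#'
#' One-way fixed contrast of aMCI versus the pooled naMCI/SMI groups, the
#' planned comparison for all group analyses, via OLS on a +/- 0.5 indicator.
#'
#' @param score Numeric per-subject scores.
#' @param group Factor/character vector with levels containing `aMCI`.
#' @return List: `F` (1, n-2) statistic, `p_value`, `mean_aMCI`,
#'   `mean_other`.
#' @export
group_contrast <- function(score, group) {
  g <- as.character(group)
  ok <- stats::complete.cases(score, g)
  score <- score[ok]; g <- g[ok]
  ind <- ifelse(g == "aMCI", 0.5, -0.5)
  fit <- stats::lm(score ~ ind)
  an <- stats::anova(fit)
  list(F = an$`F value`[1], df = c(1, an$Df[2]), p_value = an$`Pr(>F)`[1],
       mean_aMCI = mean(score[g == "aMCI"]),
       mean_other = mean(score[g != "aMCI"]))
}
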