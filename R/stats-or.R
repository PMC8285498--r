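#' Odds ratio for a single 2x2 table
#'
#' Computes the sample odds ratio, its Wald standard error on the log scale,
#' a 95\% confidence interval, and a two-sided Wald p-value for one carrier
#' table laid out as (case carriers, case non-carriers, control carriers,
#' control non-carriers).
#'
#' When any cell is zero and `continuity = "haldane"` (the default), the
#' Haldane--Anscombe correction adds 0.5 to all four cells of the table
#' before estimation. With `continuity = "none"` a zero cell yields an
#' infinite or zero odds ratio and an infinite standard error.
#'
#' @param a,b,c,d Non-negative cell counts: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @param continuity `"haldane"` (add 0.5 to every cell when any cell is 0)
#'   or `"none"`.
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return A list of class `"effect_estimate"` with elements `log_or`,
#'   `se`, `or`, `ci_low`, `ci_high`, `p`, and `corrected` (logical, whether
#'   the continuity correction was applied).
#' @examples
#' odds_ratio_2x2(163, 420, 161, 1416)   # liver-vs-other ESR1 carrier table
#' @export
odds_ratio_2x2 <- function(a, b, c, d, continuity = c("haldane", "none"),
                           conf_level = 0.95) {
  continuity <- match.arg(continuity)
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative and non-missing")
  }
  if ((a + b) == 0 || (c + d) == 0) {
    stop("untestable table: one comparison arm has no samples")
  }
  corrected <- FALSE
  if (any(cells == 0) && continuity == "haldane") {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  effect_estimate(unname(log_or), unname(se), conf_level = conf_level,
                  corrected = corrected)
}

# Shared constructor: Wald CI and two-sided p from a log-scale estimate.
# NA estimates (rank-deficient design) propagate NA throughout.
effect_estimate <- function(log_or, se, conf_level = 0.95, corrected = FALSE) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (is.na(log_or) || is.na(se)) {
    return(structure(list(log_or = NA_real_, se = NA_real_, or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, corrected = corrected),
                     class = "effect_estimate"))
  }
  p <- if (is.finite(se) && se > 0) {
    2 * stats::pnorm(-abs(log_or / se))
  } else if (log_or == 0) 1 else 0
  structure(list(
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    p = max(p, .Machine$double.xmin),
    corrected = corrected
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("OR %.*f (95%% CI %.*f-%.*f), p = %.3g\n",
              digits, x$or, digits, x$ci_low, digits, x$ci_high, x$p))
  invisible(x)
}

#' Inverse-variance fixed-effects pooling of log odds ratios
#'
#' Pools per-stratum effect estimates with weights \eqn{w_i = 1/se_i^2};
#' the pooled log-OR is the weighted mean and the pooled standard error is
#' \eqn{\sqrt{1/\sum w_i}}.
#'
#' @param estimates A list of `effect_estimate` objects (or any lists with
#'   finite `log_or` and `se` elements).
#' @return An `effect_estimate` for the pooled effect.
#' @export
fixed_effects_pool <- function(estimates) {
  ys <- vapply(estimates, `[[`, numeric(1), "log_or")
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  keep <- is.finite(ys) & is.finite(ses) & ses > 0
  if (!any(keep)) stop("no stratum with a finite standard error")
  w <- 1 / ses[keep]^2
  effect_estimate(sum(w * ys[keep]) / sum(w), sqrt(1 / sum(w)))
}

#' Random-effects pooling given a between-stratum variance
#'
#' Pools with weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}. With `tau2 = 0`
#' this reduces exactly to [fixed_effects_pool()].
#'
#' @param estimates As in [fixed_effects_pool()].
#' @param tau2 Non-negative between-stratum variance (usually the REML
#'   estimate from [heterogeneity()]).
#' @return An `effect_estimate` for the pooled effect.
#' @export
random_effects_pool <- function(estimates, tau2) {
  stopifnot(tau2 >= 0)
  ys <- vapply(estimates, `[[`, numeric(1), "log_or")
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  keep <- is.finite(ys) & is.finite(ses) & ses > 0
  if (!any(keep)) stop("no stratum with a finite standard error")
  w <- 1 / (ses[keep]^2 + tau2)
  effect_estimate(sum(w * ys[keep]) / sum(w), sqrt(1 / sum(w)))
}

#' Between-stratum heterogeneity: Cochran's Q, I-squared and REML tau-squared
#'
#' Computes Cochran's heterogeneity statistic
#' \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2} with fixed-effects weights, its
#' chi-square p-value on \eqn{k - 1} degrees of freedom, the
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} percentage, and the REML
#' estimate of the between-stratum variance \eqn{\tau^2} by the standard
#' fixed-point iteration, floored at zero.
#'
#' With fewer than two strata the convention Q = 0, df = 0, p = 1,
#' tau2 = 0 is returned.
#'
#' @param estimates A list of per-stratum `effect_estimate` objects.
#' @return A list of class `"heterogeneity_result"` with `q_stat`, `df`,
#'   `i2` (percent), `het_p`, `tau2`, and `k` (number of strata used).
#' @export
heterogeneity <- function(estimates) {
  ys <- vapply(estimates, `[[`, numeric(1), "log_or")
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  keep <- is.finite(ys) & is.finite(ses) & ses > 0
  ys <- ys[keep]; vs <- ses[keep]^2
  k <- length(ys)
  if (k < 2) {
    return(structure(list(q_stat = 0, df = 0L, i2 = 0, het_p = 1,
                          tau2 = 0, k = k),
                     class = "heterogeneity_result"))
  }
  w <- 1 / vs
  ybar <- sum(w * ys) / sum(w)
  q <- sum(w * (ys - ybar)^2)
  df <- k - 1L
  het_p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(q_stat = q, df = df, i2 = i2, het_p = het_p,
                 tau2 = reml_tau2(ys, vs), k = k),
            class = "heterogeneity_result")
}

#' REML estimate of the between-stratum variance
#'
#' Fixed-point REML iteration for the random-effects variance of a set of
#' independent estimates \eqn{y_i} with known within-stratum variances
#' \eqn{v_i}: with weights \eqn{w_i = 1/(v_i + \tau^2)} and weighted mean
#' \eqn{\hat\mu}, iterate
#' \deqn{\tau^2 \leftarrow \frac{\sum w_i^2 [(y_i - \hat\mu)^2 - v_i]}
#'   {\sum w_i^2} + \frac{1}{\sum w_i}}
#' until convergence, flooring at zero.
#'
#' @param y Numeric vector of stratum estimates (log odds ratios).
#' @param v Numeric vector of within-stratum variances (se^2).
#' @param tol Convergence tolerance on successive tau2 values.
#' @param max_iter Iteration cap.
#' @return The non-negative REML tau-squared estimate.
#' @export
reml_tau2 <- function(y, v, tol = 1e-10, max_iter = 200L) {
  stopifnot(length(y) == length(v), all(v > 0))
  if (length(y) < 2) return(0)
  tau2 <- max(0, stats::var(y) - mean(v))
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    tau2_new <- sum(w^2 * ((y - mu)^2 - v)) / sum(w^2) + 1 / sum(w)
    tau2_new <- max(0, tau2_new)
    if (abs(tau2_new - tau2) < tol) return(tau2_new)
    tau2 <- tau2_new
  }
  tau2
}

# Restricted log-likelihood of tau2 (used by tests as an independent check
# and exported so sensitivity analyses can profile it).
#' Restricted log-likelihood of the between-stratum variance
#'
#' @param tau2 Candidate non-negative between-stratum variance.
#' @param y,v Stratum estimates and within-stratum variances.
#' @return The restricted log-likelihood value at `tau2`.
#' @export
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
}

#' Stratified odds-ratio meta-analysis of one carrier table
#'
#' The central fitting function: takes a cohort-stratified set of 2x2
#' carrier tables (a [build_contingency()] result or a plain data frame
#' with columns `cohort, a, b, c, d`), estimates a per-cohort log odds
#' ratio, tests between-cohort heterogeneity, and pools by inverse-variance
#' fixed effects or, when heterogeneity is significant, REML random
#' effects.
#'
#' Strata with zero carriers in both arms carry no information about the
#' odds ratio and are dropped from pooling; strata with a zero cell (but
#' carriers somewhere) receive the Haldane--Anscombe 0.5 correction.
#'
#' Model switching: with `het_gate = "raw"` the random-effects model is
#' used when the heterogeneity p-value is below `het_alpha`. In a family of
#' tests the gate is normally applied to FDR-adjusted heterogeneity
#' p-values across the family; [meta_family()] does exactly that and
#' re-selects the model, so a standalone `or_meta()` call defaults to the
#' raw gate.
#'
#' @param contingency Data frame with columns `cohort, a, b, c, d` (per
#'   cohort: case carriers, case non-carriers, control carriers, control
#'   non-carriers), e.g. from [build_contingency()].
#' @param het_gate `"raw"` (gate on the raw heterogeneity p) — family-level
#'   FDR gating is done by [meta_family()].
#' @param het_alpha Significance threshold for the heterogeneity gate
#'   (default 0.05).
#' @param continuity Passed to [odds_ratio_2x2()].
#' @return An object of class `"or_meta"`: list with `strata` (data frame
#'   of per-cohort estimates), `fixed`, `random` (both pooled
#'   `effect_estimate`s), `het` (a `heterogeneity_result`), `model`
#'   (`"fixed"` or `"random"`), `pooled` (the selected estimate),
#'   `untestable` (logical), `k` (number of informative strata).
#' @seealso [meta_family()] for family-level FDR on joint and
#'   heterogeneity p-values, [build_contingency()] to construct the input.
#' @export
or_meta <- function(contingency, het_gate = "raw", het_alpha = 0.05,
                    continuity = "haldane") {
  tab <- as.data.frame(contingency)
  feature <- attr(contingency, "feature")
  comparison <- attr(contingency, "comparison")
  need <- c("cohort", "a", "b", "c", "d")
  if (!all(need %in% names(tab))) {
    stop("contingency must have columns cohort, a, b, c, d")
  }
  # drop strata missing an arm entirely; keep both-zero-carrier strata out
  # of pooling (no information), but report them
  informative <- (tab$a + tab$b) > 0 & (tab$c + tab$d) > 0 &
    (tab$a + tab$c) > 0
  res <- structure(list(
    feature = feature, comparison = comparison,
    strata = NULL, fixed = NULL, random = NULL, het = NULL,
    model = "fixed", pooled = NULL,
    untestable = !any(informative), k = sum(informative)
  ), class = "or_meta")
  if (res$untestable) return(res)
  use <- tab[informative, , drop = FALSE]
  ests <- lapply(seq_len(nrow(use)), function(i) {
    odds_ratio_2x2(use$a[i], use$b[i], use$c[i], use$d[i],
                   continuity = continuity)
  })
  res$strata <- data.frame(
    cohort = use$cohort, a = use$a, b = use$b, c = use$c, d = use$d,
    log_or = vapply(ests, `[[`, numeric(1), "log_or"),
    se = vapply(ests, `[[`, numeric(1), "se"),
    stringsAsFactors = FALSE
  )
  res$fixed <- fixed_effects_pool(ests)
  res$het <- heterogeneity(ests)
  res$random <- random_effects_pool(ests, res$het$tau2)
  res$model <- if (res$het$het_p < het_alpha && res$het$k >= 2) "random" else "fixed"
  res$pooled <- if (res$model == "random") res$random else res$fixed
  res
}

#' @export
print.or_meta <- function(x, ...) {
  cat("Stratified odds-ratio meta-analysis")
  if (!is.null(x$feature)) cat(" -", format(x$feature))
  cat("\n")
  if (x$untestable) {
    cat("  untestable: no informative stratum\n")
    return(invisible(x))
  }
  cat(sprintf("  %d cohort strat%s, model = %s\n", x$k,
              if (x$k == 1) "um" else "a", x$model))
  cat("  pooled "); print(x$pooled)
  cat(sprintf("  heterogeneity Q = %.3f (df %d), p = %.3g, I2 = %.1f%%, tau2 = %.4g\n",
              x$het$q_stat, x$het$df, x$het$het_p, x$het$i2, x$het$tau2))
  invisible(x)
}

#' @export
summary.or_meta <- function(object, ...) {
  print(object)
  if (!object$untestable) {
    cat("  per-cohort estimates:\n")
    s <- object$strata
    s$or <- exp(s$log_or)
    print(s, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.or_meta <- function(object, ...) {
  if (object$untestable) return(c(log_or = NA_real_))
  c(log_or = object$pooled$log_or)
}

#' @export
confint.or_meta <- function(object, parm, level = 0.95, ...) {
  if (object$untestable) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  with(object$pooled, c(log_or - z * se, log_or + z * se))
}

#' Family-level meta-analysis with FDR-gated model switching
#'
#' Runs [or_meta()] on every contingency of a test family (e.g. all genes
#' of one mutation type in one comparison), then applies
#' Benjamini--Hochberg FDR jointly: the heterogeneity p-values form one
#' family (their q-values gate the fixed/random switch at `het_alpha`), and
#' the joint p-values of the selected models form another (reported as
#' `q`). Untestable features are excluded from both FDR families.
#'
#' @param contingencies Named list of contingency tables (see [or_meta()]).
#' @param het_alpha Threshold on the heterogeneity q-value for switching to
#'   the random-effects model (default 0.05).
#' @param het_gate `"fdr"` (default, gate on FDR-adjusted heterogeneity p)
#'   or `"raw"`.
#' @param continuity Passed to [odds_ratio_2x2()].
#' @return A data frame of class `"meta_family"` with one row per feature:
#'   `feature, k, model, log_or, se, or, ci_low, ci_high, p, q, q_stat, i2,
#'   tau2, het_p, het_q, untestable`, plus the fitted `or_meta` objects in
#'   attribute `"fits"`.
#' @export
meta_family <- function(contingencies, het_alpha = 0.05,
                        het_gate = c("fdr", "raw"), continuity = "haldane") {
  het_gate <- match.arg(het_gate)
  stopifnot(length(contingencies) > 0)
  nms <- names(contingencies)
  if (is.null(nms)) nms <- as.character(seq_along(contingencies))
  fits <- lapply(contingencies, or_meta, continuity = continuity,
                 het_alpha = het_alpha)
  testable <- !vapply(fits, `[[`, logical(1), "untestable")
  het_p <- vapply(fits, function(f) if (f$untestable) NA_real_ else f$het$het_p,
                  numeric(1))
  het_q <- rep(NA_real_, length(fits))
  het_q[testable] <- bh_fdr(het_p[testable])
  gate <- if (het_gate == "fdr") het_q else het_p
  for (i in which(testable)) {
    fits[[i]]$model <- if (!is.na(gate[i]) && gate[i] < het_alpha &&
                           fits[[i]]$het$k >= 2) "random" else "fixed"
    fits[[i]]$pooled <- if (fits[[i]]$model == "random") {
      fits[[i]]$random
    } else {
      fits[[i]]$fixed
    }
  }
  p <- vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$p,
              numeric(1))
  q <- rep(NA_real_, length(fits))
  q[testable] <- bh_fdr(p[testable])
  out <- data.frame(
    feature = nms,
    k = vapply(fits, `[[`, integer(1), "k"),
    model = vapply(fits, `[[`, character(1), "model"),
    log_or = vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$log_or, numeric(1)),
    se = vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$se, numeric(1)),
    or = vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$or, numeric(1)),
    ci_low = vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$ci_low, numeric(1)),
    ci_high = vapply(fits, function(f) if (f$untestable) NA_real_ else f$pooled$ci_high, numeric(1)),
    p = p, q = q,
    q_stat = vapply(fits, function(f) if (f$untestable) NA_real_ else f$het$q_stat, numeric(1)),
    i2 = vapply(fits, function(f) if (f$untestable) NA_real_ else f$het$i2, numeric(1)),
    tau2 = vapply(fits, function(f) if (f$untestable) NA_real_ else f$het$tau2, numeric(1)),
    het_p = het_p, het_q = het_q,
    untestable = !testable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("meta_family", "data.frame")
  out
}
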