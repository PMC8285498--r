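#' Cohort-adjusted logistic regression for carrier enrichment
#'
#' Fits a binomial logistic model by iteratively reweighted least squares
#' (via `stats::glm.fit`, epsilon 1e-10, at most 100 iterations) with the
#' comparison outcome as the dependent variable and carrier status as the
#' predictor of interest, optionally adjusted for covariates such as the
#' cohort. Accepts either per-sample binary outcomes or grouped binomial
#' data (`outcome` a two-column matrix of successes/failures).
#'
#' Complete or quasi-complete separation is flagged when any fitted
#' probability is numerically 0/1 at a covariate pattern with a diverging
#' coefficient; a separated fit is reported as non-converged and should be
#' excluded from FDR families.
#'
#' @param outcome Binary vector (0/1 or logical), or a two-column matrix
#'   `cbind(successes, failures)` for grouped data.
#' @param carrier Logical/numeric carrier status per row.
#' @param covariates Optional data frame of adjustment covariates
#'   (factors/characters are expanded to treatment contrasts with the first
#'   sorted level as reference).
#' @param weights Optional per-row weights (for grouped binary outcomes).
#' @return A list of class `"carrier_glm"`: `coefficients` (data frame with
#'   `term, estimate, se, z, p`), `carrier` (an `effect_estimate` for the
#'   carrier term), `converged`, `separation_flag`, `n`, `deviance`.
#' @examples
#' # grouped 2x2: recovers the crude odds ratio exactly
#' fit <- logistic_fit(outcome = cbind(c(163, 420), c(161, 1416)),
#'                     carrier = c(1, 0))
#' exp(fit$carrier$log_or)
#' @export
logistic_fit <- function(outcome, carrier, covariates = NULL, weights = NULL) {
  if (is.matrix(outcome)) {
    stopifnot(ncol(outcome) == 2)
    n_rows <- nrow(outcome)
    tot <- rowSums(outcome)
    y <- ifelse(tot > 0, outcome[, 1] / tot, 0)
    w <- tot
  } else {
    y <- as.numeric(outcome)
    stopifnot(all(y %in% c(0, 1)))
    n_rows <- length(y)
    w <- if (is.null(weights)) rep(1, n_rows) else weights
  }
  X <- cbind(`(Intercept)` = rep(1, n_rows), carrier = as.numeric(carrier))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v)) v <- factor(v, levels = sort(unique(v)))
      if (is.factor(v)) {
        lv <- levels(droplevels(v))
        if (length(lv) < 2) next  # degenerate covariate: drop
        for (l in lv[-1]) {
          X <- cbind(X, as.numeric(v == l))
          colnames(X)[ncol(X)] <- paste0(nm, l)
        }
      } else {
        X <- cbind(X, as.numeric(v))
        colnames(X)[ncol(X)] <- nm
      }
    }
  }
  keep <- stats::complete.cases(X) & !is.na(y) & w > 0
  X <- X[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  # observed-information covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(cov))
  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(beta) > 15, na.rm = TRUE)
  z <- beta / se
  coefs <- data.frame(
    term = colnames(X), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  carrier_est <- effect_estimate(unname(beta["carrier"]), unname(se["carrier"]))
  structure(list(
    coefficients = coefs,
    carrier = carrier_est,
    converged = fit$converged && !sep,
    separation_flag = sep,
    n = sum(w),
    deviance = fit$deviance
  ), class = "carrier_glm")
}

#' @export
print.carrier_glm <- function(x, ...) {
  cat("Cohort-adjusted logistic fit (carrier term):\n  ")
  print(x$carrier)
  if (x$separation_flag) cat("  WARNING: separation detected; estimate unreliable\n")
  if (!x$converged) cat("  fit did not converge\n")
  invisible(x)
}

#' @export
coef.carrier_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 table by summation of
#' the conditional hypergeometric probabilities that do not exceed the
#' probability of the observed table (with the customary 1 + 1e-7 relative
#' tolerance on the comparison).
#'
#' @param a,b,c,d Non-negative integer cell counts (rows: group 1/2,
#'   columns: carrier/non-carrier).
#' @return The two-sided p-value; 1 for degenerate margins.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  k <- a + c       # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini--Hochberg q-values within test families
#'
#' Applies the BH step-up procedure (via `stats::p.adjust`) separately
#' within each family and returns q-values in the original order. NA
#' p-values propagate NA and do not count toward a family's size.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param family Optional vector of family labels (default: one family).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p, family = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (is.null(family)) family <- rep("all", length(p))
  stopifnot(length(family) == length(p))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f & !is.na(p))
    if (length(i)) q[i] <- stats::p.adjust(p[i], method = "BH")
  }
  q
}
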