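#' Spearman rank correlation
#'
#' Average-rank transform of both variables followed by the product-moment
#' correlation of the ranks; the two-sided p-value uses the t approximation
#' with n - 2 degrees of freedom, \code{t = rho * sqrt((n-2)/(1-rho^2))}.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return a \code{correlation_result}: list with \code{rho, p, n, method}.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant input; rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  structure(list(rho = rho, p = p, n = n, method = "spearman"),
            class = "correlation_result")
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three variables and applies the first-order partial
#' correlation formula
#' \code{(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))}; the p-value
#' uses the t approximation with n - 3 degrees of freedom.
#'
#' @param x,y variables of interest; \code{z} the variable partialled out.
#' @param z controlling variable.
#' @return a \code{correlation_result} with method \code{"partial-spearman"}.
#' @export
partial_spearman <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stopf("need at least 4 complete triples")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1)
    stopf("controlling variable perfectly correlated; partial undefined")
  rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 3)
  }
  structure(list(rho = rho, p = p, n = n, method = "partial-spearman"),
            class = "correlation_result")
}

# exact two-sided Mann-Whitney p by enumeration (no ties)
.mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  mid <- na * nb / 2
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

#' Mann-Whitney U test
#'
#' U statistic for the first group with a tie-corrected normal
#' approximation (continuity-corrected); for small samples
#' (n_a + n_b <= 12) without ties the two-sided p is computed by exact
#' enumeration of all group assignments.
#'
#' @param a,b numeric vectors, the two groups.
#' @return list with \code{U, p, n_a, n_b, exact}.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("empty group")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)
  if (n <= 12 && !has_ties) {
    p <- .mw_exact_p(a, b)
    return(list(U = u, p = p, n_a = na, n_b = nb, exact = TRUE))
  }
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sig2 <= 0) return(list(U = u, p = 1, n_a = na, n_b = nb, exact = FALSE))
  z <- (u - na * nb / 2)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
  list(U = u, p = 2 * stats::pnorm(-abs(z)), n_a = na, n_b = nb,
       exact = FALSE)
}

#' Paired t-test
#'
#' \code{t = mean(d) / (sd(d)/sqrt(n))} on the paired differences, with a
#' two-sided p on n - 1 degrees of freedom.
#'
#' @param x,y equal-length paired samples.
#' @return list with \code{t, p, df, mean_diff, n}.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  if (n < 2) stopf("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stopf("zero-variance differences; t undefined")
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), n - 1), df = n - 1,
       mean_diff = mean(d), n = n)
}

#' Two-predictor ordinary least squares with uncertainty
#'
#' Least-squares fit of \code{y ~ x1 + x2} via \code{stats::lm}, returning
#' coefficients with t-based 95% confidence intervals, R^2, the overall
#' F statistic on (2, n - 3) degrees of freedom and its p-value.
#'
#' @param y response vector.
#' @param X matrix or data.frame of two predictor columns.
#' @param conf confidence level of the intervals.
#' @return a \code{regression_result}: list with \code{coefficients} (a
#'   data.frame term/estimate/ci_lo/ci_hi/se/t/p), \code{r_squared},
#'   \code{f_stat, df1, df2, p_overall}, \code{sigma}, \code{n}.
#' @export
ols_fit <- function(y, X, conf = 0.95) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 1, nrow(X) == length(y))
  n <- length(y)
  if (n <= ncol(X) + 1) stopf("need n > k + 1 observations")
  if (qr(cbind(1, as.matrix(X)))$rank < ncol(X) + 1)
    stopf("rank-deficient design")
  dat <- data.frame(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf)
  co <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   ci_lo = ci[, 1], ci_hi = ci[, 2],
                   se = sm$coefficients[, 2],
                   t = sm$coefficients[, 3],
                   p = sm$coefficients[, 4],
                   row.names = NULL, stringsAsFactors = FALSE)
  fs <- sm$fstatistic
  structure(list(coefficients = co,
                 r_squared = sm$r.squared,
                 f_stat = unname(fs[1]), df1 = unname(fs[2]),
                 df2 = unname(fs[3]),
                 p_overall = stats::pf(fs[1], fs[2], fs[3],
                                       lower.tail = FALSE),
                 sigma = sm$sigma, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): R^2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$n, x$r_squared, x$df1, x$df2, x$f_stat, x$p_overall))
  print(x$coefficients, digits = 4)
  invisible(x)
}

.band5 <- c("theta", "alpha", "low_beta", "high_beta", "low_gamma")

#' Band-by-domain correlation grid
#'
#' Spearman correlation between each band's maximum normalized power and
#' the stimulation efficacy in each symptom domain. Bradykinesia-rigidity
#' and tremor use per-side power against the contralateral hemibody
#' improvement (tremor restricted to sides with a positive baseline);
#' axial improvement, which is not lateralized, is paired with each
#' patient's bilateral-average power.
#'
#' @param cohort analysis-ready side table with per-band \code{power_*}
#'   columns, \code{eff_brady, eff_tremor, eff_axial} (percent),
#'   \code{tremor_included} and \code{patient_id}.
#' @param holm apply a Holm correction across the grid (off by default, to
#'   mirror raw per-cell reporting).
#' @return data.frame with columns \code{domain, band, rho, p, n}.
#' @export
run_table2 <- function(cohort, holm = FALSE) {
  cells <- list()
  push <- function(domain, band, x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stopf("domain '%s' has fewer than 3 usable sides", domain)
    r <- spearman_cor(x[ok], y[ok])
    cells[[length(cells) + 1]] <<- data.frame(
      domain = domain, band = band, rho = r$rho, p = r$p, n = r$n,
      stringsAsFactors = FALSE)
  }
  for (band in .band5) {
    pw <- cohort[[paste0("power_", band)]]
    push("brady_rigidity", band, pw, cohort$eff_brady)
    tr <- cohort$tremor_included
    push("tremor", band, pw[tr], cohort$eff_tremor[tr])
    agg <- stats::aggregate(cbind(pw = pw, eff = cohort$eff_axial),
                            by = list(patient_id = cohort$patient_id), mean)
    push("axial", band, agg$pw, agg$eff)
  }
  out <- do.call(rbind, cells)
  if (holm) out$p_holm <- stats::p.adjust(out$p, "holm")
  out
}

#' Covariate association table
#'
#' Associations between baseline clinical characteristics and (i) the
#' bradykinesia-rigidity stimulation efficacy, (ii) maximum low-beta power,
#' (iii) maximum high-beta power. Continuous covariates use Spearman
#' correlation; dichotomous ones (sex, dyskinesia) use the Mann-Whitney U
#' test. Person-bound covariates are analyzed per patient with
#' bilateral-average power and efficacy.
#'
#' @param cohort analysis-ready side table (see \code{\link{run_table2}})
#'   with covariate columns \code{age, sex, duration, dyskinesia, ledd,
#'   updrs3_on_med, updrs3_off_med, levodopa_response}.
#' @return data.frame with columns \code{covariate, measure, method, rho, p,
#'   n}.
#' @export
run_table3 <- function(cohort) {
  agg <- stats::aggregate(
    cohort[, c("power_low_beta", "power_high_beta", "eff_brady")],
    by = list(patient_id = cohort$patient_id), mean)
  meta <- unique(cohort[, c("patient_id", "age", "sex", "duration",
                            "dyskinesia", "ledd", "updrs3_on_med",
                            "updrs3_off_med", "levodopa_response")])
  per_pat <- merge(agg, meta, by = "patient_id")
  measures <- c(eff_brady = "eff_brady", power_low_beta = "power_low_beta",
                power_high_beta = "power_high_beta")
  cont <- c("age", "duration", "ledd", "updrs3_off_med", "updrs3_on_med",
            "levodopa_response")
  dich <- c("sex", "dyskinesia")
  rows <- list()
  for (cv in c(cont, dich)) for (ms in names(measures)) {
    x <- per_pat[[cv]]
    y <- per_pat[[measures[ms]]]
    if (cv %in% cont) {
      if (stats::sd(x, na.rm = TRUE) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, measure = ms, method = "spearman",
          rho = NA_real_, p = NA_real_, n = sum(is.finite(x) & is.finite(y)),
          stringsAsFactors = FALSE)
        next
      }
      r <- spearman_cor(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, measure = ms, method = "spearman",
        rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
    } else {
      g <- as.factor(x)
      if (nlevels(g) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          covariate = cv, measure = ms, method = "mann-whitney",
          rho = NA_real_, p = NA_real_, n = length(y),
          stringsAsFactors = FALSE)
        next
      }
      mw <- mann_whitney(y[g == levels(g)[1]], y[g == levels(g)[2]])
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, measure = ms, method = "mann-whitney",
        rho = NA_real_, p = mw$p, n = length(y), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
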