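MODEL_REFERENCES <- c(site = "US-Colorado", sex = "female", fdr = "no",
                      hla_group = "DR4-DQ8/DR4-DQ8")

#' Fit the multivariate Poisson rate-ratio model
#'
#' Maximum-likelihood log-link Poisson regression of per-child episode
#' counts on categorical covariates, with `log(person_years)` as offset —
#' so exponentiated coefficients are rate ratios relative to each factor's
#' reference level (site US-Colorado, female, no first-degree relative
#' with T1D, HLA DR4-DQ8/DR4-DQ8).  95% confidence intervals are Wald
#' intervals on the log scale (estimate +/- 1.96 standard errors).  For
#' every factor a joint Wald chi-square tests the null that all of its
#' level contrasts are zero, with `levels - 1` degrees of freedom.
#'
#' Each modeled factor must have at least two observed levels.  A level
#' with zero events (complete separation on the count scale) is reported
#' with an infinite confidence bound and a warning.  Convergence uses a
#' deviance tolerance of 1e-8 with at most 100 iterations; non-convergence
#' is an error carrying the iteration count.
#'
#' @param frame Model frame from [aggregate_model_frame()] (columns
#'   `count`, `person_years` plus the factors).
#' @param factors Character vector of covariate columns to model.
#' @param conf_level Confidence level for the rate-ratio intervals.
#' @return Object of class `rate_model_result`: list with `coefficients`
#'   (data.frame: `factor`, `level`, `reference`, `rate_ratio`, `ci_low`,
#'   `ci_high`), `wald` (data.frame: `factor`, `chi_square`, `df`,
#'   `p_value`), `converged`, `iterations` and the underlying `glm` fit.
#' @export
fit_poisson_rate_model <- function(frame,
                                   factors = c("site", "sex", "fdr",
                                               "hla_group"),
                                   conf_level = 0.95) {
  if (length(factors) && !all(factors %in% names(frame))) {
    stop_input("model frame lacks factor columns: ",
               paste(setdiff(factors, names(frame)), collapse = ", "))
  }
  if (nrow(frame) == 0 || sum(frame$person_years) <= 0) {
    stop_input("model frame has no person-time")
  }
  canonical <- list(site = SITE_LEVELS, sex = SEX_LEVELS, fdr = FDR_LEVELS,
                    hla_group = HLA_LEVELS)
  for (f in factors) {
    obs <- unique(as.character(frame[[f]]))
    if (length(obs) < 2) {
      stop_input("factor '", f, "' has a single observed level ('",
                 obs, "'); rate ratios need at least two",
                 class = "degenerate_factor_error")
    }
    lev <- if (f %in% names(canonical)) {
      intersect(canonical[[f]], obs)
    } else sort(obs)
    ref <- MODEL_REFERENCES[[f]] %||% lev[1]
    if (ref %in% lev) lev <- c(ref, setdiff(lev, ref))
    frame[[f]] <- factor(frame[[f]], levels = lev)
  }
  fml <- if (length(factors)) {
    stats::reformulate(factors, response = "count")
  } else count ~ 1
  fit <- stats::glm(fml, family = stats::poisson(), data = frame,
                    offset = log(person_years),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    stop_input("Poisson fit did not converge in ", fit$iter, " iterations",
               class = "convergence_error")
  }
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  coef_rows <- list()
  wald_rows <- list()
  for (f in factors) {
    lev <- levels(frame[[f]])
    ref <- lev[1]
    coef_rows[[length(coef_rows) + 1]] <- data.frame(
      factor = f, level = ref, reference = ref, rate_ratio = 1,
      ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE)
    nm <- paste0(f, lev[-1])
    for (k in seq_along(nm)) {
      est <- b[[nm[k]]]
      lo <- exp(est - z * se[[nm[k]]])
      hi <- exp(est + z * se[[nm[k]]])
      if (sum(frame$count[frame[[f]] == lev[-1][k]]) == 0) {
        warning("level '", lev[-1][k], "' of factor '", f,
                "' has zero events; confidence bound is infinite",
                call. = FALSE)
        lo <- 0
        hi <- Inf
      }
      coef_rows[[length(coef_rows) + 1]] <- data.frame(
        factor = f, level = lev[-1][k], reference = ref,
        rate_ratio = exp(est), ci_low = lo, ci_high = hi,
        stringsAsFactors = FALSE)
    }
    W <- as.numeric(t(b[nm]) %*% solve(V[nm, nm, drop = FALSE]) %*% b[nm])
    wald_rows[[length(wald_rows) + 1]] <- data.frame(
      factor = f, chi_square = W, df = length(nm),
      p_value = stats::pchisq(W, df = length(nm), lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  empty_coef <- data.frame(factor = character(0), level = character(0),
                           reference = character(0),
                           rate_ratio = numeric(0), ci_low = numeric(0),
                           ci_high = numeric(0), stringsAsFactors = FALSE)
  empty_wald <- data.frame(factor = character(0), chi_square = numeric(0),
                           df = integer(0), p_value = numeric(0),
                           stringsAsFactors = FALSE)
  structure(list(coefficients = if (length(coef_rows)) {
                   do.call(rbind, coef_rows)
                 } else empty_coef,
                 wald = if (length(wald_rows)) {
                   do.call(rbind, wald_rows)
                 } else empty_wald,
                 converged = fit$converged, iterations = fit$iter,
                 conf_level = conf_level, fit = fit),
            class = "rate_model_result")
}

#' @export
print.rate_model_result <- function(x, ...) {
  cat("Poisson rate-ratio model (log link, person-years offset)\n")
  tab <- x$coefficients
  tab$rate_ratio <- sprintf("%.3f", tab$rate_ratio)
  tab$ci <- ifelse(is.na(tab$ci_low), "ref",
                   sprintf("%.3f - %.3f", tab$ci_low, tab$ci_high))
  print(tab[, c("factor", "level", "rate_ratio", "ci")], row.names = FALSE)
  cat("\nPer-factor Wald tests:\n")
  w <- x$wald
  w$chi_square <- sprintf("%.2f", w$chi_square)
  w$p_value <- format.pval(w$p_value, digits = 3)
  print(w, row.names = FALSE)
  invisible(x)
}

#' Flatten a fitted rate model to a table
#'
#' @param result A `rate_model_result`.
#' @return data.frame with one row per factor level: `factor`, `level`,
#'   `reference`, `rate_ratio`, `ci_low`, `ci_high`, `wald_chi_square`,
#'   `df`, `p_value` (test columns repeated within factor).
#' @export
rate_model_table <- function(result) {
  stopifnot(inherits(result, "rate_model_result"))
  tab <- result$coefficients
  m <- match(tab$factor, result$wald$factor)
  tab$wald_chi_square <- result$wald$chi_square[m]
  tab$df <- result$wald$df[m]
  tab$p_value <- result$wald$p_value[m]
  tab
}
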