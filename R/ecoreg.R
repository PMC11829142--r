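# Ecological regression: OLS of per-area distance to the nearest
# research-active facility on six area sociodemographic characteristics.

.eco_regressors <- c("mean_age", "pct_male", "pct_ethnic_majority",
                     "imd_decile", "rural", "coastal_border")

#' Ecological linear model of distance on area sociodemographics
#'
#' Ordinary least squares (via [stats::lm()]) of an area-level distance
#' response on exactly six regressors — area mean age, percentage male,
#' percentage in the majority ethnic group, deprivation decile (1 = most
#' deprived, entered as a single linear term), rural flag and coastal/border
#' flag (0/1) — plus an intercept. Classical (non-robust) standard errors and
#' t-distribution p-values. Unweighted by default; pass `weights` (e.g. area
#' population) for a weighted fit.
#'
#' @param data Data frame containing `response` and the six regressors, e.g.
#'   the area table joined with an [access_table()] column.
#' @param response Name of the response column (km), default `"d_active"`;
#'   a travel-time column can be supplied through the same interface.
#' @param weights Optional non-negative case weights.
#' @return An object of class `eco_fit`: list with `coefficients` (data
#'   frame: term, estimate, std_error, p_value — intercept reported as
#'   `"constant"`), `n_areas`, `r_squared`, `sigma`, and the underlying `lm`
#'   fit in `$fit`.
#' @export
fit_distance_model <- function(data, response = "d_active", weights = NULL) {
  miss <- setdiff(c(response, .eco_regressors), names(data))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  p <- length(.eco_regressors)
  if (nrow(data) <= p + 1)
    stop("need more areas than regressors + 1")
  fm <- stats::reformulate(.eco_regressors, response = response)
  fit <- if (is.null(weights)) stats::lm(fm, data = data)
         else stats::lm(fm, data = data, weights = weights)
  if (fit$rank < p + 1) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  terms <- rownames(ct)
  terms[terms == "(Intercept)"] <- "constant"
  coefs <- data.frame(term = terms, estimate = ct[, 1], std_error = ct[, 2],
                      p_value = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  # intercept last, mirroring the conventional regression-table layout
  coefs <- coefs[c(which(coefs$term != "constant"), which(coefs$term == "constant")), ]
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, n_areas = nrow(data),
                 r_squared = sm$r.squared, sigma = sm$sigma, fit = fit),
            class = "eco_fit")
}

#' @export
print.eco_fit <- function(x, ...) {
  cat(sprintf("ecological OLS fit: %d areas, R^2 = %.3f, residual SD = %.2f km\n",
              x$n_areas, x$r_squared, x$sigma))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 3)
  tab$std_error <- round(tab$std_error, 3)
  tab$p_value <- format.pval(tab$p_value, digits = 3, eps = 0.001)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.eco_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.eco_fit <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level)
  rownames(ci)[rownames(ci) == "(Intercept)"] <- "constant"
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.eco_fit <- function(x, ...) x$coefficients
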