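# Pooling of published per-trial age/sex summaries and the shared statistical
# tests (Welch's t from summary statistics, chi-squared with trend variant,
# median/IQR -> mean/SD conversion).

#' Approximate mean and SD from a median and interquartile range
#'
#' Implements the quantile-based approximation of Wan et al. (2014, BMC Med
#' Res Methodol 14:135), scenario C3: `mean = (q1 + median + q3) / 3` and
#' `sd = (q3 - q1) / (2 * z((0.75 n - 0.125) / (n + 0.25)))` with `z` the
#' standard-normal quantile. As `n` grows the divisor tends to 2 * z(0.75)
#' = 1.349, the familiar IQR/1.35 rule. Exact for symmetric three-point
#' inputs; the mean is location-equivariant and the sd location-invariant
#' and scale-equivariant.
#'
#' @param median,q1,q3 Reported median and quartiles (must satisfy
#'   `q1 <= median <= q3`).
#' @param n Sample size (>= 2).
#' @return List with `mean` and `sd` (vectors if the inputs are vectors).
#' @examples
#' mean_sd_from_median_iqr(50, 40, 60, 1e6)  # mean 50, sd ~ 14.83
#' @export
mean_sd_from_median_iqr <- function(median, q1, q3, n) {
  if (any(q3 < q1)) stop("q3 must be >= q1")
  if (any(median < q1 | median > q3)) stop("median must lie in [q1, q3]")
  if (any(n < 2)) stop("n must be >= 2")
  z <- stats::qnorm((0.75 * n - 0.125) / (n + 0.25))
  list(mean = (q1 + median + q3) / 3, sd = (q3 - q1) / (2 * z))
}

#' Pool per-trial summary statistics by subtype
#'
#' Trials reporting median/quartiles are first converted with
#' [mean_sd_from_median_iqr()]. Within each subtype the pooled mean is the
#' n-weighted mean and the pooled variance uses the exact grouped-data
#' identity `sum((n_i - 1) s_i^2 + n_i (xbar_i - xbar)^2) / (sum(n_i) - 1)`,
#' so that when every trial reports the mean/SD of its raw enrolees the
#' pooled values equal the statistics of the concatenated raw data. The male
#' percentage is `100 * sum(n_male) / sum(n)`.
#'
#' @param summaries Trial summary data frame (columns `trial_id`, `subtype`,
#'   `n`, `age_mean`, `age_sd`, `age_median`, `age_q1`, `age_q3`, `n_male`,
#'   and any metadata used by `filter`).
#' @param filter Optional predicate `function(summaries)` returning a logical
#'   vector, or a logical vector; rows failing it are dropped before pooling.
#' @return Data frame with one row per subtype: `subtype`, `n_trials`,
#'   `n_total`, `pooled_mean_age`, `pooled_sd_age`, `pct_male`.
#' @export
pool_trials <- function(summaries, filter = NULL) {
  s <- summaries
  if (is.function(filter)) s <- s[filter(s), , drop = FALSE]
  else if (!is.null(filter)) s <- s[filter, , drop = FALSE]
  if (nrow(s) == 0) stop("no trials left after filtering")
  conv <- is.na(s$age_mean)
  if (any(conv)) {
    w <- mean_sd_from_median_iqr(s$age_median[conv], s$age_q1[conv],
                                 s$age_q3[conv], s$n[conv])
    s$age_mean[conv] <- w$mean
    s$age_sd[conv] <- w$sd
  }
  if (any(s$n_male > s$n | s$n_male < 0)) stop("need 0 <= n_male <= n")
  one <- function(g) {
    N <- sum(g$n)
    m <- sum(g$n * g$age_mean) / N
    v <- sum((g$n - 1) * g$age_sd^2 + g$n * (g$age_mean - m)^2) / (N - 1)
    data.frame(subtype = g$subtype[1], n_trials = nrow(g), n_total = N,
               pooled_mean_age = m, pooled_sd_age = sqrt(v),
               pct_male = 100 * sum(g$n_male) / N, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(s, s$subtype), one))
  rownames(out) <- NULL
  out[order(out$subtype), , drop = FALSE]
}

#' Welch's two-sample t-test from summary statistics
#'
#' Two-tailed Welch's t with Welch-Satterthwaite degrees of freedom, computed
#' from group means, SDs and sizes (no raw data required). If both SDs are
#' zero: p = 1 when the means are equal (reported with a message), otherwise
#' the statistic is infinite and p = 0.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List: `statistic` (t), `df`, `p.value`. Vectorised.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("need n >= 2 in both groups")
  if (any(sd1 < 0 | sd2 < 0)) stop("sd must be >= 0")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  degenerate <- se2 == 0
  if (any(degenerate & mean1 == mean2))
    message("both SDs zero with equal means: p = 1 by convention")
  t <- ifelse(degenerate, ifelse(mean1 == mean2, 0, Inf * sign(mean1 - mean2)),
              (mean1 - mean2) / sqrt(se2))
  df <- ifelse(degenerate, n1 + n2 - 2,
               se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  list(statistic = t, df = df, p.value = p)
}

#' Pearson chi-squared test on a 2 x k table, with trend variant
#'
#' Pearson's chi-squared without continuity correction (also for 2 x 2
#' tables; a `correct = TRUE` flag restores the Yates correction). With
#' `trend = TRUE`, a Cochran-Armitage test for trend in the proportion
#' `counts[1, ] / colSums(counts)` across ordered columns with equally
#' spaced scores 1..k.
#'
#' @param counts 2 x k matrix of non-negative counts; no all-zero row or
#'   column, and all expected counts must be positive.
#' @param trend Use the Cochran-Armitage trend test (requires ordered
#'   columns).
#' @param correct Apply the Yates continuity correction (2 x 2 only;
#'   default off).
#' @return List: `statistic`, `df`, `p.value`.
#' @export
chisq_2xk <- function(counts, trend = FALSE, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must have 2 rows")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column in counts")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("all expected counts must be > 0")
  if (trend) {
    k <- ncol(counts)
    if (k < 2) stop("trend test needs k >= 2 columns")
    # prop.trend.test warns on perfectly flat/linear proportions (its internal
    # lm fits exactly); the statistic and p-value remain well defined
    ht <- suppressWarnings(
      stats::prop.trend.test(counts[1, ], colSums(counts), score = seq_len(k)))
  } else {
    ht <- stats::chisq.test(counts, correct = correct)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Representativeness of pooled trial enrolees against the registry
#'
#' For each subtype present on both sides, compares the pooled enrolee mean
#' age with the registry mean age at diagnosis (Welch's t) and the enrolee
#' male percentage with the registry male percentage (2 x k chi-squared on
#' the two-sample sex table). Scenarios restrict which trials are pooled:
#' `"all"`, `"first_line"`, `"no_age_limit"` (trials without age-restricting
#' eligibility) and `"phase2"`.
#'
#' @param trial_summaries Trial summary table (see [pool_trials()]), with
#'   logical `first_line`, `age_restricted` and character `phase` metadata.
#' @param patients Registry data frame with `subtype`, `age`, `sex`.
#' @param scenario One of `"all"`, `"first_line"`, `"no_age_limit"`,
#'   `"phase2"`.
#' @return Data frame, one row per subtype: pooled and population n, mean
#'   ages, the age difference (pooled minus population; negative means
#'   enrolees are younger) with its p-value, male percentages and their
#'   difference (percentage points) with its p-value.
#' @export
representativeness_report <- function(trial_summaries, patients,
                                      scenario = c("all", "first_line",
                                                   "no_age_limit", "phase2")) {
  scenario <- match.arg(scenario)
  keep <- switch(scenario,
                 all = rep(TRUE, nrow(trial_summaries)),
                 first_line = trial_summaries$first_line,
                 no_age_limit = !trial_summaries$age_restricted,
                 phase2 = trial_summaries$phase == "II")
  pooled <- pool_trials(trial_summaries, keep)
  subtypes <- intersect(pooled$subtype, unique(patients$subtype))
  if (length(subtypes) == 0) stop("no subtype present in both trials and registry")
  rows <- lapply(subtypes, function(s) {
    po <- pooled[pooled$subtype == s, ]
    pop <- patients[patients$subtype == s, ]
    if (nrow(pop) < 2) stop(sprintf("registry side empty or n < 2 for '%s'", s))
    tt <- welch_t(po$pooled_mean_age, po$pooled_sd_age, po$n_total,
                  mean(pop$age), stats::sd(pop$age), nrow(pop))
    n_male_pop <- sum(pop$sex == "M")
    sex_tab <- rbind(c(round(po$n_total * po$pct_male / 100),
                       round(po$n_total * (1 - po$pct_male / 100))),
                     c(n_male_pop, nrow(pop) - n_male_pop))
    ct <- chisq_2xk(sex_tab)
    data.frame(
      subtype = s, scenario = scenario,
      n_trials = po$n_trials, n_enrolled = po$n_total, n_population = nrow(pop),
      mean_age_trials = po$pooled_mean_age, mean_age_population = mean(pop$age),
      age_diff = po$pooled_mean_age - mean(pop$age), age_p = tt$p.value,
      pct_male_trials = po$pct_male,
      pct_male_population = 100 * n_male_pop / nrow(pop),
      male_diff_pp = po$pct_male - 100 * n_male_pop / nrow(pop),
      male_p = ct$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
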