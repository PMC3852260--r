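#' Inter-group comparison (Mann-Whitney U)
#'
#' Rank-sum comparison of a node metric between two groups, as used for
#' all inter-group contrasts. Exact null distribution for small samples
#' without ties, normal approximation with continuity and tie correction
#' otherwise (the default behavior of [stats::wilcox.test]).
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return List with `U` (the Mann-Whitney U statistic for `values_a`) and
#'   `p` (two-sided).
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Intra-group paired comparison (Wilcoxon signed rank)
#'
#' @param values_a,values_b numeric vectors of equal length, paired by
#'   index. Zero differences are dropped before ranking; if all
#'   differences are zero the result is the degenerate `p = 1`.
#' @return List with `V` (signed-rank statistic, `NA` in the degenerate
#'   case) and `p` (two-sided).
#' @export
compare_paired <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(values_a) == 0L) {
    stop("paired vectors must be non-empty", call. = FALSE)
  }
  d <- values_a - values_b
  if (all(d == 0)) return(list(V = NA_real_, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            paired = TRUE))
  list(V = unname(wt$statistic), p = wt$p.value)
}

#' Median split into LOW and HIGH groups
#'
#' Rank-based dichotomization guaranteeing group sizes differ by at most
#' one: values are sorted ascending with stable order, the lower half is
#' `LOW`, the upper half `HIGH`; for odd n the middle item goes to `LOW`.
#'
#' @param values numeric vector, length >= 2, not all identical.
#' @return Character vector of `"LOW"`/`"HIGH"` labels aligned to `values`.
#' @export
median_split <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least two values to split", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  ord <- order(values)  # stable: ties keep input order
  labels <- character(n)
  n_low <- ceiling(n / 2)
  labels[ord[seq_len(n_low)]] <- "LOW"
  labels[ord[seq(n_low + 1L, n)]] <- "HIGH"
  labels
}

#' Survival-analysis eligibility filter
#'
#' Applies the cohort eligibility rules in order: (a) exclude patients
#' with less than 5 years of follow-up and no relapse event (a relapse
#' before 5 years is retained); (b) exclude patients with a concurrent
#' cancer at diagnosis; (c) among the remaining patients, exclude nodes
#' whose DC percentage falls at or outside the 5th/95th percentile of the
#' remaining cohort (percentiles by linear interpolation over order
#' statistics; only the strict interior is retained).
#'
#' @param cohort data frame with columns `pct_dcs`, `followup_years`,
#'   `relapse_event`, `concurrent_cancer` (any other columns are carried
#'   through).
#' @param min_followup_years minimum event-free follow-up (default 5).
#' @param center_range central quantile range retained (default 0.90).
#' @return The eligible subset of `cohort`, row order preserved, with a
#'   logical attribute-free result (just the filtered data frame).
#' @export
filter_survival_cohort <- function(cohort, min_followup_years = 5,
                                   center_range = 0.90) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty data frame", call. = FALSE)
  }
  required <- c("pct_dcs", "followup_years", "relapse_event",
                "concurrent_cancer")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep_fu <- cohort$followup_years >= min_followup_years |
    cohort$relapse_event
  keep_cc <- !cohort$concurrent_cancer
  pre <- cohort[keep_fu & keep_cc, , drop = FALSE]
  if (nrow(pre) == 0L) return(pre)
  tail_p <- (1 - center_range) / 2
  if (tail_p <= 0) return(pre)
  q <- stats::quantile(pre$pct_dcs, probs = c(tail_p, 1 - tail_p),
                       type = 7, names = FALSE)
  pre[pre$pct_dcs > q[1L] & pre$pct_dcs < q[2L], , drop = FALSE]
}

#' Kaplan-Meier curves and log-rank test for a median-split cohort
#'
#' Product-limit survival estimates per stratum (patients without an
#' event are censored at last follow-up) and the standard two-group
#' log-rank (Mantel-Cox) test with hypergeometric variance; the p-value
#' is two-sided from the chi-square distribution with 1 df.
#'
#' @param time numeric vector of disease-free follow-up times (years, > 0).
#' @param event logical vector: `TRUE` = relapse observed.
#' @param labels stratum labels (e.g. from [median_split]); exactly two
#'   distinct values, each present at least once.
#' @return List with `fit` (a [survival::survfit] object), `chisq`
#'   (log-rank statistic), `p` (two-sided), and `strata` (the two labels
#'   in the order used).
#' @export
km_logrank <- function(time, event, labels) {
  stopifnot(length(time) == length(event),
            length(time) == length(labels))
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop("exactly two non-empty strata are required", call. = FALSE)
  }
  grp <- factor(labels, levels = sort(lev))
  srv <- survival::Surv(time, as.integer(event))
  fit <- survival::survfit(srv ~ grp)
  sd <- survival::survdiff(srv ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = p,
       strata = levels(grp))
}

#' Linear association between two node metrics
#'
#' Ordinary least squares of `y` on `x`, as used for the
#' clustering-versus-maturity association. `R2` is the squared Pearson
#' correlation; the slope p-value comes from the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` not constant.
#' @return List with `slope`, `intercept`, `r_squared`, `p`.
#' @export
linear_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]))
}
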