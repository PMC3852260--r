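# Exact two-sided Mann-Whitney p by enumeration of all rank assignments,
# used as an independent oracle on tiny inputs.
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    av <- pooled[idx]; bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2L, u_of)
  center <- na * (n - na) / 2
  mean(abs(us - center) >= abs(obs - center) - 1e-9)
}

test_that("Mann-Whitney comparison matches exact enumeration on tiny samples", {
  r <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, enumerate_mw_p(c(1, 2), c(3, 4)))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)

  r2 <- compare_groups(5, c(1, 2, 3))
  expect_equal(r2$p, enumerate_mw_p(5, c(1, 2, 3)))

  set.seed(81)
  for (i in 1:10) {
    a <- round(rnorm(sample(2:5, 1)), 3)
    b <- round(rnorm(sample(2:5, 1)), 3)
    expect_equal(compare_groups(a, b)$p, enumerate_mw_p(a, b),
                 tolerance = 1e-9)
  }

  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("paired comparison handles signs, zeros and minimal n", {
  r <- compare_paired(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$V, 0)
  expect_equal(r$p, 2 / 8)  # all three signs negative: 2 of 2^3 patterns

  expect_equal(compare_paired(c(3, 1, 4), c(3, 1, 4))$p, 1)
  expect_equal(compare_paired(1, 2)$p, 1)
  expect_error(compare_paired(1:3, 1:2), "equal length")
})

test_that("median split halves the cohort with the odd middle going LOW", {
  expect_identical(median_split(c(1, 2, 3, 4)),
                   c("LOW", "LOW", "HIGH", "HIGH"))
  expect_identical(median_split(c(3, 1, 4, 2)),
                   c("HIGH", "LOW", "HIGH", "LOW"))
  expect_identical(median_split(c(1, 2, 3)), c("LOW", "LOW", "HIGH"))
  expect_error(median_split(c(5, 5, 5)), "degenerate")

  set.seed(91)
  for (i in 1:20) {
    v <- rnorm(sample(2:25, 1))
    lab <- median_split(v)
    expect_lte(abs(sum(lab == "LOW") - sum(lab == "HIGH")), 1L)
    expect_lte(max(v[lab == "LOW"]), min(v[lab == "HIGH"]))
  }
})

test_that("eligibility filter applies follow-up, concurrency and percentile gates", {
  cohort <- data.frame(patient_id = sprintf("P%02d", 1:20),
                       pct_dcs = 1:20, followup_years = 6,
                       relapse_event = FALSE, concurrent_cancer = FALSE)
  kept <- filter_survival_cohort(cohort)
  # 5th/95th percentiles of 1..20 are 1.95 and 19.05; 1 and 20 fall outside
  expect_identical(kept$pct_dcs, 2:19)

  # early relapse retained, short event-free follow-up excluded
  cohort$followup_years[5] <- 3.0; cohort$relapse_event[5] <- TRUE
  cohort$followup_years[6] <- 3.0
  cohort$concurrent_cancer[7] <- TRUE
  kept2 <- filter_survival_cohort(cohort)
  expect_true("P05" %in% kept2$patient_id)
  expect_false("P06" %in% kept2$patient_id)
  expect_false("P07" %in% kept2$patient_id)

  expect_error(filter_survival_cohort(cohort[0, ]), "non-empty")
})

test_that("log-rank statistic matches the hand-tabulated 2x2 computation", {
  # A: events at 1 and 2; B: censored at 3 and 3.
  # Event time 1: n=4, E_A=1/2, V=1/4; time 2: n=3, E_A=1/3, V=2/9.
  # O-E = 7/6, V = 17/36, chi-square = 49/17.
  r <- km_logrank(time = c(1, 2, 3, 3),
                  event = c(TRUE, TRUE, FALSE, FALSE),
                  labels = c("A", "A", "B", "B"))
  expect_equal(r$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(r$p, pchisq(49 / 17, 1, lower.tail = FALSE))

  # exchangeable strata -> zero statistic
  r0 <- km_logrank(time = c(1, 2, 1, 2), event = rep(TRUE, 4),
                   labels = c("L", "L", "H", "H"))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)

  expect_error(km_logrank(1:3, c(TRUE, TRUE, TRUE), c("A", "A", "A")),
               "two non-empty strata")
})

test_that("KM curves are proper survival functions", {
  set.seed(101)
  time <- rexp(40, 0.2); event <- time < 8
  time <- pmin(time, 8)
  r <- km_logrank(time, event, rep(c("L", "H"), 20))
  s <- summary(r$fit)
  for (g in unique(s$strata)) {
    surv <- s$surv[s$strata == g]
    expect_true(all(diff(surv) <= 1e-12))
    expect_lte(max(surv), 1)
    expect_gte(min(surv), 0)
  }
})

test_that("linear association recovers exact, null and symmetric cases", {
  x <- 1:10
  r <- linear_assoc(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)

  r2 <- linear_assoc(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r_squared, 0)

  set.seed(111)
  n <- 50
  r2s <- replicate(200, linear_assoc(rnorm(n), rnorm(n))$r_squared)
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.3)

  expect_error(linear_assoc(rep(1, 5), rnorm(5)), "constant")
})
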