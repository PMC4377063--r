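test_that("one-factor fits equal crude rate ratios in closed form", {
  frame <- data.frame(
    child_id = c("a", "b"), count = c(10L, 30L), person_years = c(100, 100),
    site = c("US-Colorado", "Europe-Finland"), sex = "female", fdr = "no",
    hla_group = "DR4-DQ8/DR4-DQ8", stringsAsFactors = FALSE)
  fit <- fit_poisson_rate_model(frame, factors = "site")
  rr <- fit$coefficients$rate_ratio[fit$coefficients$level ==
                                      "Europe-Finland"]
  expect_equal(rr, 3, tolerance = 1e-6)
  # reference level is pinned at 1
  expect_equal(fit$coefficients$rate_ratio[fit$coefficients$level ==
                                             "US-Colorado"], 1)
  # 1-df Wald equals the squared coefficient z statistic
  z <- summary(fit$fit)$coefficients["siteEurope-Finland", "z value"]
  expect_equal(fit$wald$chi_square, z^2, tolerance = 1e-6)
  expect_equal(fit$wald$df, 1)
  # crude RR with unequal exposures: (20/50) / (10/100) = 4
  frame2 <- frame
  frame2$count <- c(10L, 20L)
  frame2$person_years <- c(100, 50)
  fit2 <- fit_poisson_rate_model(frame2, factors = "site")
  expect_equal(fit2$coefficients$rate_ratio[2], 4, tolerance = 1e-6)
})

test_that("intercept-only structure recovers the pooled rate", {
  frame <- data.frame(
    child_id = letters[1:4], count = c(2L, 3L, 4L, 1L),
    person_years = c(4, 4, 2, 2),
    site = "US-Colorado", sex = c("female", "male", "female", "male"),
    fdr = "no", hla_group = "DR4-DQ8/DR4-DQ8", stringsAsFactors = FALSE)
  # with identical covariates a factor is degenerate and refused
  expect_error(fit_poisson_rate_model(frame, factors = "site"),
               class = "degenerate_factor_error")
  # intercept-only: fitted rate is total events over total person-time
  fit0 <- fit_poisson_rate_model(frame, factors = character(0))
  expect_equal(exp(stats::coef(fit0$fit))[["(Intercept)"]],
               sum(frame$count) / sum(frame$person_years),
               tolerance = 1e-8)
  # the single modeled factor with a null effect leaves the pooled rate:
  # fitted rate at reference = events/person-time within the sex groups
  fit <- fit_poisson_rate_model(frame, factors = "sex")
  lam_f <- exp(stats::coef(fit$fit))[["(Intercept)"]]
  expect_equal(lam_f, (2 + 4) / (4 + 2), tolerance = 1e-6)
})

test_that("wald intervals, ci ordering and zero-event separation handling", {
  set.seed(20)
  n <- 400
  frame <- data.frame(
    child_id = sprintf("c%d", 1:n),
    person_years = 4,
    site = sample(c("US-Colorado", "Europe-Finland", "Europe-Sweden"), n,
                  TRUE),
    sex = sample(c("female", "male"), n, TRUE),
    fdr = "no", hla_group = "DR4-DQ8/DR4-DQ8", stringsAsFactors = FALSE)
  frame$count <- rpois(n, 4 * 2 * ifelse(frame$site == "Europe-Finland",
                                         1.5, 1))
  fit <- fit_poisson_rate_model(frame, factors = c("site", "sex"))
  co <- fit$coefficients[!is.na(fit$coefficients$ci_low), ]
  expect_true(all(co$ci_low <= co$rate_ratio &
                    co$rate_ratio <= co$ci_high))
  expect_equal(fit$wald$df, c(2, 1))
  # zero events in a level -> warning and infinite bound
  frame$count[frame$sex == "male"] <- 0L
  expect_warning(fit0 <- fit_poisson_rate_model(frame,
                                                factors = c("site", "sex")),
                 "zero events")
  male <- fit0$coefficients[fit0$coefficients$level == "male", ]
  expect_equal(male$ci_high, Inf)
})

test_that("log rate-ratio estimates are unbiased as the cohort grows", {
  cfg <- sim_config(n_children = 2000, seed = 31)
  for (n in c(500, 2000)) {
    cfg_n <- sim_config(n_children = n, seed = 31)
    roster <- simulate_children(cfg_n)$children
    reps <- 30
    est <- matrix(NA_real_, reps, 2)
    set.seed(77)
    rep_seeds <- sample.int(2^31 - 1, reps)
    for (r in seq_len(reps)) {
      fr <- simulate_episode_counts(roster, cfg_n, rep_seed = rep_seeds[r])
      m <- fit_poisson_rate_model(fr)
      co <- m$coefficients
      est[r, 1] <- log(co$rate_ratio[co$level == "Europe-Finland"])
      est[r, 2] <- log(co$rate_ratio[co$level == "male"])
    }
    bias <- colMeans(est) - c(log(1.5), log(1.04))
    mc_se <- apply(est, 2, sd) / sqrt(reps)
    expect_true(all(abs(bias) < 4 * mc_se + 1e-4))
    # spread shrinks with n: rough check at the larger size
    if (n == 2000) expect_lt(sd(est[, 1]), 0.05)
  }
})
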