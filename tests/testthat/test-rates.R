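test_that("person-time accrues from birth to capped follow-up", {
  ch <- toy_children(1)
  pt <- person_time(ch, 48)
  expect_equal(sum(pt$person_years), 4, tolerance = 1 / 365.25)

  ch2 <- toy_children(2)
  ch2$followup_end[2] <- ch2$birth_date[2] + round(24 * 30.4375)
  expect_equal(sum(person_time(ch2, 48)$person_years), 6,
               tolerance = 2 / 365.25)
  # splitting bins preserves the total
  expect_equal(sum(person_time(ch2, 3)$person_years),
               sum(person_time(ch2, 48)$person_years))
  expect_equal(nrow(person_time(ch2[0, ], 3)), 0)
})

test_that("stratified rates are counts over stratum person-years", {
  ch <- toy_children(1)
  # 13 episodes in the first 6 months of a single 4-year child:
  # stratum person-time is 0.5 py under a 6-month bin
  cl <- classified_from(seq(10, 130, by = 10), rep("OTHER", 13))
  eps <- build_episodes(cl, ch)$episodes
  r <- episode_rates(eps, ch, "age_bin", bin_months = 6)
  first <- r[r$stratum == 0 & r$episode_class == "ALL" &
               r$febrile == "all", ]
  expect_equal(first$n_episodes, 13)
  expect_equal(first$rate, 13 / first$person_years)
  expect_equal(first$person_years, 0.5, tolerance = 0.01)
  # conservation across every stratification
  for (strat in c("age_bin", "calendar_month", "season")) {
    rr <- episode_rates(eps, ch, strat)
    expect_equal(sum(rr$n_episodes[rr$episode_class == "ALL" &
                                     rr$febrile == "all"]), nrow(eps))
  }
  # febrile + nonfebrile = all
  rs <- episode_rates(eps, ch, "season", split_febrile = TRUE)
  all_n <- rs$n_episodes[rs$febrile == "all"]
  expect_equal(rs$n_episodes[rs$febrile == "febrile"] +
                 rs$n_episodes[rs$febrile == "nonfebrile"], all_n)

  # zero episodes -> all-zero rates
  r0 <- episode_rates(eps[0, ], ch, "season")
  expect_true(all(r0$n_episodes == 0))
  expect_true(all(r0$rate[r0$person_years > 0] == 0))

  # an episode outside follow-up is a contract error
  bad <- eps
  bad$onset_date[1] <- ch$birth_date[1] - 5
  expect_error(episode_rates(bad, ch, "season"), class = "contract_error")
})

test_that("rates are invariant to splitting and person-time-weighted recombination", {
  set.seed(99)
  ch <- toy_children(4)
  cl <- do.call(rbind, lapply(1:4, function(i) {
    random_classified_reports(25, seed = 500 + i,
                              child_id = sprintf("c%d", i),
                              day_range = 0:1400)
  }))
  eps <- build_episodes(cl, ch)$episodes
  fine <- episode_rates(eps, ch, "age_bin", bin_months = 3)
  coarse <- episode_rates(eps, ch, "age_bin", bin_months = 12)
  f <- fine[fine$episode_class == "ALL" & fine$febrile == "all", ]
  c12 <- coarse[coarse$episode_class == "ALL" & coarse$febrile == "all", ]
  for (k in seq_len(nrow(c12))) {
    sel <- f$stratum >= c12$stratum[k] & f$stratum < c12$stratum[k] + 12
    expect_equal(sum(f$n_episodes[sel]), c12$n_episodes[k])
    expect_equal(sum(f$rate[sel] * f$person_years[sel]) /
                   sum(f$person_years[sel]), c12$rate[k],
                 tolerance = 1e-9)
  }
})

test_that("percent reporting counts children under full-bin follow-up", {
  ch <- toy_children(4)
  # 3 of 4 children with an episode onset in months [6, 9)
  cl <- do.call(rbind, lapply(1:3, function(i) {
    classified_from(200, "OTHER", child_id = sprintf("c%d", i))
  }))
  cl$report_id <- sprintf("r%02d", seq_len(nrow(cl)))
  eps <- build_episodes(cl, ch)$episodes
  pr <- percent_reporting(eps, ch)
  expect_equal(pr$percent[pr$age_bin_start_months == 6], 75)
  expect_equal(pr$n_children[pr$age_bin_start_months == 6], 4)
  expect_true(all(pr$percent[pr$age_bin_start_months != 6] == 0))
  # every child reporting -> 100
  cl4 <- rbind(cl, classified_from(201, "OTHER", child_id = "c4"))
  cl4$report_id <- sprintf("r%02d", seq_len(nrow(cl4)))
  eps4 <- build_episodes(cl4, ch)$episodes
  pr4 <- percent_reporting(eps4, ch)
  expect_equal(pr4$percent[pr4$age_bin_start_months == 6], 100)
  # no episodes -> 0 everywhere
  expect_true(all(percent_reporting(eps[0, ], ch)$percent == 0))
})

test_that("model frame conserves filtered episode counts per child", {
  set.seed(7)
  ch <- toy_children(3)
  cl <- do.call(rbind, lapply(1:3, function(i) {
    random_classified_reports(20, seed = 600 + i,
                              child_id = sprintf("c%d", i))
  }))
  eps <- build_episodes(cl, ch)$episodes
  for (flt in c("all", "febrile", "nonfebrile")) {
    fr <- aggregate_model_frame(eps, ch, flt)
    expect_equal(nrow(fr), 3)
    want <- switch(flt, all = nrow(eps), febrile = sum(eps$febrile),
                   nonfebrile = sum(!eps$febrile))
    expect_equal(sum(fr$count), want)
  }
  fr <- aggregate_model_frame(eps, ch, "all")
  one <- aggregate_model_frame(eps[eps$child_id == "c2", ], ch, "all")
  expect_equal(one$count[one$child_id == "c2"],
               fr$count[fr$child_id == "c2"])
})
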