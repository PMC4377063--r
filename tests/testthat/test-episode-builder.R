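test_that("extraction drops chronic and non-infectious reports with counts", {
  catalog <- load_catalog()
  reports <- data.frame(
    report_id = c("r1", "r2", "r3", "r4"),
    child_id = "c1",
    onset_date = as.Date("2010-01-05") + 0:3,
    icd10_code = c("J00", "Z001", NA, "H66"),
    fever_flag = c(FALSE, FALSE, TRUE, FALSE),
    chronic_flag = c(FALSE, FALSE, FALSE, TRUE),
    professional_dx = TRUE, stringsAsFactors = FALSE)
  ext <- extract_infection_reports(reports, catalog)
  expect_equal(nrow(ext$classified), 2) # J00 + standalone fever
  expect_equal(ext$n_dropped_chronic, 1)
  expect_equal(ext$n_dropped_noninfectious, 1)
  expect_setequal(ext$classified$episode_class,
                  c("RESPIRATORY", "STANDALONE_FEVER"))

  allchron <- reports
  allchron$chronic_flag <- TRUE
  ext <- extract_infection_reports(allchron, catalog)
  expect_equal(nrow(ext$classified), 0)
  expect_equal(ext$n_dropped_chronic, 4)

  ext <- extract_infection_reports(reports[0, ], catalog)
  expect_equal(nrow(ext$classified), 0)
})

test_that("worked merging examples follow the four definitions", {
  # respiratory chain absorbs a middle-ear code and an attached fever
  x <- classified_from(c(0, 3, 3),
                       c("RESPIRATORY", "RESPIRATORY", "STANDALONE_FEVER"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$episode_class, "RESPIRATORY")
  expect_equal(ep$onset_date, as.Date("2010-01-01"))
  expect_equal(ep$n_codes, 2)
  expect_true(ep$febrile)

  # gastro symptom next to a respiratory code is absorbed, no GI episode
  x <- classified_from(c(0, 2), c("RESPIRATORY", "GI_SYMPTOM"))
  ep <- build_episodes_for_child(x)
  expect_equal(ep$episode_class, "RESPIRATORY")
  expect_equal(ep$n_codes, 2)

  # isolated standalone fever becomes its own unknown-febrile episode
  x <- classified_from(0, "STANDALONE_FEVER")
  ep <- build_episodes_for_child(x)
  expect_equal(ep$episode_class, "UNKNOWN_FEBRILE")
  expect_equal(ep$onset_date, as.Date("2010-01-01"))
  expect_equal(ep$n_codes, 0)
  expect_true(ep$febrile)

  # GI chaining across 4-day gaps
  x <- classified_from(c(0, 4, 8), rep("GASTROINTESTINAL", 3))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$episode_class, "GASTROINTESTINAL")
  expect_equal(ep$n_codes, 3)

  # other-class codes never merge
  x <- classified_from(c(0, 1), c("OTHER", "OTHER"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$episode_class, c("OTHER", "OTHER"))

  expect_equal(nrow(build_episodes_for_child(classified_from(
    integer(0), character(0)))), 0)
})

test_that("fever handling: attachment window, tie-break and lookaround", {
  # fever equidistant from respiratory and GI attaches to respiratory
  x <- classified_from(c(0, 4, 2),
                       c("RESPIRATORY", "GASTROINTESTINAL",
                         "STANDALONE_FEVER"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 2)
  resp <- ep[ep$episode_class == "RESPIRATORY", ]
  expect_true(resp$febrile)
  expect_false(ep$febrile[ep$episode_class == "GASTROINTESTINAL"])
  expect_match(resp$member_report_ids, "r03")

  # fever 6 days from the nearest code: not attachable, not unknown-febrile
  x <- classified_from(c(0, 6), c("RESPIRATORY", "STANDALONE_FEVER"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 1)
  expect_false(ep$febrile)
  expect_equal(attr(ep, "dropped_fever_ids"), "r02")

  # fever 8 days away from any code is unknown-febrile
  x <- classified_from(c(0, 8), c("RESPIRATORY", "STANDALONE_FEVER"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 2)
  expect_true("UNKNOWN_FEBRILE" %in% ep$episode_class)

  # a coded fever report (fever symptom code) can seed unknown-febrile and
  # then carries its code
  x <- classified_from(0, "FEVER_MARKER")
  ep <- build_episodes_for_child(x)
  expect_equal(ep$episode_class, "UNKNOWN_FEBRILE")
  expect_equal(ep$n_codes, 1)

  # a coded report's own fever flag marks the episode febrile but never
  # creates an unknown-febrile episode
  x <- classified_from(0, "RESPIRATORY", fever = TRUE)
  ep <- build_episodes_for_child(x)
  expect_equal(ep$episode_class, "RESPIRATORY")
  expect_true(ep$febrile)
})

test_that("gastro-symptom absorption reaches a fixed point across spans", {
  # r2 (day 10) is 5 days from the respiratory code; once absorbed it pulls
  # r3 (day 13) into range of the same episode
  x <- classified_from(c(5, 10, 13),
                       c("RESPIRATORY", "GI_SYMPTOM", "GI_SYMPTOM"))
  ep <- build_episodes_for_child(x)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$episode_class, "RESPIRATORY")
  expect_equal(ep$n_codes, 3)

  # without the bridge, the far symptom code forms a GI episode instead
  x <- classified_from(c(5, 13), c("RESPIRATORY", "GI_SYMPTOM"))
  ep <- build_episodes_for_child(x)
  expect_setequal(ep$episode_class, c("RESPIRATORY", "GASTROINTESTINAL"))

  # infective gastroenteritis codes are never absorbed into respiratory
  x <- classified_from(c(0, 2), c("RESPIRATORY", "GASTROINTESTINAL"))
  ep <- build_episodes_for_child(x)
  expect_setequal(ep$episode_class, c("RESPIRATORY", "GASTROINTESTINAL"))
})

test_that("cohort-level build assigns ids, truncates and summarizes", {
  ch <- toy_children(2)
  cl <- rbind(classified_from(c(0, 3), c("RESPIRATORY", "RESPIRATORY"),
                              child_id = "c1"),
              classified_from(c(10, 1500), c("OTHER", "OTHER"),
                              child_id = "c2"))
  cl$report_id <- sprintf("r%02d", seq_len(nrow(cl)))
  built <- build_episodes(cl, ch)
  # the day-1500 report is beyond the 48-month cap and is excluded
  expect_equal(nrow(built$episodes), 2)
  expect_equal(built$episodes$episode_id, c("E000001", "E000002"))
  expect_equal(built$summary$n_episodes, 2)
  expect_equal(built$summary$codes_per_episode, 1.5)
  sh <- built$summary$per_class$share_pct
  expect_equal(sum(sh), 100, tolerance = 1e-9)

  # mixed children in the per-child entry point is a contract error
  expect_error(build_episodes_for_child(cl), class = "contract_error")

  # N isolated fevers -> N unknown-febrile episodes, 100% febrile
  fevers <- classified_from(seq(0, 90, by = 10),
                            rep("STANDALONE_FEVER", 10), child_id = "c1")
  built <- build_episodes(fevers, ch)
  expect_equal(built$summary$per_class$n[4], 10)
  expect_equal(built$summary$per_class$febrile_pct[4], 100)
})
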