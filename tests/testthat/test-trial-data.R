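test_that("interval histories convert to alternating sojourn records", {
  # one exacerbation mid-study
  rec <- episodes_to_sojourns(data.frame(onset = 100, resolution = 110), 364)
  expect_equal(rec$state, c(1, 2, 1))
  expect_equal(rec$duration, c(100, 10, 254))
  expect_equal(rec$event, c(TRUE, TRUE, FALSE))
  # no exacerbations: a single censored asymptomatic sojourn
  rec <- episodes_to_sojourns(data.frame(onset = numeric(0),
                                         resolution = numeric(0)), 364)
  expect_equal(rec$state, 1)
  expect_equal(rec$duration, 364)
  expect_false(rec$event)
  # exacerbation ongoing at end of follow-up
  rec <- episodes_to_sojourns(data.frame(onset = 350, resolution = NA), 364)
  expect_equal(rec$state, c(1, 2))
  expect_equal(rec$duration, c(350, 14))
  expect_equal(rec$event, c(TRUE, FALSE))
  # overlapping intervals are rejected
  expect_error(episodes_to_sojourns(
    data.frame(onset = c(10, 15), resolution = c(20, 30)), 364),
    "non-overlapping")
})

test_that("dataset invariants are enforced at construction", {
  tr <- tiny_trial()
  expect_equal(n_subjects(tr), 2)
  expect_equal(nrow(tr$sojourns), 8)

  # two consecutive state-1 rows
  bad <- tr$sojourns
  bad$state[2] <- 1
  expect_error(trial_dataset(tr$subjects, bad), "alternate")
  # censoring before the final sojourn
  bad <- tr$sojourns
  bad$event[1] <- FALSE
  expect_error(trial_dataset(tr$subjects, bad), "censored")
  # sub-resolution duration
  bad <- tr$sojourns
  bad$duration[1] <- 0.2
  expect_error(trial_dataset(tr$subjects, bad), "0.5 days")
  # person-time above the study length
  bad <- tr$subjects
  bad$study_length[1] <- 300
  expect_error(trial_dataset(bad, tr$sojourns), "exceeds study length")
  # dropout flag must follow the window rule
  bad <- tr$subjects
  bad$dropout_flag[2] <- FALSE
  expect_error(trial_dataset(bad, tr$sojourns), "dropout window")
})

test_that("the dropout window rule is a strict boundary", {
  mk <- function(fu, flag, window = 30) {
    sub <- tiny_trial()$subjects[1, ]
    sub$dropout_time <- if (fu < 364) fu else NA
    sub$dropout_flag <- flag
    soj <- data.frame(subject_id = "a", episode = 1, state = 1,
                      duration = fu, event = FALSE)
    trial_dataset(sub, soj, dropout_window = window)
  }
  eps <- 0.01
  # last visit just inside the window: not a dropout
  expect_s3_class(mk(364 - 30 + eps, FALSE), "trial_dataset")
  expect_error(mk(364 - 30 + eps, TRUE), "dropout window")
  # last visit beyond the window: a dropout
  expect_s3_class(mk(364 - 30 - eps, TRUE), "trial_dataset")
  expect_error(mk(364 - 30 - eps, FALSE), "dropout window")
  # the 14-day window variant moves the boundary
  expect_s3_class(mk(364 - 14 + eps, FALSE, window = 14), "trial_dataset")
  expect_s3_class(mk(364 - 14 - eps, TRUE, window = 14), "trial_dataset")
})

test_that("person-time is conserved and censoring counts match", {
  tr <- simulate_trial(copd_trial_config(n_per_arm = 50, seed = 3,
                                         dropout = TRUE, two_arms = FALSE))
  fu <- tapply(tr$sojourns$duration, tr$sojourns$subject_id, sum)
  expect_equal(person_time(tr), sum(fu))
  expected_fu <- pmin(tr$subjects$study_length,
                      ifelse(is.na(tr$subjects$dropout_time),
                             Inf, tr$subjects$dropout_time))
  expect_equal(as.numeric(fu[tr$subjects$subject_id]), expected_fu)
  # exactly one open (censored) interval per subject, as the last episode
  open <- tr$sojourns[!tr$sojourns$event, ]
  expect_equal(nrow(open), n_subjects(tr))
  last_ep <- tapply(tr$sojourns$episode, tr$sojourns$subject_id, max)
  expect_equal(as.numeric(last_ep[open$subject_id]), open$episode)
})

test_that("the CSV dialect round-trips and rejects malformed input", {
  tr <- simulate_trial(copd_trial_config(n_per_arm = 15, seed = 9,
                                         dropout = TRUE))
  path <- tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path, dropout_window = tr$dropout_window)
  expect_equal(back$subjects, tr$subjects, tolerance = 1e-12)
  expect_equal(back$sojourns, tr$sojourns, ignore_attr = TRUE,
               tolerance = 1e-12)

  # missing column is a parse error naming the column
  raw <- utils::read.csv(path)
  utils::write.csv(raw[, setdiff(names(raw), "duration")], path,
                   row.names = FALSE, na = "")
  expect_error(read_trial(path), "duration")
})

test_that("the interval CSV layout is accepted", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,onset,resolution,treatment,disease_stage,smoke,pack_years,season,study_length,dropout_time,dropout_flag",
    "a,100,110,0,1,0,40,0,364,,FALSE",
    "a,250,260,0,1,0,40,0,364,,FALSE",
    "b,150,160,1,0,1,25.5,1,364,200,TRUE"), path)
  tr <- read_trial(path, format = "interval")
  expect_equal(n_subjects(tr), 2)
  expect_equal(tr$sojourns$duration[tr$sojourns$subject_id == "a"],
               c(100, 10, 140, 10, 104))
  # subject b censored at the dropout time
  b <- tr$sojourns[tr$sojourns$subject_id == "b", ]
  expect_equal(sum(b$duration), 200)
})
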