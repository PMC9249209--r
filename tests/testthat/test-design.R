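test_that("condition assignment is a step function with the crossover day live", {
  expect_equal(assign_condition(399, 400), "control")
  expect_equal(assign_condition(400, 400), "intervention")
  expect_equal(assign_condition(700, 400), "intervention")
  # monotone with exactly one switch per site
  days <- 0:730
  cond <- assign_condition(days, 400)
  flips <- sum(diff(cond == "intervention") != 0)
  expect_equal(flips, 1)
  expect_true(all(sort(unique(cond)) == c("control", "intervention")))
  des <- default_design()
  expect_error(assign_condition(731, 400, des), "window")
  expect_error(assign_condition(-1, 400, des), "window")
})

test_that("months map to meteorological seasons with Winter as reference", {
  expect_equal(as.character(season_of(3)), "Spring")
  expect_equal(as.character(season_of(12)), "Winter")
  expect_equal(as.character(season_of(9)), "Autumn")
  s <- season_of(1:12)
  expect_equal(levels(s)[1], "Winter")
  expect_equal(as.vector(table(s)), c(3, 3, 3, 3))
  # dummy coding: exactly one season per record
  m <- stats::model.matrix(~s)
  expect_true(all(rowSums(m[, -1]) %in% 0:1))
  expect_error(season_of(13))
})

test_that("centred time and exposure time follow their definitions", {
  expect_equal(centred_time(365, 365), 0)
  expect_equal(centred_time(0, 365), -365)
  expect_equal(centred_time(0:730)[366], 0)  # midpoint of 0..730 is 365
  expect_equal(exposure_time(450, 400), 50)
  expect_equal(exposure_time(399, 400), 0)
  expect_equal(exposure_time(400, 400), 0)
  # positive exposure implies the intervention condition
  d <- 0:730
  pos <- exposure_time(d, 400) > 0
  expect_true(all(assign_condition(d[pos], 400) == "intervention"))
})

test_that("design invariants are enforced", {
  expect_no_error(sw_design())
  expect_error(sw_design(site_ids = paste0("s", 1:6)), "7")
  expect_error(sw_design(planned_crossover_day = rep(319L, 7)), "3 distinct")
  expect_error(sw_design(actual_crossover_day = c(100L, rep(319L, 6))),
               "randomisation phase")
})

test_that("calendar-matched filter keeps the 3 Mar - 3 Sep window of the outer phases", {
  des <- default_design()  # day 0 is 1 June
  # 1 March of study year 2 is day 273; 3 March day 275; 3 Sep day 459
  d0 <- as.Date("2016-06-01")
  mk <- function(dates) data.frame(site = "site1",
                                   day = as.integer(as.Date(dates) - d0),
                                   safety_event = 0L)
  # validation phase: 1 March 2017 (excluded), 3 March 2017 is randomisation
  # phase (day 275) so use year-1 dates inside validation: June-Nov 2016
  early <- mk(c("2016-06-15", "2016-09-03", "2016-09-04", "2017-03-01"))
  f <- filter_calendar_matched(early, des)
  expect_equal(as.character(f$day + d0), c("2016-06-15", "2016-09-03"))
  # randomisation-phase record inside the calendar window is excluded
  rand <- mk("2017-06-15")
  expect_equal(nrow(filter_calendar_matched(rand, des)), 0)
  # implementation phase: 15 June 2018 kept, boundary 3 March 2018 kept
  late <- mk(c("2018-03-02", "2018-03-03", "2018-04-30"))
  f2 <- filter_calendar_matched(late, des)
  expect_equal(as.character(f2$day + d0), c("2018-03-03", "2018-04-30"))
  # exclusive boundaries drop 3 March
  f3 <- filter_calendar_matched(late, des, inclusive = FALSE)
  expect_equal(as.character(f3$day + d0), "2018-04-30")
  # idempotence
  expect_equal(filter_calendar_matched(f, des), f)
})

test_that("phase filter uses half-open boundaries and is idempotent", {
  des <- default_design()
  d <- data.frame(site = "site1",
                  day = c(des$validation_end_day - 1L, des$validation_end_day,
                          des$randomisation_end_day - 1L,
                          des$randomisation_end_day),
                  safety_event = 0L)
  f <- filter_randomisation_phase(d, des)
  expect_equal(f$day, c(des$validation_end_day, des$randomisation_end_day - 1L))
  expect_equal(filter_randomisation_phase(f, des), f)
})

test_that("cluster-period table conserves totals and localises events", {
  des <- default_design()
  dat <- generate_replica(des, sw_replica_counts(), seed = 2)
  tab <- tabulate_cluster_periods(dat, des)
  expect_equal(sum(tab$events), sum(dat$safety_event))
  expect_equal(sum(tab$denominator), nrow(dat))
  # empty dataset: all-zero full grid
  tab0 <- tabulate_cluster_periods(dat[0, ], des)
  expect_true(all(tab0$events == 0) && all(tab0$denominator == 0))
  expect_equal(nrow(tab0), 7 * 25)
  # three events in one site-month land in exactly that cell
  d3 <- data.frame(site = "site2", day = c(40L, 50L, 55L), safety_event = 1L)
  t3 <- tabulate_cluster_periods(d3, des)
  expect_equal(sum(t3$events == 3), 1)
  expect_equal(sum(t3$events), 3)
  hot <- t3[t3$events == 3, ]
  expect_equal(hot$site, "site2")
})

test_that("trial data and design round-trip through their file formats", {
  des <- default_design()
  dat <- generate_parametric(des, sw_cohort_params(), n = 200, seed = 4)
  tf <- tempfile(fileext = ".csv")
  write_trial_data(dat, tf, meta = c(seed = 4))
  back <- read_trial_data(tf)
  expect_equal(back, dat, tolerance = 1e-12)
  yf <- tempfile(fileext = ".yaml")
  write_design(des, yf)
  des2 <- read_design(yf)
  expect_equal(des2, des)
  # schema violations are caught
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(dat[, 1:4], bad, row.names = FALSE)
  expect_error(read_trial_data(bad), "missing columns")
})
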