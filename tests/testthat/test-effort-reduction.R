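# Effort-reduction machinery: focal-year subsetting, relative bias,
# SE extrapolation, random-exclusion validation.

test_that("subset_focal_year keeps the last trawl per subset station and nothing else", {
  sc <- small_scenario(years = 2000:2002, hauls_per_year = 62, seed = 41)
  flagged <- sc$stations$station_id[sc$stations$reduced_year_flag]
  sub <- subset_focal_year(sc$hauls, 2001, flagged)
  foc <- sub[sub$year == 2001, ]
  expect_lte(nrow(foc), 15L)
  expect_true(all(foc$station_id %in% flagged))
  expect_equal(anyDuplicated(foc$station_id), 0L)
  # other years untouched
  expect_equal(nrow(sub[sub$year != 2001, ]),
               nrow(sc$hauls[sc$hauls$year != 2001, ]))
  # idempotent and deterministic
  expect_equal(as.data.frame(subset_focal_year(sub, 2001, flagged)),
               as.data.frame(sub))
  # last-trawl rule: the later of two hauls at a station wins
  h <- sc$hauls[sc$hauls$year == 2000, ][1:2, ]
  h$station_id <- flagged[1]
  h$julian_day <- c(150L, 160L)
  h2 <- rbind(h, transform(h, year = 1999L,
                           haul_id = paste0(h$haul_id, "x")))
  kept <- subset_focal_year(h2, 2000, flagged)
  expect_equal(kept$julian_day[kept$year == 2000], 160L)
  expect_error(subset_focal_year(sc$hauls, 1890, flagged), "not present")
  expect_error(subset_focal_year(sc$hauls, 2000, "NOSUCH"), "no focal-year")
})

test_that("relative bias is computed per cell with the documented conventions", {
  sc <- small_scenario(years = 2000:2003, hauls_per_year = 30, seed = 42)
  res <- run_bias_simulation(sc$hauls, sc$stations, taxa = "sanddab",
                             focal_years = 2000:2002,
                             candidate_covariates = list("depth_stratum"))
  expect_s3_class(res, "effort_reduction_result")
  expect_equal(nrow(res), 3L * 2L)  # focal years x estimators
  ok <- !is.na(res$relative_bias)
  expect_equal(res$relative_bias[ok],
               ((res$x_sub - res$x_all) / res$x_all)[ok])
  sm <- summary(res)
  expect_true(all(c("median", "q1", "q3", "whisker_lo", "whisker_hi") %in%
                    names(sm)))
  expect_true(all(sm$whisker_lo <= sm$q1 & sm$q3 <= sm$whisker_hi))
})

test_that("an empty focal-year subset index gives relative bias -1", {
  ex <- worked_example()
  h <- ex$hauls
  # year 1: subset station S1 catches nothing, the others do
  h$cpue_t <- c(0, 5, 3, 9, 0, 2, 2, 1)
  res <- run_bias_simulation(h, ex$stations, taxa = "t", focal_years = 1,
                             station_subset = "S1", estimators = "naive")
  expect_equal(res$relative_bias, -1)
})

test_that("model-based relative bias on the arithmetic scale is CPUE-scale invariant", {
  sc <- small_scenario(years = 2000:2002, hauls_per_year = 40, seed = 43)
  args <- list(stations = sc$stations, taxa = "anchovy",
               focal_years = 2000:2001, estimators = "model_based",
               candidate_covariates = list("depth_stratum"),
               scale = "arithmetic")
  r1 <- do.call(run_bias_simulation, c(list(sc$hauls), args))
  h2 <- sc$hauls
  h2$cpue_anchovy <- h2$cpue_anchovy * 5
  r2 <- do.call(run_bias_simulation, c(list(h2), args))
  expect_equal(r1$relative_bias, r2$relative_bias, tolerance = 1e-8)
})

test_that("SE extrapolation obeys SD/sqrt(n) exactly", {
  idx <- structure(
    data.frame(year = 2001, point_index = 2, log_index = 1.1,
               se_log = 0.5, lower = 0.1, upper = 2.1, z_score = 0,
               n_hauls = 4L, low_info = FALSE),
    class = c("index_series", "data.frame"), taxon = "toy")
  pc <- se_extrapolation(idx, 2001, n_grid = c(1, 4, 16, 62))
  expect_equal(pc$sd_implied, 1)  # 0.5 * sqrt(4)
  expect_equal(pc$curve$predicted_se, 1 / sqrt(c(1, 4, 16, 62)))
  # exact interpolation at n_obs and the quarter-sample doubling rule
  expect_equal(pc$curve$predicted_se[pc$curve$n == 4], pc$se_obs)
  expect_equal(pc$curve$predicted_se[pc$curve$n == 16],
               pc$curve$predicted_se[pc$curve$n == 4] / 2)
  expect_true(all(diff(pc$curve$predicted_se) < 0))
  expect_error(se_extrapolation(idx, 2001, n_grid = c(0, 5)), "positive")
  expect_error(se_extrapolation(idx, 1999), "known se_log")
})

test_that("random exclusion reproduces the observed SE at full effort and needs valid n", {
  sc <- small_scenario(years = 2000, hauls_per_year = 62, seed = 44)
  res <- random_exclusion_experiment(sc$hauls, "sanddab", 2000,
                                     n_list = c(15, 62), reps = 25, seed = 45)
  full <- res[res$n == 62, ]
  expect_equal(full$mean_se, rep(attr(res, "se_full"), nrow(full)))
  expect_true(all(full$sd_se == 0))
  sub <- res[res$n == 15, ]
  expect_true(all(sub$mean_se > 0))
  expect_equal(sort(unique(res$mode)),
               c("consecutive_nights", "purely_random"))
  expect_error(random_exclusion_experiment(sc$hauls, "sanddab", 2000,
                                           n_list = 100, reps = 25),
               "exceed")
  expect_error(random_exclusion_experiment(sc$hauls, "sanddab", 2000,
                                           n_list = 10, reps = 5), ">= 20")
})
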