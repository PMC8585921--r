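# Synthetic survey generator: design, hurdle catches, diet link, env fields.

test_that("station design honours strata, the inshore subset, and the seed", {
  st <- make_design(30, seed = 1)
  expect_equal(nrow(st), 30)
  expect_equal(anyDuplicated(st$station_id), 0L)
  expect_equal(sum(st$reduced_year_flag), 15L)
  expect_lt(mean(st$bottom_depth_m[st$reduced_year_flag]),
            mean(st$bottom_depth_m[!st$reduced_year_flag]))
  # flagged stations are stochastically shallower (rank comparison)
  w <- wilcox.test(st$bottom_depth_m[st$reduced_year_flag],
                   st$bottom_depth_m[!st$reduced_year_flag],
                   alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 0.01)
  expect_identical(st, make_design(30, seed = 1))
  expect_false(identical(st, make_design(30, seed = 2)))

  all_shelf <- make_design(15, strata_spec = c(shelf = 1), seed = 3)
  expect_true(all(all_shelf$reduced_year_flag))
  expect_error(make_design(10), "reduced-year")
  expect_error(make_design(30, strata_spec = c(shelf = 0.5, slope = 0.4)),
               "sum to 1")
})

test_that("haul simulation is deterministic and reduced years hit the 15 flagged stations", {
  sc <- small_scenario(reduced_years = 2005)
  h <- sc$hauls
  expect_identical(h, simulate_hauls(sc$stations, sc$taxa, sc$years,
                                     hauls_per_year = 40,
                                     reduced_years = 2005, seed = 3))
  red <- h[h$year == 2005, ]
  expect_equal(nrow(red), 15L)
  expect_setequal(red$station_id,
                  sc$stations$station_id[sc$stations$reduced_year_flag])
  expect_true(all(red$julian_day >= 160 & red$julian_day <= 177))
  norm <- h[h$year == 2000, ]
  expect_equal(nrow(norm), 40L)
  expect_true(all(norm$julian_day >= 121 & norm$julian_day <= 180))
  expect_true(all(vapply(h[grep("^cpue_", names(h))], function(v) all(v >= 0),
                         logical(1))))
  # ~3 hauls per night
  expect_lte(max(table(norm$night_id)), 3L)
})

test_that("catches follow the hurdle structure with the stated associations", {
  st <- make_design(30, seed = 4)
  yrs <- 2000:2001
  never <- taxon_params("never", setNames(c(2, 2), yrs),
                        occurrence_intercept = -50)
  near <- taxon_params("near", setNames(c(2, 2), yrs), depth_association = 1.2)
  off <- taxon_params("off", setNames(c(2, 2), yrs), depth_association = -1.2)
  h <- simulate_hauls(st, list(never, near, off), yrs, hauls_per_year = 800,
                      seed = 5)
  expect_true(all(h$cpue_never == 0))
  stratum <- st$depth_stratum[match(h$station_id, st$station_id)]
  expect_gt(mean(h$cpue_near[stratum == "shelf"]),
            mean(h$cpue_near[stratum == "deep"]))
  expect_lt(mean(h$cpue_off[stratum == "shelf"]),
            mean(h$cpue_off[stratum == "deep"]))
})

test_that("empirical moments converge to the generative values", {
  st <- make_design(20, seed = 6)
  yrs <- 2000
  tx <- flat_taxon(yrs, lambda = 1.4, occ = 0.8, sigma = 0.7)
  n <- 4000
  h <- simulate_hauls(st, list(tx), yrs, hauls_per_year = n, seed = 7,
                      round_counts = FALSE)
  p_emp <- mean(h$cpue_flat > 0)
  p_true <- plogis(0.8)
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  pos <- log(h$cpue_flat[h$cpue_flat > 0])
  expect_lt(abs(mean(pos) - 1.4), 3 * 0.7 / sqrt(length(pos)))
  expect_lt(abs(sd(pos) - 0.7), 0.05)
})

test_that("diet link is linear, clamped, and recoverable", {
  idx <- data.frame(year = 2000:2029, log_index = seq(0, 3, length.out = 30))
  d0 <- simulate_diet(idx, slope = 0.2, intercept = 0.1, noise_sd = 0, seed = 1)
  expect_equal(d0$mean_proportion, 0.1 + 0.2 * idx$log_index)
  d_hi <- simulate_diet(idx, slope = 2, intercept = 0.5, noise_sd = 0.5,
                        seed = 2)
  expect_true(all(d_hi$mean_proportion >= 0 & d_hi$mean_proportion <= 1))
  d <- simulate_diet(idx, slope = 0.2, intercept = 0.1, noise_sd = 0.05,
                     seed = 3)
  fit <- lm(d$mean_proportion ~ idx$log_index)
  expect_lt(abs(coef(fit)[2] - 0.2), 2 * summary(fit)$coefficients[2, 2])
  expect_error(simulate_diet(idx[0, ]), "empty")
})

test_that("krill truth fields and station samples behave as constructed", {
  st <- make_design(25, seed = 8)
  yrs <- 2002:2013
  dome <- list(ner = list(species = "ner", peak_km = 12, width_km = 18,
                          amp = 3, beta_winter = 0, beta_spring = 0))
  zero_terms <- list(ner = setNames(rep(0, length(yrs)), yrs))
  k0 <- simulate_env_and_krill(st, species = dome, years = yrs,
                               patchiness_sd = 0, year_terms = zero_terms,
                               seed = 9)
  # zero patchiness noise: station samples equal truth at station cells
  key <- paste(k0$truth$cell_id, k0$truth$year)
  truth_at <- k0$truth$ln_ner[match(paste(k0$hauls$cell_id, k0$hauls$year),
                                    key)]
  expect_equal(k0$hauls$cpue_ner, expm1(truth_at), tolerance = 1e-12)
  # dome truth declines monotonically with distance beyond its peak
  one <- k0$truth[k0$truth$year == yrs[1], ]
  one <- one[order(one$distance_to_shore_km), ]
  prof <- tapply(one$ln_ner, one$distance_to_shore_km, mean)
  beyond <- prof[as.numeric(names(prof)) >= 12]
  expect_true(all(diff(beyond) <= 1e-12))
  # station-sample CV rises with patchiness noise
  cv_at <- function(sd) {
    k <- simulate_env_and_krill(st, species = dome, years = yrs,
                                patchiness_sd = sd, year_terms = zero_terms,
                                seed = 10)
    mean(tapply(k$hauls$cpue_ner, k$hauls$year,
                function(v) sd(v) / mean(v)))
  }
  expect_gt(cv_at(1.0), cv_at(0.2))
  far <- st
  far$distance_to_shore_km[1] <- 500
  expect_error(simulate_env_and_krill(far, species = dome, years = yrs),
               "outside grid extent")
})
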