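# Boosted-tree krill SDM: training, anomaly decomposition, comparisons.

krill_fixture <- function(seed = 71, years = 2002:2013, patchiness_sd = 0.5,
                          n_stations = 30) {
  st <- make_design(n_stations, seed = seed)
  simulate_env_and_krill(st, years = years, patchiness_sd = patchiness_sd,
                         seed = seed + 1)
}

fast_hyper <- list(eta = 0.05, nrounds_max = 500, early_stopping = 30)

test_that("a constant response is flagged degenerate and predicted as the constant", {
  k <- krill_fixture()
  h <- k$hauls
  h$cpue_tspin <- 7
  m <- train_sdm(h, k$env, "tspin", seed = 72)
  expect_true(m$degenerate)
  p <- predict_anomaly(m, k$env, 2002:2013, baseline_years = 2002:2012)
  expect_true(all(p$grid$pred == log1p(7)))
  expect_true(all(abs(p$grid$anomaly) < 1e-12))
})

test_that("climatology/anomaly decomposition is exact and the mask follows distance", {
  k <- krill_fixture()
  m <- train_sdm(k$hauls, k$env, "tspin", hyper = fast_hyper, seed = 73)
  expect_gt(m$best_nrounds, 0)
  p <- predict_anomaly(m, k$env, 2002:2013, baseline_years = 2002:2011,
                       stations = k$stations, mask_km = 150)
  g <- p$grid
  expect_equal(g$pred, g$climatology + g$anomaly)
  expect_true(all(g$pred >= 0))
  base_mean <- tapply(g$anomaly[g$year %in% 2002:2011],
                      g$cell_id[g$year %in% 2002:2011], mean)
  expect_lt(max(abs(base_mean)), 1e-10)
  expect_equal(g$in_domain, g$distance_to_shore_km <= 150)
  expect_equal(sort(p$station_series$year), 2002:2013)
  # error paths
  expect_error(predict_anomaly(m, k$env, 1990:2013, 2002:2011),
               "missing year")
  expect_error(predict_anomaly(m, k$env, 2002:2012, baseline_years = 2013),
               "subset")
})

test_that("tree predictions are invariant to monotone covariate rescaling", {
  k <- krill_fixture()
  hyper <- list(eta = 0.1, subsample = 1, nrounds_max = 60,
                early_stopping = 60)
  m1 <- train_sdm(k$hauls, k$env, "tspin", hyper = hyper, seed = 74)
  env2 <- k$env
  env2$distance_to_shore_km <- env2$distance_to_shore_km^3  # strictly monotone
  m2 <- train_sdm(k$hauls, env2, "tspin", hyper = hyper, seed = 74)
  X1 <- as.matrix(k$env[k$env$year == 2002, m1$covariates])
  X2 <- as.matrix(env2[env2$year == 2002, m2$covariates])
  expect_equal(predict(m1$booster, X1), predict(m2$booster, X2),
               tolerance = 1e-6)
})

test_that("permuting the response destroys held-out skill", {
  k <- krill_fixture(seed = 75)
  h <- k$hauls
  set.seed(76)
  h$cpue_tspin <- sample(h$cpue_tspin)
  m <- train_sdm(h, k$env, "tspin", hyper = fast_hyper, seed = 77)
  m_real <- train_sdm(k$hauls, k$env, "tspin", hyper = fast_hyper, seed = 77)
  # held-out RMSE of the permuted fit no better than the response SD;
  # real fit clearly better than permuted
  expect_gt(m$cv_score, 0.9 * sd(log1p(h$cpue_tspin)))
  expect_lt(m_real$cv_score, 0.8 * m$cv_score)
})

test_that("series comparison reports correlation and sign disagreement", {
  s <- data.frame(year = 2002:2011, mean_pred = 1:10)
  pred <- structure(list(species = "tspin", station_series = s,
                         grid = NULL, baseline_years = 2002:2010,
                         mask_km = 150), class = "sdm_prediction")
  gi <- structure(data.frame(year = 2002:2011, log_index = 1:10 / 3),
                  class = c("index_series", "data.frame"))
  cmp <- station_series_compare(pred, gi)
  expect_equal(cmp$r, 1, tolerance = 1e-12)
  expect_false(any(cmp$by_year$sign_disagreement))
  gi2 <- gi
  gi2$log_index <- rev(gi2$log_index)
  cmp2 <- station_series_compare(pred, gi2)
  expect_equal(cmp2$r, -1, tolerance = 1e-12)
  expect_true(all(cmp2$by_year$sign_disagreement))
  expect_error(station_series_compare(pred, gi[1:3, ]), "overlapping")
})

test_that("patchiness diagnostics: smooth model CV sits below patchy observed CV", {
  k0 <- krill_fixture(seed = 78, patchiness_sd = 0)
  m0 <- train_sdm(k0$hauls, k0$env, "tspin", hyper = fast_hyper, seed = 79)
  p0 <- predict_anomaly(m0, k0$env, 2002:2013, baseline_years = 2002:2012)
  d0 <- patchiness_diagnostics(k0$hauls, p0)
  # noise-free observations: residuals small relative to the CPUE scale
  expect_lt(median(abs(d0$resid_mean)) / mean(k0$hauls$cpue_tspin), 0.25)

  k1 <- krill_fixture(seed = 78, patchiness_sd = 0.8)
  m1 <- train_sdm(k1$hauls, k1$env, "tspin", hyper = fast_hyper, seed = 79)
  p1 <- predict_anomaly(m1, k1$env, 2002:2013, baseline_years = 2002:2012)
  d1 <- patchiness_diagnostics(k1$hauls, p1)
  expect_gt(mean(d1$cv_obs > d1$cv_pred), 0.8)
  # residual spread grows with patchiness noise
  expect_gt(mean(d1$resid_sd), mean(d0$resid_sd))
})
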