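# Delta-GLM standardization: closed-form oracles, AIC selection, transforms.

test_that("year-only fit matches the closed-form MLEs on the worked example", {
  ex <- worked_example()
  fit <- fit_delta_glm(ex$hauls, ex$stations, "t",
                       candidate_covariates = list(character(0)))
  expect_equal(unname(fit$p_hat), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(fit$mu_hat),
               c(mean(log(c(3, 9))), mean(log(c(2, 2)))), tolerance = 1e-6)
  idx <- compute_index(fit)
  expect_equal(idx$point_index, c(0.5 * sqrt(27), 1.0), tolerance = 1e-6)
  expect_equal(idx$log_index, log1p(idx$point_index))
})

test_that("year-only profiles equal observed proportions and log-means in general", {
  for (seed in c(11, 12, 13)) {
    sc <- small_scenario(years = 2000:2003, hauls_per_year = 25, seed = seed)
    fit <- fit_delta_glm(sc$hauls, sc$stations, "anchovy",
                         candidate_covariates = list(character(0)))
    obs <- tapply(sc$hauls$cpue_anchovy > 0, sc$hauls$year, mean)
    expect_equal(unname(fit$p_hat), as.numeric(obs), tolerance = 1e-6)
    pos <- sc$hauls[sc$hauls$cpue_anchovy > 0, ]
    mlog <- tapply(log(pos$cpue_anchovy), pos$year, mean)
    expect_equal(unname(fit$mu_hat[names(mlog)]), as.numeric(mlog),
                 tolerance = 1e-6)
  }
})

test_that("an always-caught taxon degenerates to the positive model alone", {
  sc <- small_scenario(years = 2000:2002, hauls_per_year = 30, seed = 14,
                       taxa = list(flat_taxon(2000:2002, 3, occ = 50)))
  fit <- fit_delta_glm(sc$hauls, sc$stations, "flat")
  expect_null(fit$binomial_fit)
  expect_equal(unname(fit$p_hat), rep(1, 3))
  idx <- compute_index(fit)
  expect_equal(idx$point_index, unname(exp(fit$mu_hat)))
})

test_that("AIC selection is a brute-force minimum and finds a strong depth effect", {
  sc <- small_scenario(years = 2000:2003, hauls_per_year = 80, seed = 15,
                       taxa = list(taxon_params(
                         "deepfx", setNames(rep(2, 4), 2000:2003),
                         depth_association = 1.5, sigma_log = 0.7)))
  fit <- fit_delta_glm(sc$hauls, sc$stations, "deepfx")
  tab <- fit$aic_table
  for (sm in unique(tab$submodel)) {
    sub <- tab[tab$submodel == sm, ]
    expect_equal(sub$aic[sub$selected], min(sub$aic))
  }
  # the intercept-only positive model must lose to one containing depth
  pos_tab <- tab[tab$submodel == "positive", ]
  expect_true(grepl("depth|station",
                    pos_tab$covariates[pos_tab$selected]))
  # never selects a strict superset with higher AIC: selected is THE minimum
  expect_true(all(pos_tab$aic[pos_tab$selected] <= pos_tab$aic + 1e-8))
})

test_that("the index is equivariant under CPUE rescaling", {
  sc <- small_scenario(years = 2000:2003, hauls_per_year = 40, seed = 16)
  fit1 <- fit_delta_glm(sc$hauls, sc$stations, "sanddab",
                        candidate_covariates = list("depth_stratum"))
  h2 <- sc$hauls
  h2$cpue_sanddab <- h2$cpue_sanddab * 7
  fit2 <- fit_delta_glm(h2, sc$stations, "sanddab",
                        candidate_covariates = list("depth_stratum"))
  expect_equal(compute_index(fit2)$point_index,
               7 * compute_index(fit1)$point_index, tolerance = 1e-8)
  expect_equal(fit1$p_hat, fit2$p_hat, tolerance = 1e-8)
})

test_that("years with no positive catches index at 0 with a flag", {
  ex <- worked_example()
  h <- ex$hauls
  h$cpue_t[h$year == 2] <- 0
  h <- rbind(h, transform(h[h$year == 2, ], year = 3, cpue_t = c(1, 2, 0, 4)))
  fit <- fit_delta_glm(h, ex$stations, "t",
                       candidate_covariates = list(character(0)))
  idx <- compute_index(fit)
  expect_equal(idx$point_index[idx$year == 2], 0)
  expect_equal(idx$log_index[idx$year == 2], 0)
  expect_true(idx$low_info[idx$year == 2])
  expect_false(any(idx$low_info[idx$year != 2]))
})

test_that("z-scores are standardized over the baseline years", {
  sc <- small_scenario(seed = 17)
  idx <- compute_index(fit_delta_glm(sc$hauls, sc$stations, "myctophids",
                                     candidate_covariates = list("region")))
  expect_equal(mean(idx$z_score), 0, tolerance = 1e-10)
  expect_equal(sd(idx$z_score), 1, tolerance = 1e-10)
  base <- sc$years[1:4]
  idx2 <- compute_index(fit_delta_glm(sc$hauls, sc$stations, "myctophids",
                                      candidate_covariates = list("region")),
                        baseline_years = base)
  zb <- idx2$z_score[idx2$year %in% base]
  expect_equal(mean(zb), 0, tolerance = 1e-10)
  expect_equal(sd(zb), 1, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected informatively", {
  ex <- worked_example()
  one_year <- ex$hauls[ex$hauls$year == 1, ]
  expect_error(fit_delta_glm(one_year, ex$stations, "t"), ">= 2 years")
  h <- ex$hauls
  h$cpue_t <- 0
  expect_error(fit_delta_glm(h, ex$stations, "t"), "never caught")
  h$cpue_t <- c(5, rep(0, 7))
  expect_error(fit_delta_glm(h, ex$stations, "t"), "positive")
  expect_error(fit_delta_glm(ex$hauls, ex$stations, "missing_taxon"),
               "cpue_missing_taxon")
})

test_that("the naive index is the per-year mean of log(CPUE + 1)", {
  ex <- worked_example()
  h <- ex$hauls[ex$hauls$year == 1, ]
  h$cpue_t <- c(0, exp(1) - 1, exp(2) - 1, 0)
  h <- rbind(h, transform(ex$hauls[ex$hauls$year == 2, ], cpue_t = 0))
  idx <- naive_index(h, "t")
  expect_equal(idx$log_index, c(mean(c(0, 1, 2, 0)), 0))
  expect_equal(idx$se_log[1], sd(c(0, 1, 2, 0)) / 2)
  expect_equal(idx$n_hauls, c(4L, 4L))
})
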