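test_that("moving windows enumerate all consecutive spans", {
  w <- sliding_windows(2001, 2011, 5)
  expect_length(w, 7)
  expect_equal(w[[1]], 2001:2005)
  expect_equal(w[[7]], 2007:2011)
  expect_length(sliding_windows(2001, 2005, 5), 1)
  expect_error(sliding_windows(2001, 2003, 5), "shorter")
})

test_that("model specs carry the outcome-dependent covariate lists", {
  s_ob <- model_spec("full", "obesity", "male", 2001:2005)
  s_pa <- model_spec("full", "sufficient_pa", "male", 2001:2005)
  expect_true("docs_per_100k" %in% s_ob$covariates)
  expect_false("docs_per_100k" %in% s_pa$covariates)
  expect_setequal(setdiff(s_ob$covariates, s_pa$covariates),
                  "docs_per_100k")
  expect_error(model_spec("naive", "obesity", "male", c(2001, 2003)),
               "consecutive")
})

test_that("design matrices have the contracted columns and exclusions", {
  st <- cached_study()
  d_naive <- build_design(st$records, st$counties,
                          model_spec("naive", "obesity", "female",
                                     2001:2005))
  X <- model.matrix(d_naive$formula, d_naive$data)
  expect_equal(ncol(X), 1 + 4 + 5 + 1)  # intercept, race, age, time
  geo <- setNames(rep(0.1, 16), st$counties$county_ids)
  d_full <- build_design(st$records, st$counties,
                         model_spec("full", "obesity", "female", 2001:2005),
                         geo_term = geo)
  Xf <- model.matrix(d_full$formula, d_full$data)
  expect_equal(ncol(Xf), 11 + 6 + 4 + 1)  # + covariates, composition, geo
  # missing-demographic records are excluded
  rec <- st$records
  rec$race[rec$sex == "female"][1:10] <- NA
  d2 <- build_design(rec, st$counties,
                     model_spec("naive", "obesity", "female", 2001:2005))
  expect_equal(nrow(d2$data), nrow(d_naive$data) - 10)
  # filtering everything out is a data error
  expect_error(build_design(st$records[0, ], st$counties,
                            model_spec("naive", "obesity", "female",
                                       2001:2005)),
               "no usable records")
})

test_that("a single-county fit collapses to ordinary logistic regression", {
  g <- populate_county_data(make_county_grid(1, 1), 2001:2005, seed = 2)
  tr <- simulate_truth(g, 2001:2005, truth_params(), seed = 2)
  rec <- add_outcomes(simulate_survey(tr, g, 150, seed = 2))
  des <- build_design(rec, g, model_spec("naive", "obesity", "female",
                                         2001:2005))
  fit <- fit_mixed_logit(des)
  ref <- glm(des$formula, binomial(), des$data)
  expect_equal(fit$sigma2_u, 0)
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-6)
  expect_match(fit$method, "single county")
})

test_that("the mixed fit exposes posteriors for every county", {
  st <- cached_study()
  fit <- fit_variant(st$records, st$counties,
                     model_spec("naive", "obesity", "female", 2001:2005))
  expect_gte(fit$sigma2_u, 0)
  expect_setequal(names(fit$u), st$counties$county_ids)
  expect_setequal(names(fit$u_var), st$counties$county_ids)
  expect_true(all(fit$u_var >= 0))
  expect_match(fit$method, "Laplace")
})

test_that("neighbor means follow the arithmetic-mean contract", {
  g <- make_county_grid(1, 3)  # c0001 - c0002 - c0003 in a row
  eff <- c(c0001 = 0.1, c0002 = 0.5, c0003 = -0.1)
  expect_equal(neighbor_mean(eff, g, "c0002"), 0.0)
  eff2 <- c(c0001 = 0.2, c0002 = 0.4, c0003 = 0.6)
  g2 <- make_county_grid(2, 2)
  eff3 <- c(c0001 = 0, c0002 = 0.2, c0003 = 0.4, c0004 = 0.6)
  expect_equal(neighbor_mean(eff3, g2, "c0001"), 0.3)  # mean(0.2, 0.4)
  expect_equal(neighbor_mean(eff, make_county_grid(1, 1), "c0001"), 0)
  expect_error(neighbor_mean(eff, g, "c0099"), "unknown county")
  expect_equal(unname(neighbor_means(eff2, g)),
               c(0.4, 0.4, 0.4))
})

test_that("an all-zero geospatial term reproduces the base fit", {
  st <- cached_study()
  spec_geo <- model_spec("geospatial", "obesity", "female", 2001:2005)
  spec_naive <- model_spec("naive", "obesity", "female", 2001:2005)
  zero_geo <- setNames(rep(0, 16), st$counties$county_ids)
  fit_g <- fit_mixed_logit(build_design(st$records, st$counties, spec_geo,
                                        geo_term = zero_geo))
  fit_n <- fit_mixed_logit(build_design(st$records, st$counties,
                                        spec_naive))
  expect_equal(unname(fit_g$coefficients["geo"]), 0)
  common <- names(fit_n$coefficients)
  expect_lt(max(abs(fit_g$coefficients[common] - fit_n$coefficients)),
            1e-8)
})

test_that("constant county covariates are diagnosed as collinear", {
  st <- cached_study()
  g <- st$counties
  for (v in county_covariates) g$covariates[[v]] <- 0.5
  expect_error(fit_variant(st$records, g,
                           model_spec("covariate", "obesity", "female",
                                      2001:2005)),
               "collinear")
})

test_that("cell predictions equal the direct inverse-logit oracle", {
  st <- cached_study()
  fit <- fit_variant(st$records, st$counties,
                     model_spec("full", "obesity", "female", 2001:2005))
  cell <- data.frame(county_id = "c0006", year = 2003,
                     age_group = "45-54", race = "black",
                     stringsAsFactors = FALSE)
  p <- predict_cell(fit, "c0006", 2003, "45-54", "black", st$counties)
  # hand-built linear predictor
  b <- fit$coefficients
  cv <- st$counties$covariates
  row <- cv[cv$county_id == "c0006" & cv$year == 2003, ]
  shares <- countyprev:::race_share_matrix(st$counties)["c0006", ]
  eta <- b[["(Intercept)"]] + b[["raceblack"]] + b[["age_group45-54"]] +
    b[["year_c"]] * 0 +
    b[["poverty"]] * row$poverty + b[["unemployment"]] * row$unemployment +
    b[["pct_rural"]] * row$pct_rural +
    b[["pct_hs_diploma"]] * row$pct_hs_diploma +
    b[["pm25"]] * row$pm25 / 10 +
    b[["docs_per_100k"]] * row$docs_per_100k / 1000 +
    b[["comp_black"]] * shares[["black"]] +
    b[["comp_hispanic"]] * shares[["hispanic"]] +
    b[["comp_native_american"]] * shares[["native_american"]] +
    b[["comp_other"]] * shares[["other"]] +
    b[["geo"]] * fit$geo[["c0006"]] + fit$u[["c0006"]]
  expect_equal(p, 1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_true(p > 0 && p < 1)
  # monotone in the county effect
  fit_up <- fit
  fit_up$u["c0006"] <- fit$u[["c0006"]] + 1
  expect_gt(predict_cell(fit_up, "c0006", 2003, "45-54", "black",
                         st$counties), p)
  expect_error(predict_cell(fit, "nope", 2003, "45-54", "black",
                            st$counties), "unknown county")
  expect_error(predict_cell(fit, "c0006", 2003, "45-54", "asian",
                            st$counties), "race")
})

test_that("activity outcomes fit through the same machinery", {
  st <- cached_study()
  # sufficient activity exists only in odd years before 2011, so the fit
  # uses roughly the odd-year share of the window's records
  f_suf <- fit_variant(st$records, st$counties,
                       model_spec("full", "sufficient_pa", "male",
                                  2001:2005),
                       fit_control(nAGQ = 0))
  f_any <- fit_variant(st$records, st$counties,
                       model_spec("naive", "any_pa", "male", 2001:2005))
  expect_false("docs_per_100k" %in% names(f_suf$coefficients))
  expect_lt(f_suf$n_obs, 0.75 * f_any$n_obs)
  odd <- st$records$year %% 2 == 1 & st$records$sex == "male"
  expect_equal(f_suf$n_obs, sum(odd & !is.na(st$records$sufficient_pa)))
  p <- predict_cell(f_suf, "c0003", 2002, "35-44", "white", st$counties)
  expect_true(p > 0 && p < 1)
})

test_that("window combination averages covering windows only", {
  wins <- sliding_windows(2002, 2010, 5)
  expect_equal(combine_windows(list(0.3), wins[1], 2004), 0.3)
  expect_equal(combine_windows(list(0.30, 0.34), wins[1:2], 2004), 0.32)
  # 2006 is inside all five windows 2002-2006 ... 2006-2010
  preds <- as.list(seq(0.1, 0.5, by = 0.1))
  expect_equal(combine_windows(preds, wins, 2006), 0.3)
  expect_error(combine_windows(preds, wins, 1999), "no window")
  # convexity: stays within the input range
  expect_true(combine_windows(preds, wins, 2006) >= 0.1)
  expect_true(combine_windows(preds, wins, 2006) <= 0.5)
})
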