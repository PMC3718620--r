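test_that("constant-logit truth gives the same prevalence everywhere", {
  g <- populate_county_data(make_county_grid(2, 2), 2001:2002, seed = 1)
  b0 <- 0.7
  tr <- simulate_truth(g, 2001:2002, flat_params(intercept = b0), seed = 1)
  grid <- expand.grid(county_id = g$county_ids, year = 2001:2002,
                      sex = sexes, age_group = age_groups,
                      race = race_groups, stringsAsFactors = FALSE)
  p <- true_prevalence(tr, g, grid, "obesity")
  expect_equal(p, rep(plogis(b0), nrow(grid)))
  expect_true(all(p > 0 & p < 1))
})

test_that("degenerate county-effect settings give u identically zero", {
  g <- populate_county_data(make_county_grid(3, 3), 2001, seed = 2)
  tr <- simulate_truth(g, 2001, flat_params(), seed = 5)
  for (oc in outcome_names)
    expect_equal(unname(tr$effects[[oc]]$u), rep(0, 9))
  expect_error(truth_params(rho = 1.3), "rho")
  expect_error(truth_params(sigma_u = -1), "sigma_u")
})

test_that("spatial mixing raises Moran's I of the county effects", {
  g <- populate_county_data(make_county_grid(10, 10), 2001, seed = 3)
  for (s in c(11, 12, 13)) {
    u_sp <- simulate_truth(g, 2001, truth_params(rho = 0.8),
                           seed = s)$effects$obesity$u
    u_in <- simulate_truth(g, 2001, truth_params(rho = 0),
                           seed = s)$effects$obesity$u
    expect_gt(morans_i(u_sp, g), morans_i(u_in, g))
    expect_equal(sd(u_sp), 0.5)  # rescaled to the stated SD
  }
})

test_that("survey generation is seed-deterministic and sized correctly", {
  st <- make_study(n = 10, seed = 9)
  st2 <- make_study(n = 10, seed = 9)
  expect_identical(st$records, st2$records)
  st3 <- make_study(n = 10, seed = 10)
  expect_false(identical(st$records, st3$records))
  expect_equal(nrow(st$records), 16 * 5 * 10)
  # n = 0 gives an empty, correctly-typed collection
  empty <- simulate_survey(st$truth, st$counties, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("year", "county_id", "reported_weight") %in%
                    names(empty)))
})

test_that("identity reporting bias reproduces true BMI exactly", {
  st <- make_study(n = 20, seed = 4,
                   bias = list(weight_scale = 1, weight_shift = 0,
                               height_shift = 0))
  rb <- compute_bmi(st$records$reported_weight, st$records$reported_height)
  expect_equal(rb, st$records$true_bmi, tolerance = 1e-12)
})

test_that("empirical outcome frequency matches the truth surface", {
  g <- populate_county_data(make_county_grid(1, 1), 2001, seed = 6)
  tr <- simulate_truth(g, 2001, truth_params(), seed = 6)
  rec <- simulate_survey(tr, g, 20000, seed = 8)
  p <- true_prevalence(tr, g, rec, "obesity")
  se <- sqrt(mean(p * (1 - p)) / nrow(rec))
  expect_lt(abs(mean(rec$true_obese) - mean(p)), 3 * se)
})

test_that("generated minutes are consistent with the drawn sufficiency", {
  st <- cached_study()
  rec <- st$records
  has <- !is.na(rec$moderate_min_week)
  expect_true(any(has))
  cls <- classify_sufficient(rec$moderate_min_week[has],
                             rec$vigorous_min_week[has])
  expect_identical(cls, rec$true_sufficient[has])
})

test_that("detailed minutes follow the odd-year questionnaire schedule", {
  g <- populate_county_data(make_county_grid(2, 2), 2001:2011, seed = 5)
  tr <- simulate_truth(g, 2001:2011, truth_params(), seed = 5)
  rec <- simulate_survey(tr, g, 5, seed = 5)
  even_pre2011 <- rec$year %% 2 == 0 & rec$year < 2011
  expect_true(all(is.na(rec$moderate_min_week[even_pre2011])))
  expect_true(all(!is.na(rec$moderate_min_week[!even_pre2011])))
  rec2 <- simulate_survey(tr, g, 5, seed = 5, odd_year_detail = FALSE)
  expect_true(all(!is.na(rec2$moderate_min_week)))
})

test_that("examination cell means match their population oracle", {
  st <- cached_study()
  cy <- list(c(2001, 2002))
  ex <- simulate_examination_cells(st$truth, st$counties, cy, exact = TRUE)
  expect_identical(ex, simulate_examination_cells(st$truth, st$counties,
                                                  cy, exact = TRUE))
  # independent oracle: direct weighted average over county x race x year
  g <- st$counties
  shares <- countyprev:::race_share_matrix(g)
  wc <- countyprev:::county_total_population(g)
  wc <- wc / sum(wc)
  s <- st$truth$params$bmi_log_sd
  m_ob <- 30 * 2 * exp(s^2 / 2) * pnorm(s)
  m_no <- 30 * 2 * exp(s^2 / 2) * pnorm(-s)
  i <- which(ex$sex == "female" & ex$age_group == "45-54")
  grid <- expand.grid(county_id = g$county_ids, race = race_groups,
                      year = 2001:2002, stringsAsFactors = FALSE)
  grid$sex <- "female"; grid$age_group <- "45-54"
  w <- wc[match(grid$county_id, g$county_ids)] *
    shares[cbind(match(grid$county_id, g$county_ids),
                 match(grid$race, race_groups))] / 2
  p <- true_prevalence(st$truth, g, grid, "obesity")
  expect_equal(ex$mean_bmi[i], sum(w * (p * m_ob + (1 - p) * m_no)),
               tolerance = 1e-12)
})

test_that("sampled examination cells converge on the population means", {
  st <- cached_study()
  cy <- list(c(2003, 2004))
  exact <- simulate_examination_cells(st$truth, st$counties, cy,
                                      exact = TRUE)
  samp <- simulate_examination_cells(st$truth, st$counties, cy,
                                     n_per_cell = 10000, seed = 21)
  expect_identical(samp, simulate_examination_cells(
    st$truth, st$counties, cy, n_per_cell = 10000, seed = 21))
  s <- st$truth$params$bmi_log_sd
  m_ob <- 30 * 2 * exp(s^2 / 2) * pnorm(s)
  m_no <- 30 * 2 * exp(s^2 / 2) * pnorm(-s)
  e2_ob <- 900 * 2 * exp(2 * s^2) * pnorm(2 * s)
  e2_no <- 900 * 2 * exp(2 * s^2) * pnorm(-2 * s)
  for (i in seq_len(nrow(exact))) {
    mu <- exact$mean_bmi[i]
    pbar <- (mu - m_no) / (m_ob - m_no)  # implied cell obesity share
    e2 <- pbar * e2_ob + (1 - pbar) * e2_no
    se <- sqrt((e2 - mu^2) / 10000)
    expect_lt(abs(samp$mean_bmi[i] - mu), 3 * se)
  }
  expect_error(simulate_examination_cells(st$truth, st$counties, list()),
               "non-empty")
  expect_error(simulate_examination_cells(st$truth, st$counties,
                                          list(c(2001, 2003))),
               "two-year")
})
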