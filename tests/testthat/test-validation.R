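fake_records <- function(counts, span = 2001:2005) {
  # counts: named vector county -> usable record count
  do.call(rbind, lapply(names(counts), function(cid) {
    n <- counts[[cid]]
    data.frame(year = rep(span, length.out = n), county_id = cid,
               sex = "female", age_group = "35-44", race = "white",
               obese = rep(c(TRUE, FALSE), length.out = n),
               stringsAsFactors = FALSE)
  }))
}

test_that("gold-standard county selection is an inclusive 900 cutoff", {
  rec <- fake_records(c(a = 900, b = 899, c = 1200))
  expect_setequal(select_gold_counties(rec, "obesity"), c("a", "c"))
  expect_setequal(select_gold_counties(rec, "obesity", min_n = 0),
                  c("a", "b", "c"))
  # records with a missing outcome do not count
  rec2 <- rec
  rec2$obese[rec2$county_id == "a"][1:5] <- NA
  expect_setequal(select_gold_counties(rec2, "obesity"), "c")
  expect_error(select_gold_counties(rec, "obesity", min_n = 1e6),
               "infeasible")
})

test_that("the gold standard is the pooled direct proportion", {
  rec <- fake_records(c(a = 900))
  expect_equal(gold_standard(rec, "a", "obesity"), 0.5)
  rec$obese <- TRUE
  expect_equal(gold_standard(rec, "a", "obesity"), 1.0)
  rec$obese[1:100] <- NA
  expect_equal(gold_standard(rec, "a", "obesity"), 1.0)  # NAs excluded
  expect_error(gold_standard(rec[0, ], "a", "obesity"), "no usable")
})

test_that("down-sampling is deterministic with separated streams", {
  rec <- fake_records(c(a = 200, b = 50))
  full <- downsample(rec, "b", 50, replicate = 1, seed = 9)
  expect_equal(nrow(full), 50)
  expect_setequal(rownames(full), rownames(rec[rec$county_id == "b", ]))
  s1 <- downsample(rec, "a", 20, replicate = 1, seed = 9)
  s1b <- downsample(rec, "a", 20, replicate = 1, seed = 9)
  expect_identical(s1, s1b)
  s2 <- downsample(rec, "a", 20, replicate = 2, seed = 9)
  expect_false(identical(rownames(s1), rownames(s2)))
  expect_error(downsample(rec, "b", 51, 1, 9), "exceeds")
})

test_that("Lin's CCC matches hand evaluation and its bounds", {
  x <- c(0.21, 0.35, 0.52, 0.18)
  expect_identical(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(c(0, 1), c(1, 0)), -1)
  expect_equal(lin_ccc(c(0, 1), c(0.5, 1.5)), 2 / 3, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    expect_lte(abs(lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
    expect_lte(abs(lin_ccc(a, b)), 1)
    # permutation invariance
    o <- sample(20)
    expect_equal(lin_ccc(a[o], b[o]), lin_ccc(a, b))
  }
  expect_error(lin_ccc(1, 1), "at least 2")
  expect_error(lin_ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("relative and squared error metrics match closed forms", {
  y <- c(0.2, 0.4)
  expect_equal(mean_relative_error(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(mean_relative_error(1.1 * y, y), 0.1)
  expect_equal(rmse(y + c(0.03, -0.04), y), sqrt(0.0025 / 2))
  expect_equal(mean_relative_error(c(0.9, 1.1) * y, y), 0)
  expect_equal(mean_relative_error(c(0.9, 1.1) * y, y, absolute = TRUE),
               0.1)
  expect_error(mean_relative_error(c(1, 2), c(0, 1)), "zero gold")
})

fake_report <- function(ccc, rmse_, mre = NULL) {
  if (is.null(mre)) mre <- setNames(rep(0, 4), model_variants)
  metrics <- do.call(rbind, lapply(model_variants, function(v)
    data.frame(variant = v, m = c(10, 10, 50, 50), replicate = c(1, 2, 1, 2),
               ccc = ccc[[v]], mre = mre[[v]], rmse = rmse_[[v]],
               failed = FALSE, stringsAsFactors = FALSE)))
  structure(list(metrics = metrics), class = "validation_report")
}

test_that("model selection ranks by CCC with RMSE/MRE tie-breaks", {
  r <- fake_report(ccc = c(naive = 0.5, covariate = 0.6, geospatial = 0.7,
                           full = 0.9),
                   rmse_ = c(naive = 0.05, covariate = 0.04,
                             geospatial = 0.03, full = 0.01))
  expect_equal(select_model(r), "full")
  tie <- fake_report(ccc = c(naive = 0.8, covariate = 0.8,
                             geospatial = 0.5, full = 0.5),
                     rmse_ = c(naive = 0.05, covariate = 0.02,
                               geospatial = 0.03, full = 0.01))
  expect_equal(select_model(tie), "covariate")
  incomplete <- r
  incomplete$metrics$failed[incomplete$metrics$variant == "naive"] <- TRUE
  expect_error(select_model(incomplete), "naive")
})

test_that("a small validation run is reproducible and well-formed", {
  st <- cached_study()
  rv <- function() run_validation(st$records, st$counties, "obesity",
                                  sexes = "female", m_values = 10L,
                                  reps = 2L, seed = 17, min_n = 60L)
  rep1 <- rv(); rep2 <- rv()
  expect_identical(rep1$metrics, rep2$metrics)
  expect_true(all(rep1$metrics$ccc >= -1 & rep1$metrics$ccc <= 1,
                  na.rm = TRUE))
  expect_true(all(rep1$metrics$rmse >= 0, na.rm = TRUE))
  expect_true(rep1$selected_variant %in% model_variants)
  expect_equal(nrow(rep1$metrics), 4 * 2)
  expect_error(run_validation(st$records, st$counties, "obesity",
                              reps = 0), "reps")
})

test_that("a variant reproducing the gold standard exactly dominates", {
  gold <- c(a = 0.2, b = 0.35, c = 0.5)
  perfect <- unname(gold)
  noisy <- perfect + c(0.05, -0.08, 0.1)
  expect_equal(lin_ccc(perfect, unname(gold)), 1)
  expect_equal(mean_relative_error(perfect, unname(gold)), 0)
  expect_equal(rmse(perfect, unname(gold)), 0)
  expect_lt(lin_ccc(noisy, unname(gold)), 1)
  expect_gt(rmse(noisy, unname(gold)), 0)
})
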