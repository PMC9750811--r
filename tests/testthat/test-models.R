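test_that("zscore standardizes to sample sd 1 and keeps back-mapping info", {
  z <- zscore(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  set.seed(16)
  x <- rnorm(50, 5, 3)
  z2 <- zscore(as.numeric(zscore(x)))
  expect_equal(as.numeric(z2), as.numeric(zscore(x)), tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "constant")
  expect_error(zscore(letters), "numeric")
})

test_that("the hierarchical fit recovers a strong simulated effect", {
  df <- sim_hier_table(20, 120, beta = 0.5, sigma_q = 1, sigma_e = 0.5,
                       seed = 17)
  fit <- quiet_fit(df, response = "y", predictors = "x", chains = 2,
                   iterations = 800, warmup = 400, seed = 1,
                   standardize = FALSE)
  expect_s3_class(fit, "hier_fit")
  expect_equal(nrow(fit$draws), 2 * 400)
  s <- fit$summary[fit$summary$parameter == "x", ]
  expect_true(s$lower95 <= 0.5 && 0.5 <= s$upper95)
  expect_gt(s$lower95, 0)
  expect_true(all(c("alpha", "x", "sigma_quadrat", "sigma_resid") %in%
                    fit$summary$parameter))
  expect_true(all(fit$draws[, "sigma_quadrat"] > 0))
  expect_true(all(fit$draws[, "sigma_resid"] > 0))
  expect_true(all(is.finite(fit$rhat)))
})

test_that("a pure-noise predictor gets a credible interval containing zero", {
  df <- sim_hier_table(25, 150, beta = 0, sigma_q = 1, sigma_e = 1, seed = 18)
  fit <- quiet_fit(df, response = "y", predictors = "x", chains = 2,
                   iterations = 800, warmup = 400, seed = 2,
                   standardize = FALSE)
  s <- fit$summary[fit$summary$parameter == "x", ]
  expect_true(s$lower95 < 0 && s$upper95 > 0)
})

test_that("duplicating rows shrinks the coefficient's posterior sd", {
  df <- sim_hier_table(15, 60, beta = 0.4, seed = 19)
  f1 <- quiet_fit(df, "y", "x", chains = 2, iterations = 800, warmup = 400,
                  seed = 3, standardize = FALSE)
  f2 <- quiet_fit(rbind(df, df), "y", "x", chains = 2, iterations = 800,
                  warmup = 400, seed = 3, standardize = FALSE)
  expect_lt(sd(f2$draws[, "x"]), sd(f1$draws[, "x"]))
})

test_that("fits validate their inputs", {
  df <- sim_hier_table(5, 20, seed = 20)
  expect_error(fit_hierarchical(df[0, ], "y", "x"), "empty")
  expect_error(fit_hierarchical(df, "nope"), "not found")
  one_q <- df[df$quadrat_id == "Q01", ]
  expect_error(fit_hierarchical(one_q, "y", "x"), "2 quadrats")
  df_na <- df; df_na$x[1] <- NA
  expect_error(fit_hierarchical(df_na, "y", "x"), "missing values")
  expect_error(fit_hierarchical(df, "y", "x", warmup = 10, iterations = 10),
               "warmup")
})

test_that("repeatability is the variance-scale ICC of the draws", {
  fake <- structure(list(
    draws = cbind(sigma_quadrat = c(1, 1, 2), sigma_resid = c(1, 1, 2)),
    converged = TRUE
  ), class = "hier_fit")
  r <- repeatability(fake)
  expect_equal(r$mean, 0.5)
  fake$draws[, "sigma_quadrat"] <- c(1e-8, 1e-9, 1e-8)
  expect_lt(repeatability(fake)$mean, 1e-10)
})

test_that("model comparison is zero on self, antisymmetric, and validated", {
  df <- sim_hier_table(15, 80, beta = 0.6, sigma_e = 0.5, seed = 21)
  base <- quiet_fit(df, "y", chains = 2, iterations = 600, warmup = 300,
                    seed = 4, standardize = FALSE)
  full <- quiet_fit(df, "y", "x", chains = 2, iterations = 600, warmup = 300,
                    seed = 4, standardize = FALSE)
  cmp <- suppressWarnings(compare_models(list(base = base, full = full), "base"))
  expect_equal(cmp$delta_elpd[cmp$model == "base"], 0)
  expect_equal(cmp$delta_se[cmp$model == "base"], 0)
  rev <- suppressWarnings(compare_models(list(base = base, full = full), "full"))
  expect_equal(rev$delta_elpd[rev$model == "base"],
               -cmp$delta_elpd[cmp$model == "full"])
  expect_equal(rev$delta_se[rev$model == "base"],
               cmp$delta_se[cmp$model == "full"])
  other <- quiet_fit(df[1:40, ], "y", chains = 2, iterations = 600,
                     warmup = 300, seed = 4, standardize = FALSE)
  expect_error(compare_models(list(a = base, b = other), "a"),
               "different observation sets")
})

test_that("band-level model encodes 4 band contrasts and recovers a
           band-specific slope", {
  set.seed(22)
  nq <- 15; bands <- SPECTRAL_BANDS
  qdf <- data.frame(quadrat_id = sprintf("Q%02d", 1:nq),
                    shannon = rnorm(nq), u = rnorm(nq, 0, 0.5))
  tab <- expand.grid(quadrat_id = qdf$quadrat_id, band = bands,
                     rep = 1:3, stringsAsFactors = FALSE)
  tab <- merge(tab, qdf, by = "quadrat_id")
  slope <- ifelse(tab$band == "G560", 0.9, 0.2)
  tab$cv <- slope * tab$shannon + tab$u + rnorm(nrow(tab), 0, 0.3)
  tab$height_m <- 2
  fit <- suppressWarnings(band_level_model(
    tab, index = "shannon", include_height = FALSE,
    chains = 2, iterations = 800, warmup = 400, seed = 5, standardize = FALSE
  ))
  expect_equal(sum(grepl("^band", fit$summary$parameter) &
                     !grepl(":", fit$summary$parameter)), 4) # blue = reference
  inter <- fit$summary[grepl(":", fit$summary$parameter), ]
  expect_equal(nrow(inter), 4)
  green <- inter[grepl("G560", inter$parameter), ]
  expect_gt(green$lower95, 0) # inflated green slope recovered
  others <- inter[!grepl("G560", inter$parameter), ]
  # null interactions stay near zero and well below the true green effect
  expect_true(all(abs(others$mean) < 0.3))
  expect_gt(green$mean, max(abs(others$mean)) + 0.3)
  expect_equal(fit$priors$coef_sd, 0.7)
  expect_equal(fit$priors$quadrat_rate, 4)
  tab4 <- tab[tab$band != "NIR840", ]
  expect_error(band_level_model(tab4), "missing band")
})

test_that("treatment contrasts use ambient as reference and detect a
           shelter artifact", {
  set.seed(23)
  nq <- 24
  treat <- rep(c("ambient", "drought", "irrigated", "procedural_control"),
               c(12, 4, 4, 4))
  qdf <- data.frame(quadrat_id = sprintf("Q%02d", 1:nq), treatment = treat,
                    u = rnorm(nq, 0, 0.3))
  tab <- merge(expand.grid(quadrat_id = qdf$quadrat_id, rep = 1:5),
               qdf, by = "quadrat_id")
  shelter <- tab$treatment %in% c("drought", "procedural_control")
  tab$cv_avg <- 1 - 0.8 * shelter + tab$u + rnorm(nrow(tab), 0, 0.3)
  fit <- suppressWarnings(treatment_model(
    tab, chains = 2, iterations = 800, warmup = 400, seed = 6,
    standardize = FALSE
  ))
  cs <- fit$summary
  expect_false(any(grepl("ambient", cs$parameter))) # reference level
  dr <- cs[grepl("drought", cs$parameter), ]
  pc <- cs[grepl("procedural", cs$parameter), ]
  ir <- cs[grepl("irrigated", cs$parameter), ]
  expect_lt(dr$upper95, 0)
  expect_lt(pc$upper95, 0)
  expect_true(ir$lower95 < 0 && ir$upper95 > 0)
  tab$treatment <- "ambient"
  expect_error(treatment_model(tab), "single level")
})

test_that("the interaction-parsimony selection rule is explicit", {
  df <- sim_hier_table(15, 90, beta = 0.5, sigma_e = 0.5, seed = 24)
  df$h <- rnorm(nrow(df))
  base <- quiet_fit(df, "y", chains = 2, iterations = 600, warmup = 300,
                    seed = 7, standardize = FALSE)
  uni <- quiet_fit(df, "y", c("x", "h"), chains = 2, iterations = 600,
                   warmup = 300, seed = 7, standardize = FALSE)
  inter <- quiet_fit(df, "y", c("x", "h", "x:h"), chains = 2,
                     iterations = 600, warmup = 300, seed = 7,
                     standardize = FALSE)
  fits <- list(base = base, univariate = uni, interaction = inter)
  cmp <- suppressWarnings(compare_models(fits, "base"))
  sel <- select_preferred_model(fits, cmp)
  if (sel$best_elpd == "interaction") {
    # no true interaction in the data: rule must fall back to univariate
    expect_true(sel$rule_applied)
    expect_equal(sel$selected, "univariate")
  } else {
    expect_false(sel$rule_applied)
  }
})
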