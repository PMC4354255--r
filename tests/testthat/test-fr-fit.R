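within_spec <- function(base_prey = "A_aquaticus")
  fr_spec(h_terms = c("predator", "fish", "parasitised",
                      "predator:fish", "predator:parasitised",
                      "parasitised:fish", "predator:parasitised:fish"),
          base = list(prey = base_prey))

test_that("indicator rows: base cell is all-zero, interactions are products", {
  units <- enumerate_design(prey_list = "A_aquaticus", replicates = 1)
  spec <- within_spec()
  X <- build_indicator_rows(units, spec)
  base <- units$predator_species == "G_d_celticus" & !units$parasitised &
    !units$fish_present
  expect_true(all(X$Xh[base, -1] == 0))
  expect_true(all(X$Xh[, 1] == 1))
  expect_equal(ncol(X$Xa), 1)  # simplified attack rate: intercept only

  # enumeration oracle over the 8 treatment cells
  cells <- unique(units[, c("predator_species", "parasitised", "fish_present")])
  Xc <- build_indicator_rows(cbind(prey_species = "A_aquaticus", cells), spec)$Xh
  P <- as.numeric(cells$predator_species == "G_pulex")
  Fi <- as.numeric(cells$fish_present)
  Pa <- as.numeric(cells$parasitised)
  oracle <- unname(cbind(1, P, Fi, Pa, P * Fi, P * Pa, Fi * Pa, P * Fi * Pa))
  expect_equal(unname(Xc[, c("intercept", "predatorG_pulex", "fishTRUE",
                             "parasitisedTRUE", "predatorG_pulex:fishTRUE",
                             "predatorG_pulex:parasitisedTRUE",
                             "fishTRUE:parasitisedTRUE",
                             "predatorG_pulex:fishTRUE:parasitisedTRUE")]),
               oracle)
})

test_that("prey-coded indicator rows mark the non-base prey species", {
  units <- enumerate_design(replicates = 1)
  spec <- fr_spec(a_terms = "prey", h_terms = "prey")
  X <- build_indicator_rows(units, spec)
  br <- units$prey_species == "B_rhodani"
  expect_true(all(X$Xa[br, "preyB_rhodani"] == 1))
  expect_true(all(X$Xa[br, "preySimulium"] == 0))
  expect_true(all(X$Xa[units$prey_species == "A_aquaticus", -1] == 0))
  # unseen base level of a coded factor errors with its name
  expect_error(build_indicator_rows(units, fr_spec(a_terms = "prey",
                                                   base = list(prey = "nope"))),
               "nope")
})

test_that("the binomial negative log-likelihood is exact and additive", {
  spec <- spec_plain()
  rec1 <- data.frame(prey_species = "A_aquaticus",
                     predator_species = "G_d_celticus", parasitised = FALSE,
                     fish_present = FALSE, density = 2L, killed = 1L)
  # choose (a, h) whose Rogers expectation is exactly half the density
  a_half <- uniroot(function(a) rogers_expected_eaten(a, 0.1, 2, 1) - 1,
                    c(0.01, 10))$root
  theta <- c(a_half, 0.1)
  expect_equal(nll_binomial(theta, rec1, spec), -log(2 * 0.5 * 0.5),
               tolerance = 1e-6)
  expect_equal(nll_binomial(theta, rec1[0, ], spec), 0)
  rec2 <- rbind(rec1, transform(rec1, density = 6L, killed = 4L))
  expect_equal(nll_binomial(theta, rec2, spec),
               nll_binomial(theta, rec1, spec) +
                 nll_binomial(theta, rec2[2, ], spec))
  # infeasible parameters are pushed away with an infinite penalty
  expect_identical(nll_binomial(c(-0.1, 0.1), rec1, spec), Inf)
  expect_identical(nll_binomial(c(0.5, -0.1), rec1, spec), Inf)
})

test_that("fit_fr recovers generating parameters on one seeded dataset", {
  sc <- test_scenario(seed = 51, replicates = 40)
  sim <- simulate_dataset(sc)
  fit <- fit_fr(base_cell(sim$trials), spec_plain(), n_starts = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["a_intercept"]] - 0.981), 3 * fit$se[["a_intercept"]])
  expect_lt(abs(fit$theta[["h_intercept"]] - 0.307), 3 * fit$se[["h_intercept"]])
})

test_that("degenerate saturated data raise the boundary flag", {
  rec <- data.frame(prey_species = "A_aquaticus",
                    predator_species = "G_d_celticus", parasitised = FALSE,
                    fish_present = FALSE,
                    density = rep(c(2L, 4L, 6L), each = 3))
  rec$killed <- rec$density
  fit <- suppressWarnings(fit_fr(rec, spec_plain(), n_starts = 2))
  expect_true(fit$boundary)
  expect_false(fit$converged)
})

test_that("contrast rows reproduce Wald arithmetic and the delta method", {
  # reporting arithmetic for a printed estimate/SE pair
  w <- wald_z(0.992, 0.155)
  expect_equal(w$z, 6.4, tolerance = 1e-3)
  expect_equal(wald_z(1.959964, 1)$p, 0.05, tolerance = 1e-6)

  sim <- simulate_dataset(test_scenario(seed = 52, replicates = 8,
                                        h_effects = c(predator = -0.15)))
  spec <- fr_spec(h_terms = "predator", base = list(prey = "A_aquaticus"))
  fit <- fit_fr(sim$trials, spec)
  ct <- contrast_table(fit)
  expect_equal(ct$z, unname(fit$theta / fit$se))
  # group-level handling time of the invasive predator: intercept + effect
  w3 <- c(0, 1, 1)
  cc <- contrast_table(fit, contrasts = list(h_pulex = w3))
  expect_equal(cc$estimate, sum(fit$theta * w3))
  expect_equal(cc$se, sqrt(drop(t(w3) %*% fit$vcov %*% w3)))
  expect_error(contrast_table(fit, contrasts = list(bad = c(1, 1))), "length")
})

test_that("swapping the base level leaves cell-level parameters invariant", {
  sim <- simulate_dataset(test_scenario(seed = 53, replicates = 8,
                                        h_effects = c(predator = -0.1,
                                                      fish = 0.05)))
  spec_a <- fr_spec(h_terms = c("predator", "fish"),
                    base = list(prey = "A_aquaticus"))
  spec_b <- fr_spec(h_terms = c("predator", "fish"),
                    base = list(prey = "A_aquaticus", predator = "G_pulex",
                                fish = TRUE))
  fit_a <- fit_fr(sim$trials, spec_a)
  fit_b <- fit_fr(sim$trials, spec_b)
  # cell-level h for (G_pulex, fish): intercept+both effects vs intercept
  h_a <- sum(fit_a$theta[c("h_intercept", "h_predatorG_pulex", "h_fishTRUE")])
  h_b <- fit_b$theta[["h_intercept"]]
  expect_equal(h_a, h_b, tolerance = 1e-4)
  expect_equal(fit_a$logLik, fit_b$logLik, tolerance = 1e-6)
})

test_that("a nested simplified model never beats the full model on logLik", {
  sim <- simulate_dataset(test_scenario(seed = 54, replicates = 4,
                                        h_effects = c(predator = -0.12)))
  full <- fit_fr(sim$trials, fr_spec(a_terms = "predator",
                                     h_terms = "predator",
                                     base = list(prey = "A_aquaticus")))
  simp <- fit_fr(sim$trials, fr_spec(h_terms = "predator",
                                     base = list(prey = "A_aquaticus")))
  expect_gte(full$logLik, simp$logLik - 1e-6)
})

test_that("MLE bias shrinks as replication grows", {
  reps_grid <- c(4, 16, 64)
  bias <- sapply(reps_grid, function(reps) {
    err <- vapply(1:12, function(s) {
      sim <- simulate_dataset(test_scenario(seed = 7000 + 100 * reps + s,
                                            replicates = reps))
      fit <- fit_fr(base_cell(sim$trials), spec_plain(), n_starts = 2)
      c(fit$theta[["a_intercept"]] - 0.981, fit$theta[["h_intercept"]] - 0.307)
    }, numeric(2))
    rowMeans(abs(err))
  })
  expect_lt(bias[1, 3], bias[1, 1])
  expect_lt(bias[2, 3], bias[2, 1])
})

test_that("null treatment effects give calibrated z-scores and uniform p", {
  ps <- vapply(1:120, function(s) {
    sim <- simulate_dataset(test_scenario(seed = 9000 + s, replicates = 4))
    fit <- fit_fr(sim$trials,
                  fr_spec(h_terms = "predator",
                          base = list(prey = "A_aquaticus")),
                  n_starts = 2)
    fit$p[["h_predatorG_pulex"]]
  }, numeric(1))
  # approximately 5% false positives at alpha = 0.05
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
  # and approximately uniform p-values
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("bootstrap envelopes are deterministic, ordered and contain the fit", {
  sim <- simulate_dataset(test_scenario(seed = 55, replicates = 8))
  cell <- base_cell(sim$trials)
  spec <- spec_plain()
  fit <- fit_fr(cell, spec)
  b1 <- bootstrap_fr(cell, spec, n_boot = 120, seed = 77, fit = fit)
  b2 <- bootstrap_fr(cell, spec, n_boot = 120, seed = 77, fit = fit)
  expect_identical(b1$envelope, b2$envelope)
  expect_true(all(b1$envelope$lower <= b1$envelope$upper))
  expect_equal(b1$n_boot - b1$n_failed, nrow(b1$draws))

  curve <- predict_curve_ci(fit, b1)
  inside <- curve$mean >= curve$lower & curve$mean <= curve$upper
  expect_gte(mean(inside), 0.95)
  expect_equal(curve$mean,
               rogers_expected_eaten(fit$theta[["a_intercept"]],
                                     fit$theta[["h_intercept"]],
                                     curve$density, 1))
})

test_that("envelope width shrinks with replication", {
  widths <- vapply(c(4L, 8L), function(reps) {
    ws <- vapply(1:6, function(s) {
      sim <- simulate_dataset(test_scenario(seed = 600 + s, replicates = reps))
      cell <- base_cell(sim$trials)
      b <- bootstrap_fr(cell, spec_plain(), n_boot = 100, seed = s)
      mean(b$envelope$upper - b$envelope$lower)
    }, numeric(1))
    mean(ws)
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("a collapsed zero-attack curve is flagged", {
  fit <- list(theta = c(a_intercept = 0, h_intercept = 0.1),
              spec = spec_plain())
  class(fit) <- "fr_fit"
  curve <- predict_curve_ci(fit, grid = c(2, 10, 30))
  expect_true(attr(curve, "collapsed"))
  expect_true(all(curve$mean == 0))
})
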