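test_that("effective_params applies treatment coding additively", {
  sc <- default_scenario()
  base <- list(prey_species = "A_aquaticus", predator_species = "G_d_celticus",
               parasitised = FALSE, fish_present = FALSE)
  expect_equal(effective_params(sc, base), c(a = 0.981, h = 0.307))

  pulex <- utils::modifyList(base, list(predator_species = "G_pulex"))
  expect_equal(effective_params(sc, pulex)[["h"]], 0.307 - 0.178)

  # three-factor cell: sum over every active main and interaction term must
  # equal a brute-force enumeration of the terms
  full <- list(prey_species = "A_aquaticus", predator_species = "G_pulex",
               parasitised = TRUE, fish_present = TRUE)
  eff <- sc$prey$A_aquaticus$h$effects
  expect_equal(effective_params(sc, full)[["h"]], 0.307 + sum(eff))
  two <- utils::modifyList(base, list(predator_species = "G_pulex",
                                      fish_present = TRUE))
  expect_equal(effective_params(sc, two)[["h"]],
               0.307 + eff[["predator"]] + eff[["fish"]] +
                 eff[["predator:fish"]])
})

test_that("a scenario implying nonpositive parameters is rejected, naming the cell", {
  prey <- list(A_aquaticus = list(
    a = list(intercept = 0.5),
    h = list(intercept = 0.1, effects = c(predator = -0.2))))
  expect_error(fr_scenario(prey = prey), "nonpositive.*G_pulex")
})

test_that("simulate_kills respects degenerate inputs in both observation models", {
  for (m in c("binomial", "event")) {
    expect_identical(simulate_kills(0, 0.1, 20, 1, m), 0L)
    expect_identical(simulate_kills(1, 0.1, 0, 1, m), 0L)
  }
})

test_that("binomial-model kill means converge to the Rogers expectation", {
  set.seed(5)
  for (N0 in c(4, 30)) {
    draws <- replicate(10000, simulate_kills(0.981, 0.307, N0, 1, "binomial"))
    expected <- rogers_expected_eaten(0.981, 0.307, N0, 1)
    se <- sqrt(expected * (1 - expected / N0)) / sqrt(10000)
    expect_lt(abs(mean(draws) - expected), 4 * se)
  }
})

test_that("event-model kills match an independent depletion-process simulation", {
  set.seed(6)
  n <- 10000
  draws <- replicate(n, simulate_kills(1, 0.1, 20, 1, "event"))
  oracle <- replicate(n, oracle_event_kills(1, 0.1, 20, 1))
  mc_se <- sqrt(stats::var(draws) / n + stats::var(oracle) / n)
  expect_lt(abs(mean(draws) - mean(oracle)), 3 * mc_se)
  # handling-limited ceiling
  expect_lte(max(draws), floor(1 / 0.1) + 1)
})

test_that("simulate_dataset matches the design and is seed-deterministic", {
  sc <- test_scenario(seed = 12)
  sim <- simulate_dataset(sc)
  expect_equal(nrow(sim$trials), 224)
  expect_s3_class(validate_records(sim$trials), "data.frame")

  sim2 <- simulate_dataset(test_scenario(seed = 12))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records(sim$trials, p1); write_records(sim2$trials, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(sim$controls, sim2$controls)

  sim3 <- simulate_dataset(test_scenario(seed = 13))
  expect_false(identical(sim$trials$killed, sim3$trials$killed))
})

test_that("partial consumption honours the recording rule and the zero curve", {
  sc <- test_scenario(seed = 14, partial = c(intercept = -50, slope = 0))
  sim <- simulate_dataset(sc)
  expect_true(all(sim$trials$partially_eaten == 0))

  sc2 <- test_scenario(seed = 14, partial = c(intercept = 10, slope = 0))
  sim2 <- simulate_dataset(sc2)
  many <- sim2$trials$killed >= 2
  expect_true(all(sim2$trials$partially_eaten[many] == sim2$trials$killed[many]))
  expect_true(all(sim2$trials$partially_eaten[!many] == 0))
})

test_that("with redraw enabled the emitted design carries no excluded replicates", {
  sc <- test_scenario(seed = 15)
  sc$p_moult <- 0.3; sc$p_acanthella <- 0.3; sc$p_multiple <- 0.2
  sc$redraw_excluded <- TRUE
  sim <- simulate_dataset(sc)
  flt <- filter_replicates(sim$trials, exclude_mismatch = FALSE)
  expect_equal(nrow(flt$excluded), 0)
  expect_equal(nrow(flt$kept), 224)
})

test_that("a zero-effect scenario yields exchangeable treatment cells", {
  # kills in any two cells of the factorial should be indistinguishable:
  # two-sample KS non-significant at alpha = 0.01 in >= 95% of seeds
  ok <- vapply(1:40, function(s) {
    sim <- simulate_dataset(test_scenario(seed = 1000 + s, replicates = 2))
    tr <- sim$trials
    g1 <- tr$killed[tr$predator_species == "G_d_celticus"]
    g2 <- tr$killed[tr$predator_species == "G_pulex"]
    suppressWarnings(stats::ks.test(g1, g2)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("scenario YAML round-trips through file", {
  sc <- default_scenario(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  scenario_to_yaml(sc, path)
  back <- scenario_from_yaml(path)
  expect_equal(back$prey$A_aquaticus$h$effects, sc$prey$A_aquaticus$h$effects)
  expect_identical(simulate_dataset(back)$trials, simulate_dataset(sc)$trials)
})
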