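test_that("the factorial design enumerates to the expected cardinalities", {
  d1 <- enumerate_design(prey_list = "A_aquaticus")
  expect_equal(nrow(d1), 224)
  d3 <- enumerate_design()
  expect_equal(nrow(d3), 3 * 224)
  expect_equal(nrow(enumerate_design(predator_levels = "G_pulex",
                                     parasitism_levels = FALSE,
                                     fish_levels = FALSE,
                                     density_ladder = 5, replicates = 1,
                                     prey_list = "Simulium")), 1)
  expect_error(enumerate_design(density_ladder = c(2, 2, 4)), "duplicate")
})

test_that("the design is balanced and uniquely keyed", {
  d <- enumerate_design(prey_list = "A_aquaticus")
  expect_equal(sum(d$parasitised), nrow(d) / 2)
  expect_equal(sum(d$fish_present), nrow(d) / 2)
  expect_equal(as.vector(table(d$predator_species)), rep(nrow(d) / 2, 2))
  key <- with(d, paste(prey_species, predator_species, parasitised,
                       fish_present, density, replicate))
  expect_false(anyDuplicated(key) > 0)
  # day blocks of 22 pots
  expect_equal(max(table(d$day)), 22)
  # seeded day assignment is reproducible and a permutation of the rotation
  d_a <- enumerate_design(prey_list = "A_aquaticus", seed = 9)
  d_b <- enumerate_design(prey_list = "A_aquaticus", seed = 9)
  expect_identical(d_a, d_b)
  expect_equal(sort(d_a$day), sort(d$day))
})

test_that("trial CSV round-trip is lossless, including booleans", {
  sim <- simulate_dataset(test_scenario(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(sim$trials, path)
  back <- read_records(path)
  expect_equal(back, sim$trials, ignore_attr = TRUE)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_controls(sim$controls, cpath)
  expect_equal(read_controls(cpath), sim$controls, ignore_attr = TRUE)
})

test_that("schema and invariant violations are reported with row context", {
  sim <- simulate_dataset(test_scenario(seed = 3))
  bad <- sim$trials
  bad$killed[5] <- bad$density[5] + 1L
  expect_error(validate_records(bad), "row 5")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$trials[, -1], path, row.names = FALSE)
  expect_error(read_records(path), "pot_id")
  # header-only file reads to an empty collection
  empty <- sim$trials[0, ]
  write_records(empty, path)
  expect_equal(nrow(read_records(path)), 0)
})

test_that("replicate exclusion assigns a reason to every dropped record", {
  sim <- simulate_dataset(test_scenario(seed = 4))
  rec <- sim$trials
  rec$moulted[1] <- TRUE
  rec$parasitised[2] <- TRUE; rec$infection_stage[2] <- "multiple_cystacanths"
  rec$parasitised[3] <- TRUE; rec$infection_stage[3] <- "acanthella"
  rec$parasitised[4] <- TRUE; rec$infection_stage[4] <- "none"
  rec$parasitised[5:nrow(rec)] <- FALSE
  rec$infection_stage[5:nrow(rec)] <- "none"
  flt <- filter_replicates(rec)
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(rec))
  expect_setequal(flt$excluded$reason[1:4],
                  c("moulted", "multiple_cystacanths", "acanthella",
                    "parasite_status_mismatch"))
  expect_true(all(!is.na(flt$excluded$reason)))
  # mismatch exclusion is configurable
  flt2 <- filter_replicates(rec, exclude_mismatch = FALSE)
  expect_equal(nrow(flt2$excluded), 3)
  # identical input gives identical reasons
  expect_identical(filter_replicates(rec)$excluded, flt$excluded)
})

test_that("control survival QC computes stratified proportions and a pass flag", {
  ctl <- data.frame(prey_species = rep(c("A_aquaticus", "Simulium"), each = 2),
                    density = c(10, 10, 10, 10),
                    fish_present = c(FALSE, TRUE, FALSE, TRUE),
                    dead = c(0, 0, 0, 0))
  q <- control_survival_qc(ctl)
  expect_equal(q$overall, 1)
  expect_true(q$pass)
  ctl$dead <- c(0, 0, 8, 8)  # 16/40 dead overall
  q2 <- control_survival_qc(ctl)
  expect_equal(q2$overall, 0.6)
  false_strata <- q2$by_stratum[q2$by_stratum$prey_species == "Simulium", ]
  expect_equal(false_strata$survival, c(0.2, 0.2))
  expect_false(q2$pass)
  # survival of 0.96 fails the 0.965 threshold
  ctl3 <- data.frame(prey_species = "A_aquaticus", density = 100,
                     fish_present = FALSE, dead = 4)
  expect_false(control_survival_qc(ctl3)$pass)
  expect_equal(control_survival_qc(ctl3)$overall, 0.96)
  # all dead
  ctl3$dead <- 100
  expect_equal(control_survival_qc(ctl3)$overall, 0)
  expect_error(control_survival_qc(ctl3[0, ]), "control")
})

test_that("day-bias diagnostic recovers degenerate correlations and exact p", {
  rec <- data.frame(prey_species = "A_aquaticus", day = rep(1:5, each = 2),
                    killed = 3)
  db <- day_bias_diagnostic(rec)
  expect_equal(db$summary$rho, 0)

  rec2 <- data.frame(prey_species = "A_aquaticus", day = 1:6, killed = 1:6)
  expect_equal(day_bias_diagnostic(rec2)$summary$rho, 1)

  # n = 5, arbitrary tie-free values: exact permutation enumeration over 5!
  set.seed(20)
  rec3 <- data.frame(prey_species = "A_aquaticus", day = c(3, 1, 4, 2, 5),
                     killed = c(2, 9, 4, 7, 1))
  db3 <- day_bias_diagnostic(rec3)
  expect_equal(db3$summary$p,
               oracle_spearman_exact(rec3$day, rec3$killed), tolerance = 1e-12)

  # single day is flagged, not an error
  rec4 <- data.frame(prey_species = "A_aquaticus", day = 1, killed = c(1, 2))
  expect_false(day_bias_diagnostic(rec4)$summary$assessable)
})
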