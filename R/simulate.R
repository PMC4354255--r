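#' Simulation scenarios for community-module experiments
#'
#' A scenario bundles everything needed to generate a synthetic
#' community-module dataset: the treatment coding of attack rate and
#' handling time per prey species (intercept plus treatment-coded main and
#' interaction effects, matching the indicator-variable parameterisation
#' used by the fitting machinery), the trial duration, the factorial design,
#' the observation model for kills, the density-dependent partial-consumption
#' curve per prey, per-individual control mortality, replicate-exclusion
#' probabilities, and a root seed.
#'
#' Effects are keyed by the factor indicators \code{"predator"}
#' (1 for \emph{G. pulex}), \code{"parasitised"} and \code{"fish"}, with
#' interactions written \code{"predator:fish"} etc.; an interaction term is
#' active exactly when all its main-effect indicators are 1, and the cell
#' value is the intercept plus the sum of active effects (treatment coding).
#'
#' @param prey named list, one element per prey species; each element is a
#'   list with components \code{a} and \code{h}, each itself
#'   \code{list(intercept = , effects = c(...))} (effects optional), and
#'   optionally \code{partial = c(intercept = , slope = )} giving the
#'   logit-linear dependence of the per-killed-prey partial-consumption
#'   probability on density.
#' @param T trial duration in experiment-duration units (default 1, the
#'   40-h trial).
#' @param density_ladder prey densities (default 2, 4, 6, 8, 10, 20, 30).
#' @param replicates replicates per treatment cell (default 4).
#' @param observation_model \code{"binomial"} (kills drawn
#'   Binomial(N0, expected/N0) — exactly the fitting likelihood) or
#'   \code{"event"} (mechanistic alternating search/handling process,
#'   deliberately slightly misspecified relative to the likelihood).
#' @param control_mortality per-individual death probability in control
#'   pots (default 0.015, keeping control survival comfortably above the
#'   0.965 QC threshold).
#' @param control_replicates control pots per prey density and fish level
#'   (default 4).
#' @param p_moult probability a replicate's amphipod moults during the
#'   trial (default 0.02).
#' @param p_acanthella,p_multiple probabilities that a parasitised
#'   \emph{G. pulex} harbours early-stage acanthella or multiple
#'   cystacanths (default 0.08 each); both trigger exclusion downstream.
#' @param redraw_excluded if \code{TRUE}, excluded replicates are redrawn
#'   with a fresh animal so the emitted design stays balanced (mirroring
#'   the repeat-with-new-animal protocol); if \code{FALSE} (default) the
#'   flagged records are emitted for the exclusion filter to handle.
#' @param seed root integer seed; per-unit substream seeds are drawn from
#'   it once and assigned by unit index, so row order never changes draws.
#' @return an object of class \code{"fr_scenario"}.
#' @seealso \code{\link{default_scenario}} for the default three-prey
#'   configuration, \code{\link{simulate_dataset}}.
#' @export
fr_scenario <- function(prey, T = 1, density_ladder = DENSITY_LADDER,
                        replicates = 4,
                        observation_model = c("binomial", "event"),
                        control_mortality = 0.015, control_replicates = 4,
                        p_moult = 0.02, p_acanthella = 0.08, p_multiple = 0.08,
                        redraw_excluded = FALSE, seed = 1L) {
  observation_model <- match.arg(observation_model)
  if (is.null(names(prey)) || any(!nzchar(names(prey))))
    stop("`prey` must be a named list (one element per prey species)")
  for (p in c(control_mortality, p_moult, p_acanthella, p_multiple))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  sc <- structure(list(prey = prey, T = T, density_ladder = density_ladder,
                       replicates = replicates,
                       observation_model = observation_model,
                       control_mortality = control_mortality,
                       control_replicates = control_replicates,
                       p_moult = p_moult, p_acanthella = p_acanthella,
                       p_multiple = p_multiple,
                       redraw_excluded = redraw_excluded,
                       seed = as.integer(seed)),
                  class = "fr_scenario")
  # every treatment cell must imply strictly positive a and h
  units <- enumerate_design(density_ladder = density_ladder,
                            replicates = 1, prey_list = names(prey))
  for (i in seq_len(nrow(units))) effective_params(sc, units[i, ])
  sc
}

#' Default community-module scenario
#'
#' The study conditions used throughout: three prey species
#' (\emph{A. aquaticus}, \emph{Simulium} spp., \emph{B. rhodani}), a
#' 2 x 2 x 2 factorial (predator species x parasitism x fish) over seven
#' densities with four replicates (224 trials per prey species), Type II
#' consumption with an intercept-only attack rate per prey and a fully
#' treatment-coded handling time, and logistic-in-density partial
#' consumption calibrated so pooled partial-consumption proportions are
#' rare for \emph{A. aquaticus} and substantial for \emph{Simulium} and
#' \emph{B. rhodani}.
#'
#' @param seed root seed.
#' @param ... overrides passed on to \code{\link{fr_scenario}}.
#' @return an \code{fr_scenario}.
#' @export
default_scenario <- function(seed = 1L, ...) {
  prey <- list(
    A_aquaticus = list(
      a = list(intercept = 0.981),
      h = list(intercept = 0.307,
               effects = c(predator = -0.178, fish = 0.047,
                           parasitised = -0.004,
                           "predator:fish" = 0.059,
                           "predator:parasitised" = 0.104,
                           "parasitised:fish" = -0.034,
                           "predator:parasitised:fish" = -0.135)),
      partial = c(intercept = -4.95, slope = 0.02)),
    Simulium = list(
      a = list(intercept = 2.564),
      h = list(intercept = 0.162,
               effects = c(predator = -0.056, fish = 0.003,
                           parasitised = -0.041,
                           "predator:fish" = -0.016,
                           "predator:parasitised" = -0.002,
                           "parasitised:fish" = 0.010,
                           "predator:parasitised:fish" = 0.030)),
      partial = c(intercept = -3.0, slope = 0.07)),
    B_rhodani = list(
      a = list(intercept = 1.362),
      h = list(intercept = 0.063,
               effects = c(predator = 0.008, fish = 0.023,
                           parasitised = 0.016,
                           "predator:fish" = -0.032,
                           "predator:parasitised" = 0.059,
                           "parasitised:fish" = -0.075,
                           "predator:parasitised:fish" = 0.047)),
      partial = c(intercept = -2.6, slope = 0.08)))
  fr_scenario(prey = prey, seed = seed, ...)
}

unit_indicators <- function(unit) {
  c(predator = as.numeric(unit$predator_species == "G_pulex"),
    parasitised = as.numeric(isTRUE(unit$parasitised) || unit$parasitised == TRUE),
    fish = as.numeric(isTRUE(unit$fish_present) || unit$fish_present == TRUE))
}

eval_coding <- function(coding, ind) {
  val <- coding$intercept
  eff <- coding$effects
  if (length(eff)) {
    for (nm in names(eff)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (any(!parts %in% names(ind)))
        stop("unknown factor in effect name: ", nm)
      if (all(ind[parts] == 1)) val <- val + eff[[nm]]
    }
  }
  val
}

#' Effective attack rate and handling time for one treatment cell
#'
#' Resolves the scenario's treatment coding for one experimental unit:
#' intercept plus the sum of effects whose indicator products are 1.
#'
#' @param scenario an \code{\link{fr_scenario}}.
#' @param unit a one-row experimental-unit data.frame (or list) with
#'   \code{prey_species}, \code{predator_species}, \code{parasitised},
#'   \code{fish_present}.
#' @return named numeric vector \code{c(a = , h = )}, strictly positive.
#' @examples
#' sc <- default_scenario()
#' u <- list(prey_species = "A_aquaticus", predator_species = "G_pulex",
#'           parasitised = FALSE, fish_present = FALSE)
#' effective_params(sc, u)  # h = 0.307 - 0.178 = 0.129
#' @export
effective_params <- function(scenario, unit) {
  prey <- as.character(unit$prey_species)
  cfg <- scenario$prey[[prey]]
  if (is.null(cfg)) stop("prey species not covered by scenario: ", prey)
  ind <- unit_indicators(unit)
  a <- eval_coding(cfg$a, ind)
  h <- eval_coding(cfg$h, ind)
  if (a <= 0 || h <= 0)
    stop(sprintf(
      "scenario implies nonpositive parameters (a = %g, h = %g) in cell %s/%s/par=%s/fish=%s",
      a, h, prey, unit$predator_species, unit$parasitised, unit$fish_present))
  c(a = a, h = h)
}

#' Draw the number of prey killed in one trial
#'
#' Two generative models. \code{"binomial"}: kills are
#' Binomial(\code{N0}, expected/\code{N0}) around the Rogers expectation —
#' exactly the distribution assumed by the fitting likelihood, so
#' parameter-recovery checks are unconfounded by misspecification.
#' \code{"event"}: a mechanistic alternating renewal process — search times
#' exponential with total hazard \code{a * n} (n prey remaining), each kill
#' followed by a fixed handling block of length \code{h} — run until time
#' \code{T} or prey exhaustion; its kill distribution differs slightly from
#' binomial, which is the point (robustness testing).
#'
#' Uses the current RNG state.
#'
#' @param a,h attack rate and handling time (\code{>= 0}).
#' @param N0 initial prey count.
#' @param T trial duration.
#' @param observation_model \code{"binomial"} or \code{"event"}.
#' @return integer number of prey killed, in \code{[0, N0]}.
#' @export
simulate_kills <- function(a, h, N0, T = 1,
                           observation_model = c("binomial", "event")) {
  observation_model <- match.arg(observation_model)
  if (a < 0 || h < 0 || N0 < 0 || T <= 0) stop("invalid simulation arguments")
  if (N0 == 0 || a == 0) return(0L)
  if (observation_model == "binomial") {
    p <- rogers_expected_eaten(a, h, N0, T) / N0
    return(stats::rbinom(1L, N0, p))
  }
  t <- 0; n <- N0; kills <- 0L
  repeat {
    if (n == 0) break
    t <- t + stats::rexp(1L, rate = a * n)
    if (t > T) break
    kills <- kills + 1L
    n <- n - 1L
    t <- t + h
  }
  kills
}

draw_infection_stage <- function(unit, p_acanthella, p_multiple) {
  if (!unit$parasitised) return("none")
  if (unit$predator_species == "G_d_celticus") return("spore_mass")
  u <- stats::runif(1)
  if (u < p_acanthella) "acanthella"
  else if (u < p_acanthella + p_multiple) "multiple_cystacanths"
  else "single_cystacanth"
}

#' Simulate a community-module dataset
#'
#' Generates one trial record per experimental unit of the scenario's
#' factorial design, plus control-pot records. Kills are drawn by
#' \code{\link{simulate_kills}} at the cell's effective (a, h); the number
#' of partially eaten prey is Binomial(kills, p(density)) when two or more
#' prey were killed (the recording rule) and 0 otherwise, with p a logistic
#' function of density — partial consumption tracks density, independent of
#' the treatment factors. Moulting and disqualifying infection stages are
#' drawn per replicate; with \code{redraw_excluded = TRUE} such replicates
#' are redrawn with a fresh substream, keeping the emitted design balanced.
#'
#' Each unit uses its own RNG substream whose seed is drawn once from the
#' root-seeded stream and assigned by unit index, so the same root seed
#' yields an identical dataset regardless of evaluation order, and the
#' substreams are mutually decorrelated.
#'
#' @param scenario an \code{\link{fr_scenario}}.
#' @return list with \code{trials} (trial records, see
#'   \code{\link{read_records}} for the schema) and \code{controls}.
#' @export
simulate_dataset <- function(scenario) {
  units <- enumerate_design(density_ladder = scenario$density_ladder,
                            replicates = scenario$replicates,
                            prey_list = names(scenario$prey),
                            seed = scenario$seed)
  old <- local_rng(scenario$seed)
  on.exit(restore_rng(old), add = TRUE)

  n <- nrow(units)
  n_ctl <- 2L * length(scenario$density_ladder) * scenario$control_replicates *
    length(scenario$prey)
  # per-unit substream seeds drawn from the root stream: random, unaligned
  # seeds give decorrelated streams (arithmetically spaced seeds produce
  # weak but consequential cross-stream correlation under Mersenne-Twister
  # initialisation), and indexing by unit keeps draws row-order invariant
  unit_seeds <- sample.int(2147483647L, n + n_ctl, replace = FALSE)
  # effective (a, h) per treatment cell, then vectorized expectations
  cell_key <- paste(units$prey_species, units$predator_species,
                    units$parasitised, units$fish_present)
  first_of_cell <- !duplicated(cell_key)
  cell_ab <- vapply(which(first_of_cell),
                    function(i) effective_params(scenario, units[i, ]),
                    numeric(2))
  colnames(cell_ab) <- cell_key[first_of_cell]
  a_row <- cell_ab["a", cell_key]
  h_row <- cell_ab["h", cell_key]
  binom_p <- rogers_expected_eaten(a_row, h_row, units$density, scenario$T) /
    units$density
  partial_p <- vapply(seq_len(n), function(i) {
    pp <- scenario$prey[[units$prey_species[i]]]$partial
    if (is.null(pp)) 0
    else stats::plogis(pp[["intercept"]] + pp[["slope"]] * units$density[i])
  }, numeric(1))

  killed <- integer(n); partial <- integer(n)
  moulted <- logical(n); stage <- character(n)
  for (i in seq_len(n)) {
    unit <- list(parasitised = units$parasitised[i],
                 predator_species = units$predator_species[i])
    set.seed(unit_seeds[i])
    attempt <- 0L
    repeat {
      # a redraw (fresh animal for an excluded replicate) continues the
      # unit's own substream
      m <- stats::runif(1) < scenario$p_moult
      st <- draw_infection_stage(unit, scenario$p_acanthella, scenario$p_multiple)
      excluded <- m || st %in% c("acanthella", "multiple_cystacanths")
      if (!scenario$redraw_excluded || !excluded || attempt >= 100L) break
      attempt <- attempt + 1L
    }
    ne <- if (scenario$observation_model == "binomial")
      stats::rbinom(1L, units$density[i], binom_p[i])
    else
      simulate_kills(a_row[i], h_row[i], units$density[i], scenario$T, "event")
    pe <- if (ne >= 2 && partial_p[i] > 0) stats::rbinom(1L, ne, partial_p[i])
    else 0L
    killed[i] <- ne; partial[i] <- pe; moulted[i] <- m; stage[i] <- st
  }
  trials <- cbind(units, killed = killed, partially_eaten = partial,
                  moulted = moulted, infection_stage = stage,
                  stringsAsFactors = FALSE)
  validate_records(trials)

  ctl <- expand.grid(replicate = seq_len(scenario$control_replicates),
                     density = scenario$density_ladder,
                     fish_present = c(FALSE, TRUE),
                     prey_species = names(scenario$prey),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctl <- ctl[order(ctl$prey_species, ctl$fish_present, ctl$density, ctl$replicate), ]
  rownames(ctl) <- NULL
  ctl$dead <- vapply(seq_len(nrow(ctl)), function(j) {
    set.seed(unit_seeds[n + j])
    stats::rbinom(1L, ctl$density[j], scenario$control_mortality)
  }, integer(1))
  list(trials = trials,
       controls = ctl[, c("prey_species", "density", "fish_present", "dead")])
}

#' Read and write scenario files
#'
#' Scenarios serialise to YAML so a pipeline run is fully described by a
#' config file plus a seed.
#'
#' @param path YAML file path.
#' @param scenario an \code{\link{fr_scenario}}.
#' @return \code{scenario_from_yaml} returns an \code{fr_scenario};
#'   \code{scenario_to_yaml} returns \code{path} invisibly.
#' @export
scenario_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (p in names(raw$prey)) {
    for (comp in c("a", "h")) {
      eff <- raw$prey[[p]][[comp]]$effects
      if (!is.null(eff)) raw$prey[[p]][[comp]]$effects <- unlist(eff)
    }
    if (!is.null(raw$prey[[p]]$partial))
      raw$prey[[p]]$partial <- unlist(raw$prey[[p]]$partial)
  }
  if (!is.null(raw$density_ladder)) raw$density_ladder <- unlist(raw$density_ladder)
  do.call(fr_scenario, raw)
}

#' @rdname scenario_from_yaml
#' @export
scenario_to_yaml <- function(scenario, path) {
  out <- unclass(scenario)
  # named atomic vectors must become maps, or YAML drops the names
  for (p in names(out$prey)) {
    for (comp in c("a", "h")) {
      eff <- out$prey[[p]][[comp]]$effects
      if (!is.null(eff)) out$prey[[p]][[comp]]$effects <- as.list(eff)
    }
    if (!is.null(out$prey[[p]]$partial))
      out$prey[[p]]$partial <- as.list(out$prey[[p]]$partial)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
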