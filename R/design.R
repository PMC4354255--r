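#' @keywords internal
"_PACKAGE"

# canonical factor levels for community-module experiments
PREY_LEVELS     <- c("A_aquaticus", "Simulium", "B_rhodani")
PREDATOR_LEVELS <- c("G_d_celticus", "G_pulex")
INFECTION_LEVELS <- c("none", "single_cystacanth", "acanthella",
                      "multiple_cystacanths", "spore_mass")
DENSITY_LADDER  <- c(2, 4, 6, 8, 10, 20, 30)

TRIAL_COLUMNS <- c("pot_id", "prey_species", "predator_species", "parasitised",
                   "fish_present", "density", "replicate", "day", "killed",
                   "partially_eaten", "moulted", "infection_stage")
CONTROL_COLUMNS <- c("prey_species", "density", "fish_present", "dead")

#' Enumerate a fully factorial community-module design
#'
#' Builds the table of experimental units for a randomised, balanced, fully
#' factorial design: focal predator species x parasitism x higher-order fish
#' predator x prey density, replicated, per prey species. The default
#' configuration (2 x 2 x 2 factorial, seven densities 2-30, four
#' replicates) gives 224 units per prey species.
#'
#' Units are returned in a deterministic order (prey, predator, parasitism,
#' fish, density, replicate varying fastest from the right). Experiment days
#' are assigned in blocks of \code{pots_per_day} pots started every
#' \code{day_step} days within each prey species; the assignment of units to
#' start days is a fixed rotation unless \code{seed} is supplied, in which
#' case units are randomly permuted into day blocks (the randomised part of
#' the design). Day is bookkeeping for the day-bias diagnostic and is never
#' used by the fitting machinery.
#'
#' @param predator_levels,parasitism_levels,fish_levels factor levels;
#'   parasitism and fish levels must be logical.
#' @param density_ladder distinct positive prey densities.
#' @param replicates replicates per treatment cell, \code{>= 1}.
#' @param prey_list prey species levels.
#' @param pots_per_day number of pots initiated per start day (default 22).
#' @param day_step days between successive start days (default 3).
#' @param seed optional integer; when supplied, units are randomly assigned
#'   to day blocks.
#' @return a data.frame of experimental units with columns \code{pot_id},
#'   \code{prey_species}, \code{predator_species}, \code{parasitised},
#'   \code{fish_present}, \code{density}, \code{replicate}, \code{day}.
#' @examples
#' d <- enumerate_design()
#' nrow(d) / length(unique(d$prey_species))  # 224 units per prey species
#' @export
enumerate_design <- function(predator_levels = PREDATOR_LEVELS,
                             parasitism_levels = c(FALSE, TRUE),
                             fish_levels = c(FALSE, TRUE),
                             density_ladder = DENSITY_LADDER,
                             replicates = 4,
                             prey_list = PREY_LEVELS,
                             pots_per_day = 22,
                             day_step = 3,
                             seed = NULL) {
  if (!length(predator_levels) || !length(parasitism_levels) ||
      !length(fish_levels) || !length(density_ladder) || !length(prey_list))
    stop("all factor level lists must be nonempty")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (anyDuplicated(density_ladder)) stop("duplicate densities in ladder")
  if (any(density_ladder <= 0)) stop("densities must be positive counts")

  units <- expand.grid(replicate = seq_len(replicates),
                       density = density_ladder,
                       fish_present = fish_levels,
                       parasitised = parasitism_levels,
                       predator_species = predator_levels,
                       prey_species = prey_list,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[, c("prey_species", "predator_species", "parasitised",
                     "fish_present", "density", "replicate")]
  ord <- do.call(order, units)
  units <- units[ord, , drop = FALSE]
  rownames(units) <- NULL
  units$pot_id <- sprintf("pot_%04d", seq_len(nrow(units)))

  # day blocks within each prey species: pots_per_day pots per start day
  units$day <- NA_integer_
  for (prey in unique(units$prey_species)) {
    idx <- which(units$prey_species == prey)
    slot <- seq_along(idx)
    if (!is.null(seed)) {
      rng <- local_rng(seed + match(prey, unique(units$prey_species)))
      slot <- sample(slot)
      restore_rng(rng)
    }
    units$day[idx] <- 1L + day_step * ((slot - 1L) %/% pots_per_day)
  }
  units[, c("pot_id", "prey_species", "predator_species", "parasitised",
            "fish_present", "density", "replicate", "day")]
}

# save/restore .Random.seed so package internals never disturb the user's RNG
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Validate consumption-trial records
#'
#' Checks the trial-record invariants: mandatory columns present, counts in
#' range (\code{0 <= killed <= density},
#' \code{0 <= partially_eaten <= killed}, partial consumption only recorded
#' when two or more prey were killed), and categorical levels recognised.
#'
#' @param records a trial-record data.frame (see \code{\link{read_records}}).
#' @return \code{records}, invisibly, if valid; otherwise an error naming
#'   the offending column or row.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(records$killed > records$density | records$killed < 0)
  if (length(bad))
    stop(sprintf("row %d: killed (%d) outside [0, density = %d]",
                 bad[1L], records$killed[bad[1L]], records$density[bad[1L]]))
  bad <- which(records$partially_eaten > records$killed | records$partially_eaten < 0)
  if (length(bad))
    stop(sprintf("row %d: partially_eaten (%d) outside [0, killed = %d]",
                 bad[1L], records$partially_eaten[bad[1L]], records$killed[bad[1L]]))
  bad <- which(records$partially_eaten > 0 & records$killed < 2)
  if (length(bad))
    stop(sprintf("row %d: partial consumption recorded with fewer than 2 kills", bad[1L]))
  bad <- which(!records$infection_stage %in% INFECTION_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: unknown infection_stage '%s'",
                 bad[1L], records$infection_stage[bad[1L]]))
  invisible(records)
}

bool_to_csv <- function(x) ifelse(x, "true", "false")
bool_from_csv <- function(x) {
  out <- tolower(as.character(x)) %in% c("true", "t", "1")
  bad <- !tolower(as.character(x)) %in% c("true", "false", "t", "f", "1", "0")
  if (any(bad)) stop("unparseable boolean value: ", x[which(bad)[1L]])
  out
}

#' Read and write consumption-trial records
#'
#' Plain-text CSV interchange for trial records. The schema is
#' \code{pot_id, prey_species, predator_species, parasitised, fish_present,
#' density, replicate, day, killed, partially_eaten, moulted,
#' infection_stage} (UTF-8, comma-delimited, header mandatory); booleans are
#' encoded \code{"true"}/\code{"false"}. Unknown columns are preserved on
#' read and written back, so \code{write_records(read_records(path))} is
#' the identity on valid files.
#'
#' @param path file path.
#' @param records data.frame of trial records.
#' @return \code{read_records} returns a validated data.frame;
#'   \code{write_records} returns \code{path} invisibly.
#' @export
read_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  rec <- raw
  for (col in c("density", "replicate", "day", "killed", "partially_eaten"))
    rec[[col]] <- as.integer(rec[[col]])
  for (col in c("parasitised", "fish_present", "moulted"))
    rec[[col]] <- bool_from_csv(rec[[col]])
  validate_records(rec)
  rec
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  validate_records(records)
  out <- records
  for (col in c("parasitised", "fish_present", "moulted"))
    out[[col]] <- bool_to_csv(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write control-pot records
#'
#' CSV schema \code{prey_species, density, fish_present, dead}; booleans
#' \code{"true"}/\code{"false"}.
#'
#' @param path file path.
#' @param controls data.frame of control records.
#' @return \code{read_controls} returns a data.frame; \code{write_controls}
#'   returns \code{path} invisibly.
#' @export
read_controls <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(CONTROL_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  ctl <- raw
  ctl$density <- as.integer(ctl$density)
  ctl$dead <- as.integer(ctl$dead)
  ctl$fish_present <- bool_from_csv(ctl$fish_present)
  bad <- which(ctl$dead > ctl$density | ctl$dead < 0)
  if (length(bad))
    stop(sprintf("row %d: dead (%d) outside [0, density = %d]",
                 bad[1L], ctl$dead[bad[1L]], ctl$density[bad[1L]]))
  ctl
}

#' @rdname read_controls
#' @export
write_controls <- function(controls, path) {
  out <- controls
  out$fish_present <- bool_to_csv(out$fish_present)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the replicate-exclusion rules
#'
#' Partitions trial records into kept and excluded sets. A replicate is
#' excluded when the amphipod moulted during the trial (moulting suppresses
#' Gammarus feeding), when a nominally parasitised individual harboured
#' early-stage acanthella or multiple cystacanths (infection age and
#' intensity alter the response to predator cues), or — optionally — when
#' post-trial dissection contradicted the initial parasite-status
#' assignment.
#'
#' @param records validated trial records.
#' @param exclude_mismatch drop records whose dissected infection stage
#'   contradicts the assigned parasitism status (default \code{TRUE}).
#' @return a list with elements \code{kept} (data.frame) and
#'   \code{excluded} (data.frame with an extra \code{reason} column, one of
#'   \code{moulted}, \code{acanthella}, \code{multiple_cystacanths},
#'   \code{parasite_status_mismatch}).
#' @export
filter_replicates <- function(records, exclude_mismatch = TRUE) {
  validate_records(records)
  reason <- rep(NA_character_, nrow(records))
  mismatch <- (records$parasitised & records$infection_stage == "none") |
    (!records$parasitised & records$infection_stage != "none")
  if (exclude_mismatch) reason[mismatch] <- "parasite_status_mismatch"
  reason[records$infection_stage == "multiple_cystacanths"] <- "multiple_cystacanths"
  reason[records$infection_stage == "acanthella"] <- "acanthella"
  reason[records$moulted] <- "moulted"
  excl <- !is.na(reason)
  excluded <- records[excl, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[excl]
  else excluded$reason <- character(0)
  list(kept = records[!excl, , drop = FALSE], excluded = excluded)
}

#' Control-pot survival quality control
#'
#' Prey survival in the absence of the amphipod predator, per
#' (prey species, fish presence) stratum and overall. High control survival
#' justifies attributing treatment-pot mortality to amphipod predation.
#'
#' @param controls control-pot records.
#' @param threshold overall survival proportion that must be exceeded
#'   (default 0.965).
#' @return a list with \code{by_stratum} (data.frame: prey_species,
#'   fish_present, n_pots, n_prey, survival), \code{overall} (proportion),
#'   and \code{pass} (logical, \code{overall > threshold}).
#' @export
control_survival_qc <- function(controls, threshold = 0.965) {
  if (is.null(controls) || nrow(controls) == 0) stop("no control records supplied")
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  strata <- unique(controls[, c("prey_species", "fish_present")])
  strata <- strata[order(strata$prey_species, strata$fish_present), , drop = FALSE]
  by_stratum <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- controls$prey_species == strata$prey_species[i] &
      controls$fish_present == strata$fish_present[i]
    data.frame(prey_species = strata$prey_species[i],
               fish_present = strata$fish_present[i],
               n_pots = sum(sel),
               n_prey = sum(controls$density[sel]),
               survival = 1 - sum(controls$dead[sel]) / sum(controls$density[sel]))
  }))
  rownames(by_stratum) <- NULL
  overall <- 1 - sum(controls$dead) / sum(controls$density)
  list(by_stratum = by_stratum, overall = overall, pass = overall > threshold)
}

# all permutations of 1..n as an n! x n matrix (n <= 9 or so)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry)
}

#' Day-bias diagnostic
#'
#' Trials were started in batches over several weeks; a trend of kills with
#' experiment day would confound treatment comparisons. This diagnostic
#' computes the Spearman rank correlation between day and the number of
#' prey killed within each module, with an exact permutation p-value for
#' small samples (n <= 8) and the large-sample t approximation otherwise,
#' plus a plot-ready (day, killed) table.
#'
#' @param records trial records.
#' @param module_key character vector of columns defining a module
#'   (default \code{"prey_species"}).
#' @return a list with \code{summary} (one row per module: module, n,
#'   n_days, rho, p, assessable) and \code{table} (day, killed, module).
#'   Modules observed on a single day are flagged \code{assessable = FALSE}
#'   with \code{rho = NA}.
#' @export
day_bias_diagnostic <- function(records, module_key = "prey_species") {
  key <- interaction(records[, module_key, drop = FALSE], drop = TRUE, sep = ":")
  rows <- lapply(levels(key), function(mod) {
    sel <- key == mod
    day <- records$day[sel]; ne <- records$killed[sel]
    n_days <- length(unique(day))
    if (n_days < 2) {
      return(data.frame(module = mod, n = sum(sel), n_days = n_days,
                        rho = NA_real_, p = NA_real_, assessable = FALSE))
    }
    rho <- spearman_rho(day, ne)
    n <- sum(sel)
    if (n <= 8) {
      perms <- all_permutations(n)
      rhos <- apply(perms, 1, function(ix) spearman_rho(day, ne[ix]))
      p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
      tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    data.frame(module = mod, n = n, n_days = n_days, rho = rho, p = p,
               assessable = TRUE)
  })
  tab <- data.frame(module = as.character(key), day = records$day,
                    killed = records$killed)
  list(summary = do.call(rbind, rows), table = tab[order(tab$module, tab$day), ])
}
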