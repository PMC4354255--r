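# Independent oracles used to cross-check the implementation. These are kept
# deliberately separate from the package's own algorithms: different methods,
# different code paths.

# Newton iteration on w * exp(w) = z (principal branch, z > -1/e)
oracle_lambert_newton <- function(z) {
  w <- if (z > 0) log(1 + z) else z
  for (i in 1:200) {
    f <- w * exp(w) - z
    if (abs(f) < 1e-15) break
    w <- w - f / (exp(w) * (1 + w))
  }
  w
}

# bisection root of the implicit depletion equation in Ne on [0, N0]
oracle_rogers_bisect <- function(a, h, N0, T) {
  f <- function(ne) ne - N0 * (1 - exp(a * (ne * h - T)))
  stats::uniroot(f, c(0, N0), tol = 1e-12)$root
}

# Newton-Raphson binomial-logit MLE with analytic score and information
oracle_logit_newton <- function(X, successes, trials) {
  beta <- rep(0, ncol(X))
  for (i in 1:100) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(t(X) %*% (successes - trials * mu))
    info <- t(X) %*% (X * (trials * mu * (1 - mu)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# depletion predation process, re-implemented as cumulative kill times:
# kill k occurs at S_k + (k-1) h where S_k is the sum of k exponential
# search times with rates a * (N0 - j + 1)
oracle_event_kills <- function(a, h, N0, T) {
  if (N0 == 0 || a == 0) return(0L)
  s <- cumsum(stats::rexp(N0, rate = a * (N0 - seq_len(N0) + 1)))
  kill_time <- s + (seq_len(N0) - 1) * h
  sum(kill_time <= T)
}

# tie-corrected Kruskal-Wallis H written directly from the formula
oracle_kw_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ssq <- sum(tapply(r, groups, sum)^2 / tabulate(groups))
  H <- 12 / (N * (N + 1)) * ssq - 3 * (N + 1)
  tc <- table(r)
  corr <- 1 - sum(tc^3 - tc) / (N^3 - N)
  if (corr <= 0) 0 else H / corr
}

# full enumeration of the Kruskal-Wallis permutation distribution by
# recursively permuting the group-label vector (distinct label orderings)
oracle_kw_perm <- function(values, groups) {
  groups <- as.character(groups)
  perms <- unique_label_perms(groups)
  vapply(perms, function(g) oracle_kw_H(values, g), numeric(1))
}

unique_label_perms <- function(labels) {
  if (length(labels) == 1L) return(list(labels))
  out <- list()
  for (lv in unique(labels)) {
    rest <- labels[-match(lv, labels)]
    for (p in unique_label_perms(rest)) out[[length(out) + 1L]] <- c(lv, p)
  }
  unique(out)
}

# exact two-sided Spearman permutation p for tie-free data, brute force
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rho_of <- function(yy) {
    d <- rank(x) - rank(yy)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  }
  obs <- rho_of(y)
  perms <- unique_label_perms(as.character(seq_len(n)))
  rhos <- vapply(perms, function(ix) rho_of(y[as.integer(ix)]), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# small single-prey scenario used across tests: base cell only matters
test_scenario <- function(seed = 1, replicates = 4, h_effects = NULL,
                          partial = c(intercept = -3, slope = 0.07),
                          observation_model = "binomial", ...) {
  fr_scenario(prey = list(A_aquaticus = list(
    a = list(intercept = 0.981),
    h = list(intercept = 0.307, effects = h_effects),
    partial = partial)),
    replicates = replicates, observation_model = observation_model,
    p_moult = 0, p_acanthella = 0, p_multiple = 0, seed = seed, ...)
}

base_cell <- function(trials) {
  trials[trials$predator_species == "G_d_celticus" & !trials$parasitised &
           !trials$fish_present, , drop = FALSE]
}

spec_plain <- function() fr_spec(base = list(prey = "A_aquaticus"))
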