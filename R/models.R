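# Nucleotide substitution models (TN93 family) used by both the distance
# estimators and the simulator.

# TN93 rate matrix with base frequencies `pi` (A,C,G,T), purine transition /
# transversion ratio k1 (A<->G), pyrimidine ratio k2 (C<->T), scaled so the
# expected substitution rate at stationarity is 1 (distances are then in
# substitutions per site).
tn93_q <- function(pi, k1 = 1, k2 = 1) {
  stopifnot(length(pi) == 4, abs(sum(pi) - 1) < 1e-8, k1 > 0, k2 > 0)
  rate <- matrix(1, 4, 4)  # order A,C,G,T
  rate[1, 3] <- rate[3, 1] <- k1
  rate[2, 4] <- rate[4, 2] <- k2
  q <- rate * rep(pi, each = 4)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))
  q / mu
}

# A reusable model object: eigendecomposition of Q, transition probabilities
# P(d), and the expected proportion of differing sites p(d) between two
# sequences whose total divergence is d substitutions/site.
tn93_model <- function(pi, k1 = 1, k2 = 1) {
  q <- tn93_q(pi, k1, k2)
  eig <- eigen(q)
  vinv <- solve(eig$vectors)
  pmat <- function(d) {
    p <- eig$vectors %*% diag(exp(eig$values * d)) %*% vinv
    p <- Re(p)
    p[p < 0] <- 0
    p / rowSums(p)
  }
  pdiff <- function(d) {
    p <- pmat(d)
    # both lineages at stationarity; d is the total path length between them
    1 - sum(pi * diag(p))
  }
  list(pi = pi, k1 = k1, k2 = k2, q = q, pmat = pmat, pdiff = pdiff)
}

# Maximum expected difference proportion (saturation plateau).
tn93_pmax <- function(model) model$pdiff(1e3)

# Invert p(d) = p_obs for d; NA when at/over the plateau.
tn93_invert_p <- function(model, p_obs, upper = 20) {
  if (is.na(p_obs)) return(NA_real_)
  if (p_obs <= 0) return(0)
  if (p_obs >= tn93_pmax(model) - 1e-12) return(NA_real_)
  uniroot(function(d) model$pdiff(d) - p_obs, c(0, upper), tol = 1e-12)$root
}

# Classic single-pair corrections --------------------------------------------

jc_distance <- function(p, n) {
  p <- unname(p); n <- unname(n)
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(c(d = NA_real_, var = NA_real_))
  d <- -3 / 4 * log(arg)
  c(d = d, var = p * (1 - p) / (n * arg^2))
}

k2p_distance <- function(P, Q, n) {
  P <- unname(P); Q <- unname(Q); n <- unname(n)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(c(d = NA_real_, var = NA_real_))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 0.5 * (1 / w1 + 1 / w2)
  v <- (c1^2 * P + c2^2 * Q - (c1 * P + c2 * Q)^2) / n
  c(d = d, var = v)
}

# Two-state silent-site model -----------------------------------------------
#
# Third positions of two-fold degenerate codons toggle between two
# exchangeable states (e.g. the AT- and GC-type silent nucleotides) with
# stationary bias (p1, p2). The fraction of sites identical in a pair decays
# from 1 to the equilibrium identity q = p1^2 + p2^2 as
#   f2(T) = q + (1 - q) * exp(-2 r T / (1 - q)),
# where T is the divergence time (years since the common ancestor) and r the
# silent substitution rate per site per year; the calibration makes the
# initial decay rate equal 2r (two diverging lineages).

silent_equilibrium_identity <- function(bias) {
  stopifnot(length(bias) == 2, abs(sum(bias) - 1) < 1e-8)
  sum(bias^2)
}

#' Expected fraction of two-fold sites unchanged at a given divergence time
#'
#' The forward model inverted by [trex_date()]: under the two-state silent
#' model with stationary bias `bias` and silent substitution rate `rate`
#' (per site per year), the expected identity fraction after `t_years` of
#' divergence.
#'
#' @param t_years Divergence time in years (since the common ancestor).
#' @param rate Silent substitution rate, substitutions/site/year.
#' @param bias Length-2 equilibrium bias of the two silent states.
#' @return Expected f2 in (q, 1].
#' @export
f2_expected <- function(t_years, rate, bias) {
  q <- silent_equilibrium_identity(bias)
  q + (1 - q) * exp(-2 * rate * t_years / (1 - q))
}

# Simulate n two-fold sites for a diverging pair at divergence time t_years.
# Returns the observed fraction unchanged. The chain has stationary
# distribution `bias` and total substitution flux `rate` per site per year.
#' Simulate the silent-site identity fraction for a diverging pair
#'
#' Draws `n` two-fold degenerate sites from the stationary two-state silent
#' model, evolves both lineages exactly for `t_years`, and returns the
#' observed fraction of sites still identical — the simulation counterpart
#' of [f2_expected()] used for clock-calibration checks.
#'
#' @param n Number of two-fold sites.
#' @inheritParams f2_expected
#' @return Observed f2 (a single proportion).
#' @export
simulate_silent_pair <- function(n, t_years, rate, bias = c(0.52, 0.48)) {
  q <- silent_equilibrium_identity(bias)
  beta <- rate / (1 - q)  # eigenvalue rate of the two-state chain
  # P(state j at time t | i) = bias_j + (delta_ij - bias_j) e^{-beta t}
  anc <- rbinom(n, 1, bias[2])  # 0 = state1, 1 = state2
  evolve <- function(s, t) {
    e <- exp(-beta * t)
    p2 <- bias[2] + (s - bias[2]) * e
    rbinom(length(s), 1, p2)
  }
  a <- evolve(anc, t_years)
  b <- evolve(anc, t_years)
  mean(a == b)
}
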