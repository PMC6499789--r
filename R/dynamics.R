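law_codes <- function(params) {
  list(inh = match(params$inhibition_law,
                   c("linear", "threshold", "growth_inhibition")) - 1L,
       fac = match(params$facilitation_law, c("monod", "moser")) - 1L)
}

#' Per-capita growth rates at given mediator concentrations
#'
#' Evaluates \eqn{r_i = r_{0i} + \sum_l fac(C_l; \rho^+_{il}, K_{il}) -
#' \sum_l inh(C_l; \rho^-_{il}, K_{il})} under the community's configured
#' facilitation and inhibition laws. Influences of different mediators are
#' additive; rates may be negative (net death is permitted).
#'
#' @param params a [community_params()] object.
#' @param C mediator concentration vector (fmol/ml), `>= 0`.
#' @return Numeric vector of per-capita growth rates (1/h).
#' @export
per_capita_growth_rates <- function(params, C) {
  C <- as.numeric(C)
  if (length(C) != params$n_mediators)
    stop("C must have length n_mediators")
  if (any(C < 0)) stop("concentrations must be non-negative")
  n <- params$n_species; m <- params$n_mediators
  CM <- matrix(C, n, m, byrow = TRUE)
  K <- params$K
  fac_mag <- pmax(params$rho, 0)
  inh_mag <- pmax(-params$rho, 0)
  fac_term <- switch(params$facilitation_law,
    monod = CM / (CM + K),
    moser = {
      cn <- CM^params$moser_n
      cn / (cn + K^params$moser_n)
    })
  inh_term <- switch(params$inhibition_law,
    linear = CM / K,
    threshold = pmax(CM - params$c_th, 0) / K,
    growth_inhibition = ifelse(CM > params$c_th,
                               1 / (1 + K / (CM - params$c_th)), 0))
  # links only: zero magnitudes kill non-link terms (including any 0/0)
  fac_term[fac_mag == 0] <- 0
  inh_term[inh_mag == 0] <- 0
  params$r0 + rowSums(fac_mag * fac_term) - rowSums(inh_mag * inh_term)
}

#' Mediator concentration fluxes
#'
#' Evaluates \eqn{dC_l/dt = \sum_i \beta_{li} S_i - \sum_i \alpha_{li}
#' C_l/(C_l + K_{il}) S_i - decay_l C_l}; the Monod-saturating consumption
#' term applies only where the depletable mask is set.
#'
#' @param params a [community_params()] object.
#' @param state a [community_state()] object.
#' @return Numeric vector of `dC_l/dt` (fmol/ml/h).
#' @export
mediator_fluxes <- function(params, state) {
  S <- state$S; C <- state$C
  if (length(S) != params$n_species || length(C) != params$n_mediators)
    stop("state dimensions do not match params")
  n <- params$n_species; m <- params$n_mediators
  CM <- matrix(C, m, n) # (l, i): C_l recycled down columns
  Kt <- t(params$K)     # (l, i)
  monod <- CM / (CM + Kt)
  monod[CM == 0] <- 0
  cons <- params$alpha * params$depletable * monod
  as.vector(params$beta %*% S) - as.vector(cons %*% S) - params$decay * C
}

#' Advance a community by one forward-Euler step
#'
#' Updates densities multiplicatively, `S <- S * (1 + r dt)` floored at 0,
#' and concentrations additively, clamped at 0 if an Euler step would
#' over-consume a mediator.
#'
#' @param params a [community_params()] object.
#' @param state a [community_state()] object.
#' @param dt timestep (h); the enrichment default is 0.01.
#' @return The updated `community_state`.
#' @export
step_community <- function(params, state, dt = 0.01) {
  stopifnot(dt > 0)
  r <- per_capita_growth_rates(params, state$C)
  flux <- mediator_fluxes(params, state)
  if (any(!is.finite(r)) || any(!is.finite(flux)))
    stop("non-finite intermediate values in Euler step at t = ", state$t)
  community_state(S = pmax(state$S * (1 + r * dt), 0),
                  C = pmax(state$C + flux * dt, 0),
                  t = state$t + dt)
}

cpp_run <- function(params, state, dt, dil_threshold, ext_threshold, t_max,
                    max_steps = Inf, record_every = 0L) {
  codes <- law_codes(params)
  cpp_simulate(params$r0, params$rho, params$K, params$alpha, params$beta,
               params$depletable, params$decay, codes$inh, codes$fac,
               params$moser_n, params$c_th, state$S, state$C, state$t, dt,
               dil_threshold, ext_threshold, t_max, max_steps,
               as.integer(record_every))
}

#' Grow a community until a total-density threshold is crossed
#'
#' Repeatedly applies the Euler step until the summed density reaches
#' `total_density_threshold` (`reached = TRUE`) or `t_max` hours elapse
#' without crossing (`reached = FALSE`, community stalled). Species whose
#' density falls below `extinction_density` during growth are zeroed and
#' stay extinct.
#'
#' @param params a [community_params()] object.
#' @param state a [community_state()] object; `sum(state$S)` must be below
#'   the threshold at entry.
#' @param total_density_threshold dilution-trigger total density (1/ml).
#' @param t_max stall cap (h), measured from entry.
#' @param dt Euler timestep (h).
#' @param extinction_density density (1/ml) below which a species is zeroed;
#'   0 disables the check.
#' @return A list with elements `state` (the final [community_state()]) and
#'   `reached` (logical).
#' @export
grow_until <- function(params, state, total_density_threshold, t_max = 1e4,
                       dt = 0.01, extinction_density = 0) {
  if (sum(state$S) >= total_density_threshold)
    stop("total density already at or above the threshold at entry")
  res <- cpp_run(params, state, dt, total_density_threshold,
                 extinction_density, t_max)
  list(state = community_state(res$S, res$C, res$t), reached = res$reached)
}

#' Record a community trajectory
#'
#' Integrates forward for `t_end` hours (or until a dilution threshold, if
#' given) recording every `record_every` steps, and returns a long-format
#' table suitable for [write_trajectory_csv()].
#'
#' @inheritParams grow_until
#' @param t_end duration to simulate (h).
#' @param record_every record every this many Euler steps.
#' @return A data.frame with columns `t`, `entity_type`
#'   (`"species"`/`"mediator"`), `entity_id`, `value`.
#' @export
simulate_trajectory <- function(params, state, t_end, dt = 0.01,
                                record_every = 10L,
                                total_density_threshold = Inf,
                                extinction_density = 0) {
  res <- cpp_run(params, state, dt, total_density_threshold,
                 extinction_density, t_end, record_every = record_every)
  rec <- res$record
  n <- params$n_species; m <- params$n_mediators
  t <- rec[, 1]
  data.frame(
    t = c(rep(t, n), rep(t, m)),
    entity_type = rep(c("species", "mediator"), c(length(t) * n, length(t) * m)),
    entity_id = c(rep(seq_len(n), each = length(t)),
                  rep(seq_len(m), each = length(t))),
    value = c(as.vector(rec[, 1 + seq_len(n), drop = FALSE]),
              as.vector(rec[, 1 + n + seq_len(m), drop = FALSE])))
}
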