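#' Stochastic recipe for a random initial species pool
#'
#' Describes the binomial (Erdos-Renyi) bipartite network from which initial
#' pools are sampled: production links (species -> mediator, "c-links") are
#' present with probability `q_p`, growth-rate influence links (mediator ->
#' species, "f-links") with probability `q_c`. Influence magnitudes are
#' uniform on `(0, rho_max)`, signs facilitative with probability
#' `fac_fraction`; consumption factors, production rates and saturation
#' concentrations are uniform within +/-50% of their means; basal rates are
#' uniform on `(r0_low, r0_high)`.
#'
#' @param n_species number of species types in the pool (N_c).
#' @param n_mediators number of possible mediators (N_m).
#' @param q_p probability of a production link per (mediator, species) pair.
#' @param q_c probability of an influence link per (species, mediator) pair.
#' @param fac_fraction probability an influence is facilitative.
#' @param depletable_fraction probability an influence link is depletable
#'   (the recipient consumes/degrades the mediator).
#' @param rho_max maximum influence magnitude (1/h); realized magnitudes are
#'   uniform on `(0, rho_max)` so the mean strength is `rho_max / 2`.
#' @param strength_distribution `"uniform"`, or `"weak_biased"` for a
#'   square-transformed alternative biased toward weak influences.
#' @param alpha_mean mean consumption factor (fmol per cell).
#' @param beta_mean mean production rate (fmol per cell per h).
#' @param K_sat saturation concentration scale (fmol/ml).
#' @param r0_low,r0_high bounds of the uniform basal growth rate (1/h).
#' @param seed optional integer seed making [sample_pool()] deterministic.
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(n_species = 20, n_mediators = 15, q_p = 0.2, q_c = 0.2,
                      fac_fraction = 0.5, depletable_fraction = 0.5,
                      rho_max = 0.2,
                      strength_distribution = c("uniform", "weak_biased"),
                      alpha_mean = 1, beta_mean = 0.1, K_sat = 1e4,
                      r0_low = 0.08, r0_high = 0.12, seed = NULL) {
  strength_distribution <- match.arg(strength_distribution)
  spec <- structure(
    list(n_species = as.integer(n_species),
         n_mediators = as.integer(n_mediators),
         q_p = q_p, q_c = q_c, fac_fraction = fac_fraction,
         depletable_fraction = depletable_fraction, rho_max = rho_max,
         strength_distribution = strength_distribution,
         alpha_mean = alpha_mean, beta_mean = beta_mean, K_sat = K_sat,
         r0_low = r0_low, r0_high = r0_high, seed = seed),
    class = "pool_spec")
  validate_pool_spec(spec)
  spec
}

validate_pool_spec <- function(spec) {
  probs <- c(spec$q_p, spec$q_c, spec$fac_fraction, spec$depletable_fraction)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0, 1]")
  if (spec$rho_max <= 0) stop("rho_max must be positive")
  if (spec$r0_low >= spec$r0_high) stop("r0_low must be below r0_high")
  if (spec$n_species < 1 || spec$n_mediators < 1)
    stop("pool must have at least one species and one mediator")
  invisible(spec)
}

#' @export
print.pool_spec <- function(x, ...) {
  cat("<pool_spec> N_c = ", x$n_species, ", N_m = ", x$n_mediators,
      "; q_p = ", x$q_p, ", q_c = ", x$q_c, "\n", sep = "")
  cat("  facilitation fraction ", x$fac_fraction, ", depletable fraction ",
      x$depletable_fraction, ", rho_max ", x$rho_max, " /h (",
      x$strength_distribution, ")\n", sep = "")
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a random initial pool
#'
#' Draws one [community_params()] realization from a [pool_spec()]. The
#' number and order of random draws is fixed (full matrices are always
#' drawn, then masked), so two specs sharing a seed but differing in, say,
#' `depletable_fraction` yield pools that are identical except in the
#' entries the changed parameter masks.
#'
#' @param spec a [pool_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [community_params()] object.
#' @export
sample_pool <- function(spec, seed = spec$seed) {
  validate_pool_spec(spec)
  n <- spec$n_species; m <- spec$n_mediators
  with_seed(seed, {
    prod_mask <- matrix(runif(m * n) < spec$q_p, m, n)
    beta <- matrix(runif(m * n, 0.5 * spec$beta_mean, 1.5 * spec$beta_mean),
                   m, n) * prod_mask
    infl_mask <- matrix(runif(n * m) < spec$q_c, n, m)
    sign <- matrix(ifelse(runif(n * m) < spec$fac_fraction, 1, -1), n, m)
    mag <- matrix(runif(n * m), n, m)
    if (spec$strength_distribution == "weak_biased") mag <- mag^2
    rho <- infl_mask * sign * mag * spec$rho_max
    K <- matrix(runif(n * m, 0.5 * spec$K_sat, 1.5 * spec$K_sat), n, m)
    depl <- matrix(runif(m * n) < spec$depletable_fraction, m, n) &
      t(infl_mask)
    alpha <- matrix(runif(m * n, 0.5 * spec$alpha_mean, 1.5 * spec$alpha_mean),
                    m, n) * depl
    r0 <- runif(n, spec$r0_low, spec$r0_high)
    community_params(r0 = r0, rho = rho, K = K, alpha = alpha, beta = beta,
                     depletable = depl)
  })
}

#' Network perturbation
#'
#' @param flip_fraction fraction of nonzero influences whose sign is flipped.
#' @param scale_factor multiplicative factor applied to all influence
#'   magnitudes.
#' @param consumption_to_production_ratio if not `NULL`, target ratio of the
#'   mean nonzero consumption factor to the mean nonzero production rate;
#'   `alpha` is rescaled to meet it.
#' @return An object of class `network_perturbation`.
#' @export
network_perturbation <- function(flip_fraction = 0, scale_factor = 1,
                                 consumption_to_production_ratio = NULL) {
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must be in [0, 1]")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  structure(list(flip_fraction = flip_fraction, scale_factor = scale_factor,
                 consumption_to_production_ratio =
                   consumption_to_production_ratio),
            class = "network_perturbation")
}

#' Apply a perturbation to a community network
#'
#' Negates a uniformly chosen fraction of nonzero influence strengths,
#' scales all magnitudes, and (optionally) rescales consumption factors to a
#' requested consumption-to-production ratio. The zero pattern (topology) is
#' unchanged.
#'
#' @param params a [community_params()] object.
#' @param pert a [network_perturbation()].
#' @param seed optional seed for the choice of flipped influences.
#' @return A perturbed copy of `params`.
#' @export
perturb_network <- function(params, pert, seed = NULL) {
  out <- params
  with_seed(seed, {
    nz <- which(out$rho != 0)
    k <- round(pert$flip_fraction * length(nz))
    if (k > 0) {
      idx <- if (k == length(nz)) nz else sample(nz, k)
      out$rho[idx] <- -out$rho[idx]
    }
  })
  out$rho <- out$rho * pert$scale_factor
  ratio <- pert$consumption_to_production_ratio
  if (!is.null(ratio)) {
    mean_a <- mean(out$alpha[out$alpha > 0])
    mean_b <- mean(out$beta[out$beta > 0])
    if (is.finite(mean_a) && is.finite(mean_b) && mean_a > 0)
      out$alpha <- out$alpha * (ratio * mean_b / mean_a)
  }
  validate_community_params(out)
  out
}

#' Remove one influence link
#'
#' Sets the influence strength of `(species, mediator)` to zero, together
#' with any consumption tied to that influence; everything else is
#' unchanged.
#'
#' @param params a [community_params()] object.
#' @param species,mediator indices of an existing influence link.
#' @return A copy of `params` without the link.
#' @export
knockout_link <- function(params, species, mediator) {
  if (params$rho[species, mediator] == 0)
    stop("no influence link from mediator ", mediator, " to species ", species)
  out <- params
  out$rho[species, mediator] <- 0
  out$alpha[mediator, species] <- 0
  out$depletable[mediator, species] <- FALSE
  out
}
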