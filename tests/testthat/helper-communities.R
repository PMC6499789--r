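# Hand-built communities used across test files.

# Mutualistic cross-feeding pair: each species produces a depletable
# mediator that strongly facilitates the other. Basal-rate gap 0.04/h.
pair_mutualistic <- function(r0 = c(0.08, 0.12), rho = 0.2, alpha = 1,
                             beta = 0.1, K = 1e4, depletable = TRUE) {
  rho_m <- matrix(0, 2, 2)
  rho_m[2, 1] <- rho # mediator 1 (made by sp 1) boosts sp 2
  rho_m[1, 2] <- rho # mediator 2 (made by sp 2) boosts sp 1
  beta_m <- matrix(0, 2, 2)
  beta_m[1, 1] <- beta
  beta_m[2, 2] <- beta
  alpha_m <- matrix(0, 2, 2)
  if (depletable) {
    alpha_m[1, 2] <- alpha # sp 2 consumes mediator 1
    alpha_m[2, 1] <- alpha
  }
  community_params(r0 = r0, rho = rho_m, K = matrix(K, 2, 2),
                   alpha = alpha_m, beta = beta_m)
}

# Non-interacting exponential competitors.
competitors <- function(r0) {
  n <- length(r0)
  community_params(r0 = r0, rho = matrix(0, n, 1), K = matrix(1e4, n, 1),
                   alpha = matrix(0, 1, n), beta = matrix(0, 1, n))
}

# One obligate commensal: species 2 needs the mediator species 1 produces.
pair_commensal <- function(r0 = c(0.12, 0.02), rho = 0.2, depletable = TRUE) {
  p <- pair_mutualistic(r0 = r0, rho = rho, depletable = depletable)
  p$rho[1, 2] <- 0 # no return favor
  p$beta[2, 2] <- 0
  p$alpha[2, 1] <- 0
  p$depletable <- p$alpha > 0
  p
}

# 2 species x 2 mediators with one influence from each of the four
# categories: sp1 self-facilitation (med1), sp2 other-facilitation (med1),
# sp2 self-restraint (med2), sp1 other-inhibition (med2).
four_category_community <- function() {
  rho <- matrix(0, 2, 2)
  rho[1, 1] <- 0.1   # sp1 <- med1 (sp1 produces med1): self-facilitation
  rho[2, 1] <- 0.15  # sp2 <- med1: other-facilitation
  rho[2, 2] <- -0.1  # sp2 <- med2 (sp2 produces med2): self-restraint
  rho[1, 2] <- -0.05 # sp1 <- med2: other-inhibition
  beta <- matrix(0, 2, 2)
  beta[1, 1] <- 0.1
  beta[2, 2] <- 0.1
  community_params(r0 = c(0.1, 0.1), rho = rho, K = matrix(1e4, 2, 2),
                   alpha = matrix(0, 2, 2), beta = beta)
}

# Small random-but-valid parameter set for property tests.
random_params <- function(seed, n_species = 5, n_mediators = 4, ...) {
  sample_pool(pool_spec(n_species = n_species, n_mediators = n_mediators,
                        seed = seed, ...))
}

# Independent reference integration of the same community model with
# deSolve's stiff solver (no Euler discretization), including the serial
# grow-dilute protocol. Used as an oracle for the hand-built communities.
desolve_enrichment <- function(params, config = enrichment_config(),
                               n_rounds = config$n_rounds) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  n <- params$n_species
  m <- params$n_mediators
  deriv <- function(t, y, parms) {
    S <- pmax(y[seq_len(n)], 0)
    C <- pmax(y[n + seq_len(m)], 0)
    fac <- pmax(params$rho, 0)
    inh <- pmax(-params$rho, 0)
    CM <- matrix(C, n, m, byrow = TRUE)
    r <- params$r0 + rowSums(fac * CM / (CM + params$K)) -
      rowSums(inh * CM / params$K)
    monod <- t(CM / (CM + params$K))
    dC <- as.vector(params$beta %*% S) -
      as.vector((params$alpha * params$depletable * monod) %*% S)
    list(c(r * S, dC))
  }
  root <- function(t, y, parms) sum(y[seq_len(n)]) - config$sum_S_dil
  S <- rep(config$sum_S_init / n, n)
  C <- rep(0, m)
  snaps <- matrix(NA_real_, n_rounds, n)
  for (r in seq_len(n_rounds)) {
    out <- deSolve::lsodar(c(S, C), times = c(0, 1e5), func = deriv,
                           rootfunc = root, rtol = 1e-8, atol = 1e-6)
    y <- out[nrow(out), -1]
    S <- pmax(y[seq_len(n)], 0)
    C <- pmax(y[n + seq_len(m)], 0)
    f <- config$sum_S_init / sum(S)
    S <- S * f
    C <- C * f
    S[S > 0 & S < config$sum_S_ext] <- 0
    snaps[r, ] <- S
  }
  list(S = S, snapshots = snaps,
       derived = which(S > 0 & snaps[n_rounds, ] >=
                         (1 - config$decline_threshold) * snaps[n_rounds - 1, ]))
}
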