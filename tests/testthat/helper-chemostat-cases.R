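# Hand-built N <= 4 strong-interaction communities with a clear expected
# outcome, used to compare the chemostat eigenvalue prediction with the
# serial-dilution survivors.

hand_community <- function(r0, links = list(), prods = list(),
                           N = length(r0), M = 3) {
  rho <- matrix(0, N, M); beta <- matrix(0, M, N); alpha <- matrix(0, M, N)
  for (lk in links) rho[lk[1], lk[2]] <- lk[3]
  for (pr in prods) beta[pr[1], pr[2]] <- 0.1
  community_params(r0 = r0, rho = rho, K = matrix(1e4, N, M),
                   alpha = alpha, beta = beta)
}

concordance_cases <- function() {
  list(
    competitors3 = hand_community(c(0.08, 0.12, 0.10)),
    mutual_pair = hand_community(c(0.10, 0.10),
      links = list(c(2, 1, 0.2), c(1, 2, 0.2)),
      prods = list(c(1, 1), c(2, 2))),
    toxin_pair = hand_community(c(0.12, 0.11),
      links = list(c(2, 1, -0.25)), prods = list(c(1, 1))),
    self_restraint = hand_community(c(0.12, 0.10),
      links = list(c(1, 1, -0.25)), prods = list(c(1, 1))),
    self_facilitation = hand_community(c(0.08, 0.12),
      links = list(c(1, 1, 0.25)), prods = list(c(1, 1))),
    pair_plus_outsider = hand_community(c(0.10, 0.10, 0.11),
      links = list(c(2, 1, 0.2), c(1, 2, 0.2)),
      prods = list(c(1, 1), c(2, 2))),
    pair_excludes_third = hand_community(c(0.10, 0.10, 0.11),
      links = list(c(2, 1, 0.2), c(1, 2, 0.2), c(3, 3, -0.25)),
      prods = list(c(1, 1), c(2, 2), c(3, 1))),
    cycle3 = hand_community(c(0.10, 0.10, 0.10),
      links = list(c(2, 1, 0.2), c(3, 2, 0.2), c(1, 3, 0.2)),
      prods = list(c(1, 1), c(2, 2), c(3, 3))),
    broad_toxin = hand_community(c(0.12, 0.10),
      links = list(c(1, 1, -0.25), c(2, 1, -0.25)),
      prods = list(c(1, 1))),
    weak_mutual_pair = hand_community(c(0.05, 0.05),
      links = list(c(2, 1, 0.2), c(1, 2, 0.2)),
      prods = list(c(1, 1), c(2, 2))))
}
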