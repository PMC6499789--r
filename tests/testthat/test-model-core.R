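test_that("growth rates reduce to r0 at zero concentration and obey the laws", {
  p <- pair_mutualistic()
  expect_equal(per_capita_growth_rates(p, c(0, 0)), p$r0)

  # Monod half-saturation: one facilitative link at C = K gives r0 + rho/2
  expect_equal(per_capita_growth_rates(p, c(p$K[2, 1], 0))[2],
               p$r0[2] + 0.2 / 2)

  # linear inhibition: r0 = 0.1, rho- = 0.2, K = 1e4, C = 5e3 -> rate 0
  # (hand evaluation: 0.1 - 0.2 * 5e3/1e4 = 0)
  pin <- community_params(r0 = 0.1, rho = matrix(-0.2, 1, 1),
                          K = matrix(1e4, 1, 1), alpha = matrix(0, 1, 1),
                          beta = matrix(0, 1, 1))
  expect_equal(per_capita_growth_rates(pin, 5e3), 0)
  # inhibition may push the net rate negative
  expect_lt(per_capita_growth_rates(pin, 2e4), 0)

  expect_error(per_capita_growth_rates(p, c(-1, 0)), "non-negative")
  expect_error(per_capita_growth_rates(p, 0), "length")
})

test_that("influences are additive across mediators", {
  rho <- matrix(c(0.1, -0.06, 0.04), 1, 3)
  p <- community_params(r0 = 0.1, rho = rho, K = matrix(1e4, 1, 3),
                        alpha = matrix(0, 3, 1), beta = matrix(0, 3, 1))
  C <- c(2e3, 7e3, 4e4)
  single <- vapply(1:3, function(l) {
    Cl <- rep(0, 3); Cl[l] <- C[l]
    per_capita_growth_rates(p, Cl) - p$r0
  }, numeric(1))
  expect_equal(per_capita_growth_rates(p, C), p$r0 + sum(single))
})

test_that("response laws agree in their limiting cases", {
  base <- pair_mutualistic()
  base$rho[1, 2] <- -0.15 # make one link inhibitory
  C <- c(3e3, 8e3)
  lin <- base; lin$inhibition_law <- "linear"
  thr <- base; thr$inhibition_law <- "threshold"; thr$c_th <- 0
  expect_equal(per_capita_growth_rates(thr, C),
               per_capita_growth_rates(lin, C))
  mon <- base
  mos <- base; mos$facilitation_law <- "moser"; mos$moser_n <- 1
  expect_equal(per_capita_growth_rates(mos, C),
               per_capita_growth_rates(mon, C))
  # threshold law is inert below the threshold
  thr$c_th <- 1e4
  expect_equal(per_capita_growth_rates(thr, c(3e3, 9e3))[1], base$r0[1])
  # growth-inhibition law saturates at r_inh for large C
  gi <- base; gi$inhibition_law <- "growth_inhibition"; gi$c_th <- 0
  r_inf <- per_capita_growth_rates(gi, c(0, 1e12))[1]
  expect_equal(r_inf, base$r0[1] - 0.15, tolerance = 1e-6)
})

test_that("mediator fluxes follow production, saturating consumption and decay", {
  p <- pair_mutualistic()
  # no cells -> no fluxes (no decay by default)
  st0 <- community_state(S = c(0, 0), C = c(5e3, 1e3))
  expect_equal(mediator_fluxes(p, st0), c(0, 0))
  # single producer: beta * S (sp1 produces med1 at 0.1 fmol/h/cell)
  st1 <- community_state(S = c(1e4, 0), C = c(0, 0))
  expect_equal(mediator_fluxes(p, st1), c(0.1 * 1e4, 0))
  # consumption only where depletable; reusable link leaves C untouched
  ru <- pair_mutualistic(depletable = FALSE)
  st2 <- community_state(S = c(0, 1e6), C = c(5e3, 0))
  expect_equal(mediator_fluxes(ru, st2), c(0, 0.1 * 1e6))
  # depletable: consumption = alpha * C/(C+K) * S
  dp <- pair_mutualistic()
  expect_equal(mediator_fluxes(dp, st2)[1], -1 * 5e3 / (5e3 + 1e4) * 1e6)
  # decay
  dc <- pair_mutualistic()
  dc$decay <- c(0.1, 0)
  expect_equal(mediator_fluxes(dc, st0), c(-0.1 * 5e3, 0))
})

test_that("the Euler step updates multiplicatively with floors and clamps", {
  p0 <- community_params(r0 = 0.1, rho = matrix(0, 1, 1),
                         K = matrix(1e4, 1, 1), alpha = matrix(0, 1, 1),
                         beta = matrix(0, 1, 1))
  st0 <- community_state(S = 1e4, C = 0)
  s1 <- step_community(p0, st0, dt = 0.01)
  expect_equal(s1$S, 1e4 * 1.001)
  expect_equal(s1$t, 0.01)

  # all-zero rates leave the state unchanged
  pz <- community_params(r0 = 0, rho = matrix(0, 1, 1), K = matrix(1e4, 1, 1),
                         alpha = matrix(0, 1, 1), beta = matrix(0, 1, 1))
  sz <- step_community(pz, st0, dt = 0.01)
  expect_equal(sz$S, st0$S)
  expect_equal(sz$C, st0$C)

  # over-consumption in one step clamps C at 0 rather than going negative
  ko <- pair_mutualistic(alpha = 1e6)
  stc <- community_state(S = c(0, 1e8), C = c(1, 0))
  expect_equal(step_community(ko, stc, dt = 0.01)$C[1], 0)

  # strong inhibition floors the density at 0
  pin <- community_params(r0 = 0.1, rho = matrix(-0.2, 1, 1),
                          K = matrix(1e4, 1, 1), alpha = matrix(0, 1, 1),
                          beta = matrix(0, 1, 1))
  sneg <- step_community(pin, community_state(S = 100, C = 1e8), dt = 0.01)
  expect_equal(sneg$S, 0)
})

test_that("R step and compiled integrator agree step for step", {
  p <- random_params(seed = 4, depletable_fraction = 0.7)
  set.seed(2)
  st <- community_state(S = runif(5, 100, 1000), C = runif(4, 0, 2e3))
  st_r <- st
  for (k in 1:200) st_r <- step_community(p, st_r, dt = 0.01)
  res <- medcoex:::cpp_run(p, st, dt = 0.01, dil_threshold = Inf,
                           ext_threshold = 0, t_max = Inf, max_steps = 200)
  expect_equal(res$S, st_r$S, tolerance = 1e-12)
  expect_equal(res$C, st_r$C, tolerance = 1e-12)
  expect_equal(res$t, st_r$t)
})

test_that("states stay non-negative for random parameter sets", {
  for (seed in 1:8) {
    p <- random_params(seed, fac_fraction = 0.3, depletable_fraction = 0.5)
    st <- community_state(S = rep(500, 5), C = rep(0, 4))
    res <- medcoex:::cpp_run(p, st, dt = 0.01, dil_threshold = Inf,
                             ext_threshold = 0, t_max = Inf, max_steps = 5000)
    expect_true(all(res$S >= 0))
    expect_true(all(res$C >= 0))
  }
})

test_that("grow_until reproduces closed-form exponential growth", {
  p <- competitors(0.1)
  st <- community_state(S = 1e4, C = 0)
  g <- grow_until(p, st, 1e10, t_max = 1e4)
  expect_true(g$reached)
  # ln(1e6)/0.1 = 138.2 h; Euler crosses within a fraction of an hour
  expect_equal(g$state$t, log(1e6) / 0.1, tolerance = 5e-3)
  expect_gte(sum(g$state$S), 1e10)

  # stalled community: zero growth never reaches the threshold
  p0 <- competitors(0)
  g0 <- grow_until(p0, st, 1e10, t_max = 50)
  expect_false(g0$reached)
  expect_equal(sum(g0$state$S), 1e4)

  expect_error(grow_until(p, community_state(S = 1e10, C = 0), 1e9),
               "threshold")
})

test_that("the faster of two neutral competitors gains frequency all round", {
  p <- competitors(c(0.12, 0.08))
  st <- community_state(S = c(5e3, 5e3), C = 0)
  traj <- simulate_trajectory(p, st, t_end = 100, record_every = 100)
  s1 <- traj$value[traj$entity_type == "species" & traj$entity_id == 1]
  s2 <- traj$value[traj$entity_type == "species" & traj$entity_id == 2]
  freq1 <- s1 / (s1 + s2)
  expect_true(all(diff(freq1) > 0))
})

test_that("halving the timestep changes the outcome only at Euler order", {
  p <- random_params(seed = 11, n_species = 3, n_mediators = 3,
                     q_p = 0.5, q_c = 0.5)
  st <- community_state(S = rep(500, 3), C = rep(0, 3))
  out <- lapply(c(0.01, 0.001), function(dt)
    grow_until(p, st, 1e8, t_max = 1e4, dt = dt)$state)
  f1 <- out[[1]]$S / sum(out[[1]]$S)
  f2 <- out[[2]]$S / sum(out[[2]]$S)
  expect_lt(max(abs(f1 - f2)), 0.01)
})

test_that("zero-interaction dynamics are exactly exponential to Euler order", {
  p <- competitors(c(0.1, 0.09))
  st <- community_state(S = c(100, 100), C = 0)
  res <- medcoex:::cpp_run(p, st, dt = 0.01, dil_threshold = Inf,
                           ext_threshold = 0, t_max = Inf, max_steps = 1000)
  expect_equal(res$S, 100 * (1 + p$r0 * 0.01)^1000, tolerance = 1e-12)
})

test_that("invalid parameter sets are rejected", {
  expect_error(community_params(r0 = 0.1, rho = matrix(0.1, 1, 1),
                                K = matrix(0, 1, 1), alpha = matrix(0, 1, 1),
                                beta = matrix(0, 1, 1)),
               "strictly positive")
  expect_error(community_params(r0 = 0.1, rho = matrix(0.1, 1, 1),
                                K = matrix(1e4, 1, 1),
                                alpha = matrix(1, 1, 1),
                                beta = matrix(0, 1, 1),
                                depletable = matrix(FALSE, 1, 1)),
               "depletable")
  expect_error(community_params(r0 = c(0.1, 0.1), rho = matrix(0, 1, 1),
                                K = matrix(1, 1, 1), alpha = matrix(0, 1, 1),
                                beta = matrix(0, 1, 1)),
               "n_species")
  expect_error(community_state(S = -1, C = 0), "non-negative")
})
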