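test_that("influence classification covers the four categories exactly", {
  p <- four_category_community()
  recs <- classify_influences(p)
  expect_equal(nrow(recs), 4)
  expect_setequal(recs$category,
                  c("self-facilitation", "other-facilitation",
                    "self-restraint", "other-inhibition"))
  # definitional checks
  sf <- recs[recs$species == 1 & recs$mediator == 1, ]
  expect_equal(sf$category, "self-facilitation") # rho > 0, beta > 0
  oi <- recs[recs$species == 1 & recs$mediator == 2, ]
  expect_equal(oi$category, "other-inhibition")  # rho < 0, beta = 0
  expect_equal(nrow(classify_influences(competitors(c(0.1, 0.1)))), 0)
})

test_that("active influences require a surviving producer and recipient", {
  p <- four_category_community()
  # both present: all four links active
  expect_equal(nrow(active_influences(p, c(1, 2))), 4)
  # species 2 alone: med1 has no producer, so only its self-restraint remains
  a2 <- active_influences(p, 2)
  expect_equal(a2$category, "self-restraint")
  # fully consumed mediators carry no realized influence
  a0 <- active_influences(p, c(1, 2), C = c(0, 3e3))
  expect_setequal(a0$category, c("self-restraint", "other-inhibition"))
  expect_equal(nrow(active_influences(p, integer(0))), 0)
})

test_that("mean excess richness follows its definition with a bootstrap CI", {
  # all singletons: MER 0 with a degenerate interval
  m0 <- mer(rep(1, 50))
  expect_equal(m0$mer, 0)
  expect_equal(m0$ci, c(0, 0))
  # p = {1: 0.5, 2: 0.5} -> 0.5; p = {1: .7, 2: .2, 3: .1} -> 0.4
  expect_equal(mer(rep(c(1, 2), 50))$mer, 0.5)
  expect_equal(mer(rep(c(1, 2, 3), c(70, 20, 10)))$mer, 0.4)
  m <- mer(rep(c(1, 2, 3), c(70, 20, 10)), seed = 1)
  expect_true(m$ci[1] <= m$mer && m$mer <= m$ci[2])
  expect_error(mer(integer(0)), "empty")
  # CI width shrinks roughly as 1/sqrt(n)
  set.seed(4)
  pop <- sample(1:3, 6400, TRUE, prob = c(.6, .3, .1))
  w <- vapply(c(100, 6400), function(n) diff(mer(pop[1:n], seed = 2)$ci),
              numeric(1))
  expect_gt(w[1] / w[2], 4) # expect ~8
})

test_that("an ensemble screen tabulates richness and category fractions", {
  spec <- pool_spec(n_species = 8, n_mediators = 6, fac_fraction = 0.7,
                    depletable_fraction = 1)
  s <- richness_screen(spec, n_pools = 12, seed = 5, control = TRUE)
  expect_s3_class(s, "screen_summary")
  expect_equal(s$n_pools, 12)
  expect_equal(sum(s$richness_pmf), 1)
  expect_gte(s$mer, 0)
  expect_true(s$mer_ci[1] <= s$mer && s$mer <= s$mer_ci[2])
  expect_equal(nrow(s$pools), 12)
  expect_equal(s$control$n_pools, 12)
  # single-pool screen: point-mass pmf
  s1 <- richness_screen(spec, n_pools = 1, seed = 5)
  expect_equal(sum(s1$richness_pmf == 1), 1)
  # determinism under the seed
  s2 <- richness_screen(spec, n_pools = 12, seed = 5)
  expect_equal(s2$pools, s$pools)
})

test_that("category enrichment summarises qualifying pools", {
  specs <- lapply(c(0.3, 0.7), function(f)
    pool_spec(n_species = 10, n_mediators = 8, fac_fraction = f,
              depletable_fraction = 1))
  ce <- category_enrichment(specs, n_pools = 15, seed = 6)
  expect_true(all(ce$pools$richness >= 2))
  expect_true(all(ce$pools$n_fac_derived + ce$pools$n_inh_derived >= 1))
  for (f in c("frac_only_facilitation", "frac_facilitation_favored")) {
    expect_gte(ce[[f]], 0); expect_lte(ce[[f]], 1)
  }
  # a pool built from only facilitative influences retains only facilitation
  all_fac <- pool_spec(n_species = 6, n_mediators = 5, fac_fraction = 1,
                       depletable_fraction = 1, seed = 3)
  ce2 <- category_enrichment(all_fac, n_pools = 10, seed = 7)
  if (ce2$n_qualifying > 0) {
    expect_equal(ce2$frac_only_facilitation, 1)
    expect_true(is.na(ce2$frac_only_self_restraint_given_inhibition))
  }
})

test_that("knockout screens group outcomes by category in both modes", {
  spec <- pool_spec(n_species = 10, n_mediators = 8, fac_fraction = 0.6,
                    depletable_fraction = 1)
  ens <- derived_ensemble(spec, n_pools = 30, seed = 8)
  expect_true(length(ens) > 0)
  expect_true(all(vapply(ens, function(e) e$richness >= 2, logical(1))))
  kd <- knockout_screen(ens, "from_derived")
  if (!is.null(kd$knockouts)) {
    expect_true(all(kd$by_category$n_tested >= 1))
    expect_true(all(kd$by_category$disruption_rate >= 0 &
                      kd$by_category$disruption_rate <= 1))
  }
  kp <- knockout_screen(ens, "from_pool")
  if (!is.null(kp$knockouts)) {
    expect_true(all(kp$knockouts$outcome %in% c("drop", "unchanged", "gain")))
    # tallies sum to tested links
    expect_equal(sum(table(kp$knockouts$outcome)), nrow(kp$knockouts))
  }
  # knocking out a link in an extinct branch cannot change the outcome:
  # from_pool on a link whose recipient died leaves the derived set intact
  p <- pair_commensal(r0 = c(0.12, 0.02))
  p$rho[2, 2] <- -0.05 # inhibition onto sp2 via its own (unproduced) med2
  p$beta[2, 2] <- 0
  dc <- derive_community(p)
  ko <- knockout_link(p, 2, 2)
  expect_setequal(derive_community(ko)$derived, dc$derived)
})

test_that("depletable mediators promote coexistence (mechanism screen)", {
  spec <- pool_spec(fac_fraction = 0.5)
  ms <- mechanism_screen(spec, depletable_fractions = c(0, 1), n_pools = 40,
                         seed = 9)
  expect_equal(nrow(ms), 2)
  expect_gt(ms$mer[ms$depletable_fraction == 1],
            ms$mer[ms$depletable_fraction == 0])
})

test_that("the strength sweep shares topology across strength levels", {
  spec <- pool_spec(n_species = 8, n_mediators = 6)
  sw <- strength_sweep(spec, strength_ratios = c(0.1, 10), n_pools = 15,
                       seed = 10)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$rho_max, 2 * c(0.1, 10) * (0.12 - 0.08) / sqrt(12))
  expect_true(all(sw$coexistence_likelihood >= 0 &
                    sw$coexistence_likelihood <= 1))
})

test_that("sign flips disturb enrichment outcomes more than strength scaling", {
  spec <- pool_spec(fac_fraction = 0.5, depletable_fraction = 1,
                    n_species = 12, n_mediators = 9)
  set.seed(24)
  seeds <- sample.int(2^31 - 2, 30)
  d_flip <- d_scale <- integer(0)
  for (s in seeds) {
    p <- sample_pool(spec, seed = s)
    base <- length(derive_community(p)$derived)
    flip <- perturb_network(p, network_perturbation(flip_fraction = 0.25),
                            seed = s)
    scale <- perturb_network(p, network_perturbation(scale_factor = 1.25))
    d_flip <- c(d_flip, abs(length(derive_community(flip)$derived) - base))
    d_scale <- c(d_scale, abs(length(derive_community(scale)$derived) - base))
  }
  expect_gt(mean(d_flip), mean(d_scale))
})

test_that("perturbation recovery distinguishes stabilized from neutral pairs", {
  p <- pair_mutualistic()
  # zero kick: trivially recovered
  expect_true(perturbation_recovery(p, c(1, 2), kick = 0))
  # a stabilized mutualistic pair absorbs a 20% frequency kick
  expect_true(perturbation_recovery(p, c(1, 2), kick = 0.2))
  # a neutral pair (identical rates, no interactions) stays displaced
  n <- competitors(c(0.1, 0.1))
  expect_false(perturbation_recovery(n, c(1, 2), kick = 0.2))
})
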