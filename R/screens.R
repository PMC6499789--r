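#' Classify the influence links of a community
#'
#' One record per nonzero influence strength. The locus is `"self"` iff the
#' recipient species also produces the mediator, so each influence falls in
#' exactly one of four categories: self-facilitation, other-facilitation,
#' self-restraint, other-inhibition.
#'
#' @param params a [community_params()] object.
#' @return A data.frame with columns `species`, `mediator`, `sign`
#'   (`"facilitation"`/`"inhibition"`), `locus` (`"self"`/`"other"`),
#'   `category`, `strength` (1/h, magnitude), `depletable`.
#' @export
classify_influences <- function(params) {
  idx <- which(params$rho != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(species = integer(), mediator = integer(),
                      sign = character(), locus = character(),
                      category = character(), strength = numeric(),
                      depletable = logical()))
  i <- idx[, 1]; l <- idx[, 2]
  rho <- params$rho[idx]
  sign <- ifelse(rho > 0, "facilitation", "inhibition")
  locus <- ifelse(params$beta[cbind(l, i)] > 0, "self", "other")
  category <- paste0(ifelse(locus == "self", "self-", "other-"),
                     ifelse(sign == "facilitation", "facilitation",
                            "inhibition"))
  category[sign == "inhibition" & locus == "self"] <- "self-restraint"
  out <- data.frame(species = i, mediator = l, sign = sign, locus = locus,
                    category = category, strength = abs(rho),
                    depletable = params$depletable[cbind(l, i)])
  out[order(out$species, out$mediator), , drop = FALSE]
}

#' Influences active in a community subset
#'
#' Keeps the influence links that remain dynamically relevant when only
#' `members` are present: the recipient must be a member and at least one
#' member must produce the mediator (otherwise its concentration stays
#' zero). If end-state mediator concentrations `C` are supplied, links
#' whose mediator is fully consumed (concentration exactly 0) are dropped
#' too — such links exert no influence on the realized dynamics even
#' though producer and recipient coexist.
#'
#' @param params a [community_params()] object.
#' @param members integer vector of member species indices.
#' @param C optional end-state mediator concentration vector (e.g.
#'   `final_state$C` of an [run_enrichment()] result).
#' @return The subset of [classify_influences()] records.
#' @export
active_influences <- function(params, members, C = NULL) {
  recs <- classify_influences(params)
  if (nrow(recs) == 0 || length(members) == 0)
    return(recs[integer(0), , drop = FALSE])
  produced <- vapply(recs$mediator, function(l)
    any(params$beta[l, members] > 0), logical(1))
  keep <- recs$species %in% members & produced
  if (!is.null(C)) keep <- keep & C[recs$mediator] > 0
  recs[keep, , drop = FALSE]
}

frac_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

influence_fractions <- function(recs) {
  n_fac <- sum(recs$sign == "facilitation")
  n_inh <- sum(recs$sign == "inhibition")
  list(n_fac = n_fac, n_inh = n_inh,
       frac_fac = frac_or_na(recs$sign == "facilitation"),
       frac_sr = frac_or_na(recs$locus[recs$sign == "inhibition"] == "self"))
}

#' Enrich an ensemble of random pools
#'
#' Samples `n_pools` pools from one spec (or from each of a list of specs,
#' pooled), runs enrichment plus the coexistence filter on every pool, and
#' tabulates per-pool outcomes: derived richness and the facilitation /
#' self-restraint fractions among influence links, in the initial pool and
#' among the influences active in the derived community. Self-restraint
#' fractions are computed within inhibitory influences (`NA` when there are
#' none). Stalled or collapsed runs count as no coexistence (richness 1 or
#' 0).
#'
#' @param spec a [pool_spec()] or a list of them (e.g. several
#'   facilitation:inhibition ratios, pooled).
#' @param config an [enrichment_config()].
#' @param n_pools pools sampled per spec.
#' @param seed integer seed; per-pool sub-seeds are drawn from it.
#' @return A data.frame, one row per pool, with the sampled pool seed so any
#'   pool can be regenerated.
#' @export
enrich_ensemble <- function(spec, config = enrichment_config(), n_pools,
                            seed = 1L) {
  specs <- if (inherits(spec, "pool_spec")) list(spec) else spec
  rows <- with_seed(seed, {
    pool_seeds <- sample.int(.Machine$integer.max - 1L,
                             n_pools * length(specs))
    out <- vector("list", n_pools * length(specs))
    k <- 0L
    for (si in seq_along(specs)) {
      for (j in seq_len(n_pools)) {
        k <- k + 1L
        params <- sample_pool(specs[[si]], seed = pool_seeds[k])
        dc <- derive_community(params, config)
        init <- influence_fractions(classify_influences(params))
        act <- influence_fractions(
          active_influences(params, dc$derived,
                            C = dc$result$final_state$C))
        richness <- if (dc$result$stalled || dc$result$collapsed)
          min(1L, length(dc$result$survivors)) else length(dc$derived)
        out[[k]] <- data.frame(
          spec_id = si, pool_seed = pool_seeds[k], richness = richness,
          stalled = dc$result$stalled, collapsed = dc$result$collapsed,
          n_fac_init = init$n_fac, n_inh_init = init$n_inh,
          frac_fac_init = init$frac_fac, frac_sr_init = init$frac_sr,
          n_fac_derived = act$n_fac, n_inh_derived = act$n_inh,
          frac_fac_derived = act$frac_fac, frac_sr_derived = act$frac_sr)
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Mean excess richness with bootstrap confidence interval
#'
#' MER is the average richness beyond single-species dominance,
#' \eqn{\sum_i (i - 1) p_i}, over an ensemble of derived communities. The
#' confidence interval is a nonparametric bootstrap over pools (3000
#' resamples with replacement by default).
#'
#' @param richness integer vector of per-pool derived richness values.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional seed for the bootstrap.
#' @return A list with `mer` and `ci` (length-2 vector).
#' @export
mer <- function(richness, n_boot = 3000, conf = 0.95, seed = NULL) {
  if (length(richness) == 0) stop("empty richness vector")
  point <- mean(richness - 1)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b)
      mean(sample(richness, replace = TRUE) - 1), numeric(1))
    unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  })
  list(mer = point, ci = ci)
}

#' Richness screen over an ensemble of random pools
#'
#' Runs [enrich_ensemble()] and aggregates the richness distribution, MER
#' with bootstrap interval, and mean influence-category fractions. With
#' `control = TRUE` a matched no-chemical-interaction ensemble (influence
#' links removed) is scored alongside, the competitive-exclusion reference.
#'
#' @inheritParams enrich_ensemble
#' @param control also run the no-interaction control ensemble.
#' @return An object of class `screen_summary`.
#' @export
richness_screen <- function(spec, config = enrichment_config(), n_pools,
                            seed = 1L, control = FALSE) {
  pools <- enrich_ensemble(spec, config, n_pools, seed)
  summ <- summarize_screen(pools)
  if (control) {
    spec0 <- if (inherits(spec, "pool_spec")) spec else spec[[1]]
    spec0$q_c <- 0
    summ$control <- summarize_screen(enrich_ensemble(spec0, config, n_pools,
                                                     seed))
  }
  summ
}

summarize_screen <- function(pools) {
  rich <- pools$richness
  tab <- table(factor(rich, levels = 0:max(rich, 1)))
  pmf <- as.numeric(tab) / length(rich)
  m <- mer(rich, seed = 0L)
  structure(list(
    n_pools = length(rich),
    richness_values = as.integer(names(tab)),
    richness_pmf = pmf,
    richness_pmf_sd = sqrt(pmf * (1 - pmf) / length(rich)),
    mer = m$mer, mer_ci = m$ci,
    coexistence_likelihood = mean(rich >= 2),
    category_fractions_initial = c(
      facilitation = mean(pools$frac_fac_init, na.rm = TRUE),
      self_restraint_within_inhibition = mean(pools$frac_sr_init,
                                              na.rm = TRUE)),
    category_fractions_derived = c(
      facilitation = mean(pools$frac_fac_derived, na.rm = TRUE),
      self_restraint_within_inhibition = mean(pools$frac_sr_derived,
                                              na.rm = TRUE)),
    pools = pools), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary> ", x$n_pools, " pools; P(richness >= 2) = ",
      format(x$coexistence_likelihood, digits = 3), "\n", sep = "")
  cat("  MER = ", format(x$mer, digits = 3), "  (95% CI ",
      format(x$mer_ci[1], digits = 3), " - ",
      format(x$mer_ci[2], digits = 3), ")\n", sep = "")
  inline <- paste(x$richness_values, format(x$richness_pmf, digits = 2),
                  sep = ":", collapse = "  ")
  cat("  richness pmf  ", inline, "\n", sep = "")
  invisible(x)
}

#' Influence-category enrichment from initial pools to derived communities
#'
#' Scores, over the qualifying pools of an ensemble (derived community of at
#' least two species), how the facilitation fraction among influences and
#' the self-restraint fraction among inhibitory influences changed from the
#' initial pool to the active influences of the derived community.
#' "Favored" means the derived fraction strictly exceeds the initial one;
#' ties count as unchanged.
#'
#' Qualifying pools are those whose derived community has at least two
#' species and retains at least one active influence (communities with no
#' retained influence have undefined category fractions and correspond to
#' neutral near-ties).
#'
#' @inheritParams enrich_ensemble
#' @param pools optionally, a precomputed [enrich_ensemble()] table (then
#'   `spec`/`n_pools`/`seed` are ignored).
#' @return A list with the per-pool table (`pools`, qualifying rows only)
#'   and summary fractions: `frac_only_facilitation` (derived communities
#'   whose active influences include facilitation and no inhibition),
#'   `frac_only_self_restraint_given_inhibition`,
#'   `frac_facilitation_favored`, and
#'   `frac_self_restraint_favored_in_remainder` (among pools where
#'   facilitation was not favored).
#' @export
category_enrichment <- function(spec = NULL, config = enrichment_config(),
                                n_pools = NULL, seed = 1L, pools = NULL) {
  if (is.null(pools))
    pools <- enrich_ensemble(spec, config, n_pools, seed)
  q <- pools[pools$richness >= 2 & !pools$stalled & !pools$collapsed &
               (pools$n_fac_derived + pools$n_inh_derived) >= 1, ,
             drop = FALSE]
  only_fac <- q$n_inh_derived == 0 & q$n_fac_derived >= 1
  has_inh <- q$n_inh_derived >= 1
  only_sr <- has_inh & q$frac_sr_derived == 1
  fac_favored <- !is.na(q$frac_fac_derived) &
    q$frac_fac_derived > q$frac_fac_init
  sr_favored <- !is.na(q$frac_sr_derived) & !is.na(q$frac_sr_init) &
    q$frac_sr_derived > q$frac_sr_init
  remainder <- !fac_favored
  list(pools = q,
       n_qualifying = nrow(q),
       frac_only_facilitation = frac_or_na(only_fac),
       frac_only_self_restraint_given_inhibition =
         if (any(has_inh)) mean(only_sr[has_inh]) else NA_real_,
       n_with_inhibition = sum(has_inh),
       frac_facilitation_favored = frac_or_na(fac_favored),
       n_remainder = sum(remainder),
       frac_self_restraint_favored_in_remainder =
         if (any(remainder)) mean(sr_favored[remainder]) else NA_real_)
}

#' Build an ensemble of derived communities for knock-out screens
#'
#' Samples pools, keeps those whose derived community has at least
#' `min_richness` species, and (optionally) verifies stability by
#' re-simulation.
#'
#' @inheritParams enrich_ensemble
#' @param min_richness minimum derived richness to keep a pool.
#' @param check_stability run [stability_check()] on each kept pool.
#' @return A list of entries, each with `params`, `derived`, `pool_seed`,
#'   and `stable` (if checked).
#' @export
derived_ensemble <- function(spec, config = enrichment_config(), n_pools,
                             seed = 1L, min_richness = 2,
                             check_stability = TRUE) {
  specs <- if (inherits(spec, "pool_spec")) list(spec) else spec
  with_seed(seed, {
    pool_seeds <- sample.int(.Machine$integer.max - 1L,
                             n_pools * length(specs))
    out <- list()
    k <- 0L
    for (si in seq_along(specs)) for (j in seq_len(n_pools)) {
      k <- k + 1L
      params <- sample_pool(specs[[si]], seed = pool_seeds[k])
      dc <- derive_community(params, config)
      if (length(dc$derived) < min_richness || dc$result$stalled ||
          dc$result$collapsed) next
      entry <- list(params = params, derived = dc$derived,
                    richness = length(dc$derived), pool_seed = pool_seeds[k])
      if (check_stability)
        entry$stable <- stability_check(params, dc$derived, config)
      out[[length(out) + 1L]] <- entry
    }
    out
  })
}

#' In-silico influence knock-out screen
#'
#' For each derived community in the ensemble, removes one active influence
#' at a time and measures the consequence, grouped by influence category.
#' Mode `"from_pool"` removes the influence from the initial pool and reruns
#' the whole enrichment, recording the change in derived richness. Mode
#' `"from_derived"` removes the influence from the derived community itself
#' and re-simulates a further full enrichment; only ensemble entries
#' verified stable are used in this mode. Disruption is scored as
#' `"extinction"` (default: some original member no longer persists — the
#' same species no longer coexist) or `"filter"` (the stricter test: the
#' filtered derived set differs, so a member may merely have started
#' declining).
#'
#' @param ensemble a [derived_ensemble()] list.
#' @param mode `"from_derived"` or `"from_pool"`.
#' @param config an [enrichment_config()].
#' @param disruption criterion for mode `"from_derived"`; see Details.
#' @return A list with the per-knockout table (`knockouts`) and a
#'   `by_category` summary data.frame (tested counts, disruption or
#'   richness-drop rates).
#' @export
knockout_screen <- function(ensemble, mode = c("from_derived", "from_pool"),
                            config = enrichment_config(),
                            disruption = c("extinction", "filter")) {
  mode <- match.arg(mode)
  disruption <- match.arg(disruption)
  rows <- list()
  for (e in ensemble) {
    if (mode == "from_derived" && !isTRUE(e$stable)) next
    recs <- active_influences(e$params, e$derived)
    if (nrow(recs) == 0) next
    for (rr in seq_len(nrow(recs))) {
      sp <- recs$species[rr]; md <- recs$mediator[rr]
      if (mode == "from_pool") {
        ko <- knockout_link(e$params, sp, md)
        dc <- derive_community(ko, config)
        delta <- length(dc$derived) - e$richness
        rows[[length(rows) + 1L]] <- data.frame(
          pool_seed = e$pool_seed, species = sp, mediator = md,
          category = recs$category[rr], delta_richness = delta,
          outcome = if (delta < 0) "drop" else if (delta > 0) "gain"
          else "unchanged")
      } else {
        sub <- subset_species(e$params, e$derived)
        idx <- attr(sub, "species_index")
        ko <- knockout_link(sub, match(sp, idx), md)
        dc <- derive_community(ko, config)
        after <- if (disruption == "extinction") dc$result$survivors
        else dc$derived
        disrupted <- dc$result$stalled || dc$result$collapsed ||
          !setequal(idx[after], e$derived)
        rows[[length(rows) + 1L]] <- data.frame(
          pool_seed = e$pool_seed, species = sp, mediator = md,
          category = recs$category[rr], disrupted = disrupted,
          outcome = if (disrupted) "disrupted" else "kept")
      }
    }
  }
  knockouts <- if (length(rows)) do.call(rbind, rows) else NULL
  by_category <- NULL
  if (!is.null(knockouts)) {
    cats <- sort(unique(knockouts$category))
    by_category <- do.call(rbind, lapply(cats, function(cc) {
      sub <- knockouts[knockouts$category == cc, , drop = FALSE]
      if (mode == "from_derived")
        data.frame(category = cc, n_tested = nrow(sub),
                   disruption_rate = mean(sub$disrupted))
      else
        data.frame(category = cc, n_tested = nrow(sub),
                   drop_rate = mean(sub$outcome == "drop"),
                   gain_rate = mean(sub$outcome == "gain"),
                   mean_delta = mean(sub$delta_richness))
    }))
  }
  list(mode = mode, knockouts = knockouts, by_category = by_category)
}

#' Depletable-versus-reusable mediator screen
#'
#' Runs a richness screen at each depletable fraction on matched pools: the
#' same pool seeds are used at every fraction, so pools differ only in
#' which influence links carry consumption (and their `alpha` entries).
#'
#' @inheritParams enrich_ensemble
#' @param depletable_fractions numeric vector in `[0, 1]`.
#' @return A data.frame with one row per fraction: MER, bootstrap CI,
#'   coexistence likelihood.
#' @export
mechanism_screen <- function(spec, config = enrichment_config(),
                             depletable_fractions = c(0, 0.5, 1),
                             n_pools, seed = 1L) {
  stopifnot(all(depletable_fractions >= 0 & depletable_fractions <= 1))
  out <- lapply(depletable_fractions, function(f) {
    sp <- spec; sp$depletable_fraction <- f
    pools <- enrich_ensemble(sp, config, n_pools, seed) # same seed: matched
    m <- mer(pools$richness, seed = 0L)
    data.frame(depletable_fraction = f, mer = m$mer,
               mer_lo = m$ci[1], mer_hi = m$ci[2],
               coexistence_likelihood = mean(pools$richness >= 2),
               n_pools = nrow(pools))
  })
  do.call(rbind, out)
}

#' Influence-strength sweep
#'
#' Scores coexistence at several interaction strengths, expressed as the
#' ratio of the mean influence strength to the standard deviation of basal
#' growth rates (`rho / sigma_r0`). Pool seeds are matched across strengths,
#' so topologies and all other parameters are shared and only the influence
#' magnitudes scale.
#'
#' @inheritParams enrich_ensemble
#' @param strength_ratios target values of mean strength over `sigma_r0`.
#' @return A data.frame with one row per ratio: realized `rho_max`,
#'   coexistence likelihood, MER and CI.
#' @export
strength_sweep <- function(spec, config = enrichment_config(),
                           strength_ratios = c(0.1, 1, 10, 100),
                           n_pools, seed = 1L) {
  sigma_r0 <- (spec$r0_high - spec$r0_low) / sqrt(12)
  out <- lapply(strength_ratios, function(ratio) {
    sp <- spec; sp$rho_max <- 2 * ratio * sigma_r0 # mean strength = rho_max/2
    pools <- enrich_ensemble(sp, config, n_pools, seed)
    m <- mer(pools$richness, seed = 0L)
    data.frame(strength_ratio = ratio, rho_max = sp$rho_max,
               coexistence_likelihood = mean(pools$richness >= 2),
               mer = m$mer, mer_lo = m$ci[1], mer_hi = m$ci[2],
               n_pools = nrow(pools))
  })
  do.call(rbind, out)
}

#' Frequency-perturbation recovery test
#'
#' Establishes the steady post-dilution frequency pattern of a derived
#' community, displaces it by moving a fraction `kick` of total frequency
#' from the most to the least abundant member, re-simulates a full
#' enrichment from the displaced composition, and reports whether the
#' frequencies return to the unperturbed pattern within `tol`.
#'
#' @param params full-pool [community_params()].
#' @param derived derived-community indices (at least 2 species).
#' @param kick frequency displacement in `[0, 1)`.
#' @param config an [enrichment_config()].
#' @param tol maximum absolute frequency deviation counted as recovered.
#' @return `TRUE` if the perturbed community returns to the steady pattern.
#' @export
perturbation_recovery <- function(params, derived, kick = 0.2,
                                  config = enrichment_config(), tol = 0.05) {
  stopifnot(length(derived) >= 2, kick >= 0, kick < 1)
  sub <- subset_species(params, derived)
  base <- run_enrichment(sub, config)
  if (base$stalled || base$collapsed) return(FALSE)
  f_star <- base$final_state$S / sum(base$final_state$S)
  f0 <- f_star
  if (kick > 0) {
    hi <- which.max(f0)
    lo <- which.min(replace(f0, hi, Inf)) # distinct from hi even under ties
    shift <- min(kick, f0[hi] * 0.99)
    f0[hi] <- f0[hi] - shift
    f0[lo] <- f0[lo] + shift
    f0 <- f0 / sum(f0)
  }
  start <- community_state(S = f0 * config$sum_S_init,
                           C = rep(0, sub$n_mediators), t = 0)
  rerun <- run_enrichment(sub, config, init_state = start)
  if (rerun$stalled || rerun$collapsed) return(FALSE)
  f_end <- rerun$final_state$S / sum(rerun$final_state$S)
  max(abs(f_end - f_star)) <= tol
}
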