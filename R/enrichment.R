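#' Enrichment protocol configuration
#'
#' Parameters of the serial grow-dilute protocol: communities grow from a
#' total post-dilution density `sum_S_init` to the dilution trigger
#' `sum_S_dil`, are diluted back, and species below the extinction density
#' `sum_S_ext` are removed. One round spans
#' `log2(sum_S_dil / sum_S_init)` (about 20) generations, so `n_rounds = 10`
#' corresponds to roughly 200 generations.
#'
#' @param sum_S_init total post-dilution density (1/ml).
#' @param sum_S_dil dilution-trigger total density (1/ml).
#' @param sum_S_ext extinction density (1/ml); corresponds to one cell in
#'   the inoculum at a 10 ml reference volume.
#' @param n_rounds number of dilution rounds.
#' @param decline_window_generations span (generations) of the final-decline
#'   test; with the default densities one round covers it.
#' @param decline_threshold fractional decline (over the window) beyond
#'   which a persisting species is still removed from the derived community.
#' @param t_max_per_round stall cap per growth round (h).
#' @param dt Euler timestep (h).
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(sum_S_init = 1e4, sum_S_dil = 1e10,
                              sum_S_ext = 0.1, n_rounds = 10,
                              decline_window_generations = 20,
                              decline_threshold = 0.10,
                              t_max_per_round = 1e4, dt = 0.01) {
  if (!(sum_S_ext < sum_S_init && sum_S_init < sum_S_dil))
    stop("need sum_S_ext < sum_S_init < sum_S_dil")
  if (n_rounds < 1) stop("n_rounds must be at least 1")
  if (dt <= 0 || t_max_per_round <= 0) stop("dt and t_max_per_round must be positive")
  structure(list(sum_S_init = sum_S_init, sum_S_dil = sum_S_dil,
                 sum_S_ext = sum_S_ext, n_rounds = as.integer(n_rounds),
                 decline_window_generations = decline_window_generations,
                 decline_threshold = decline_threshold,
                 t_max_per_round = t_max_per_round, dt = dt),
            class = "enrichment_config")
}

#' Dilute a culture back to the initial density
#'
#' Multiplies all densities by `sum_S_init / sum(S)` and co-dilutes mediator
#' concentrations by the same factor (transfer into fresh medium). Species
#' falling below the extinction density after dilution are zeroed.
#'
#' @param state a [community_state()] with `sum(S) >= sum_S_init`.
#' @param config an [enrichment_config()].
#' @return The diluted `community_state`, with an attribute `"extinct"`
#'   listing species zeroed by this dilution.
#' @export
dilute <- function(state, config = enrichment_config()) {
  tot <- sum(state$S)
  if (tot == 0)
    stop("community collapse: no live cells to dilute", call. = FALSE)
  if (tot < config$sum_S_init)
    stop("total density below sum_S_init; dilution undefined")
  f <- config$sum_S_init / tot
  S <- state$S * f
  ext <- which(S > 0 & S < config$sum_S_ext)
  S[ext] <- 0
  out <- community_state(S = S, C = state$C * f, t = state$t)
  attr(out, "extinct") <- ext
  out
}

#' Run the grow-dilute enrichment protocol
#'
#' Starting from all species at equal proportions (total `sum_S_init`, no
#' mediators), alternates [grow_until()] and [dilute()] for
#' `config$n_rounds` rounds. Species dropping below the extinction density
#' (during growth or at dilution) are removed for the rest of the
#' simulation. If a growth round never reaches the dilution threshold
#' within `t_max_per_round`, the run is flagged stalled and stops.
#'
#' @param params a [community_params()] object.
#' @param config an [enrichment_config()].
#' @param init_state optional [community_state()] overriding the
#'   equal-proportion start.
#' @return An object of class `enrichment_result`: `survivors` (indices
#'   alive at the end), `generations_elapsed` (total log2 fold-growth),
#'   `round_S`/`round_C` (post-dilution snapshots, one row per completed
#'   round), `extinctions` (species, round), `stalled`, `collapsed`,
#'   `final_state`, `n_rounds_done`.
#' @export
run_enrichment <- function(params, config = enrichment_config(),
                           init_state = NULL) {
  n <- params$n_species; m <- params$n_mediators
  state <- if (is.null(init_state)) {
    community_state(S = rep(config$sum_S_init / n, n), C = rep(0, m), t = 0)
  } else init_state
  round_S <- matrix(NA_real_, config$n_rounds, n)
  round_C <- matrix(NA_real_, config$n_rounds, m)
  extinctions <- data.frame(species = integer(), round = integer())
  generations <- 0
  stalled <- FALSE
  collapsed <- FALSE
  rounds_done <- 0L
  for (r in seq_len(config$n_rounds)) {
    alive_before <- state$S > 0
    g <- grow_until(params, state, config$sum_S_dil,
                    t_max = config$t_max_per_round, dt = config$dt,
                    extinction_density = config$sum_S_ext)
    state <- g$state
    died_growing <- which(alive_before & state$S == 0)
    if (length(died_growing))
      extinctions <- rbind(extinctions,
                           data.frame(species = died_growing, round = r))
    if (sum(state$S) == 0) { collapsed <- TRUE; break }
    if (!g$reached) { stalled <- TRUE; break }
    generations <- generations + log2(sum(state$S) / config$sum_S_init)
    state <- dilute(state, config)
    ext <- attr(state, "extinct")
    if (length(ext))
      extinctions <- rbind(extinctions, data.frame(species = ext, round = r))
    round_S[r, ] <- state$S
    round_C[r, ] <- state$C
    rounds_done <- r
  }
  structure(list(survivors = which(state$S > 0),
                 generations_elapsed = generations,
                 round_S = round_S, round_C = round_C,
                 extinctions = extinctions, stalled = stalled,
                 collapsed = collapsed, final_state = state,
                 n_rounds_done = rounds_done, config = config),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$n_rounds_done, " rounds, ",
      format(x$generations_elapsed, digits = 4), " generations\n", sep = "")
  cat("  survivors: ", paste(x$survivors, collapse = ", "),
      if (x$stalled) "  [stalled]", if (x$collapsed) "  [collapsed]",
      "\n", sep = "")
  invisible(x)
}

#' Operational coexistence filter
#'
#' Removes from the survivor set any species whose final post-dilution
#' density has dropped more than `decline_threshold` (strictly) below a
#' reference level: such species are presumed to be slowly going extinct.
#' With `reference = "peak"` (default) the reference is the species'
#' running maximum post-dilution density over the enrichment, so a slow
#' but sustained decline is caught even when its per-round decrement is
#' small; with `reference = "previous"` only the decline across the final
#' round (about 20 generations under the default densities) is tested.
#' A species sitting exactly at the threshold is retained (strict `>`
#' decline removes). The remaining set is the derived community.
#'
#' @param result an [run_enrichment()] result (not stalled).
#' @param config the [enrichment_config()] used (defaults to the one stored
#'   in `result`).
#' @param reference decline baseline, `"peak"` or `"previous"`.
#' @return Integer vector of derived-community species indices.
#' @export
coexistence_filter <- function(result, config = result$config,
                               reference = c("peak", "previous")) {
  reference <- match.arg(reference)
  if (result$stalled) stop("coexistence is undefined for a stalled run")
  surv <- result$survivors
  last <- result$n_rounds_done
  if (last < 2 || length(surv) == 0) return(surv)
  d_last <- result$round_S[last, surv]
  d_ref <- if (reference == "previous") result$round_S[last - 1, surv]
  else apply(result$round_S[seq_len(last), surv, drop = FALSE], 2, max)
  keep <- d_last >= (1 - config$decline_threshold) * d_ref
  surv[keep]
}

#' Enrich a pool and apply the coexistence filter
#'
#' Convenience wrapper returning both the raw enrichment result and the
#' derived community. Stalled or collapsed runs yield an empty derived set
#' (scored as no coexistence).
#'
#' @inheritParams run_enrichment
#' @return A list with `result` and `derived`.
#' @export
derive_community <- function(params, config = enrichment_config()) {
  result <- run_enrichment(params, config)
  derived <- if (result$stalled || result$collapsed) integer(0)
  else coexistence_filter(result, config)
  list(result = result, derived = derived)
}

#' Re-simulation stability check
#'
#' Restarts the derived community alone, at equal proportions, for another
#' full enrichment (about 200 more generations) and reports whether the
#' same species still coexist. With `criterion = "persistence"` (default)
#' that means every member persists (none goes extinct); with
#' `criterion = "coexistence"` the re-run must additionally reproduce the
#' full filter-passing set, a stricter demand under which a member merely
#' dipping below its running peak counts as instability.
#'
#' @param params the full-pool [community_params()].
#' @param derived integer vector of derived-community species indices
#'   (non-empty), in full-pool indexing.
#' @param config an [enrichment_config()].
#' @param criterion `"persistence"` or `"coexistence"`.
#' @return `TRUE` iff the same species coexist again.
#' @export
stability_check <- function(params, derived, config = enrichment_config(),
                            criterion = c("persistence", "coexistence")) {
  criterion <- match.arg(criterion)
  stopifnot(length(derived) >= 1)
  sub <- subset_species(params, derived)
  idx <- attr(sub, "species_index")
  out <- derive_community(sub, config)
  if (out$result$stalled || out$result$collapsed) return(FALSE)
  after <- if (criterion == "persistence") out$result$survivors else out$derived
  setequal(idx[after], derived)
}
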