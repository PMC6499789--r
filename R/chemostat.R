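#' Chemostat steady-state problem
#'
#' In a continuous-growth environment with dilution rate `delta`, mediators
#' are assumed either saturating (`theta_l = 1`, accumulating well above
#' their saturation concentration) or depleted (`theta_l = 0`), so the
#' species dynamics reduce to a linear system
#' \deqn{d\mathbf{S}/dt = (-\delta + \mathbf{r}_0 + \mathbf{P}\Theta)\mathbf{S}.}
#' Steady-state coexistence corresponds to the species subset whose
#' effective growth matrix has the largest leading eigenvalue with a
#' strictly positive leading eigenvector (the dilution rate is then matched
#' to that eigenvalue). The problem keeps the mediator-resolved influence
#' matrix so the per-subset producer attribution can be formed exactly.
#'
#' @param params a [community_params()] object.
#' @param delta dilution rate (1/h), `>= 0`.
#' @return An object of class `chemostat_problem`.
#' @export
chemostat_problem <- function(params, delta = 0) {
  stopifnot(delta >= 0)
  structure(list(r0 = params$r0, rho = params$rho,
                 producers = params$beta > 0, # M x N
                 consumers = t(params$rho != 0) & params$depletable &
                   params$alpha > 0,          # M x N
                 n_species = params$n_species,
                 n_mediators = params$n_mediators, delta = delta),
            class = "chemostat_problem")
}

theta_for_subset <- function(problem, subset) {
  # A mediator accumulates (theta = 1) iff some subset member produces it
  # and no subset member consumes/degrades it; otherwise it is depleted or
  # absent (theta = 0).
  vapply(seq_len(problem$n_mediators), function(l) {
    produced <- any(problem$producers[l, subset])
    consumed <- any(problem$consumers[l, subset])
    as.numeric(produced && !consumed)
  }, numeric(1))
}

#' Effective growth matrix of a species subset
#'
#' Restricts the linearized chemostat dynamics to `subset` under a given
#' saturation assignment `theta`: the diagonal carries basal rates, and for
#' each accumulating mediator the net influence on each recipient is
#' attributed equally to the mediator's producers within the subset. Returns
#' the restricted matrix and its leading eigenvalue (largest real part),
#' which a matched dilution rate balances at steady state.
#'
#' @param problem a [chemostat_problem()].
#' @param subset non-empty integer vector of species indices.
#' @param theta binary vector over mediators; defaults to the consistency
#'   rule (accumulate iff produced by the subset and consumed by nobody in
#'   it).
#' @return A list with `matrix`, `eigenvalue`, `eigenvector` (leading), and
#'   `theta`.
#' @export
effective_growth_matrix <- function(problem, subset,
                                    theta = theta_for_subset(problem, subset)) {
  subset <- sort(unique(as.integer(subset)))
  stopifnot(length(subset) >= 1, all(theta %in% c(0, 1)))
  ns <- length(subset)
  A <- diag(problem$r0[subset], ns)
  for (l in which(theta == 1)) {
    prods <- which(problem$producers[l, subset])
    if (length(prods) == 0) next
    w <- 1 / length(prods)
    infl <- problem$rho[subset, l]
    for (jj in prods) A[, jj] <- A[, jj] + infl * w
  }
  ev <- eigen(A)
  lead <- which.max(Re(ev$values))
  v <- ev$vectors[, lead]
  if (all(Mod(Im(v)) < 1e-9)) v <- Re(v)
  list(matrix = A, eigenvalue = Re(ev$values[lead]), eigenvector = v,
       theta = theta, subset = subset)
}

positive_eigenvector <- function(v, tol = 1e-9) {
  if (is.complex(v)) return(FALSE)
  v <- v / v[which.max(abs(v))]
  all(v > tol)
}

#' Fastest consistent sub-community in a chemostat
#'
#' Enumerates all species subsets (exhaustive; `n_species <= max_n`),
#' assigns each mediator's saturation indicator by the consistency rule
#' (accumulates iff net-produced by the subset and depleted by none of its
#' members), and returns the subset whose effective growth matrix attains
#' the largest leading eigenvalue with a strictly positive leading
#' eigenvector. Singletons are always consistent, so the best single
#' species is the fallback.
#'
#' @param problem a [chemostat_problem()].
#' @param max_n brute-force cap on the number of species.
#' @return The [effective_growth_matrix()] result of the winning subset.
#' @export
fastest_consistent_subcommunity <- function(problem, max_n = 12) {
  n <- problem$n_species
  if (n > max_n)
    stop("exhaustive enumeration limited to ", max_n, " species")
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0)
    res <- effective_growth_matrix(problem, subset)
    if (!positive_eigenvector(res$eigenvector)) next
    if (is.null(best) || res$eigenvalue > best$eigenvalue) best <- res
  }
  best
}
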