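#' Community parameterization
#'
#' Bundles every rate and matrix defining one community's dynamics. Species
#' densities `S_i` (cells/ml) and mediator concentrations `C_l` (fmol/ml)
#' evolve as
#' \deqn{dS_i/dt = [r_{0i} + \sum_l fac(C_l) - \sum_l inh(C_l)] S_i}
#' \deqn{dC_l/dt = \sum_i \beta_{li} S_i - \sum_i \alpha_{li}
#'   \frac{C_l}{C_l + K_{il}} S_i - decay_l C_l}
#' where facilitation follows a Monod (or Moser) saturating law and
#' inhibition a linear (or threshold / saturating "growth inhibition") law.
#'
#' @param r0 numeric length-N vector of basal net growth rates (1/h).
#' @param rho N x M signed influence-strength matrix (1/h): positive entries
#'   are facilitation, negative entries inhibition, 0 = no influence link.
#' @param K N x M saturation/normalization concentration matrix (fmol/ml);
#'   must be strictly positive wherever `rho` is nonzero or `alpha` positive.
#' @param alpha M x N maximum consumption factor matrix (fmol per cell);
#'   0 for reusable links. A positive entry requires the corresponding
#'   `depletable` flag.
#' @param beta M x N production rate matrix (fmol per cell per h).
#' @param depletable M x N logical mask, `TRUE` where the recipient
#'   consumes/degrades the mediator. Defaults to `alpha > 0`.
#' @param inhibition_law one of `"linear"`, `"threshold"`,
#'   `"growth_inhibition"`.
#' @param facilitation_law one of `"monod"`, `"moser"`.
#' @param moser_n Moser exponent (1 reduces to Monod).
#' @param c_th threshold concentration (fmol/ml) for the threshold and
#'   growth-inhibition laws.
#' @param decay optional mediator decay rate vector length M (1/h),
#'   default all 0.
#'
#' @return An object of class `community_params`.
#' @export
community_params <- function(r0, rho, K, alpha, beta,
                             depletable = NULL,
                             inhibition_law = c("linear", "threshold",
                                                "growth_inhibition"),
                             facilitation_law = c("monod", "moser"),
                             moser_n = 1, c_th = 0, decay = NULL) {
  inhibition_law <- match.arg(inhibition_law)
  facilitation_law <- match.arg(facilitation_law)
  r0 <- as.numeric(r0)
  n <- length(r0)
  rho <- as.matrix(rho); K <- as.matrix(K)
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  m <- ncol(rho)
  if (is.null(depletable)) depletable <- alpha > 0
  depletable <- matrix(as.logical(depletable), nrow = nrow(alpha),
                       ncol = ncol(alpha))
  if (is.null(decay)) decay <- rep(0, m)
  params <- structure(
    list(n_species = n, n_mediators = m, r0 = r0, rho = rho, K = K,
         alpha = alpha, beta = beta, depletable = depletable,
         inhibition_law = inhibition_law,
         facilitation_law = facilitation_law,
         moser_n = moser_n, c_th = c_th, decay = as.numeric(decay)),
    class = "community_params")
  validate_community_params(params)
  params
}

validate_community_params <- function(p) {
  stopifnot(is.numeric(p$r0), all(is.finite(p$r0)))
  n <- p$n_species; m <- p$n_mediators
  if (!all(dim(p$rho) == c(n, m)) || !all(dim(p$K) == c(n, m)))
    stop("rho and K must be n_species x n_mediators")
  if (!all(dim(p$alpha) == c(m, n)) || !all(dim(p$beta) == c(m, n)) ||
      !all(dim(p$depletable) == c(m, n)))
    stop("alpha, beta and depletable must be n_mediators x n_species")
  if (any(p$alpha < 0) || any(p$beta < 0))
    stop("alpha and beta must be non-negative")
  linked <- (t(p$rho) != 0) | (p$alpha > 0) # M x N positions that use K
  if (any(p$K[t(linked)] <= 0))
    stop("K must be strictly positive wherever an influence or consumption link exists")
  if (any(p$alpha > 0 & !p$depletable))
    stop("alpha > 0 requires the depletable flag (reusable links have alpha = 0)")
  if (length(p$decay) != m || any(p$decay < 0))
    stop("decay must be a non-negative vector of length n_mediators")
  if (p$moser_n <= 0) stop("moser_n must be positive")
  if (p$c_th < 0) stop("c_th must be non-negative")
  invisible(p)
}

#' @export
print.community_params <- function(x, ...) {
  n_infl <- sum(x$rho != 0)
  cat("<community_params> ", x$n_species, " species, ", x$n_mediators,
      " mediators\n", sep = "")
  cat("  influence links: ", n_infl, " (", sum(x$rho > 0), " facilitative, ",
      sum(x$rho < 0), " inhibitory)\n", sep = "")
  cat("  production links: ", sum(x$beta > 0), "; depletable links: ",
      sum(x$alpha > 0 & x$depletable), "\n", sep = "")
  cat("  laws: facilitation = ", x$facilitation_law,
      if (x$facilitation_law == "moser") paste0(" (n = ", x$moser_n, ")"),
      ", inhibition = ", x$inhibition_law, "\n", sep = "")
  invisible(x)
}

#' Community state
#'
#' Live cell densities, mediator concentrations and elapsed time.
#'
#' @param S numeric length-N vector of live cell densities (1/ml), `>= 0`.
#' @param C numeric length-M vector of mediator concentrations (fmol/ml),
#'   `>= 0`.
#' @param t elapsed time (h).
#' @return An object of class `community_state`.
#' @export
community_state <- function(S, C, t = 0) {
  S <- as.numeric(S); C <- as.numeric(C)
  if (any(S < 0) || any(C < 0))
    stop("densities and concentrations must be non-negative")
  if (!is.finite(t) || t < 0) stop("t must be finite and non-negative")
  structure(list(S = S, C = C, t = t), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("<community_state> t = ", format(x$t), " h; total density ",
      format(sum(x$S), digits = 4), " /ml; ",
      sum(x$S > 0), "/", length(x$S), " species alive\n", sep = "")
  invisible(x)
}

#' Restrict a community to a subset of species
#'
#' Keeps all mediators but drops the rows/columns of every species-indexed
#' container outside `species`. Used to re-simulate derived communities on
#' their own.
#'
#' @param params a [community_params()] object.
#' @param species integer vector of species indices to keep.
#' @return A `community_params` object over `length(species)` species. The
#'   original indices are kept in attribute `"species_index"`.
#' @export
subset_species <- function(params, species) {
  species <- sort(unique(as.integer(species)))
  stopifnot(all(species >= 1), all(species <= params$n_species))
  out <- community_params(
    r0 = params$r0[species],
    rho = params$rho[species, , drop = FALSE],
    K = params$K[species, , drop = FALSE],
    alpha = params$alpha[, species, drop = FALSE],
    beta = params$beta[, species, drop = FALSE],
    depletable = params$depletable[, species, drop = FALSE],
    inhibition_law = params$inhibition_law,
    facilitation_law = params$facilitation_law,
    moser_n = params$moser_n, c_th = params$c_th, decay = params$decay)
  attr(out, "species_index") <- species
  out
}
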