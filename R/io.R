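#' Write a community network specification to CSV
#'
#' The file starts with a commented header block of scalars (`# key value`:
#' dimensions, basal rates, response laws, default saturation), followed by
#' one row per link: `kind` in `production` (value = beta, fmol/cell/h),
#' `influence` (value = signed rho, 1/h; `depletable` flag set),
#' `consumption` (value = alpha, fmol/cell) or `saturation` (value = K,
#' fmol/ml, written for every influence/consumption position). The format
#' round-trips through [read_network_csv()].
#'
#' @param params a [community_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(params, path) {
  hdr <- c(
    paste("# n_species", params$n_species),
    paste("# n_mediators", params$n_mediators),
    paste("# r0", paste(format(params$r0, digits = 17), collapse = ",")),
    paste("# decay", paste(format(params$decay, digits = 17), collapse = ",")),
    paste("# inhibition_law", params$inhibition_law),
    paste("# facilitation_law", params$facilitation_law),
    paste("# moser_n", format(params$moser_n, digits = 17)),
    paste("# c_th", format(params$c_th, digits = 17)),
    paste("# k_default", format(1e4, digits = 17)))
  rows <- list()
  add <- function(kind, sp, md, value, depl = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, species = sp, mediator = md, value = value,
      depletable = depl)
  }
  bidx <- which(params$beta > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bidx)))
    add("production", bidx[r, 2], bidx[r, 1], params$beta[bidx[r, , drop = FALSE]])
  iidx <- which(params$rho != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(iidx))) {
    i <- iidx[r, 1]; l <- iidx[r, 2]
    add("influence", i, l, params$rho[i, l], params$depletable[l, i])
    add("saturation", i, l, params$K[i, l])
    if (params$alpha[l, i] > 0) add("consumption", i, l, params$alpha[l, i])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), species = integer(), mediator = integer(),
               value = numeric(), depletable = logical())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub("\\s.*$", "", kv)
  vals <- sub("^\\S+\\s+", "", kv)
  setNames(as.list(vals), keys)
}

#' Read a community network specification from CSV
#'
#' @param path a file written by [write_network_csv()] (or hand-authored in
#'   the same dialect).
#' @return A [community_params()] object. Saturation concentrations default
#'   to the header `k_default` at positions without a `saturation` row.
#' @export
read_network_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr <- parse_header(lines[is_hdr])
  tab <- read.csv(text = paste(lines[!is_hdr], collapse = "\n"),
                  stringsAsFactors = FALSE)
  n <- as.integer(hdr$n_species)
  m <- as.integer(hdr$n_mediators)
  r0 <- as.numeric(strsplit(hdr$r0, ",")[[1]])
  decay <- as.numeric(strsplit(hdr$decay, ",")[[1]])
  k_default <- as.numeric(hdr$k_default)
  rho <- matrix(0, n, m); K <- matrix(k_default, n, m)
  alpha <- matrix(0, m, n); beta <- matrix(0, m, n)
  depl <- matrix(FALSE, m, n)
  for (r in seq_len(nrow(tab))) {
    i <- as.integer(tab$species[r]); l <- as.integer(tab$mediator[r])
    v <- as.numeric(tab$value[r])
    switch(tab$kind[r],
           production = { beta[l, i] <- v },
           influence = {
             rho[i, l] <- v
             depl[l, i] <- isTRUE(as.logical(tab$depletable[r]))
           },
           consumption = { alpha[l, i] <- v },
           saturation = { K[i, l] <- v },
           stop("unknown link kind: ", tab$kind[r]))
  }
  community_params(r0 = r0, rho = rho, K = K, alpha = alpha, beta = beta,
                   depletable = depl, inhibition_law = hdr$inhibition_law,
                   facilitation_law = hdr$facilitation_law,
                   moser_n = as.numeric(hdr$moser_n),
                   c_th = as.numeric(hdr$c_th), decay = decay)
}

#' Write a long-format trajectory table to CSV
#'
#' @param traj a data.frame from [simulate_trajectory()] (columns `t`,
#'   `entity_type`, `entity_id`, `value`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(all(c("t", "entity_type", "entity_id", "value") %in% names(traj)))
  write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format plate-reader export
#'
#' Expects columns `time` (h), `well`, `value` and optionally `group`;
#' comment lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return A data.frame usable with [growth_rates_from_plate()].
#' @export
read_plate_csv <- function(path) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "well", "value")
  if (!all(need %in% names(tab)))
    stop("plate CSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Read a pool specification from a YAML/JSON-style config file
#'
#' Any field of [pool_spec()] may appear; missing fields take the defaults.
#'
#' @param path YAML file path.
#' @return A [pool_spec()].
#' @export
read_pool_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pool_spec))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown pool_spec fields: ", paste(unknown, collapse = ", "))
  do.call(pool_spec, vals)
}

#' Write a pool specification to YAML
#'
#' @param spec a [pool_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pool_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec)[!vapply(unclass(spec), is.null, logical(1))],
                   path)
  invisible(path)
}
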