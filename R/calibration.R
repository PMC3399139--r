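# one-sided 99% standard-normal quantile used by the SD rule
Z99 <- stats::qnorm(0.99)

#' Standard deviation for a probabilistic island calibration
#'
#' The probabilistic scheme replaces a fixed island-age calibration with a
#' normal prior centred on the island age. The standard deviation is chosen
#' so that the lower 99% limit of the normal reaches the present (age 0):
#' `sd = mean / z[0.99]`, rounded to the nearest 0.1 Ma. This gives the node
#' age ample room to move toward the present while keeping the island age
#' as the prior mode.
#'
#' @param mean island age in Ma; must be positive.
#' @return standard deviation in Ma, a multiple of 0.1.
#' @export
compute_prior_sd <- function(mean) {
  if (any(mean <= 0)) stop("calibration mean must be > 0 Ma", call. = FALSE)
  round(round(mean / Z99, 10) * 10) / 10
}

#' Hard-bounded interval emulating a punctual calibration
#'
#' Fixed-age ("punctual") calibrations are emulated as very narrow uniform
#' intervals with hard bounds at `mean - 0.01` and `mean + 0.01` Ma; ages
#' outside carry zero probability.
#'
#' @param mean island age in Ma; must exceed the 0.01 Ma half-width.
#' @return numeric `c(lower, upper)`.
#' @export
punctual_interval <- function(mean) {
  if (any(mean <= 0.01))
    stop("calibration mean must exceed the 0.01 Ma half-width", call. = FALSE)
  c(lower = mean - 0.01, upper = mean + 0.01)
}

#' Calibration prior densities
#'
#' Two families are supported: `normal(mean, sd)` and `hard_uniform(lower,
#' upper)`. Normal priors are not truncated at zero here; nonnegativity is
#' imposed by the dating model's node-age support, which renormalizes the
#' density implicitly.
#'
#' @param mean,sd normal parameters in Ma (`sd > 0`).
#' @return object of class `calibration_prior`.
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(sd > 0)
  structure(list(kind = "normal", mean = mean, sd = sd),
            class = "calibration_prior")
}

#' @rdname prior_normal
#' @param lower,upper hard bounds in Ma (`0 <= lower < upper`).
#' @export
prior_hard_uniform <- function(lower, upper) {
  stopifnot(lower >= 0, lower < upper)
  structure(list(kind = "hard_uniform", lower = lower, upper = upper),
            class = "calibration_prior")
}

#' @export
print.calibration_prior <- function(x, ...) {
  if (x$kind == "normal")
    cat(sprintf("normal calibration: %.4g +/- %.4g Ma\n", x$mean, x$sd))
  else
    cat(sprintf("punctual calibration: [%.4g, %.4g] Ma\n", x$lower, x$upper))
  invisible(x)
}

#' @rdname prior_normal
#' @param prior a `calibration_prior`.
#' @param age node age(s) in Ma.
#' @return log-density; `-Inf` outside hard bounds.
#' @export
prior_log_density <- function(prior, age) {
  stopifnot(inherits(prior, "calibration_prior"))
  if (prior$kind == "normal") {
    stats::dnorm(age, prior$mean, prior$sd, log = TRUE)
  } else {
    ifelse(age >= prior$lower & age <= prior$upper,
           -log(prior$upper - prior$lower), -Inf)
  }
}

#' Sample directly from a calibration prior (used by prior-level checks)
#' @keywords internal
prior_sample <- function(prior, n) {
  if (prior$kind == "normal") stats::rnorm(n, prior$mean, prior$sd)
  else stats::runif(n, prior$lower, prior$upper)
}

#' Build the two calibration schemes from island ages
#'
#' Given a table of calibrated nodes and island ages, returns the parallel
#' probabilistic (all-normal, via [compute_prior_sd()]) and punctual
#' (all-hard-uniform, via [punctual_interval()]) calibration tables used by
#' the two dating analyses.
#'
#' @param table data frame with columns `taxonA`, `taxonB`, `island_name`,
#'   `island_age_Ma` (one row per calibrated node).
#' @return list with elements `normal` and `punctual`, each a calibration
#'   table with `prior_kind`, `param1`, `param2` filled in
#'   (mean/sd, resp. lower/upper).
#' @export
build_schemes <- function(table) {
  table <- as.data.frame(table)
  req <- c("taxonA", "taxonB", "island_name", "island_age_Ma")
  if (!all(req %in% names(table)))
    stop("calibration table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(table) == 0L)
    stop("at least one calibration is required to anchor the timescale",
         call. = FALSE)
  if (any(table$island_age_Ma <= 0))
    stop("island ages must be > 0 Ma", call. = FALSE)
  normal <- punctual <- table[req]
  normal$prior_kind <- "normal"
  normal$param1 <- table$island_age_Ma
  normal$param2 <- compute_prior_sd(table$island_age_Ma)
  punctual$prior_kind <- "hard_uniform"
  punctual$param1 <- table$island_age_Ma - 0.01
  punctual$param2 <- table$island_age_Ma + 0.01
  list(normal = normal, punctual = punctual)
}

#' Read / write calibration tables
#'
#' Tab-separated with columns `taxonA`, `taxonB`, `island_name`,
#' `island_age_Ma` and, for scheme files, `prior_kind`, `param1`, `param2`.
#'
#' @param path file path.
#' @export
read_calibration_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_calibration_table
#' @param table calibration table data frame.
#' @export
write_calibration_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# turn one scheme row into a calibration_prior
row_prior <- function(row) {
  switch(row$prior_kind,
         normal = prior_normal(row$param1, row$param2),
         hard_uniform = prior_hard_uniform(row$param1, row$param2),
         stop("unknown prior_kind: ", row$prior_kind, call. = FALSE))
}

#' Resolve a calibration scheme against a tree
#'
#' Maps each row's taxon pair to its MRCA and attaches the prior. MRCAs
#' must be distinct across rows.
#'
#' @param tree `phylo` or [dated_tree()].
#' @param scheme a scheme table (see [build_schemes()]).
#' @return data frame with `node`, `island_name`, `island_age_Ma` plus a
#'   list-column `prior` of `calibration_prior` objects.
#' @export
resolve_calibrations <- function(tree, scheme) {
  if (nrow(scheme) == 0L) stop("empty calibration scheme", call. = FALSE)
  nodes <- vapply(seq_len(nrow(scheme)), function(i)
    resolve_mrca(tree, c(scheme$taxonA[i], scheme$taxonB[i])), integer(1))
  if (anyDuplicated(nodes))
    stop("two calibrations resolve to the same node (", nodes[duplicated(nodes)][1],
         ")", call. = FALSE)
  out <- data.frame(node = nodes,
                    island_name = scheme$island_name,
                    island_age_Ma = scheme$island_age_Ma)
  out$prior <- lapply(seq_len(nrow(scheme)), function(i) row_prior(scheme[i, ]))
  out
}
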