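#' Highest posterior density interval
#'
#' Chen–Shao estimator: the shortest contiguous interval containing
#' `ceiling(mass * n)` of the sorted samples.
#'
#' @param samples numeric MCMC samples, `n >= 100`, non-constant.
#' @param mass interval mass in `(0, 1)` (0.95 by default).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples for an HPD", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  if (stats::var(samples) == 0)
    stop("constant samples: HPD degenerate", call. = FALSE)
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(low = x[1], high = x[n]))
  starts <- seq_len(n - k)
  widths <- x[starts + k] - x[starts]
  i <- which.min(widths)
  c(low = x[i], high = x[i + k])
}

#' Kullback–Leibler divergence between calibration prior and posterior
#'
#' Estimates `KL(posterior || prior)` (the information the data add beyond
#' the calibration) as the sample average of `log q(x) - log p(x)`, where
#' `q` is a Gaussian kernel density estimate of the posterior (Silverman
#' bandwidth) and `p` the calibration prior density. Negative estimates —
#' possible through estimator noise when the two distributions coincide —
#' are clamped to zero. The direction can be flipped to
#' `KL(prior || posterior)`, evaluated by Monte-Carlo over fresh prior
#' draws. Values are in nats.
#'
#' @param posterior_samples numeric samples, `n >= 1000`.
#' @param prior a normal `calibration_prior` (a hard-bounded prior assigns
#'   zero density to almost any posterior draw, so it cannot serve as the
#'   reference; use the normal calibration).
#' @param direction `"posterior_from_prior"` (default) or
#'   `"prior_from_posterior"`.
#' @return nonnegative divergence in nats.
#' @export
kl_divergence <- function(posterior_samples, prior,
                          direction = c("posterior_from_prior",
                                        "prior_from_posterior")) {
  direction <- match.arg(direction)
  x <- as.numeric(posterior_samples)
  if (length(x) < 1000L)
    stop("need at least 1000 posterior samples", call. = FALSE)
  stopifnot(inherits(prior, "calibration_prior"))
  if (prior$kind == "hard_uniform")
    stop("hard-bounded priors have zero density outside their interval; ",
         "use the normal calibration prior as the KL reference",
         call. = FALSE)
  kde <- stats::density(x, bw = "nrd0", n = 2048, cut = 4)
  qdens <- function(v) {
    d <- stats::approx(kde$x, kde$y, xout = v, yleft = 0, yright = 0)$y
    pmax(d, 1e-300)
  }
  if (direction == "posterior_from_prior") {
    est <- mean(log(qdens(x)) - prior_log_density(prior, x))
  } else {
    z <- stats::qnorm(seq(0.5, length(x) - 0.5) / length(x),
                      prior$mean, prior$sd)
    est <- mean(prior_log_density(prior, z) - log(qdens(z)))
  }
  max(est, 0)
}

#' Classify a calibrated divergence against its island age
#'
#' The null hypothesis of cladogenesis concomitant with island formation
#' is rejected only when the island age falls strictly outside the 95% HPD
#' of the node age: below it the divergence predates the island
#' (`pre_island`), above it the divergence postdates it (`post_island`).
#' Island ages exactly at an endpoint stay `concomitant_not_rejected`
#' (conservative).
#'
#' @param hpd numeric `c(low, high)`.
#' @param island_age island age in Ma.
#' @return one of `"pre_island"`, `"concomitant_not_rejected"`,
#'   `"post_island"`.
#' @export
classify_node <- function(hpd, island_age) {
  stopifnot(length(hpd) == 2L, hpd[1] < hpd[2])
  if (island_age < hpd[1]) "pre_island"
  else if (island_age > hpd[2]) "post_island"
  else "concomitant_not_rejected"
}

#' Per-node difference between the two calibration schemes
#'
#' Absolute difference of posterior-mean node ages between the
#' probabilistic (normal) and punctual analyses of the same tree.
#'
#' @param trace_normal,trace_punctual `posterior_trace` data frames sharing
#'   the same `age_` columns.
#' @return named numeric vector of differences (Ma) with a `range`
#'   attribute `c(min, max)`.
#' @export
compare_schemes <- function(trace_normal, trace_punctual) {
  a1 <- grep("^age_", names(trace_normal), value = TRUE)
  a2 <- grep("^age_", names(trace_punctual), value = TRUE)
  if (!identical(a1, a2))
    stop("traces do not share the same node schema", call. = FALSE)
  d <- vapply(a1, function(p)
    abs(mean(trace_normal[[p]]) - mean(trace_punctual[[p]])), numeric(1))
  names(d) <- sub("^age_", "", a1)
  attr(d, "range") <- c(min = min(d), max = max(d))
  d
}

#' Assess every calibrated node
#'
#' The headline analysis: for each calibrated node, the posterior mean and
#' 95% HPD of its age under the probabilistic scheme, the KL divergence
#' between its normal calibration prior and the posterior, the
#' pre-island / concomitant / post-island classification against the
#' island age, and (when a punctual-scheme trace is supplied) the
#' between-scheme posterior-mean difference. Prior and posterior density
#' curves on a common age grid are attached for plotting.
#'
#' @param trace_normal `posterior_trace` from the normal-scheme run.
#' @param tree the `phylo` topology the traces were sampled on.
#' @param scheme_normal the normal calibration scheme table.
#' @param trace_punctual optional punctual-scheme trace; `NA` scheme
#'   differences when absent.
#' @param mass HPD mass.
#' @param grid_n points in each density curve.
#' @return data frame of class `node_assessment` (one row per calibrated
#'   node: `node`, `island_name`, `island_age`, `post_mean`, `hpd_low`,
#'   `hpd_high`, `kl_div`, `classification`, `scheme_diff`) with a
#'   `density_curves` attribute (list of per-node data frames `age`,
#'   `prior`, `posterior`).
#' @export
assess_all <- function(trace_normal, tree, scheme_normal,
                       trace_punctual = NULL, mass = 0.95, grid_n = 512L) {
  calib <- resolve_calibrations(tree, scheme_normal)
  cols <- paste0("age_", calib$node)
  missing <- setdiff(cols, names(trace_normal))
  if (length(missing))
    stop("trace lacks node columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sd_diff <- if (!is.null(trace_punctual))
    compare_schemes(trace_normal, trace_punctual) else NULL
  curves <- vector("list", nrow(calib))
  out <- data.frame(node = calib$node, island_name = calib$island_name,
                    island_age = calib$island_age_Ma,
                    post_mean = NA_real_, hpd_low = NA_real_,
                    hpd_high = NA_real_, kl_div = NA_real_,
                    classification = NA_character_, scheme_diff = NA_real_)
  for (i in seq_len(nrow(calib))) {
    x <- trace_normal[[cols[i]]]
    h <- hpd_interval(x, mass)
    pr <- calib$prior[[i]]
    out$post_mean[i] <- mean(x)
    out$hpd_low[i] <- h[1]; out$hpd_high[i] <- h[2]
    out$kl_div[i] <- kl_divergence(x, pr)
    out$classification[i] <- classify_node(h, calib$island_age_Ma[i])
    if (!is.null(sd_diff))
      out$scheme_diff[i] <- sd_diff[[as.character(calib$node[i])]]
    grid <- seq(min(x, pr$mean - 4 * pr$sd), max(x, pr$mean + 4 * pr$sd),
                length.out = grid_n)
    kde <- stats::density(x, bw = "nrd0", n = grid_n,
                          from = grid[1], to = grid[grid_n])
    curves[[i]] <- data.frame(age = kde$x,
                              prior = exp(prior_log_density(pr, kde$x)),
                              posterior = kde$y)
  }
  out <- out[order(out$node), ]
  rownames(out) <- NULL
  names(curves) <- paste0("node_", calib$node)
  curves <- curves[order(calib$node)]
  structure(out, class = c("node_assessment", "data.frame"),
            density_curves = curves)
}

#' Write an assessment report and its density curves
#'
#' The report is tab-separated; each node's prior/posterior curve goes to
#' `density_node_<id>.tsv` beside it.
#'
#' @param assessment a `node_assessment` from [assess_all()].
#' @param path report file path.
#' @param curves_dir directory for the per-node density grids (defaults to
#'   the report's directory); `NULL` suppresses them.
#' @export
write_assessment <- function(assessment, path, curves_dir = dirname(path)) {
  utils::write.table(as.data.frame(assessment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(curves_dir)) {
    cv <- attr(assessment, "density_curves")
    for (nm in names(cv))
      utils::write.table(cv[[nm]],
                         file.path(curves_dir, paste0("density_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
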