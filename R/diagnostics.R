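#' Effective sample size of an MCMC series
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with empirical autocorrelations summed
#' up to (not including) the first nonpositive lag estimate, the truncation
#' used by common trace viewers; capped at `n`.
#'
#' @param samples numeric series of length >= 10; must not be constant.
#' @return effective sample size in `(0, n]`.
#' @export
ess <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (stats::var(samples) == 0)
    stop("constant series: autocorrelation undefined", call. = FALSE)
  rho <- stats::acf(samples, lag.max = n - 2L, plot = FALSE,
                    demean = TRUE)$acf[-1]
  npos <- which(rho <= 0)[1]
  s <- if (is.na(npos)) sum(rho) else if (npos == 1L) 0 else
    sum(rho[seq_len(npos - 1L)])
  min(n / (1 + 2 * s), n)
}

#' Convergence check over two replicate chains
#'
#' Applies the ESS >= `threshold` rule to every parameter in both
#' replicates and checks replicate agreement of node-age means to within
#' two combined Monte-Carlo standard errors. Failing reports carry a
#' recommended chain-extension factor `ceiling(threshold / min ESS)`.
#' Constant columns (e.g. a parameter fixed by the model) are skipped.
#'
#' @param trace_pair list of two `posterior_trace` data frames with
#'   identical columns.
#' @param threshold minimum acceptable ESS (200 by default).
#' @return list of class `diagnostics_report`: `ess` (matrix parameter x
#'   replicate), `agreement` (named logical for age columns), `pass`,
#'   `extension_factor`.
#' @export
check_and_extend <- function(trace_pair, threshold = 200) {
  stopifnot(is.list(trace_pair), length(trace_pair) == 2L)
  t1 <- as.data.frame(trace_pair[[1]]); t2 <- as.data.frame(trace_pair[[2]])
  if (!identical(names(t1), names(t2)))
    stop("replicate traces have different parameter schemas", call. = FALSE)
  pars <- setdiff(names(t1), c("state", "loglik", "logprior", "logpost"))
  keep <- vapply(pars, function(p)
    stats::var(t1[[p]]) > 0 && stats::var(t2[[p]]) > 0, logical(1))
  pars <- pars[keep]
  em <- cbind(rep1 = vapply(pars, function(p) ess(t1[[p]]), numeric(1)),
              rep2 = vapply(pars, function(p) ess(t2[[p]]), numeric(1)))
  rownames(em) <- pars
  age_pars <- grep("^age_", pars, value = TRUE)
  agree <- vapply(age_pars, function(p) {
    se <- sqrt(stats::var(t1[[p]]) / em[p, 1] + stats::var(t2[[p]]) / em[p, 2])
    abs(mean(t1[[p]]) - mean(t2[[p]])) <= 2 * se
  }, logical(1))
  ess_ok <- all(em >= threshold)
  pass <- ess_ok && all(agree)
  structure(list(ess = em, agreement = agree, pass = pass,
                 threshold = threshold,
                 extension_factor = if (ess_ok) 1L else
                   as.integer(ceiling(threshold / min(em)))),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("Convergence diagnostics: %s (min ESS %.0f, threshold %g)\n",
              if (x$pass) "PASS" else "FAIL", min(x$ess), x$threshold))
  if (!x$pass)
    cat(sprintf("  recommended chain extension factor: %d\n",
                x$extension_factor))
  invisible(x)
}

#' Write a diagnostics report as TSV
#' @param report a `diagnostics_report`.
#' @param path file path.
#' @export
write_diagnostics <- function(report, path) {
  df <- data.frame(parameter = rownames(report$ess),
                   ess_rep1 = report$ess[, 1], ess_rep2 = report$ess[, 2])
  df$agreement <- NA
  df$agreement[match(names(report$agreement), df$parameter)] <-
    report$agreement
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
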