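#' GTR + discrete-gamma substitution model
#'
#' Exchangeabilities are in the order AC, AG, AT, CG, CT, GT with GT fixed
#' to 1 as the reference. The rate matrix is normalized so the mean
#' substitution rate at stationarity is 1, making branch lengths expected
#' substitutions per site. Among-site rate variation uses a discrete gamma
#' with `n_categories` equal-probability categories (6 by default).
#'
#' @param exchangeabilities 6 positive reals (AC, AG, AT, CG, CT, GT).
#' @param base_freqs 4 nonnegative reals summing to 1 (A, C, G, T).
#' @param gamma_shape positive shape of the gamma rate distribution.
#' @param n_categories number of discrete gamma categories.
#' @return object of class `subst_model`.
#' @export
substitution_model <- function(exchangeabilities = rep(1, 6),
                               base_freqs = rep(0.25, 4),
                               gamma_shape = 1,
                               n_categories = 6L) {
  stopifnot(length(exchangeabilities) == 6, all(exchangeabilities > 0),
            length(base_freqs) == 4, gamma_shape > 0, n_categories >= 1)
  if (any(base_freqs <= 0))
    stop("base frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(base_freqs) - 1) > 1e-8)
    stop("base frequencies must sum to 1", call. = FALSE)
  exchangeabilities <- exchangeabilities / exchangeabilities[6]  # GT == 1
  structure(list(exch = as.numeric(exchangeabilities),
                 freqs = as.numeric(base_freqs),
                 gamma_shape = as.numeric(gamma_shape),
                 n_categories = as.integer(n_categories)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("GTR+G%d model; shape %.3g; freqs %s\n", x$n_categories,
              x$gamma_shape, paste(signif(x$freqs, 3), collapse = " ")))
  invisible(x)
}

#' Normalized GTR rate matrix
#'
#' @param model a [substitution_model()].
#' @return 4x4 matrix Q with rows summing to 0 and mean rate 1.
#' @export
gtr_rate_matrix <- function(model) {
  s <- model$exch
  pi <- model$freqs
  R <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  R[1, 2] <- R[2, 1] <- s[1]  # AC
  R[1, 3] <- R[3, 1] <- s[2]  # AG
  R[1, 4] <- R[4, 1] <- s[3]  # AT
  R[2, 3] <- R[3, 2] <- s[4]  # CG
  R[2, 4] <- R[4, 2] <- s[5]  # CT
  R[3, 4] <- R[4, 3] <- s[6]  # GT
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

#' GTR transition probability matrix
#'
#' `P = exp(Q t)` computed through the eigendecomposition of the
#' similarity-transformed (symmetric) rate matrix.
#'
#' @param model a [substitution_model()].
#' @param branch_length expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix.
#' @export
gtr_transition_matrix <- function(model, branch_length) {
  stopifnot(branch_length >= 0)
  Q <- gtr_rate_matrix(model)
  pi <- model$freqs
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * branch_length)) %*%
    t(e$vectors) %*% diag(sq)
  dimnames(P) <- dimnames(Q)
  P
}

#' Discrete-gamma category rates
#'
#' Mean rates of `k` equal-probability categories of a Gamma(shape, shape)
#' distribution (mean 1), the standard discretization for among-site rate
#' variation.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return numeric vector of length `k` with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  p <- stats::pgamma(b, shape = shape + 1, rate = shape)
  k * diff(p)
}

# map IUPAC symbol -> 4-bit state mask (A=1, C=2, G=4, T=8)
iupac_mask <- function(sym) {
  tab <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
           R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
           B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, "-" = 15L)
  out <- tab[sym]
  if (anyNA(out)) stop("unknown symbol: ",
                       paste(unique(sym[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  unname(out)
}
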