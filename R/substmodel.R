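#' Reversible nucleotide substitution models by rate-grouping code
#'
#' The model space is indexed by six-digit codes giving, in alphabetical
#' order of the unordered pairs (A-C, A-G, A-T, C-G, C-T, G-T), the rate
#' group of each exchangeability.  Codes are kept in canonical
#' restricted-growth form: the first digit is 1 and every digit is at most
#' one more than the maximum of the preceding digits.  `121121` is HKY
#' (transitions share one group, transversions another), `111111` is
#' JC69/F81, `123456` is GTR/SYM.
#'
#' @name model_codes
NULL

## positions of the two transitions among the six alphabetical pairs
TRANSITION_POS <- c(2L, 5L)   # A-G, C-T
TRANSVERSION_POS <- c(1L, 3L, 4L, 6L)

#' Canonicalize a six-digit rate grouping
#'
#' Group labels are relabeled by order of first appearance, giving the
#' restricted-growth representative of the partition.  Idempotent.
#'
#' @param grouping integer vector of 6 positive group ids, or a 6-character
#'   digit string
#' @return 6-character code string
#' @export
canonical_code <- function(grouping) {
  if (is.character(grouping) && length(grouping) == 1L)
    grouping <- as.integer(strsplit(grouping, "")[[1]])
  grouping <- as.integer(grouping)
  if (length(grouping) != 6L || any(is.na(grouping)) || any(grouping < 1L))
    stop("grouping must be 6 positive integers")
  first <- unique(grouping)
  paste(match(grouping, first), collapse = "")
}

code_groups <- function(code) as.integer(strsplit(code, "")[[1]])

#' Enumerate the substitution-model space
#'
#' `all_reversible` is every set partition of the six rates in canonical
#' form (203 models).  `no_ti_tv_sharing` keeps only partitions in which no
#' group mixes a transition with a transversion, re-admitting `111111`
#' (JC69/F81) as the customary exception.
#'
#' @param restriction `"all_reversible"` or `"no_ti_tv_sharing"`
#' @return character vector of canonical codes, lexicographically sorted
#' @export
enumerate_model_set <- function(restriction = c("all_reversible",
                                                "no_ti_tv_sharing")) {
  restriction <- match.arg(restriction)
  codes <- character(0)
  rec <- function(digits) {
    if (length(digits) == 6L) {
      codes[[length(codes) + 1L]] <<- paste(digits, collapse = "")
      return(invisible())
    }
    for (d in seq_len(max(digits) + 1L)) rec(c(digits, d))
  }
  rec(1L)
  if (restriction == "no_ti_tv_sharing") {
    ok <- vapply(codes, function(cd) {
      g <- code_groups(cd)
      !any(g[TRANSITION_POS] %in% g[TRANSVERSION_POS])
    }, logical(1))
    codes <- sort(unique(c(codes[ok], "111111")))
  }
  sort(codes)
}

#' Construct a site model
#'
#' Bundles the substitution model code with its free parameters, base
#' frequencies, discrete-gamma rate heterogeneity and a proportion of
#' invariable sites, mirroring the three model indicators (frequency
#' equality, gamma on/off, invariant proportion on/off) that are averaged
#' over during reversible-jump MCMC.
#'
#' @param code canonical 6-digit code (string or integer vector)
#' @param group_rates positive rates, one per distinct group in `code`
#' @param base_freqs 4 positive frequencies summing to 1 (A,C,G,T)
#' @param freqs_equal force equal frequencies (overrides `base_freqs`)
#' @param gamma_shape positive shape of the gamma rate mixture
#' @param use_gamma enable gamma heterogeneity
#' @param n_categories number of discrete gamma categories
#' @param p_inv proportion of invariable sites in [0, 1)
#' @param use_inv enable the invariable-site class
#' @return object of class `site_model`
#' @export
site_model <- function(code = "111111", group_rates = NULL,
                       base_freqs = rep(0.25, 4), freqs_equal = FALSE,
                       gamma_shape = 1, use_gamma = FALSE, n_categories = 4L,
                       p_inv = 0, use_inv = FALSE) {
  code <- canonical_code(code)
  k <- max(code_groups(code))
  if (is.null(group_rates)) group_rates <- rep(1, k)
  if (length(group_rates) != k || any(group_rates <= 0))
    stop("need ", k, " positive group rates for code ", code)
  if (freqs_equal) base_freqs <- rep(0.25, 4)
  if (length(base_freqs) != 4 || any(base_freqs <= 0))
    stop("base_freqs must be 4 positive numbers")
  base_freqs <- base_freqs / sum(base_freqs)
  if (!use_gamma) n_categories <- 1L
  if (!use_inv) p_inv <- 0
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  structure(list(code = code, group_rates = as.numeric(group_rates),
                 base_freqs = base_freqs, freqs_equal = freqs_equal,
                 gamma_shape = gamma_shape, use_gamma = use_gamma,
                 n_categories = as.integer(n_categories),
                 p_inv = p_inv, use_inv = use_inv),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("site_model %s%s%s%s\n", x$code,
              if (x$freqs_equal) "" else "+F",
              if (x$use_gamma) sprintf("+G%d(shape=%.3g)", x$n_categories,
                                       x$gamma_shape) else "",
              if (x$use_inv) sprintf("+I(%.3g)", x$p_inv) else ""))
  invisible(x)
}

## unordered pair index for the six exchangeabilities, alphabetical order
PAIR_INDEX <- matrix(0L, 4, 4)
PAIR_INDEX[1, 2] <- PAIR_INDEX[2, 1] <- 1L  # A-C
PAIR_INDEX[1, 3] <- PAIR_INDEX[3, 1] <- 2L  # A-G
PAIR_INDEX[1, 4] <- PAIR_INDEX[4, 1] <- 3L  # A-T
PAIR_INDEX[2, 3] <- PAIR_INDEX[3, 2] <- 4L  # C-G
PAIR_INDEX[2, 4] <- PAIR_INDEX[4, 2] <- 5L  # C-T
PAIR_INDEX[3, 4] <- PAIR_INDEX[4, 3] <- 6L  # G-T

#' Build the normalized reversible rate matrix
#'
#' Off-diagonals are `Q[i,j] = r[i,j] * pi[j]` with `r` the shared group rate
#' of the unordered pair; rows sum to zero and the matrix is scaled so the
#' expected substitution rate at equilibrium, `-sum(pi * diag(Q))`, is 1.
#'
#' @param model a `site_model`
#' @return list with the 4x4 generator `Q` and frequencies `pi`
#' @export
build_rate_matrix <- function(model) {
  g <- code_groups(model$code)
  rates <- model$group_rates
  if (any(rates <= 0) || any(model$base_freqs <= 0))
    stop("rates and frequencies must be positive")
  ## saturated-space semantics: the indicator wins over the stored values
  pi <- if (model$freqs_equal) rep(0.25, 4) else model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- rates[g[PAIR_INDEX[i, j]]] * pi[j]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  list(Q = Q, pi = pi)
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of the symmetrized generator
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`, which is exact for reversible models;
#' falls back to scaling-and-squaring via repeated series squaring when the
#' symmetric decomposition is numerically degenerate.
#'
#' @param rm result of [build_rate_matrix()]
#' @param t non-negative time (expected substitutions when the clock rate is
#'   folded into `t`)
#' @return 4x4 stochastic matrix
#' @export
transition_probabilities <- function(rm, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  sp <- sqrt(rm$pi)
  S <- (rm$Q * rep(sp, times = 4)) / rep(sp, each = 4)  # diag(sp) Q diag(1/sp)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  expS <- eg$vectors %*% (exp(eg$values * t) * t(eg$vectors))
  P <- expS * outer(1 / sp, sp)   # undo the similarity transform
  ## guard tiny negative entries from round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete gamma rate categories (mean-of-bin construction)
#'
#' `ncat` equal-probability categories whose rates are the conditional means
#' of a Gamma(shape, shape) distribution on each probability bin, so the
#' mixture mean is exactly 1.
#'
#' @param shape positive shape parameter
#' @param ncat number of categories (>= 1)
#' @return numeric vector of `ncat` positive rates with mean 1
#' @export
discrete_gamma_rates <- function(shape, ncat) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be positive and finite")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("ncat must be >= 1")
  if (ncat == 1L) return(1)
  ## bin mean of Gamma(a, a) between quantiles: uses the identity
  ## E[X; X<q] = P(Gamma(a+1, a) < q) for a Gamma(a, a) variable
  brk <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape, rate = shape)
  cum <- stats::pgamma(brk, shape + 1, rate = shape)
  rates <- diff(cum) * ncat
  rates / mean(rates)  # exact renormalization against quadrature round-off
}

## per-category relative rates and weights for a site model, including the
## invariable class as rate 0 when p_inv > 0
site_rate_mixture <- function(model) {
  rates <- if (model$use_gamma)
    discrete_gamma_rates(model$gamma_shape, model$n_categories) else 1
  pinv <- if (model$use_inv) model$p_inv else 0
  w <- rep(1 / length(rates), length(rates))
  list(rates = rates, weights = w * (1 - pinv), p_inv = pinv)
}
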