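#' Gamma scale making the expected within-group distance constant
#'
#' For the gamma-mixture scenario of the normal simulator, the per-sample
#' dispersion is \eqn{v_i \sim Gamma(\alpha, \kappa)} (shape/scale) and the
#' expected Euclidean distance between two samples of the same group is
#' proportional to \eqn{E\sqrt{v_i + v_j}}. Using \eqn{E\sqrt{X} =
#' \sqrt{\kappa}\,\Gamma(a + 1/2)/\Gamma(a)} for \eqn{X \sim Gamma(a,
#' \kappa)} and \eqn{v_i + v_j \sim Gamma(2\alpha, \kappa)}, the choice
#'
#' \deqn{\kappa = \left(\frac{\Gamma(2\alpha + 1/2)}{\Gamma(2\alpha)}\right)^{-2}}
#'
#' makes \eqn{E\sqrt{v_i + v_j} = 1} for every \eqn{\alpha}, so the expected
#' within-group distance is the same in all groups even when \eqn{\alpha}
#' (hence the shape of the dispersion distribution) differs. Tests that only
#' compare mean dispersion should then have negligible power, while tests
#' that compare the full dispersion distribution retain power.
#'
#' @param alpha gamma shape, \eqn{> 0}.
#' @return the gamma scale \eqn{\kappa}.
#' @examples
#' gamma_kappa(0.25)  # (Gamma(1)/Gamma(0.5))^-2 = pi
#' @export
gamma_kappa <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("'alpha' must be > 0")
  exp(-2 * (lgamma(2 * alpha + 0.5) - lgamma(2 * alpha)))
}

# Table of mixing-distribution parameters for the normal scale-mixture
# scenarios. theta = 0 collapses every scenario to identical groups.
# Non-null groups sit in slots (2) for G=2, (2,3) for G=3 and (3,5) for G=5,
# following the common pattern of all scenario rows. S1 keeps
# mu_g + sigma_g^2/2 = 3/2 so E(v_i) is constant across groups; S0 uses
# gamma_kappa() so the expected within-group distance is constant.
normal_scenario_params <- function(scenario, G, theta) {
  stopifnot(theta >= 0)
  bad <- function() stop("unknown scenario/G combination: ", scenario, ", G = ", G)
  if (!G %in% c(2L, 3L, 5L)) bad()
  par <- switch(scenario,
    S0 = {
      alpha <- switch(as.character(G),
        "2" = c(1, 1 + 3 * theta),
        "3" = c(1, 1 + 6 * theta, 1 + 3 * theta),
        "5" = c(1, 1, 1 + 6 * theta, 1, 1 + 3 * theta))
      list(kind = "gamma", alpha = alpha, kappa = gamma_kappa(alpha))
    },
    S1 = {
      mu <- switch(as.character(G),
        "2" = c(1, 1 - theta),
        "3" = c(1, 1 - theta / 2, 1 - theta),
        "5" = c(1, 1, 1 - theta / 2, 1, 1 - theta))
      list(kind = "lognormal", mu = mu, sigma2 = 3 - 2 * mu)
    },
    S2 = {
      sigma2 <- switch(as.character(G),
        "2" = c(1, 1 + 2 * theta),
        "3" = c(1, 1 + theta, 1 + 2 * theta),
        "5" = c(1, 1, 1 + theta, 1, 1 + 2 * theta))
      list(kind = "lognormal", mu = rep(1, G), sigma2 = sigma2)
    },
    S3 = {
      v <- switch(as.character(G),
        "2" = c(1, exp(theta / 80)),
        "3" = c(1, exp(theta / 40), exp(theta / 80)),
        "5" = c(1, 1, exp(theta / 40), 1, exp(theta / 80)))
      list(kind = "fixed", v = v)
    },
    bad())
  par
}

# Negative-binomial scenario parameters: the per-sample size parameter r is
# inverse-gamma (S1: alpha/beta vary jointly with alpha = beta so the mean
# dispersion E(1/r) = alpha/beta stays 1; S2: alpha fixed, beta varies so
# mean dispersion varies) or deterministic (S3). Same slot pattern as the
# normal scenarios.
negbin_scenario_params <- function(scenario, G, theta) {
  stopifnot(theta >= 0)
  bad <- function() stop("unknown scenario/G combination: ", scenario, ", G = ", G)
  if (!G %in% c(2L, 3L, 5L)) bad()
  switch(scenario,
    S1 = {
      alpha <- 5 * switch(as.character(G),
        "2" = c(1, exp(-theta)),
        "3" = c(1, exp(-theta / 2), exp(-theta)),
        "5" = c(1, 1, exp(-theta / 2), 1, exp(-theta)))
      list(kind = "invgamma", alpha = alpha, beta = alpha)
    },
    S2 = {
      beta <- 5 * switch(as.character(G),
        "2" = c(1, exp(-theta / 10)),
        "3" = c(1, exp(-theta / 20), exp(-theta / 10)),
        "5" = c(1, 1, exp(-theta / 20), 1, exp(-theta / 10)))
      list(kind = "invgamma", alpha = rep(3, G), beta = beta)
    },
    S3 = {
      r <- switch(as.character(G),
        "2" = c(1, exp(theta / 30)),
        "3" = c(1, exp(theta / 60), exp(theta / 30)),
        "5" = c(1, 1, exp(theta / 60), 1, exp(theta / 30)))
      list(kind = "fixed", r = r)
    },
    bad())
}

split_sizes <- function(n, G) {
  base <- n %/% G
  sizes <- rep(base, G)
  extra <- n - base * G
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

#' Simulate multivariate normal scale mixtures with group-specific dispersion
#'
#' Generates `n` samples in `G` groups: each sample draws a dispersion
#' \eqn{v_i} from its group's mixing distribution, then a d-dimensional
#' vector \eqn{Y_i \sim N_d(0, v_i I_d)}. Group means are identical, so any
#' difference between groups lies purely in the dispersion distribution.
#' Scenarios:
#'
#' * `S0`: \eqn{v_i \sim Gamma(\alpha_g, \kappa_g)} with \eqn{\kappa_g =}
#'   [gamma_kappa()]`(`\eqn{\alpha_g}`)`, keeping the expected within-group
#'   distance constant across groups.
#' * `S1`: \eqn{v_i} log-normal with \eqn{\mu_g + \sigma_g^2/2 = 3/2}, so the
#'   mean dispersion \eqn{E(v_i) = e^{3/2}} is constant but its distribution
#'   differs.
#' * `S2`: log-normal with common \eqn{\mu} and group-varying
#'   \eqn{\sigma_g^2}, so mean dispersion differs (the classical setting).
#' * `S3`: deterministic \eqn{v_g} per group (a pure scale shift).
#'
#' `theta = 0` collapses every scenario to identical groups (the null).
#'
#' @param scenario one of `"S0"`, `"S1"`, `"S2"`, `"S3"`.
#' @param G number of groups: 2, 3 or 5.
#' @param theta deviation from the null, \eqn{\ge 0}; defaults 0. The study
#'   grid uses \eqn{0, 0.5, \ldots, 2}.
#' @param n total sample size, split as evenly as possible (default 150).
#' @param d dimension (default 500).
#' @param group_sizes optional explicit per-group sizes overriding the even
#'   split.
#' @param seed optional integer seed.
#' @return list with `table` (an `n x d` matrix), `group` (factor), and
#'   `dispersions` (the drawn \eqn{v_i}).
#' @export
simulate_normal <- function(scenario = c("S0", "S1", "S2", "S3"), G = 2,
                            theta = 0, n = 150, d = 500,
                            group_sizes = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  G <- as.integer(G)
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (is.null(group_sizes)) split_sizes(n, G) else as.integer(group_sizes)
  if (length(sizes) != G || any(sizes < 2L)) stop("need G group sizes, all >= 2")
  n <- sum(sizes)
  par <- normal_scenario_params(scenario, G, theta)
  group <- factor(rep(paste0("g", seq_len(G)), sizes))
  v <- numeric(n)
  for (g in seq_len(G)) {
    idx <- which(as.integer(group) == g)
    v[idx] <- switch(par$kind,
      gamma     = rgamma(length(idx), shape = par$alpha[g], scale = par$kappa[g]),
      lognormal = rlnorm(length(idx), meanlog = par$mu[g],
                         sdlog = sqrt(par$sigma2[g])),
      fixed     = par$v[g])
  }
  y <- matrix(rnorm(n * d, mean = 0, sd = sqrt(v)), nrow = n, ncol = d)
  rownames(y) <- paste0("sample", seq_len(n))
  colnames(y) <- paste0("f", seq_len(d))
  list(table = y, group = group, dispersions = v)
}

#' Simulate negative-binomial count data with group-specific overdispersion
#'
#' Generates microbiome-like count tables: for sample \eqn{i} in group
#' \eqn{g}, a size parameter \eqn{r_i} is drawn (scenarios `S1`/`S2`:
#' \eqn{r_i \sim InvGamma(\alpha_g, \beta_g)}, i.e. \eqn{1/r_i \sim
#' Gamma(\alpha_g, rate = \beta_g)} with mean dispersion \eqn{E(1/r_i) =
#' \alpha_g/\beta_g}; `S3`: \eqn{r_i = r_g} fixed), then `d` independent
#' counts \eqn{Y_{ij} \sim NB} with \eqn{E(Y_{ij} | r_i) = \mu} and
#' \eqn{Var(Y_{ij} | r_i) = \mu + \mu^2 / r_i} (success probability
#' \eqn{p = r/(\mu + r)}). The mean \eqn{\mu} is constant across groups so
#' only the dispersion differs; unconditionally \eqn{Var(Y_{ij}) = \mu +
#' \mu^2 \alpha_g/\beta_g} for the inverse-gamma scenarios.
#'
#' In `S1` \eqn{\beta_g = \alpha_g}, so the mean dispersion
#' \eqn{\alpha_g/\beta_g = 1} is constant while its distribution varies; `S2`
#' varies \eqn{\beta_g} at fixed \eqn{\alpha}, changing the mean dispersion;
#' `S3` is a deterministic dispersion shift. `theta = 0` is the null. The
#' study grid uses \eqn{\theta \in \{0, 0.5, \ldots, 3\}}.
#'
#' @param scenario one of `"S1"`, `"S2"`, `"S3"`.
#' @param mu common negative-binomial mean per feature (default 10).
#' @inheritParams simulate_normal
#' @return list with `table` (an `n x d` integer count matrix), `group`,
#'   and `size_params` (the drawn \eqn{r_i}).
#' @export
simulate_negbin <- function(scenario = c("S1", "S2", "S3"), G = 2, theta = 0,
                            n = 150, d = 500, mu = 10,
                            group_sizes = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  G <- as.integer(G)
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (is.null(group_sizes)) split_sizes(n, G) else as.integer(group_sizes)
  if (length(sizes) != G || any(sizes < 2L)) stop("need G group sizes, all >= 2")
  n <- sum(sizes)
  par <- negbin_scenario_params(scenario, G, theta)
  if (par$kind == "invgamma" && (any(par$alpha <= 0) || any(par$beta <= 0)))
    stop("inverse-gamma parameters must be positive")
  group <- factor(rep(paste0("g", seq_len(G)), sizes))
  r <- numeric(n)
  for (g in seq_len(G)) {
    idx <- which(as.integer(group) == g)
    r[idx] <- switch(par$kind,
      invgamma = 1 / rgamma(length(idx), shape = par$alpha[g], rate = par$beta[g]),
      fixed    = par$r[g])
  }
  y <- matrix(rnbinom(n * d, size = rep(r, d), mu = mu), nrow = n, ncol = d)
  rownames(y) <- paste0("sample", seq_len(n))
  colnames(y) <- paste0("taxon", seq_len(d))
  list(table = y, group = group, size_params = r)
}

#' Simulate continuous data whose dispersion follows a continuous covariate
#'
#' A generic covariate-dispersion simulator: \eqn{x_i \sim Uniform(0,1)} and
#' \eqn{Y_i \sim N_d(0, e^{s x_i} I_d)} with `dispersion_slope` \eqn{s};
#' \eqn{s = 0} is the null of no association. Combine with
#' [discretize_covariate()] and [dth_test()] to test the association.
#'
#' @param n number of samples (\eqn{\ge 6}).
#' @param d dimension.
#' @param dispersion_slope log-dispersion slope \eqn{s}.
#' @param seed optional integer seed.
#' @return list with `table` and `covariate`.
#' @export
simulate_continuous <- function(n = 150, d = 500, dispersion_slope = 0,
                                seed = NULL) {
  if (n < 6) stop("need at least 6 samples")
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n)
  v <- exp(dispersion_slope * x)
  y <- matrix(rnorm(n * d, mean = 0, sd = sqrt(v)), nrow = n, ncol = d)
  rownames(y) <- paste0("sample", seq_len(n))
  colnames(y) <- paste0("f", seq_len(d))
  list(table = y, covariate = x)
}
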