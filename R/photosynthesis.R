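#' Light-response parameter set (Ye model)
#'
#' Parameters of the net photosynthesis light-response curve
#' `A(Q) = alpha * (1 - beta*Q) / (1 + gamma*Q) * Q - Rd`: the initial
#' slope `alpha` (umol CO2 per umol photons), the photoinhibition
#' coefficient `beta` and saturation coefficient `gamma` (both
#' dimensionless per unit PPFD), and the dark respiration rate `Rd`
#' (umol m-2 s-1).
#'
#' @param alpha initial slope, > 0.
#' @param beta photoinhibition coefficient, >= 0.
#' @param gamma saturation coefficient, > 0.
#' @param Rd dark respiration rate, >= 0.
#' @param layer canopy layer label (`"upper"`, `"ear"`, `"lower"`) or NA.
#' @param cultivar cultivar label or NA.
#' @return object of class `light_response_params`.
#' @export
light_response_params <- function(alpha, beta, gamma, Rd,
                                  layer = NA_character_,
                                  cultivar = NA_character_) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (Rd < 0) stop("Rd must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, Rd = Rd,
                 layer = layer, cultivar = cultivar),
            class = "light_response_params")
}

#' @export
print.light_response_params <- function(x, ...) {
  cat(sprintf(
    "light_response_params [%s %s]: alpha=%.4g beta=%.3g gamma=%.3g Rd=%.3g Amax=%.4g\n",
    x$cultivar, x$layer, x$alpha, x$beta, x$gamma, x$Rd, amax(x)))
  invisible(x)
}

#' Net photosynthesis rate at a given PPFD (Ye model)
#'
#' `A = alpha * (1 - beta*Q) * Q / (1 + gamma*Q) - Rd`. Negative values
#' (respiration-dominated) are valid; at `Q = 0` the rate is `-Rd`.
#'
#' @param params a [light_response_params()] (or list with alpha, beta,
#'   gamma, Rd).
#' @param ppfd incident PPFD, umol m-2 s-1 (vectorized, >= 0).
#' @return net photosynthesis, umol CO2 m-2 s-1.
#' @export
net_photosynthesis <- function(params, ppfd) {
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  params$alpha * (1 - params$beta * ppfd) / (1 + params$gamma * ppfd) *
    ppfd - params$Rd
}

#' Light-saturated maximum net photosynthesis rate
#'
#' Closed form of the Ye-model maximum:
#' `Amax = alpha * ((sqrt(beta + gamma) - sqrt(beta)) / gamma)^2 - Rd`,
#' attained at `Qopt = (sqrt((beta + gamma) / beta) - 1) / gamma` when
#' `beta > 0`; as `beta -> 0` it tends to the saturation asymptote
#' `alpha / gamma - Rd`.
#'
#' @inheritParams net_photosynthesis
#' @return `Amax`, umol m-2 s-1.
#' @export
amax <- function(params) {
  if (params$gamma <= 0)
    stop("gamma must be > 0: the unsaturated linear model has no maximum")
  with(params, alpha * ((sqrt(beta + gamma) - sqrt(beta)) / gamma)^2 - Rd)
}

#' PPFD at which the Ye model attains its maximum
#'
#' @inheritParams net_photosynthesis
#' @return optimum PPFD, umol m-2 s-1 (`Inf` when `beta = 0`).
#' @export
optimum_ppfd <- function(params) {
  if (params$gamma <= 0) stop("gamma must be > 0")
  if (params$beta <= 0) return(Inf)
  with(params, (sqrt((beta + gamma) / beta) - 1) / gamma)
}

#' Solve beta and gamma from a printed (alpha, Amax, Rd) triple
#'
#' Light-response tables usually print only alpha, Amax and Rd. Fixing a
#' small photoinhibition coefficient `beta`, the saturation coefficient
#' `gamma` is recovered by inverting the closed-form maximum (monotone in
#' gamma, solved by bisection).
#'
#' @param alpha,Amax,Rd printed values.
#' @param beta fixed photoinhibition coefficient (default 5e-5).
#' @return a [light_response_params()] whose [amax()] equals `Amax`.
#' @export
solve_beta_gamma <- function(alpha, Amax, Rd, beta = 5e-5) {
  target <- Amax + Rd
  # the closed-form maximum tends to alpha/(4*beta) as gamma -> 0
  if (target <= 0 || target >= alpha / (4 * beta))
    stop("inconsistent (alpha, Amax, Rd) triple for fixed beta")
  f <- function(g) alpha * ((sqrt(beta + g) - sqrt(beta)) / g)^2 - target
  g <- stats::uniroot(f, c(1e-8, 1), tol = 1e-14)$root
  light_response_params(alpha, beta, g, Rd)
}

#' PPFD levels of the standard A-Q measurement protocol
#'
#' @return the 12 chamber PPFD set points, umol m-2 s-1.
#' @export
aq_ppfd_levels <- function() {
  c(2000, 1800, 1500, 1200, 1000, 750, 500, 250, 150, 100, 50, 0)
}

#' Fit the Ye light-response model to A-Q measurements
#'
#' Bounded Levenberg-Marquardt least squares (via `minpack.lm::nlsLM`)
#' minimising the squared residuals of the Ye model, restarted from 8
#' initial parameter points; the best converged fit is returned with R^2
#' against the observations.
#'
#' @param data data.frame with columns `ppfd` and `A` (>= 5 distinct PPFD
#'   levels including 0).
#' @param n_starts number of multistart initial points (default 8).
#' @return list: `params` ([light_response_params()]), `Amax`, `r_squared`,
#'   `residuals`, `rss`, `converged`.
#' @export
fit_light_response <- function(data, n_starts = 8L) {
  stopifnot(all(c("ppfd", "A") %in% names(data)))
  lv <- unique(data$ppfd)
  if (length(lv) < 5 || !any(lv == 0))
    stop("need >= 5 distinct PPFD levels including 0")
  if (stats::sd(data$A) < 1e-12) stop("degenerate data: constant A")
  lower <- c(alpha = 1e-4, beta = 0, gamma = 1e-5, Rd = 0)
  upper <- c(alpha = 0.15, beta = 1e-2, gamma = 0.1, Rd = 10)
  rd0 <- max(0, -mean(data$A[data$ppfd == 0]))
  a0 <- {
    lo <- data$ppfd > 0 & data$ppfd <= 300
    if (any(lo)) max(1e-3, mean((data$A[lo] + rd0) / data$ppfd[lo]))
    else 0.05
  }
  amax0 <- max(data$A)
  g0 <- max(2e-4, a0 / max(amax0 + rd0, 1) - 1e-5)
  # deterministic multistart layout without disturbing the caller's RNG
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  set.seed(7L)
  starts <- list(c(a0, 5e-5, g0, rd0))
  for (k in seq_len(n_starts - 1L)) {
    starts[[k + 1L]] <- c(a0 * stats::runif(1, 0.5, 1.8),
                          stats::runif(1, 0, 5e-4),
                          g0 * stats::runif(1, 0.3, 3),
                          max(0.05, rd0 * stats::runif(1, 0.5, 1.8)))
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-8), upper - 1e-8)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ alpha * (1 - beta * ppfd) / (1 + gamma * ppfd) * ppfd - Rd,
        data = data,
        start = list(alpha = s[1], beta = s[2], gamma = s[3], Rd = s[4]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("fit_light_response: no start converged")
  cf <- stats::coef(best$fit)
  pars <- light_response_params(cf[["alpha"]], cf[["beta"]], cf[["gamma"]],
                                cf[["Rd"]])
  r2 <- 1 - best$rss / sum((data$A - mean(data$A))^2)
  list(params = pars, Amax = amax(pars), r_squared = r2,
       residuals = stats::resid(best$fit), rss = best$rss, converged = TRUE)
}
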