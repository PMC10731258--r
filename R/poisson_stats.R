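#' Poisson occupancy probability for droplet encapsulation
#'
#' Probability that a droplet contains exactly `k` particles when particles
#' are Poisson-distributed across droplets with mean occupancy `lambda`
#' (the familiar digital-assay encapsulation model).
#'
#' @param lambda Mean number of particles per droplet (dimensionless, >= 0).
#' @param k Particle count (non-negative integer); vectorised.
#' @return Numeric vector of probabilities \eqn{e^{-\lambda}\lambda^k / k!}.
#' @examples
#' occupancy_pmf(0.08, 0)   # fraction of empty droplets at mean load 0.08
#' occupancy_pmf(2, 0:5)
#' @export
occupancy_pmf <- function(lambda, k) {
  stopifnot(is.numeric(lambda), is.numeric(k))
  if (any(lambda < 0)) stop("`lambda` must be non-negative.", call. = FALSE)
  if (any(k < 0) || any(k != floor(k))) {
    stop("`k` must be a non-negative integer.", call. = FALSE)
  }
  stats::dpois(k, lambda)
}

#' Probability that an occupied droplet holds a single particle
#'
#' Conditional Poisson probability \eqn{P(K = 1 \mid K \ge 1) =
#' \lambda e^{-\lambda} / (1 - e^{-\lambda})}. This is the "purity" of single
#' encapsulation: at low mean occupancy nearly every occupied droplet holds
#' exactly one particle, which is what makes limiting-dilution droplet
#' isolation clonal.
#'
#' As `lambda` tends to 0 the value tends to 1; the limit itself is not
#' returned because the conditioning event has probability 0 there.
#'
#' @param lambda Mean number of particles per droplet (> 0).
#' @return Probability in (0, 1).
#' @examples
#' prob_single_given_occupied(0.08)  # ~0.96: occupied droplets are clonal
#' @export
prob_single_given_occupied <- function(lambda) {
  stopifnot(is.numeric(lambda))
  if (any(lambda <= 0)) {
    stop("`lambda` must be strictly positive (the limit at 0 is 1).",
         call. = FALSE)
  }
  lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Expected empty-droplet fraction
#'
#' Convenience inverse of [lambda_from_negative_fraction()]:
#' \eqn{p_0 = e^{-\lambda}}.
#'
#' @param lambda Mean particles per droplet (>= 0).
#' @return Probability that a droplet is empty.
#' @export
p_empty <- function(lambda) {
  occupancy_pmf(lambda, rep(0L, length(lambda)))
}

#' Estimate mean occupancy from the negative-droplet fraction
#'
#' Inverts the Poisson zero-class probability: if a fraction `p0_hat` of
#' droplets shows no signal after cultivation, the mean phage load per
#' droplet at encapsulation is \eqn{\hat\lambda = -\ln \hat p_0}. The 95%
#' confidence interval is obtained by computing a binomial interval for the
#' negative fraction and pushing both bounds through \eqn{-\ln(\cdot)}.
#'
#' The default binomial interval is the Wilson score interval, which remains
#' well behaved as \eqn{p_0 \to 1} (the low-occupancy regime these assays
#' are run in); the exact Clopper-Pearson interval is available via
#' `ci_method`.
#'
#' @param p0_hat Observed fraction of negative (non-fluorescent) droplets,
#'   in (0, 1]. A value of 0 is rejected: with every droplet occupied the
#'   estimator diverges and the sample must be diluted.
#' @param n_droplets Number of droplets the fraction was measured on.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A one-row tibble of class `occupancy_estimate` with columns
#'   `lambda_hat`, `method`, `ci_low`, `ci_high`, `p0_hat`, `n_droplets`.
#' @examples
#' lambda_from_negative_fraction(exp(-0.2), n_droplets = 40000)
#' @export
lambda_from_negative_fraction <- function(p0_hat, n_droplets,
                                          conf_level = 0.95,
                                          ci_method = c("wilson",
                                                        "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.numeric(p0_hat), length(p0_hat) == 1,
            is.numeric(n_droplets), length(n_droplets) == 1,
            n_droplets >= 1)
  if (p0_hat <= 0) {
    stop("All droplets are occupied (p0 = 0): lambda is unbounded. ",
         "Dilute the sample and re-measure.", call. = FALSE)
  }
  if (p0_hat > 1) stop("`p0_hat` must lie in (0, 1].", call. = FALSE)

  x <- round(p0_hat * n_droplets)
  ci_p0 <- binom_interval(x, n_droplets, conf_level, ci_method)
  new_occupancy_estimate(
    lambda_hat = -log(p0_hat),
    method     = "from_negative_fraction",
    # p0 and lambda are inversely related, so the bounds swap
    ci_low     = -log(ci_p0[["upper"]]),
    ci_high    = if (ci_p0[["lower"]] > 0) -log(ci_p0[["lower"]]) else Inf,
    p0_hat     = p0_hat,
    n_droplets = as.integer(n_droplets)
  )
}

#' Estimate mean occupancy from titer and droplet volume
#'
#' Converts an independently measured phage concentration into the mean
#' number of particles per droplet: \eqn{\hat\lambda = c \times V} with the
#' concentration in PFU/mL and the droplet volume in pL (1 pL =
#' \eqn{10^{-9}} mL). If a standard error for the titer is supplied a normal
#' interval on the concentration is propagated through the (linear) product;
#' otherwise the interval collapses onto the point estimate.
#'
#' @param conc_pfu_per_ml Phage concentration of the aqueous phase (PFU/mL,
#'   >= 0).
#' @param geometry A [droplet_geometry()], or a single droplet volume in pL.
#' @param titer_se Optional standard error of `conc_pfu_per_ml`.
#' @param conf_level Confidence level when `titer_se` is given.
#' @return A one-row `occupancy_estimate` tibble (see
#'   [lambda_from_negative_fraction()]).
#' @examples
#' lambda_from_concentration(5.32e7, droplet_geometry(volume_pL = 18.8))
#' @export
lambda_from_concentration <- function(conc_pfu_per_ml, geometry,
                                      titer_se = NULL, conf_level = 0.95) {
  stopifnot(is.numeric(conc_pfu_per_ml), length(conc_pfu_per_ml) == 1)
  if (conc_pfu_per_ml < 0) {
    stop("`conc_pfu_per_ml` must be non-negative.", call. = FALSE)
  }
  if (is.numeric(geometry) && length(geometry) == 1) {
    geometry <- droplet_geometry(volume_pL = geometry)
  }
  v <- geometry$volume_pL
  if (!is.numeric(v) || v <= 0) {
    stop("Droplet volume must be positive.", call. = FALSE)
  }
  lam <- conc_pfu_per_ml * v * 1e-9
  if (is.null(titer_se)) {
    lo <- hi <- lam
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- max(0, (conc_pfu_per_ml - z * titer_se)) * v * 1e-9
    hi <- (conc_pfu_per_ml + z * titer_se) * v * 1e-9
  }
  new_occupancy_estimate(
    lambda_hat = lam, method = "from_concentration",
    ci_low = lo, ci_high = hi, p0_hat = NA_real_, n_droplets = NA_integer_
  )
}

#' Droplet geometry: diameter and volume
#'
#' Holds the diameter/volume convention used to convert titers into per-
#' droplet occupancies. Supply either the diameter (the volume is filled in
#' by the sphere formula) or the volume directly. Droplet generators in this
#' class produce ~30 um droplets; note that a 30 um sphere holds 14.1 pL
#' while downstream calculations in the assay literature often quote an
#' effective volume of 18.8 pL (a ~33 um sphere) — both conventions are
#' representable here and neither silently overrides the other.
#'
#' @param diameter_um Droplet diameter in micrometres (> 0), optional.
#' @param volume_pL Droplet volume in picolitres (> 0), optional.
#' @return A list of class `droplet_geometry` with `diameter_um` and
#'   `volume_pL`.
#' @examples
#' droplet_geometry(diameter_um = 30)
#' droplet_geometry(volume_pL = 18.8)
#' @export
droplet_geometry <- function(diameter_um = NULL, volume_pL = NULL) {
  if (is.null(diameter_um) && is.null(volume_pL)) {
    stop("Supply `diameter_um` or `volume_pL`.", call. = FALSE)
  }
  if (!is.null(diameter_um)) {
    stopifnot(is.numeric(diameter_um), length(diameter_um) == 1)
    if (diameter_um <= 0) stop("`diameter_um` must be positive.", call. = FALSE)
    v_from_d <- volume_from_diameter(diameter_um)
    if (is.null(volume_pL)) {
      volume_pL <- v_from_d
    } else if (abs(volume_pL - v_from_d) > 1e-6 * v_from_d) {
      warning("Supplied volume_pL does not match the sphere volume of the ",
              "supplied diameter; keeping both as given.", call. = FALSE)
    }
  }
  stopifnot(is.numeric(volume_pL), length(volume_pL) == 1)
  if (volume_pL <= 0) stop("`volume_pL` must be positive.", call. = FALSE)
  structure(list(diameter_um = diameter_um, volume_pL = volume_pL),
            class = "droplet_geometry")
}

#' Sphere volume of a droplet from its diameter
#'
#' \eqn{V = (\pi/6) d^3}, converted from cubic micrometres to picolitres
#' (1 um^3 = 1e-3 pL).
#'
#' @param diameter_um Droplet diameter in micrometres (> 0); vectorised.
#' @return Volume in picolitres.
#' @examples
#' volume_from_diameter(30)    # 14.14 pL
#' volume_from_diameter(33.05) # ~18.9 pL
#' @export
volume_from_diameter <- function(diameter_um) {
  stopifnot(is.numeric(diameter_um))
  if (any(diameter_um <= 0)) {
    stop("`diameter_um` must be positive.", call. = FALSE)
  }
  (pi / 6) * diameter_um^3 * 1e-3
}

# --- internal -----------------------------------------------------------

new_occupancy_estimate <- function(lambda_hat, method, ci_low, ci_high,
                                   p0_hat, n_droplets) {
  out <- tibble::tibble(
    lambda_hat = lambda_hat, method = method,
    ci_low = ci_low, ci_high = ci_high,
    p0_hat = p0_hat, n_droplets = n_droplets
  )
  class(out) <- c("occupancy_estimate", class(out))
  out
}

# Binomial interval for x successes in n trials. Wilson score by default;
# Clopper-Pearson (beta quantile form) as the exact option.
binom_interval <- function(x, n, conf_level = 0.95,
                           method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
    # the score interval cannot exclude the boundary when it is observed
    if (x == 0) lower <- 0
    if (x == n) upper <- 1
  } else {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  }
  c(lower = lower, upper = upper)
}
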