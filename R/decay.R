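# Conceptual burial model for foraminiferal DNA in the sediment column.
#
# Living benthic foraminifera inhabit the top of the core: their standing
# stock declines linearly from B_surface at 0 cm to B_bottom at the bottom of
# the inhabited zone. Planktonic eDNA arrives at the surface and decays
# exponentially with burial. Below the inhabited zone benthic DNA is purely
# environmental too and decays exponentially, at a lower rate than the
# planktonic pool because it never transited the water column. The observable
# is the planktonic fraction P/(P+B) of foraminiferal amplicons versus depth.

#' Decay-model parameters
#'
#' @param N0 initial planktonic eDNA abundance at the surface (arbitrary
#'   units).
#' @param lambda_p planktonic eDNA decay constant (per decay-coordinate
#'   unit).
#' @param tau_scale depth-to-decay-coordinate scaling (model units per cm).
#'   The decay coordinate of depth `z` is `tau_scale * z`.
#' @param B_surface living benthic abundance at 0 cm.
#' @param B_bottom living benthic abundance at the bottom of the inhabited
#'   zone.
#' @param z_inhabited depth (cm) of the bottom of the zone inhabited by
#'   living benthic foraminifera.
#' @param lambda_b benthic eDNA decay constant below the inhabited zone; must
#'   be smaller than `lambda_p`.
#' @return object of class `decay_params`.
#' @export
decay_params <- function(N0 = 1, lambda_p = 1, tau_scale = 0.02,
                         B_surface = 99, B_bottom = 1, z_inhabited = 10,
                         lambda_b = 0.9) {
  p <- structure(list(N0 = N0, lambda_p = lambda_p, tau_scale = tau_scale,
                      B_surface = B_surface, B_bottom = B_bottom,
                      z_inhabited = z_inhabited, lambda_b = lambda_b),
                 class = "decay_params")
  validate_decay_params(p)
}

validate_decay_params <- function(p) {
  stopifnot(p$N0 > 0, p$lambda_p > 0, p$tau_scale > 0,
            p$B_surface > 0, p$B_bottom > 0,
            p$B_surface > p$B_bottom,
            p$z_inhabited > 0,
            p$lambda_b > 0, p$lambda_b < p$lambda_p)
  p
}

#' Benthic foraminiferal DNA abundance at depth
#'
#' Linear decline of the living standing stock through the inhabited zone;
#' exponential decay of the residual environmental DNA below it (continuous
#' at the boundary).
#'
#' @param z depth in cm (vectorized, `z >= 0`).
#' @param params a [decay_params()] object.
#' @return abundance (arbitrary units).
#' @export
benthic_abundance <- function(z, params = decay_params()) {
  if (any(z < 0)) stop("depth must be non-negative")
  p <- params
  lin <- p$B_surface + (p$B_bottom - p$B_surface) * z / p$z_inhabited
  expo <- p$B_bottom * exp(-p$lambda_b * p$tau_scale * (z - p$z_inhabited))
  ifelse(z <= p$z_inhabited, lin, expo)
}

#' Planktonic eDNA abundance at depth
#'
#' Exponential decay `N0 * exp(-lambda_p * tau_scale * z)`.
#'
#' @inheritParams benthic_abundance
#' @return abundance (arbitrary units).
#' @export
planktonic_abundance <- function(z, params = decay_params()) {
  if (any(z < 0)) stop("depth must be non-negative")
  params$N0 * exp(-params$lambda_p * params$tau_scale * z)
}

#' Planktonic amplicon fraction profile
#'
#' @param depths sorted non-negative depths (cm).
#' @param params a [decay_params()] object.
#' @return data.frame of class `depth_profile` with columns `depth`,
#'   `planktonic`, `benthic`, `fraction`.
#' @export
fraction_profile <- function(depths, params = decay_params()) {
  if (is.unsorted(depths)) stop("depths must be sorted")
  P <- planktonic_abundance(depths, params)
  B <- benthic_abundance(depths, params)
  structure(data.frame(depth = depths, planktonic = P, benthic = B,
                       fraction = P / (P + B)),
            class = c("depth_profile", "data.frame"))
}

# Closed-form logit fraction used by the fitter: log P - log B.
logit_fraction <- function(z, lambda_p, tau_scale, params) {
  p <- params
  logB <- ifelse(z <= p$z_inhabited,
                 log(p$B_surface +
                       (p$B_bottom - p$B_surface) * z / p$z_inhabited),
                 log(p$B_bottom) -
                   p$lambda_b * tau_scale * (z - p$z_inhabited))
  log(p$N0) - lambda_p * tau_scale * z - logB
}

#' Fit decay parameters to an observed depth/fraction profile
#'
#' Least squares on the logit of the planktonic fraction, which respects the
#' (0, 1) bounds of the observable. `lambda_p` and `tau_scale` are free; the
#' remaining parameters are fixed at their values in `params`. Both free
#' parameters are identifiable when the observations span depths above and
#' below the inhabited zone, because `tau_scale` also controls the benthic
#' decay slope.
#'
#' @param depth,fraction observed profile; fractions strictly inside (0, 1).
#' @param params fixed parameters and starting point, a [decay_params()].
#' @param start optional named list with starting values for `lambda_p` and
#'   `tau_scale`.
#' @return list with `params` (fitted [decay_params()]), `estimates` (named
#'   vector), `rss`, `residuals` (logit scale), `converged`.
#' @export
fit_decay_params <- function(depth, fraction, params = decay_params(),
                             start = list(lambda_p = 0.5, tau_scale = 0.05)) {
  if (length(depth) != length(fraction))
    stop("depth and fraction must have equal length")
  if (length(depth) < 2)
    stop("need at least as many points as free parameters (2)")
  if (any(fraction <= 0) || any(fraction >= 1))
    stop("fractions must lie strictly inside (0, 1)")
  y <- qlogis(fraction)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      y ~ logit_fraction(depth, lp, ts, params),
      start = list(lp = start$lambda_p, ts = start$tau_scale),
      lower = c(lp = params$lambda_b * (1 + 1e-6), ts = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(params = params,
                estimates = c(lambda_p = NA_real_, tau_scale = NA_real_),
                rss = NA_real_, residuals = rep(NA_real_, length(y)),
                converged = FALSE))
  }
  est <- coef(fit)
  out <- params
  out$lambda_p <- unname(est["lp"])
  out$tau_scale <- unname(est["ts"])
  list(params = validate_decay_params(out),
       estimates = c(lambda_p = out$lambda_p, tau_scale = out$tau_scale),
       rss = sum(resid(fit)^2),
       residuals = as.numeric(resid(fit)),
       converged = fit$convInfo$isConv)
}
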