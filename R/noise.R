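#' Measurement noise model
#'
#' Observed concentrations are the noiseless simulated values corrupted by
#' additive and multiplicative Gaussian noise and floored at zero:
#' `v_noise = max(0, v + C1 * xi1 + C2 * xi2 * v)` with independent standard
#' normal draws `xi1`, `xi2` per value. The reported measurement uncertainty
#' is `sigma = sqrt(C1^2 + (C2 * y_obs)^2)`, computed from the noisy
#' observation.
#'
#' @param C1 Additive noise scale (concentration units), default 0.1.
#' @param C2 Multiplicative noise scale (dimensionless), default 0.2.
#' @param assay_sd Log-scale standard deviation of gel-shift assay
#'   observations of K and h, default 0.1.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(C1 = 0.1, C2 = 0.2, assay_sd = 0.1) {
  stopifnot(C1 >= 0, C2 >= 0, assay_sd > 0)
  structure(list(C1 = C1, C2 = C2, assay_sd = assay_sd),
            class = "noise_model")
}

#' Add measurement noise to simulated values
#'
#' @param v Numeric vector of noiseless values.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return Noisy values, element-wise `max(0, v + C1*xi1 + C2*xi2*v)`.
#' @export
add_noise <- function(v, noise = noise_model(), seed = NULL) {
  stopifnot(all(is.finite(v)))
  draw <- function() {
    xi1 <- stats::rnorm(length(v))
    xi2 <- stats::rnorm(length(v))
    pmax(0, v + noise$C1 * xi1 + noise$C2 * xi2 * v)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Reported uncertainty for a (possibly noisy) observed value.
sigma_for <- function(y_obs, noise) {
  sqrt(noise$C1^2 + (noise$C2 * y_obs)^2)
}
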