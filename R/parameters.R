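#' Names of the PBK model parameters
#'
#' The full parameter vector of the BPA model: physiological volumes and
#' flows, uptake fractions, plasma-binding fractions, microsomal protein
#' yields, rate constants, in vitro metabolic constants, and tissue:blood
#' partition coefficients for BPA, BPAG and BPAS, plus the ingestion duration
#' `DRINKTIME` (h).
#'
#' @return Character vector of parameter names.
#' @export
pbk_parameter_names <- function() {
  c(bpa_priors()$parameter, "DRINKTIME")
}

# Fractional tissue volumes that must leave positive residual mass for the
# carcass, and fractional blood flows that must sum to exactly one.
.volume_params <- c("VliC", "VstC", "VguC", "VkiC", "VlymphC", "VfaC",
                    "VspdC", "VrpdC", "VBldC")
.flow_params <- c("QhepartC", "QstC", "QguC", "QkiC", "QfaC", "QspdC",
                  "QrpdC")
.fraction_params <- c("FB_BPA", "FB_BPAG", "FB_BPAS",
                      "FracDOSEHep", "FracDOSELymph")

#' Default parameter values
#'
#' Central values of the prior table: means for normal parameters, the
#' median (exponentiated log-mean) for the lognormal body weight, and range
#' midpoints for uniform parameters.  `DRINKTIME` defaults to 0.1 h.
#'
#' @param priors Prior table as returned by [bpa_priors()].
#' @return Named list of parameter values.
#' @export
default_parameters <- function(priors = bpa_priors()) {
  val <- ifelse(priors$distribution == "uniform",
                (priors$lower + priors$upper) / 2,
                ifelse(priors$distribution == "lognormal",
                       exp(priors$mean), priors$mean))
  out <- as.list(stats::setNames(val, priors$parameter))
  out$DRINKTIME <- 0.1
  out
}

#' Build a validated PBK parameter set
#'
#' Applies the mass-balance re-parameterisation contract: every model
#' parameter must be present and strictly positive, binding and dose
#' fractions must lie in \[0, 1\] with `FracDOSEHep + FracDOSELymph <= 1`,
#' fractional tissue volumes must sum to less than one (the remainder is
#' carcass), and fractional blood flows are renormalised to sum to exactly
#' one while preserving their relative magnitudes.
#'
#' @param raw_draws Named list or vector mapping parameter name to value;
#'   must cover every name in [pbk_parameter_names()].
#' @param on_volume_overflow `"error"` (construction contract: volumes
#'   summing above one are a domain error) or `"rescale"`, used when the
#'   draws come from independent samplers (GSA, ABC) whose box ranges can
#'   jointly exceed the anatomical budget: fractional volumes are then
#'   rescaled, preserving ratios, to leave at least 5% residual carcass.
#' @return A named list of class `pbk_parameters` satisfying the invariants.
#' @examples
#' p <- build_parameter_set(default_parameters())
#' sum(unlist(p[c("QhepartC", "QstC", "QguC", "QkiC", "QfaC",
#'                "QspdC", "QrpdC")]))  # exactly 1
#' @export
build_parameter_set <- function(raw_draws,
                                on_volume_overflow = c("error", "rescale")) {
  on_volume_overflow <- match.arg(on_volume_overflow)
  draws <- as.list(raw_draws)
  needed <- pbk_parameter_names()
  missing <- setdiff(needed, names(draws))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  draws <- draws[needed]
  vals <- unlist(draws)
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(needed[!is.finite(vals)], collapse = ", "))
  }
  if (any(vals <= 0 & !needed %in% .fraction_params)) {
    bad <- needed[vals <= 0 & !needed %in% .fraction_params]
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  fr <- unlist(draws[.fraction_params])
  if (any(fr < 0 | fr > 1)) {
    stop("binding/dose fractions outside [0, 1]: ",
         paste(.fraction_params[fr < 0 | fr > 1], collapse = ", "))
  }
  if (draws$FracDOSEHep + draws$FracDOSELymph > 1) {
    stop("FracDOSEHep + FracDOSELymph exceeds 1")
  }
  vsum <- sum(unlist(draws[.volume_params]))
  if (vsum > 0.95 && on_volume_overflow == "rescale") {
    for (nm in .volume_params) draws[[nm]] <- draws[[nm]] * 0.95 / vsum
    vsum <- 0.95
  }
  if (vsum > 1) {
    stop("fractional tissue volumes sum to ", signif(vsum, 4),
         " > 1: no residual carcass mass")
  }
  qsum <- sum(unlist(draws[.flow_params]))
  if (abs(qsum - 1) > .Machine$double.eps * 100) {
    for (nm in .flow_params) draws[[nm]] <- draws[[nm]] / qsum
  }
  structure(draws, class = "pbk_parameters", flow_scale = 1 / qsum)
}

#' @export
print.pbk_parameters <- function(x, ...) {
  cat("<pbk_parameters> ", length(x), " parameters\n", sep = "")
  cat("  flows renormalised by ", signif(attr(x, "flow_scale"), 6), "\n",
      sep = "")
  invisible(x)
}

#' Scale an in vitro maximum metabolic rate to the whole organ
#'
#' Converts a microsomal rate (pmol/min/mg protein) to a whole-organ maximum
#' rate (mg/h) using the microsomal protein yield and organ mass:
#' `vmax * mpy * organ_mass * 60 * mw * 1e-9`.
#'
#' @param vmax_invitro In vitro maximum rate, pmol/min/mg microsomal protein.
#' @param mpy Microsomal protein yield, mg protein per g tissue.
#' @param organ_mass Organ mass, g.
#' @param molecular_weight Substrate molecular weight, g/mol.
#' @return Whole-organ maximum rate, mg/h.
#' @examples
#' scale_vmax(4494, 34, 1500, 228.291)  # ~3139 mg/h for the whole liver
#' @export
scale_vmax <- function(vmax_invitro, mpy, organ_mass, molecular_weight) {
  args <- c(vmax_invitro = vmax_invitro, mpy = mpy, organ_mass = organ_mass,
            molecular_weight = molecular_weight)
  if (any(args <= 0)) {
    stop("all inputs must be > 0; got non-positive ",
         paste(names(args)[args <= 0], collapse = ", "))
  }
  vmax_invitro * mpy * organ_mass * 60 * molecular_weight * 1e-9
}

#' Draw parameter values from the prior table
#'
#' Independent draws from each parameter's prior family truncated at the
#' tabulated bounds.  Normals are sampled by inverse-CDF truncation; the
#' lognormal body weight is sampled on the log scale.
#'
#' @param n Number of draws.
#' @param priors Prior table ([bpa_priors()] layout).
#' @param parameters Optional subset of parameter names to draw; default all.
#' @return Tibble with `n` rows, one column per parameter.
#' @export
sample_priors <- function(n, priors = bpa_priors(), parameters = NULL) {
  if (!is.null(parameters)) {
    priors <- priors[priors$parameter %in% parameters, , drop = FALSE]
  }
  cols <- lapply(seq_len(nrow(priors)), function(i) {
    p <- priors[i, ]
    switch(p$distribution,
      uniform = stats::runif(n, p$lower, p$upper),
      normal = rtruncnorm(n, p$mean, p$sd, p$lower, p$upper),
      lognormal = exp(rtruncnorm(n, p$mean, p$sd, p$lower, p$upper)),
      stop("unknown distribution: ", p$distribution)
    )
  })
  names(cols) <- priors$parameter
  tibble::as_tibble(cols)
}

# inverse-CDF sampler for the truncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# prior density on the truncated support (used by the calibration sampler)
dprior <- function(x, dist, mean, sd, lower, upper, log = TRUE) {
  if (x < lower || x > upper) return(if (log) -Inf else 0)
  ld <- switch(dist,
    uniform = -log(upper - lower),
    normal = stats::dnorm(x, mean, sd, log = TRUE) -
      log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)),
    lognormal = stats::dnorm(log(x), mean, sd, log = TRUE) - log(x) -
      log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)),
    stop("unknown distribution: ", dist)
  )
  if (log) ld else exp(ld)
}
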