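#' @keywords internal
#' @useDynLib qivive
"_PACKAGE"

#' Define an oral dose event
#'
#' @param dose_per_bw Dose in ug per kg body weight.
#' @param start_time Start of ingestion, h.
#' @param duration Ingestion period, h; by convention tied to `DRINKTIME`.
#' @return A `dose_event` list.
#' @export
dose_event <- function(dose_per_bw = 100, start_time = 0, duration = 0.1) {
  if (dose_per_bw < 0) stop("dose_per_bw must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(dose_per_bw = dose_per_bw, start_time = start_time,
                 duration = duration), class = "dose_event")
}

# order must match the #define table in src/pbk_model.c
pbk_parms_vector <- function(p, dose, bile_lag = 4, gut_loss_all = FALSE,
                             metabolism = TRUE) {
  bw <- p$BW
  qc <- p$QCC * bw^0.75
  vli <- p$VliC * bw
  vgu <- p$VguC * bw
  c(
    vli, p$VstC * bw, vgu, p$VkiC * bw, p$VfaC * bw, p$VspdC * bw,
    p$VrpdC * bw, p$VBldC * bw,
    p$QhepartC * qc, p$QstC * qc, p$QguC * qc, p$QkiC * qc, p$QfaC * qc,
    p$QspdC * qc, p$QrpdC * qc,
    p$FracDOSEHep, p$FracDOSELymph, p$DRINKTIME,
    p$FB_BPA, p$FB_BPAG, p$FB_BPAS,
    p$BELLYPERM, p$GIPERM, p$BELLYPERMLymph, p$GIPERMLymph,
    p$KEMAX, p$KEMIN,
    p$K1_BPA_GUT, p$K1_BPAG_GUT, p$K1_BPAS_GUT,
    p$K1_BPA_LIVER, p$K1_BPAG_LIVER, p$K1_BPAS_LIVER,
    p$K1_BPA_Urine, p$K1_BPAG_Urine, p$K1_BPAS_Urine,
    p$K1_BPA_REMOVED_PLASMA, p$K1_BPAG_REMOVED_PLASMA,
    p$K1_BPAS_REMOVED_PLASMA,
    p$K1Lymph, p$Lymphlag,
    # whole-organ Vmax in ug/h (scale_vmax gives mg/h), KM in ug/L
    1000 * scale_vmax(p$Vmax_liv_BPA_in_vitro, p$MPY, vli * 1000, MW_BPA),
    1000 * p$KM_liv_BPA_in_vitro,
    1000 * scale_vmax(p$Vmax_liv_BPAS_in_vitro, p$MPY, vli * 1000, MW_BPA),
    1000 * p$KM_liv_BPAS_in_vitro,
    1000 * scale_vmax(p$Vmax_gut_BPAG_in_vitro, p$MPYgu, vgu * 1000, MW_BPA),
    1000 * p$KM_gut_BPAG_in_vitro,
    1000 * scale_vmax(p$Vmax_gut_BPAS_in_vitro, p$MPYgu, vgu * 1000, MW_BPA),
    1000 * p$KM_gut_BPAS_in_vitro,
    p$Plib, p$Pkib, p$Pfab, p$Pgub, p$Pstb, p$Prpdb, p$Pspdb,
    p$PliG, p$PkiG, p$PfaG, p$PguG, p$PstG, p$PrpdG, p$PspdG,
    p$PliS, p$PkiS, p$PfaS, p$PguS, p$PstS, p$PrpdS, p$PspdS,
    dose$dose_per_bw * bw, dose$start_time, dose$duration,
    bile_lag, MW_BPAG / MW_BPA, MW_BPAS / MW_BPA,
    as.numeric(gut_loss_all), as.numeric(metabolism), 0
  )
}

pbk_state_names <- function() {
  route <- c("stomach_hep", "gutlumen_hep", "stomach_lym", "gutlumen_lym",
             "stomach_unabs", "gutlumen_unabs", "lymph", "lymph_transit")
  blk <- c("gutlumen_recirc", "bile", "gut", "stomach", "liver", "kidney",
           "fat", "slow", "rapid", "blood_unbound", "blood_bound",
           "urine", "faeces")
  c(route, paste0(blk, "_BPA"), paste0(blk, "_BPAG"), paste0(blk, "_BPAS"))
}

#' Simulate the BPA PBK model
#'
#' Solves the flow-limited PBK model for BPA and its conjugates as a delay
#' differential system: zero-order ingestion, declining first-order stomach
#' emptying, absorption into the hepatic portal and lymphatic routes with an
#' unabsorbed fraction lost in faeces, first-pass gut and liver metabolism,
#' per-analyte bound/unbound blood pools, enterohepatic recirculation with a
#' fixed biliary transit delay, lymphatic delivery to venous blood after
#' `Lymphlag`, and first-order urinary elimination from kidney tissue.
#'
#' @param params A [build_parameter_set()] result (or a named list coerced
#'   through it).
#' @param dose A [dose_event()].
#' @param duration Simulation length, h.
#' @param step Output step, h.
#' @param bile_lag Biliary transit delay, h.
#' @param gut_loss_all If `TRUE` the faecal elimination rates act on all gut
#'   lumen pools, not only the bile-recirculated pool.
#' @param metabolism If `FALSE`, gut and liver metabolism is switched off
#'   (the conjugate sub-models then stay identically zero).
#' @param rtol,atol Solver tolerances.
#' @return A `pbk_sim` object with elements `times`, `states` (amount matrix,
#'   ug), `series` (tibble of plasma concentrations in ug/L and the liver and
#'   kidney tissue concentrations `CVli`, `CVki` in mg/L), `params`, `dose`.
#' @examples
#' sim <- simulate_pbk(build_parameter_set(default_parameters()),
#'                     dose_event(100), duration = 6, step = 0.05)
#' head(sim$series)
#' @export
simulate_pbk <- function(params, dose = dose_event(), duration = 24,
                         step = 0.01, bile_lag = 4, gut_loss_all = FALSE,
                         metabolism = TRUE, rtol = 1e-7, atol = 1e-7) {
  if (!inherits(params, "pbk_parameters")) {
    params <- build_parameter_set(params)
  }
  if (duration < dose$start_time + dose$duration) {
    stop("duration must cover the dose event")
  }
  if (step <= 0) stop("step must be > 0")
  times <- seq(0, duration, by = step)
  pv <- pbk_parms_vector(params, dose, bile_lag = bile_lag,
                         gut_loss_all = gut_loss_all,
                         metabolism = metabolism)
  y0 <- stats::setNames(numeric(47), pbk_state_names())
  out <- deSolve::dede(y = y0, times = times, func = "qivive_pbk_derivs",
                       parms = pv, dllname = "qivive",
                       initfunc = "qivive_pbk_init",
                       rtol = rtol, atol = atol * max(pv[71], 1),
                       control = list(mxhist = 1e5))
  if (attr(out, "istate")[1] < 0) {
    stop("PBK solver did not converge (istate = ",
         attr(out, "istate")[1], ")")
  }
  states <- unclass(out)[, -1, drop = FALSE]
  dose_total <- pv[71]
  neg <- min(states)
  if (neg < -1e-4 * max(dose_total, 1)) {
    stop("integrity error: state went negative beyond tolerance (",
         signif(neg, 3), " ug)")
  }
  bw <- params$BW
  vbld <- params$VBldC * bw
  vli <- params$VliC * bw
  vki <- params$VkiC * bw
  series <- tibble::tibble(
    time = times,
    plasma_BPA = (states[, "blood_unbound_BPA"] +
                    states[, "blood_bound_BPA"]) / vbld,
    plasma_BPAG = (states[, "blood_unbound_BPAG"] +
                     states[, "blood_bound_BPAG"]) / vbld,
    plasma_BPAS = (states[, "blood_unbound_BPAS"] +
                     states[, "blood_bound_BPAS"]) / vbld,
    CVli = states[, "liver_BPA"] / (vli * params$Plib) / 1000,
    CVki = states[, "kidney_BPA"] / (vki * params$Pkib) / 1000
  )
  structure(list(times = times, states = states, series = series,
                 params = params, dose = dose, dose_total = dose_total),
            class = "pbk_sim")
}

#' @export
print.pbk_sim <- function(x, ...) {
  cat("<pbk_sim> ", length(x$times), " time points over ",
      max(x$times), " h; dose ", x$dose$dose_per_bw, " ug/kg\n", sep = "")
  invisible(x)
}

#' Mass balance of a PBK simulation
#'
#' Total mass in all compartments plus cumulative eliminations, expressed in
#' BPA equivalents (conjugate amounts are molar-corrected), compared with the
#' mass ingested up to each output time.
#'
#' @param sim A `pbk_sim` object.
#' @return Tibble with `time`, `ingested`, `total` (ug BPA equivalents) and
#'   `rel_error` relative to the administered dose.
#' @export
pbk_mass_balance <- function(sim) {
  s <- sim$states
  nm <- colnames(s)
  bpa <- rowSums(s[, !grepl("_BPAG$|_BPAS$", nm), drop = FALSE])
  g <- rowSums(s[, grepl("_BPAG$", nm), drop = FALSE]) * MW_BPA / MW_BPAG
  su <- rowSums(s[, grepl("_BPAS$", nm), drop = FALSE]) * MW_BPA / MW_BPAS
  d <- sim$dose
  ingested <- sim$dose_total *
    pmin(pmax((sim$times - d$start_time) / d$duration, 0), 1)
  tibble::tibble(
    time = sim$times, ingested = ingested, total = bpa + g + su,
    rel_error = (bpa + g + su - ingested) / max(sim$dose_total, 1e-12)
  )
}

#' Trapezoidal area under a concentration series
#'
#' @param time Time grid, h.
#' @param value Concentration values on the grid.
#' @param window Two-element window `[t0, t1]` within the grid.
#' @return Area (concentration x time).
#' @examples
#' auc_trapz(0:3, rep(1, 4))          # 3
#' auc_trapz(c(0, 2), c(0, 2))        # 2 (triangle)
#' @export
auc_trapz <- function(time, value, window = range(time)) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be an increasing [t0, t1] pair")
  }
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9) {
    stop("window outside the simulated grid")
  }
  keep <- time >= window[1] & time <= window[2]
  t <- time[keep]
  v <- value[keep]
  # close the window ends by linear interpolation if they fall between points
  if (length(t) == 0 || t[1] > window[1]) {
    v <- c(stats::approx(time, value, xout = window[1])$y, v)
    t <- c(window[1], t)
  }
  if (t[length(t)] < window[2]) {
    v <- c(v, stats::approx(time, value, xout = window[2])$y)
    t <- c(t, window[2])
  }
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' AUC of a simulated output series
#'
#' @param sim A `pbk_sim` object.
#' @param series Column of `sim$series` to integrate (e.g. `"CVli"`).
#' @param window Integration window in h (the QIVIVE tissue-dose window is
#'   0-3 h; the sensitivity-analysis window is 0-5 h).
#' @return Scalar AUC.
#' @export
pbk_auc <- function(sim, series = "CVli", window = c(0, 3)) {
  if (!series %in% names(sim$series)) stop("unknown series: ", series)
  auc_trapz(sim$series$time, sim$series[[series]], window)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pbk_sim
#' @export
tidy.pbk_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -"time", names_to = "series",
                      values_to = "value")
}

#' @method autoplot pbk_sim
#' @export
autoplot.pbk_sim <- function(object, series = c("plasma_BPA", "plasma_BPAG",
                                                "plasma_BPAS"), ...) {
  df <- tidy.pbk_sim(object)
  df <- df[df$series %in% series, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Count local maxima of a series
#'
#' Peak counting used to detect the lymphatic double peak in plasma BPA.
#' A point is a local maximum if it exceeds its neighbours and stands more
#' than `prominence` times the series maximum above the higher of the two
#' adjacent local minima.
#'
#' @param value Numeric series.
#' @param prominence Minimum relative prominence of a peak.
#' @return Integer count of peaks.
#' @export
count_peaks <- function(value, prominence = 0.01) {
  n <- length(value)
  if (n < 3) return(0L)
  thr <- prominence * max(value)
  peaks <- 0L
  prev_min <- value[1]
  climbing <- TRUE
  for (i in 2:n) {
    if (climbing) {
      if (value[i] < value[i - 1] - 1e-15) {
        if (value[i - 1] - prev_min > thr) peaks <- peaks + 1L
        climbing <- FALSE
        prev_min <- value[i]
      }
    } else {
      prev_min <- min(prev_min, value[i])
      if (value[i] > prev_min + thr) climbing <- TRUE
    }
  }
  # a series still climbing at the end counts its running maximum as a peak
  if (climbing && value[n] - prev_min > thr) peaks <- peaks + 1L
  peaks
}
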