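#' Morris elementary-effects screening
#'
#' One-at-a-time trajectory design over a `levels`-point grid.  For each of
#' `trajectories` random trajectories every parameter is perturbed once by
#' `delta = levels / (2 * (levels - 1))` (in unit-cube coordinates); the
#' absolute elementary effects are averaged into `mu_star` and their spread
#' into `sigma`.  Because the design is stochastic, the screening is run
#' `repeats` times and the final rank of each parameter is the mode of its
#' per-repeat ranks (ties broken by mean rank).
#'
#' @param model_fn Function taking a named numeric vector of parameter values
#'   and returning a scalar.
#' @param ranges Named list (or two-column data frame) of `(lower, upper)`
#'   bounds per parameter.
#' @param trajectories Trajectories per repeat (>= 4).
#' @param levels Grid levels.
#' @param repeats Independent screening repeats used for the modal ranking.
#' @param seed Integer seed.
#' @return Tibble with one row per parameter: `mu_star`, `sigma` (averaged
#'   over repeats), `rank` (modal rank, 1 = most influential), sorted by
#'   rank.
#' @export
morris_rank <- function(model_fn, ranges, trajectories = 50, levels = 8,
                        repeats = 6, seed = 1) {
  ranges <- as_ranges(ranges)
  if (trajectories < 4) stop("trajectories must be >= 4")
  if (repeats < 1) stop("repeats must be >= 1")
  k <- nrow(ranges)
  per_rep <- lapply(seq_len(repeats), function(r) {
    set.seed(seed + r - 1)
    ee <- morris_effects(model_fn, ranges, trajectories, levels)
    mu_star <- colMeans(abs(ee))
    tibble::tibble(parameter = ranges$parameter, mu_star = mu_star,
                   sigma = apply(ee, 2, stats::sd),
                   rank = rank(-mu_star, ties.method = "first"),
                   repeat_id = r)
  })
  all <- dplyr::bind_rows(per_rep)
  dplyr::arrange(dplyr::summarise(
    dplyr::group_by(all, .data$parameter),
    mu_star = mean(.data$mu_star), sigma = mean(.data$sigma),
    rank_mode = modal_rank(.data$rank), rank_mean = mean(.data$rank),
    .groups = "drop"
  ), .data$rank_mode, .data$rank_mean) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("parameter", "mu_star", "sigma", "rank", "rank_mode",
                  "rank_mean")
}

modal_rank <- function(r) {
  tab <- table(r)
  as.integer(names(tab)[which.max(tab)])
}

as_ranges <- function(ranges) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("parameter", "lower", "upper") %in% names(ranges)))
    out <- tibble::as_tibble(ranges[c("parameter", "lower", "upper")])
  } else {
    out <- tibble::tibble(
      parameter = names(ranges),
      lower = purrr::map_dbl(ranges, 1),
      upper = purrr::map_dbl(ranges, 2)
    )
  }
  if (any(out$lower >= out$upper)) {
    stop("each range needs lower < upper")
  }
  out
}

# one repeat of the trajectory design; returns trajectories x k matrix of
# (signed) elementary effects on the natural parameter scale
morris_effects <- function(model_fn, ranges, trajectories, levels) {
  k <- nrow(ranges)
  delta <- levels / (2 * (levels - 1))
  grid <- seq(0, 1 - delta, length.out = levels / 2)
  ee <- matrix(NA_real_, trajectories, k,
               dimnames = list(NULL, ranges$parameter))
  for (tr in seq_len(trajectories)) {
    x <- grid[sample.int(length(grid), k, replace = TRUE)]
    dirs <- sample(c(-1, 1), k, replace = TRUE)
    # flip direction where the step would leave the unit interval
    dirs[x + dirs * delta > 1 | x + dirs * delta < 0] <-
      -dirs[x + dirs * delta > 1 | x + dirs * delta < 0]
    order_i <- sample.int(k)
    y0 <- model_fn(unit_to_range(x, ranges))
    for (i in order_i) {
      x2 <- x
      x2[i] <- x[i] + dirs[i] * delta
      y1 <- model_fn(unit_to_range(x2, ranges))
      ee[tr, i] <- (y1 - y0) / (dirs[i] * delta)
      x <- x2
      y0 <- y1
    }
  }
  ee
}

unit_to_range <- function(u, ranges) {
  stats::setNames(ranges$lower + u * (ranges$upper - ranges$lower),
                  ranges$parameter)
}

#' eFAST variance-based sensitivity indices
#'
#' Extended Fourier Amplitude Sensitivity Test: each parameter in turn is
#' assigned the driving frequency and the rest of the set low interference
#' frequencies; first-order (`S_M`) and total-order (`S_T`) indices are
#' read off the Fourier spectrum of the model output along the search curve.
#'
#' @param model_fn Function of a named numeric vector returning a scalar or
#'   a named vector (indices are then computed per output element).
#' @param ranges Named list or data frame of `(lower, upper)` bounds;
#'   parameters are sampled uniformly.
#' @param samples_per_param Points per search curve (>= 65).
#' @param M Interference factor (number of harmonics).
#' @param resamples Random-phase curves averaged per parameter.
#' @param seed Integer seed.
#' @return Tibble with columns `parameter`, `output`, `S_M`, `S_T`, plus a
#'   `degenerate` flag set when the output variance is (numerically) zero,
#'   in which case all indices for that output are zero.
#' @export
efast <- function(model_fn, ranges, samples_per_param = 1025, M = 4,
                  resamples = 2, seed = 1) {
  ranges <- as_ranges(ranges)
  k <- nrow(ranges)
  if (k < 2) stop("eFAST needs at least two parameters")
  ns <- samples_per_param
  w_max <- floor((ns - 1) / (2 * M))
  if (w_max < 8) stop("samples_per_param too small for the interference factor")
  w_comp_max <- max(1, floor(w_max / (2 * M)))
  set.seed(seed)
  s <- 2 * pi * (seq_len(ns) - 1) / ns
  res <- list()
  for (i in seq_len(k)) {
    freqs <- integer(k)
    freqs[i] <- w_max
    # spread the complement frequencies across the admissible band: cycling
    # 1, 2, ... leaves small complement sets on closed low-order Lissajous
    # curves that sample the complementary space poorly
    freqs[-i] <- round(seq(1, w_comp_max, length.out = k - 1))
    acc <- NULL
    for (r in seq_len(resamples)) {
      phase <- stats::runif(k, 0, 2 * pi)
      u <- vapply(seq_len(k), function(j) {
        0.5 + asin(sin(freqs[j] * s + phase[j])) / pi
      }, numeric(ns))
      x <- t(t(u) * (ranges$upper - ranges$lower) + ranges$lower)
      colnames(x) <- ranges$parameter
      first <- model_fn(stats::setNames(x[1, ], ranges$parameter))
      onames <- names(first) %||% (
        if (length(first) == 1) "y" else paste0("y", seq_along(first)))
      y <- matrix(NA_real_, ns, length(first))
      y[1, ] <- as.numeric(first)
      for (m in 2:ns) {
        y[m, ] <- as.numeric(model_fn(stats::setNames(x[m, ],
                                                      ranges$parameter)))
      }
      idx <- fast_indices(y, w_max, w_comp_max, M)
      idx$output <- onames
      acc <- if (is.null(acc)) idx else
        dplyr::mutate(acc, vi = .data$vi + idx$vi, vc = .data$vc + idx$vc,
                      v = .data$v + idx$v,
                      degenerate = .data$degenerate & idx$degenerate)
    }
    # pool the spectral variance components over the random-phase curves
    acc$S_M <- ifelse(acc$v > 0, acc$vi / acc$v, 0)
    acc$S_T <- ifelse(acc$v > 0, 1 - acc$vc / acc$v, 0)
    acc$parameter <- ranges$parameter[i]
    res[[i]] <- acc
  }
  dplyr::select(dplyr::bind_rows(res), "parameter", "output", "S_M", "S_T",
                "degenerate")
}

# spectrum-based indices for one driving frequency; y is ns x n_outputs
fast_indices <- function(y, w_max, w_comp_max, M) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  out <- lapply(seq_len(ncol(y)), function(j) {
    yy <- y[, j]
    ns <- length(yy)
    f <- stats::fft(yy - mean(yy))
    half <- 2:floor((ns + 1) / 2)
    p <- (Mod(f[half])^2) / ns^2 * 2   # one-sided power at freq 1..
    v <- sum(p)
    if (v < .Machine$double.eps * max(1, mean(yy)^2)) {
      return(tibble::tibble(vi = 0, vc = 0, v = 0, degenerate = TRUE))
    }
    vi <- sum(p[pmin(seq_len(M) * w_max, length(p))])
    vc <- sum(p[seq_len(min(floor(w_max / 2), length(p)))])
    tibble::tibble(vi = vi, vc = vc, v = v, degenerate = FALSE)
  })
  dplyr::bind_rows(out)
}

#' Lowry ribbon bounds from eFAST indices
#'
#' With parameters sorted by descending total effect, the cumulative main
#' effects bound the explained variance from below and the running minimum of
#' the cumulative total effects (capped at 1) from above; the gap is the
#' variance attributable to interactions.
#'
#' @param result Tibble with `parameter`, `S_M`, `S_T` (single output).
#' @return Tibble with per-position `lower` and `upper` ribbon bounds.
#' @export
lowry_bounds <- function(result) {
  stopifnot(all(c("parameter", "S_M", "S_T") %in% names(result)))
  res <- dplyr::arrange(result, dplyr::desc(.data$S_T))
  lower <- pmin(cumsum(res$S_M), 1)
  upper <- pmax(pmin(cumsum(res$S_T), 1), lower)
  tibble::tibble(parameter = res$parameter,
                 position = seq_len(nrow(res)),
                 S_M = res$S_M, S_T = res$S_T,
                 lower = lower, upper = upper)
}

#' Lowry plot
#'
#' Stacked main-effect and interaction bars per parameter with the
#' interaction ribbon bounded by the cumulative main effects and the
#' cumulative total effects.
#'
#' @param result eFAST result for a single output (`parameter`, `S_M`,
#'   `S_T`).
#' @return A ggplot object.
#' @export
plot_lowry <- function(result) {
  rb <- lowry_bounds(result)
  rb$parameter <- factor(rb$parameter, levels = rb$parameter)
  long <- tidyr::pivot_longer(
    dplyr::mutate(rb, interaction = .data$S_T - .data$S_M),
    c("S_M", "interaction"), names_to = "component", values_to = "share")
  long$component <- factor(long$component, levels = c("interaction", "S_M"),
                           labels = c("interactions", "main effect"))
  ggplot2::ggplot(rb, ggplot2::aes(x = .data$parameter)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      group = 1), fill = "lightblue",
                         alpha = 0.6) +
    ggplot2::geom_col(data = long,
                      ggplot2::aes(y = .data$share, fill = .data$component)) +
    ggplot2::scale_fill_manual(values = c("main effect" = "darkgreen",
                                          "interactions" = "tan4")) +
    ggplot2::labs(x = NULL, y = "proportion of variance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Parameter ranges from the calibrated posterior summaries
#'
#' Builds eFAST/ABC sampling ranges for a set of parameters from the
#' posterior tables: global parameters take their 95% interval; parameters
#' calibrated per individual take the minimum and maximum of the interval
#' endpoints over the 14 volunteers; parameters that were not calibrated
#' fall back to their prior bounds.
#'
#' @param parameters Character vector of parameter names.
#' @param global,individual,priors Posterior and prior tables
#'   ([bpa_posterior_global()] etc.).
#' @return Ranges tibble (`parameter`, `lower`, `upper`).
#' @export
posterior_ranges <- function(parameters,
                             global = bpa_posterior_global(),
                             individual = bpa_posterior_individual(),
                             priors = bpa_priors()) {
  rows <- lapply(parameters, function(p) {
    if (p %in% individual$parameter) {
      d <- individual[individual$parameter == p, ]
      c(min(d$q2.5), max(d$q97.5))
    } else if (p %in% global$parameter) {
      d <- global[global$parameter == p, ]
      c(d$q2.5, d$q97.5)
    } else if (p %in% priors$parameter) {
      d <- priors[priors$parameter == p, ]
      c(d$lower, d$upper)
    } else {
      stop("no posterior or prior information for parameter ", p)
    }
  })
  tibble::tibble(parameter = parameters,
                 lower = purrr::map_dbl(rows, 1),
                 upper = purrr::map_dbl(rows, 2))
}

#' Scalar PBK output for sensitivity analysis
#'
#' Returns a closure mapping a named parameter draw (a subset of the full
#' parameter vector) onto a scalar PBK model output; remaining parameters
#' are held at `base`.
#'
#' @param output `"CVli"`, `"CVki"` or a plasma series name.
#' @param base Baseline parameter list (defaults to [default_parameters()]).
#' @param window AUC window, h.
#' @param statistic `"auc"` (default) or `"instantaneous"` (value at the
#'   window end).
#' @param dose A [dose_event()].
#' @param step Output step used in the underlying simulation.
#' @return Function suitable for [morris_rank()] / [efast()].
#' @export
pbk_output_fn <- function(output = "CVli", base = default_parameters(),
                          window = c(0, 5), statistic = c("auc",
                                                          "instantaneous"),
                          dose = dose_event(100), step = 0.05) {
  statistic <- match.arg(statistic)
  force(base)
  function(draw) {
    p <- base
    p[names(draw)] <- as.list(unname(draw))
    sim <- simulate_pbk(build_parameter_set(p, "rescale"), dose,
                        duration = window[2], step = step)
    if (statistic == "auc") {
      pbk_auc(sim, output, window)
    } else {
      sim$series[[output]][length(sim$times)]
    }
  }
}
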