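#' Validate a continuous dose-response set
#'
#' @param dose Doses (>= 0), at least 4 distinct levels.
#' @param response Natural-scale continuous responses (> 0; the lognormal
#'   response assumption requires strictly positive values).
#' @return Tibble `dose`, `response` of class `dose_response_set`.
#' @export
dose_response_set <- function(dose, response) {
  if (length(dose) != length(response)) stop("dose/response length mismatch")
  if (any(dose < 0)) stop("doses must be >= 0")
  if (length(unique(dose)) < 4) stop("need at least 4 distinct dose levels")
  if (any(response <= 0)) {
    stop("responses must be > 0 after preprocessing (lognormal assumption)")
  }
  structure(tibble::tibble(dose = dose, response = response),
            class = c("dose_response_set", "tbl_df", "tbl", "data.frame"))
}

# The four EFSA-default continuous families (increasing direction), with the
# median response f(x) parameterised as:
#   exp3:  a * exp(b * x^d)
#   exp5:  a * (c - (c - 1) * exp(-b * x^d))
#   hill3: a * (1 + x^d / (b^d + x^d))
#   hill5: a * (1 + (c - 1) * x^d / (b^d + x^d))
# theta is optimised on the log scale of (a, b, [c - 1], d).
bmd_families <- function() {
  list(
    exp3 = list(
      npar = 3,
      f = function(th, x) th[1] * exp(th[2] * x^th[3]),
      bmd = function(th, bmr) (log(1 + bmr) / th[2])^(1 / th[3])
    ),
    exp5 = list(
      npar = 4,
      f = function(th, x) {
        cc <- 1 + th[3]
        th[1] * (cc - (cc - 1) * exp(-th[2] * x^th[4]))
      },
      bmd = function(th, bmr) {
        cc <- 1 + th[3]
        if (cc <= 1 + bmr) return(NA_real_)   # plateau below the BMR
        (-log((cc - 1 - bmr) / (cc - 1)) / th[2])^(1 / th[4])
      }
    ),
    hill3 = list(
      npar = 3,
      f = function(th, x) th[1] * (1 + x^th[3] / (th[2]^th[3] + x^th[3])),
      bmd = function(th, bmr) th[2] * (bmr / (1 - bmr))^(1 / th[3])
    ),
    hill5 = list(
      npar = 4,
      f = function(th, x) {
        cc <- 1 + th[3]
        th[1] * (1 + (cc - 1) * x^th[4] / (th[2]^th[4] + x^th[4]))
      },
      bmd = function(th, bmr) {
        cc <- 1 + th[3]
        if (cc <= 1 + bmr) return(NA_real_)
        r <- bmr / (cc - 1)
        th[2] * (r / (1 - r))^(1 / th[4])
      }
    )
  )
}

#' Fit the continuous dose-response model families
#'
#' Maximum-likelihood fits of the four nested continuous families
#' (exponential and Hill, 3- and 5-parameter) under a lognormal response:
#' `log(y) ~ Normal(log f(x), sigma^2)`.  Each family is fitted from a small
#' grid of starting values with `stats::nlminb`; a family that fails to
#' converge is flagged and excluded from averaging.
#'
#' @param data A [dose_response_set()] (or tibble with `dose`, `response`).
#' @return A `bmd_fitset`: tibble with one row per family (`model`,
#'   `converged`, `loglik`, `k` (parameter count incl. sigma), `aic`,
#'   `sigma`, `theta` list-column).
#' @export
fit_model_family <- function(data) {
  x <- data$dose
  logy <- log(data$response)
  n <- length(x)
  fams <- bmd_families()

  # flat-response guard: no dose-related signal to fit
  if (stats::sd(logy) < 1e-12) {
    out <- tibble::tibble(
      model = names(fams), converged = FALSE, loglik = NA_real_,
      k = vapply(fams, `[[`, numeric(1), "npar") + 1, aic = NA_real_,
      sigma = 0, theta = rep(list(NULL), length(fams))
    )
    attr(out, "flat") <- TRUE
    class(out) <- c("bmd_fitset", class(out))
    return(out)
  }

  a0 <- exp(mean(logy[x == min(x)]))
  ymax <- exp(max(stats::ave(logy, x)))
  c0 <- max(ymax / a0, 1.2)
  xmid <- stats::median(x[x > 0])

  fit_one <- function(name) {
    fam <- fams[[name]]
    ssr <- function(lpar) {
      th <- exp(lpar)
      mu <- log(fam$f(th, x))
      if (any(!is.finite(mu))) return(1e10)
      sum((logy - mu)^2)
    }
    starts <- list()
    for (d0 in c(0.6, 1, 2)) {
      starts[[length(starts) + 1]] <- switch(name,
        exp3 = log(c(a0, log(max(c0, 1.02)) / max(x)^d0, d0)),
        exp5 = log(c(a0, 2 / xmid^d0, max(c0 - 1, 0.2), d0)),
        hill3 = log(c(a0, xmid, d0)),
        hill5 = log(c(a0, xmid, max(c0 - 1, 0.2), d0))
      )
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::nlminb(s, ssr, control = list(iter.max = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$objective) &&
          (is.null(best) || fit$objective < best$objective)) {
        best <- fit
      }
    }
    if (is.null(best)) {
      return(list(converged = FALSE, loglik = NA_real_, sigma = NA_real_,
                  theta = NULL))
    }
    sig2 <- best$objective / n
    ll <- -n / 2 * (log(2 * pi * sig2) + 1) - sum(logy)
    list(converged = TRUE, loglik = ll, sigma = sqrt(sig2),
         theta = exp(best$par))
  }

  rows <- lapply(names(fams), fit_one)
  out <- tibble::tibble(
    model = names(fams),
    converged = vapply(rows, `[[`, logical(1), "converged"),
    loglik = vapply(rows, `[[`, numeric(1), "loglik"),
    k = vapply(fams, `[[`, numeric(1), "npar") + 1,
    sigma = vapply(rows, `[[`, numeric(1), "sigma"),
    theta = lapply(rows, `[[`, "theta")
  )
  out$aic <- -2 * out$loglik + 2 * out$k
  attr(out, "flat") <- FALSE
  class(out) <- c("bmd_fitset", class(out))
  out
}

#' Model-averaged benchmark dose at a benchmark response
#'
#' Solves each family's BMD as the dose giving a `bmr` relative change in
#' the median response over the modelled background and averages across
#' converged families with Akaike weights.
#'
#' @param fits A `bmd_fitset` from [fit_model_family()].
#' @param bmr Benchmark response as a relative change (default 0.10).
#' @param dose_range Optional observed dose range; a BMD outside it gains an
#'   extrapolation warning attribute.
#' @return List with `bmd` (averaged), `by_model` (tibble with per-family
#'   `bmd` and `weight`), and `extrapolated`.
#' @export
bmd_at_bmr <- function(fits, bmr = 0.10, dose_range = NULL) {
  if (isTRUE(attr(fits, "flat"))) {
    stop("flat response: BMD undefined (all families reduce to a constant)")
  }
  ok <- fits$converged
  if (!any(ok)) stop("no family converged")
  fams <- bmd_families()
  bmds <- vapply(seq_len(nrow(fits)), function(i) {
    if (!fits$converged[i]) return(NA_real_)
    fams[[fits$model[i]]]$bmd(fits$theta[[i]], bmr)
  }, numeric(1))
  use <- ok & is.finite(bmds)
  if (!any(use)) stop("no converged family attains the benchmark response")
  daic <- fits$aic - min(fits$aic[use])
  w <- ifelse(use, exp(-daic / 2), 0)
  w <- w / sum(w)
  bmd <- sum(w[use] * bmds[use])
  extrapolated <- !is.null(dose_range) &&
    (bmd < min(dose_range) || bmd > max(dose_range))
  if (extrapolated) {
    warning("averaged BMD ", signif(bmd, 3),
            " lies outside the observed dose range")
  }
  list(bmd = bmd,
       by_model = dplyr::mutate(fits[, c("model", "converged", "aic")],
                                bmd = bmds, weight = w),
       extrapolated = extrapolated)
}

#' Bootstrap confidence limits for the model-averaged BMD
#'
#' Parametric bootstrap under the averaged fit: each replicate draws a
#' family with probability equal to its Akaike weight, regenerates lognormal
#' responses from that family's fitted curve and error SD, refits all
#' families and recomputes the averaged BMD.  `BMDL`/`BMDU` are the 5% and
#' 95% quantiles of the replicate BMDs (the one-sided 95% limits of the
#' 90% interval).
#'
#' @param data A [dose_response_set()].
#' @param bmr Benchmark response (default 0.10).
#' @param replicates Bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @return A `bmd_result`: `bmd`, `bmdl10`, `bmdu10`, `by_model`,
#'   `replicates` (successful count), `seed`.
#' @export
bootstrap_bmdl <- function(data, bmr = 0.10, replicates = 1000, seed = 1) {
  if (replicates < 200) stop("replicates must be >= 200")
  fits <- fit_model_family(data)
  central <- bmd_at_bmr(fits, bmr, dose_range = range(data$dose))
  fams <- bmd_families()
  w <- central$by_model$weight
  set.seed(seed)
  boots <- numeric(replicates)
  fail <- 0L
  for (r in seq_len(replicates)) {
    m <- sample.int(nrow(fits), 1, prob = w)
    th <- fits$theta[[m]]
    mu <- log(fams[[fits$model[m]]]$f(th, data$dose))
    ystar <- exp(stats::rnorm(length(mu), mu, fits$sigma[m]))
    b <- tryCatch({
      f2 <- fit_model_family(dose_response_set(data$dose, ystar))
      suppressWarnings(bmd_at_bmr(f2, bmr)$bmd)
    }, error = function(e) NA_real_)
    if (is.na(b)) fail <- fail + 1L
    boots[r] <- b
  }
  if (fail > replicates / 2) {
    stop("instability error: ", fail, "/", replicates,
         " bootstrap replicates failed")
  }
  boots <- boots[is.finite(boots)]
  structure(list(
    bmd = central$bmd,
    bmdl10 = stats::quantile(boots, 0.05, names = FALSE),
    bmdu10 = stats::quantile(boots, 0.95, names = FALSE),
    by_model = central$by_model,
    bmr = bmr,
    replicates = length(boots),
    failed = fail,
    seed = seed,
    data = tibble::as_tibble(data)
  ), class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat("<bmd_result> BMR ", x$bmr * 100, "%: BMD ", signif(x$bmd, 4),
      ", BMDL ", signif(x$bmdl10, 4), ", BMDU ", signif(x$bmdu10, 4),
      " (", x$replicates, " bootstrap replicates)\n", sep = "")
  invisible(x)
}

#' @method tidy bmd_result
#' @export
tidy.bmd_result <- function(x, ...) x$by_model

#' @method glance bmd_result
#' @export
glance.bmd_result <- function(x, ...) {
  tibble::tibble(bmd = x$bmd, bmdl10 = x$bmdl10, bmdu10 = x$bmdu10,
                 bmr = x$bmr, replicates = x$replicates, failed = x$failed)
}

#' @method autoplot bmd_result
#' @export
autoplot.bmd_result <- function(object, ...) {
  dr <- object$data
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(object$bmdl10, object$bmd,
                                       object$bmdu10),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response") +
    ggplot2::theme_minimal()
}

#' Apply a chemical-specific adjustment factor
#'
#' @param bmdl Benchmark dose lower limit.
#' @param csaf Chemical-specific adjustment factor (>= 1).
#' @return `bmdl / csaf`.
#' @examples
#' apply_csaf(1300, 2.52)  # 516
#' @export
apply_csaf <- function(bmdl, csaf) {
  if (csaf < 1) stop("csaf must be >= 1")
  bmdl / csaf
}

#' Human equivalent dose and tolerable daily intake arithmetic
#'
#' `hed = bmdl * hedf` (the human equivalent dose factor is the
#' animal-to-human AUC ratio) and `tdi = hed / uf` with `uf` the overall
#' uncertainty factor.
#'
#' @param bmdl Benchmark dose lower limit.
#' @param hedf Human equivalent dose factor.
#' @param uf Overall uncertainty factor.
#' @return Named list `hed`, `tdi`.
#' @examples
#' hed_and_tdi(8960, 0.068, 150)  # hed ~609, tdi ~4
#' @export
hed_and_tdi <- function(bmdl, hedf, uf) {
  if (any(c(bmdl, hedf, uf) <= 0)) stop("all inputs must be > 0")
  hed <- bmdl * hedf
  list(hed = hed, tdi = hed / uf)
}
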