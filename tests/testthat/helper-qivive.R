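# shared fixtures: cheap simulations and analytic toy models

default_ps <- function(overrides = list()) {
  p <- default_parameters()
  p[names(overrides)] <- overrides
  build_parameter_set(p)
}

quick_sim <- function(overrides = list(), dose = dose_event(100),
                      duration = 12, step = 0.02, ...) {
  simulate_pbk(default_ps(overrides), dose, duration = duration,
               step = step, ...)
}

ishigami <- function(p) {
  sin(p[["x1"]]) + 7 * sin(p[["x2"]])^2 +
    0.1 * p[["x3"]]^4 * sin(p[["x1"]])
}

ishigami_ranges <- list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi))

# closed-form Ishigami variance decomposition (a = 7, b = 0.1)
ishigami_indices <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  list(S_M = c(x1 = v1 / v, x2 = v2 / v, x3 = 0),
       S_T = c(x1 = (v1 + v13) / v, x2 = v2 / v, x3 = v13 / v))
}

# dose-response data generated from a known Hill curve, n doses x reps
hill_data <- function(a = 1, top = 5, ac50 = 100, h = 1.5,
                      doses = c(10, 30, 100, 300, 1000, 3000), reps = 3,
                      sigma = 0.1, seed = 42) {
  set.seed(seed)
  x <- rep(doses, each = reps)
  mu <- a * (1 + top * x^h / (ac50^h + x^h))
  y <- exp(rnorm(length(x), log(mu), sigma))
  dose_response_set(x, y)
}
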