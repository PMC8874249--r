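#' Packaged study tables
#'
#' Loaders for the configuration shipped with the package: prior parameter
#' distributions for the BPA PBK model, posterior summaries from the
#' calibration against the volunteer plasma data, the Morris/eFAST parameter
#' rankings, the physicochemical constants used by the in vitro
#' fate-and-distribution model, the four ToxCast concentration-response
#' datasets, and the reconstructed oral-dose (PORALDOSE) posterior summaries.
#'
#' All loaders return tibbles (or a named list for [bpa_physchem()]) read from
#' plain CSV under `inst/extdata`, so the packaged values are inspectable and
#' diffable.
#'
#' @param block Which prior block to load: `"refined"` (the default, the
#'   post-model-development distributions) is currently the only shipped block.
#' @return A tibble, except `bpa_physchem()` which returns a named list of
#'   physicochemical constants.
#' @name qivive-data
NULL

qivive_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qivive")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname qivive-data
#' @export
bpa_priors <- function(block = "refined") {
  block <- match.arg(block)
  qivive_extdata("priors_bpa.csv")
}

#' @rdname qivive-data
#' @export
bpa_posterior_global <- function() qivive_extdata("posterior_global_bpa.csv")

#' @rdname qivive-data
#' @export
bpa_posterior_individual <- function() {
  qivive_extdata("posterior_individual_bpa.csv")
}

#' @rdname qivive-data
#' @export
bpa_posterior_sigma <- function() qivive_extdata("posterior_sigma_bpa.csv")

#' @rdname qivive-data
#' @export
bpa_sensitivity_ranking <- function() {
  qivive_extdata("sensitivity_ranking_bpa.csv")
}

#' @rdname qivive-data
#' @export
bpa_physchem <- function() {
  tab <- qivive_extdata("physchem_bpa.csv")
  as.list(stats::setNames(tab$value, tab$parameter))
}

#' @rdname qivive-data
#' @export
bpa_assays <- function() qivive_extdata("assays_bpa.csv")

#' @rdname qivive-data
#' @export
bpa_poraldose <- function() qivive_extdata("poraldose_bpa.csv")

# Molecular weights (g/mol).  The conjugates are BPA + glucuronic acid - H2O
# and BPA + SO3; used for molar bookkeeping of metabolite mass.
MW_BPA  <- 228.291
MW_BPAG <- 404.418
MW_BPAS <- 308.355

#' Molecular weights of BPA and its conjugates
#'
#' @return Named numeric vector (g/mol) for BPA, BPAG and BPAS.
#' @export
bpa_molecular_weights <- function() {
  c(BPA = MW_BPA, BPAG = MW_BPAG, BPAS = MW_BPAS)
}
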