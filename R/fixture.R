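#' Per-patient printed score table
#'
#' The packaged table of all 86 study patients: impairment label, Composite3,
#' SSHO2D and Composite5 scores, the four published predicted-label columns
#' (random forest on Composite3, linear cuts on SSHO2D and Composite5, and
#' random forest on the five-feature space F16), and demographics. Scores are
#' kept at their printed 3-decimal precision. The file checksum is verified on
#' every load; a corrupted fixture is a hard error.
#'
#' @return A data frame with 86 rows and columns \code{impaired},
#'   \code{composite3}, \code{pd_composite3_rf}, \code{ssho2d},
#'   \code{pd_ssho2d_linear}, \code{composite5}, \code{pd_composite5_linear},
#'   \code{pd_f16}, \code{age}, \code{gender}, \code{income},
#'   \code{education}, \code{race}. Income/education keep the special codes
#'   (\code{"D"}, \code{"777"}, \code{"*"}) as opaque categories.
#' @examples
#' fx <- load_printed_fixture()
#' nrow(fx)           # 86
#' sum(fx$impaired)   # 19
#' @export
load_printed_fixture <- function() {
  path <- system.file("extdata", "printed_scores.csv", package = "mycog",
                      mustWork = TRUE)
  expected <- "e4eaf994f58a59135c9c3416eebca0d7"
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected))
    stop("printed score fixture is corrupted (md5 ", got,
         ", expected ", expected, ")")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(income = "character",
                                      education = "character"))
  stopifnot(nrow(d) == 86L)
  d
}

#' Table of published composite-score coefficients
#'
#' The five composite models: an ordinary least squares fit of the 0/1
#' impairment label on a small set of score features, reported as intercept
#' plus coefficients, applied through a logistic transform. Feature naming
#' follows the score bundle convention (see \code{\link{classical_scores}}
#' and \code{\link{eap_scores}}): Composite1 uses classical scores
#' (accuracy rates for DCCS/ARW, number-correct for PSM/MFS/NSM); Composite2
#' uses the five-domain IRT scores plus total response times; Composite3/4
#' use the two-domain IRT scores (plus age for Composite3); Composite5 uses
#' the DCCS accuracy rate, the PSM number-correct and age.
#'
#' Composite2's response-time coefficients are on a millisecond scale, so it
#' cannot be applied to second-scale bundles; \code{\link{apply_composite}}
#' refuses unless \code{rt_unit = "ms"} is declared.
#'
#' @return A named list of five \code{\link{composite_model}} objects.
#' @export
load_composite_fixture <- function() {
  path <- system.file("extdata", "composite_coefficients.csv",
                      package = "mycog", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_map <- list(
    composite1 = c(arw = "rate_arw", psm = "nc_psm", nsm = "nc_nsm",
                   dccs = "rate_dccs", mfs = "nc_mfs"),
    composite2 = c(ssho = "ssho", arw = "d5_arw", psm = "d5_psm",
                   nsm = "d5_nsm", dccs = "d5_dccs", mfs = "d5_mfs",
                   arw_rt = "rt_arw", dccs_rt = "rt_dccs", psm_rt = "rt_psm"),
    composite3 = c(ssho = "ssho2d", psm = "d2_psm", dccs = "d2_dccs",
                   age = "age"),
    composite4 = c(ssho = "ssho2d", psm = "d2_psm", dccs = "d2_dccs"),
    composite5 = c(psm = "nc_psm", dccs = "rate_dccs", age = "age"))
  out <- lapply(names(feature_map), function(cn) {
    col <- d[[cn]]
    names(col) <- d$term
    fm <- feature_map[[cn]]
    coefs <- col[names(fm)]
    names(coefs) <- fm
    stopifnot(!anyNA(coefs))
    composite_model(name = cn, intercept = col[["intercept"]], coef = coefs,
                    rt_unit = if (cn == "composite2") "ms" else "s")
  })
  names(out) <- names(feature_map)
  out
}
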