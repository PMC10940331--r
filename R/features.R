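#' Encode categorical demographics as integer codes
#'
#' The published scaling: gender F=0, M=1; race Asian=0, Black=1,
#' Unreported=2, White=3; income levels 2..9 mapped to 0..7 with the special
#' code \code{"D"} as 8. Education codes are already numeric (4..11, 777);
#' the printed missing marker \code{"*"} becomes \code{NA}.
#'
#' @param x vector of codes as stored in the cohort/fixture.
#' @param what one of \code{"gender"}, \code{"race"}, \code{"income"},
#'   \code{"education"}.
#' @return Numeric codes.
#' @export
encode_demographic <- function(x, what = c("gender", "race", "income",
                                           "education")) {
  what <- match.arg(what)
  x <- as.character(x)
  out <- switch(what,
    gender = c(F = 0, M = 1)[x],
    race = c(A = 0, B = 1, U = 2, W = 3)[x],
    income = stats::setNames(c(0:7, 8), c(as.character(2:9), "D"))[x],
    education = suppressWarnings(as.numeric(ifelse(x == "*", NA, x))))
  unname(out)
}

#' Feature-space registry
#'
#' The sixteen feature spaces explored by the benchmark, named F1..F16.
#' Feature names refer to score-bundle columns: five-domain IRT scores
#' (\code{ssho}, \code{d5_*}), two-domain IRT scores (\code{ssho2d},
#' \code{d2_dccs}, \code{d2_psm}), total response times (\code{rt_*},
#' seconds), composite probabilities (\code{composite1..5}), classical
#' scores and encoded demographics.
#'
#' @return Named list of character vectors (ordered feature names).
#' @examples
#' lengths(feature_spaces())[c("F1", "F15")]  # 13 and 2
#' @export
feature_spaces <- function() {
  d5 <- c("ssho", "d5_dccs", "d5_psm", "d5_arw", "d5_mfs", "d5_nsm")
  rt3 <- c("rt_psm", "rt_arw", "rt_dccs")
  demo <- c("race", "gender", "income", "education")
  d2 <- c("ssho2d", "d2_dccs", "d2_psm")
  list(
    F1 = c(d5, rt3, demo),
    F2 = c(d5, rt3),
    F3 = c(demo, d5),
    F4 = d5,
    F5 = c(demo, d2, "rt_dccs", "rt_psm"),
    F6 = c(demo, d2),
    F7 = d2,
    F8 = "composite1",
    F9 = "composite2",
    F10 = "composite3",
    F11 = c("age", "composite4"),
    F12 = "composite5",
    F13 = c("d5_psm", "rt_psm", "age"),
    F14 = c("d5_dccs", "rt_dccs", "age"),
    F15 = c("age", "ssho2d"),
    F16 = c("age", "d2_dccs", "d2_psm", "rt_dccs", "rt_psm"))
}

#' Build a numeric feature matrix for one feature space
#'
#' @param bundle data frame of per-patient scores and demographics. The
#'   demographic columns may hold raw codes (\code{"F"}, \code{"W"},
#'   \code{"D"}, ...); they are encoded via
#'   \code{\link{encode_demographic}}.
#' @param space a feature-space name (\code{"F1"}..\code{"F16"}) or a
#'   character vector of feature names.
#' @return Numeric matrix with columns in registry order.
#' @export
build_feature_matrix <- function(bundle, space) {
  feats <- if (length(space) == 1L && space %in% names(feature_spaces()))
    feature_spaces()[[space]] else space
  spname <- if (length(space) == 1L) space else "(custom)"
  miss <- setdiff(feats, names(bundle))
  if (length(miss) > 0L)
    stop("feature space ", spname, ": missing feature(s) ",
         paste(miss, collapse = ", "))
  cols <- lapply(feats, function(f) {
    v <- bundle[[f]]
    if (f %in% c("gender", "race", "income", "education") && !is.numeric(v))
      v <- encode_demographic(v, f)
    as.numeric(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- feats
  m
}
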