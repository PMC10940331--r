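#' Construct a validated patient cohort
#'
#' A cohort bundles, for each patient: the 0/1 impairment label, demographics
#' (age in years; gender, race as categorical codes; income and education as
#' ordinal codes, with the special codes \code{"D"}, \code{"777"} and
#' \code{"*"} preserved verbatim), per-instrument binary item responses, and
#' total response times in seconds for DCCS, PSM and ARW.
#'
#' @param patients data frame with columns \code{patient_id}, \code{impaired},
#'   \code{age}, \code{gender}, \code{race}, \code{income}, \code{education}.
#' @param responses named list of 0/1/NA matrices (one per instrument, rows =
#'   patients, columns = items). Missing entries are allowed only for MFS and
#'   NSM.
#' @param rt data frame of positive total response times in seconds with
#'   columns \code{DCCS}, \code{PSM}, \code{ARW}.
#' @return An object of class \code{cog_cohort}.
#' @export
cog_cohort <- function(patients, responses, rt) {
  stopifnot(is.data.frame(patients), is.list(responses), is.data.frame(rt))
  need <- c("patient_id", "impaired", "age", "gender", "race", "income", "education")
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0L)
    stop("patients is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(patients)
  if (!all(patients$impaired %in% c(0L, 1L)))
    stop("impaired must be 0/1")
  patients$income <- as.character(patients$income)
  patients$education <- as.character(patients$education)
  sp <- instrument_specs()
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]
    m <- responses[[nm]]
    if (is.null(m)) stop("responses is missing instrument ", nm)
    m <- as.matrix(m)
    if (nrow(m) != n)
      stop("response matrix for ", nm, " has ", nrow(m), " rows; expected ", n)
    if (ncol(m) != sp$n_items[i])
      stop("instrument ", nm, ": expected ", sp$n_items[i],
           " items, got ", ncol(m))
    vals <- m[!is.na(m)]
    if (!all(vals %in% c(0, 1)))
      stop("instrument ", nm, ": responses must be 0, 1 or missing")
    if (!sp$allows_missing[i] && anyNA(m))
      stop("instrument ", nm, " does not allow missing responses")
    storage.mode(m) <- "integer"
    colnames(m) <- paste0(nm, "_", seq_len(ncol(m)))
    responses[[nm]] <- m
  }
  for (nm in rt_instruments()) {
    if (is.null(rt[[nm]])) stop("rt is missing instrument ", nm)
    if (nrow(rt) != n) stop("rt has ", nrow(rt), " rows; expected ", n)
    if (any(!is.finite(rt[[nm]])) || any(rt[[nm]] <= 0))
      stop("rt for ", nm, " must be positive and finite")
  }
  structure(
    list(patients = patients,
         responses = responses[sp$name],
         rt = rt[rt_instruments()]),
    class = "cog_cohort")
}

#' @export
print.cog_cohort <- function(x, ...) {
  n <- nrow(x$patients)
  cat("Cognitive screening cohort: ", n, " patients (",
      sum(x$patients$impaired), " impaired)\n", sep = "")
  sp <- instrument_specs()
  for (nm in sp$name) {
    m <- x$responses[[nm]]
    cat(sprintf("  %-4s %3d items, %5.1f%% missing\n", nm, ncol(m),
                100 * mean(is.na(m))))
  }
  invisible(x)
}

#' @export
length.cog_cohort <- function(x) nrow(x$patients)

cohort_columns <- function() {
  sp <- instrument_specs()
  resp_cols <- unlist(lapply(seq_len(nrow(sp)), function(i)
    paste0(sp$name[i], "_", seq_len(sp$n_items[i]))))
  c("patient_id", "impaired", "age", "gender", "race", "income", "education",
    paste0("rt_", rt_instruments()), resp_cols)
}

#' Read a cohort from CSV
#'
#' One row per patient; item responses live in contiguous columns named
#' \code{<instrument>_<item>} (1-based), missing responses are empty cells,
#' and total response times in \code{rt_DCCS}, \code{rt_PSM}, \code{rt_ARW}.
#' This is the same dialect \code{\link{write_cohort_csv}} emits, so
#' write-then-read is the identity on validated cohorts.
#'
#' @param path CSV file path.
#' @return A \code{\link{cog_cohort}}.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(patient_id = "character",
                                      income = "character",
                                      education = "character"),
                       check.names = FALSE)
  if (nrow(d) == 0L) return(empty_cohort())
  need <- cohort_columns()
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("cohort CSV is missing column(s): ", paste(utils::head(miss, 5), collapse = ", "))
  sp <- instrument_specs()
  responses <- list()
  for (i in seq_len(nrow(sp))) {
    nm <- sp$name[i]
    cols <- paste0(nm, "_", seq_len(sp$n_items[i]))
    m <- as.matrix(d[cols])
    bad <- which(!(m %in% c(0, 1)) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop("malformed response in row ", bad[1, 1], ", column ",
           cols[bad[1, 2]])
    responses[[nm]] <- m
  }
  rt <- d[paste0("rt_", rt_instruments())]
  names(rt) <- rt_instruments()
  cog_cohort(d[c("patient_id", "impaired", "age", "gender", "race",
                 "income", "education")],
             responses, rt)
}

empty_cohort <- function() {
  sp <- instrument_specs()
  responses <- lapply(seq_len(nrow(sp)), function(i)
    matrix(integer(0), 0, sp$n_items[i]))
  names(responses) <- sp$name
  p <- data.frame(patient_id = character(0), impaired = integer(0),
                  age = integer(0), gender = character(0), race = character(0),
                  income = character(0), education = character(0),
                  stringsAsFactors = FALSE)
  rt <- data.frame(DCCS = numeric(0), PSM = numeric(0), ARW = numeric(0))
  structure(list(patients = p, responses = responses, rt = rt),
            class = "cog_cohort")
}

#' Write a cohort to CSV
#'
#' @param cohort a \code{\link{cog_cohort}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cog_cohort"))
  rt <- cohort$rt
  names(rt) <- paste0("rt_", names(rt))
  d <- cbind(cohort$patients, rt,
             as.data.frame(do.call(cbind, unname(cohort$responses))))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Stack the per-instrument response matrices into one matrix
#'
#' @param cohort a \code{\link{cog_cohort}}.
#' @param instruments instrument names to include (default all five).
#' @return An n x J 0/1/NA integer matrix with an \code{"domain"} attribute
#'   giving each column's instrument as a factor.
#' @export
response_matrix <- function(cohort, instruments = instrument_names()) {
  stopifnot(inherits(cohort, "cog_cohort"))
  m <- do.call(cbind, cohort$responses[instruments])
  domain <- factor(rep(instruments,
                       vapply(cohort$responses[instruments], ncol, 0L)),
                   levels = instruments)
  attr(m, "domain") <- domain
  m
}
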