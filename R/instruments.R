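#' Instrument registry
#'
#' The five cognitive instruments of the MyCog / Mobile Toolbox battery and
#' their fixed item counts: Dimensional Change Card Sort (DCCS, cognitive
#' flexibility, 30 items), Picture Sequence Memory (PSM, episodic memory,
#' 12 items), Arrow Matching (ARW, inhibitory control, 50 items), Sequences
#' (MFS, working memory, 30 items) and Number-Symbol Match (NSM, processing
#' speed, 144 items). MFS and NSM administer items until a stopping rule or
#' the time limit hits, so unattempted items are recorded as missing; the
#' other three instruments never contain missing responses. Total response
#' times (seconds) are collected for DCCS, PSM and ARW.
#'
#' @return A data frame with one row per instrument and columns
#'   \code{name}, \code{n_items}, \code{allows_missing}, \code{has_rt}.
#' @examples
#' instrument_specs()
#' @export
instrument_specs <- function() {
  data.frame(
    name = c("DCCS", "PSM", "ARW", "MFS", "NSM"),
    n_items = c(30L, 12L, 50L, 30L, 144L),
    allows_missing = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    has_rt = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

instrument_names <- function() instrument_specs()$name

rt_instruments <- function() {
  sp <- instrument_specs()
  sp$name[sp$has_rt]
}
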