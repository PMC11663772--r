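#' Relative change in HDRS from baseline to follow-up
#'
#' The Hamilton Depression Rating Scale (HDRS, 17-item) ranges 0-52. The
#' relative change is `(baseline - followup) / baseline`; positive values
#' mean symptomatic improvement.
#'
#' @param baseline,followup HDRS scores in `[0, 52]`; `baseline` must be > 0.
#' @return Numeric vector of relative changes (vectorised).
#' @export
#' @examples
#' relative_change(24, 12) # 0.5
relative_change <- function(baseline, followup) {
  check_hdrs(baseline); check_hdrs(followup)
  if (any(baseline == 0, na.rm = TRUE))
    stop("relative change undefined for baseline HDRS of 0")
  (baseline - followup) / baseline
}

#' Label 6-month treatment outcome from HDRS scores
#'
#' A subject with a reduction of at least 50% in HDRS relative to baseline
#' is labeled a positive outcome (`"PO"`), otherwise a negative outcome
#' (`"NO"`). The 50% boundary is inclusive.
#'
#' @inheritParams relative_change
#' @return Factor with levels `c("PO", "NO")`, `NA` where follow-up is
#'   missing (such subjects are dropped from outcome analyses).
#' @export
#' @examples
#' label_outcome(c(24, 20, 18), c(12, 11, 0)) # PO NO PO
label_outcome <- function(baseline, followup) {
  rc <- relative_change(baseline, followup)
  factor(ifelse(rc >= 0.5, "PO", "NO"), levels = c("PO", "NO"))
}

check_hdrs <- function(x) {
  if (any(x < 0 | x > 52, na.rm = TRUE))
    stop("HDRS scores must lie in [0, 52]")
  invisible(x)
}
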