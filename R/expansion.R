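#' Classify acute hematoma expansion
#'
#' Expansion is a relative growth of at least 30% **or** an absolute growth
#' of at least 5 mL from the baseline scan; both thresholds are inclusive.
#' Vectorised over scans.
#'
#' @param baselineML baseline total hematoma volume(s), mL; must be positive
#'   (volumes below 2 mL are excluded upstream by the eligibility filter).
#' @param followupML follow-up total volume(s), mL.
#' @return data.frame with columns `baselineML`, `followupML`,
#'   `relativeGrowth` (fraction), `absoluteGrowthML` and `expanded`.
#' @examples
#' classifyExpansion(10, 13)$expanded   # TRUE, exactly 30% growth
#' classifyExpansion(40, 46)$expanded   # TRUE, 6 mL despite only 15%
#' classifyExpansion(10, 12.9)$expanded # FALSE, 29% and 2.9 mL
#' @export
classifyExpansion <- function(baselineML, followupML) {
  if (length(baselineML) != length(followupML))
    stop("baseline and follow-up volumes must have equal length")
  if (any(!is.finite(baselineML)) || any(!is.finite(followupML)))
    stop("volumes must be finite")
  if (any(baselineML <= 0))
    stop("baseline volume must be positive")
  rel <- (followupML - baselineML) / baselineML
  abs_ <- followupML - baselineML
  data.frame(baselineML = baselineML, followupML = followupML,
             relativeGrowth = rel, absoluteGrowthML = abs_,
             expanded = rel >= 0.30 | abs_ >= 5.0)
}

#' Write expansion calls as JSON
#'
#' @param calls data.frame from [classifyExpansion()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpansionCalls <- function(calls, path) {
  jsonlite::write_json(calls, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
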