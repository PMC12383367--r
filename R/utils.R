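# Internal helpers shared across modules.

#' Circular mean of clock times
#'
#' Mean of times on a circle of the given period, mapped back to
#' `[0, period)`. Used to average acrophase estimates, where ordinary
#' arithmetic means are biased near the period boundary.
#'
#' @param x numeric vector of times in hours.
#' @param period circle period in hours (default 24).
#' @return a single value in `[0, period)`.
#' @export
circular_mean_hours <- function(x, period = 24) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  w <- 2 * pi / period
  (atan2(mean(sin(w * x)), mean(cos(w * x))) / w) %% period
}

#' Strip a species prefix from miRNA identifiers
#'
#' Removes a leading three-letter species code (e.g. `rno-`, `hsa-`)
#' from miRNA ids, so rat identifiers can be matched against
#' human-indexed target tables.
#'
#' @param ids character vector of miRNA identifiers.
#' @return character vector with any leading `xxx-` prefix removed.
#' @export
strip_species_prefix <- function(ids) {
  sub("^[a-z]{3}-", "", ids)
}

#' Derive the miRNA family id from a mature arm id
#'
#' Drops a trailing `-5p`/`-3p` arm suffix, so the two arms of a duplex
#' map to a common family label (e.g. `miR-150-5p` -> `miR-150`).
#'
#' @param mature_id character vector of mature miRNA ids.
#' @return character vector of family ids.
#' @export
mirna_family <- function(mature_id) {
  sub("-[35]p$", "", mature_id)
}

# stop() with a consistent prefix so callers can distinguish validation
# failures from R-level errors.
format_error <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
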