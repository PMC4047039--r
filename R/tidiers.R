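# broom-style accessors for the result objects.

strip_profile <- function(x) {
  out <- as_tibble(x)
  attr(out, "totals") <- NULL
  attr(out, "matches") <- NULL
  attr(out, "released") <- NULL
  attr(out, "total_released") <- NULL
  attr(out, "counting") <- NULL
  attr(out, "total_mg_per_day") <- NULL
  class(out) <- class(tibble())
  out
}

#' @describeIn scan_intact Per-category rows as a plain tibble.
#' @param x An `intact_profile`.
#' @param ... Unused.
#' @method tidy intact_profile
#' @export
tidy.intact_profile <- function(x, ...) strip_profile(x)

#' @describeIn scan_intact Per-protein totals: `total_count` (occurrences
#'   over all activity categories) and `overall_freq_A`.
#' @method glance intact_profile
#' @export
glance.intact_profile <- function(x, ...) attr(x, "totals")

#' @describeIn match_digest Per-category counts as a plain tibble.
#' @param x A `digest_profile`.
#' @param ... Unused.
#' @method tidy digest_profile
#' @export
tidy.digest_profile <- function(x, ...) strip_profile(x)

#' @describeIn match_digest One-row tibble with `total_released`.
#' @method glance digest_profile
#' @export
glance.digest_profile <- function(x, ...) {
  tibble(total_released = attr(x, "total_released"))
}

#' @describeIn profile_digest Per-category counts as a plain tibble.
#' @param x A `scenario_profile`.
#' @param ... Unused.
#' @method tidy scenario_profile
#' @export
tidy.scenario_profile <- function(x, ...) strip_profile(x)

#' @describeIn profile_digest Per-protein totals with `total_released`
#'   and `freq_AD`.
#' @method glance scenario_profile
#' @export
glance.scenario_profile <- function(x, ...) attr(x, "totals")

#' @describeIn daily_total Per-item rows as a plain tibble.
#' @param x A `quantity_estimate`.
#' @param ... Unused.
#' @method tidy quantity_estimate
#' @export
tidy.quantity_estimate <- function(x, ...) strip_profile(x)

#' @describeIn daily_total One-row tibble with `total_mg_per_day`.
#' @method glance quantity_estimate
#' @export
glance.quantity_estimate <- function(x, ...) {
  tibble(total_mg_per_day = attr(x, "total_mg_per_day"))
}
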