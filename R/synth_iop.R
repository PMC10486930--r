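# Synthetic intraocular pressure time courses.
#
# Microbead occlusion elevates IOP with a peak near day 7 followed by a
# gradual return to baseline; saline-injected eyes stay at baseline. The
# deterministic microbead shape is a gamma-like pulse
#   baseline + amplitude * (t/peak_day) * exp(1 - t/peak_day)
# whose argmax is exactly `peak_day`. Defaults: baseline 15 mmHg (mouse
# rebound tonometry), amplitude 10 mmHg (peak ~25 mmHg), measurements twice
# weekly over one month.

#' Generate a synthetic IOP time series
#'
#' @param profile `"saline"` (stationary at baseline) or `"microbead"`
#'   (pulse peaking at `peak_day`, decaying toward baseline).
#' @param days measurement days (>= 2 values, strictly increasing).
#' @param baseline_mmHg baseline pressure (default 15).
#' @param amplitude_mmHg peak elevation above baseline (default 10).
#' @param peak_day day of maximal elevation (default 7).
#' @param noise_sd measurement noise sigma in mmHg (default 0).
#' @param label eye/group label stored with the series.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return an `iop_series`: data.frame with columns `day`, `iop`, `group`.
#' @examples
#' make_iop_series("microbead", noise_sd = 0)
#' @export
make_iop_series <- function(profile = c("saline", "microbead"),
                            days = c(0, 3, 7, 10, 14, 17, 21, 24, 28),
                            baseline_mmHg = 15, amplitude_mmHg = 10,
                            peak_day = 7, noise_sd = 0, label = NULL,
                            seed = NULL) {
  profile <- match.arg(profile)
  if (length(days) < 2L || any(diff(days) <= 0))
    stop_gq("days must be >= 2 strictly increasing values")
  if (noise_sd > 0 && is.null(seed))
    stop_gq("a seed is required when noise_sd > 0")
  mu <- if (profile == "saline") rep(baseline_mmHg, length(days)) else
    baseline_mmHg + amplitude_mmHg * (days / peak_day) * exp(1 - days / peak_day)
  iop <- with_seed(seed, mu + if (noise_sd > 0) rnorm(length(days), 0, noise_sd) else 0)
  iop <- pmax(iop, 1)                    # pressures stay physical
  structure(data.frame(day = days, iop = iop,
                       group = label %||% profile),
            class = c("iop_series", "data.frame"))
}
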