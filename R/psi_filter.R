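# PSI computation and the retention filter.

#' Retention-filter configuration
#'
#' Defaults reproduce the census thresholds: an event is retained in a sample
#' when 0.1 < PSI < 0.9 (strict) and its skipping junction count is >= 5.
#'
#' @param psi_low,psi_high open PSI interval bounds.
#' @param min_sjc minimum skipping junction count (inclusive).
#' @param normalized use the form-length-normalized PSI (rMATS convention,
#'   default) or the raw `ijc/(ijc+sjc)` ratio.
#' @return a `filter_config` list.
#' @export
filter_config <- function(psi_low = 0.1, psi_high = 0.9, min_sjc = 5,
                          normalized = TRUE) {
  stopifnot(psi_low >= 0, psi_low < psi_high, psi_high <= 1, min_sjc >= 0)
  structure(list(psi_low = psi_low, psi_high = psi_high, min_sjc = min_sjc,
                 normalized = normalized),
            class = "filter_config")
}

#' Percent spliced in from junction counts
#'
#' PSI is the form-length-normalized inclusion fraction
#' \deqn{\psi = \frac{I/l_I}{I/l_I + S/l_S}}
#' where \eqn{I} and \eqn{S} are the inclusion and skipping junction counts
#' and \eqn{l_I}, \eqn{l_S} the effective form lengths of the two isoforms.
#' With `normalized = FALSE` the raw ratio `ijc/(ijc+sjc)` is used instead.
#' PSI is missing (`NA`) when a sample has no junction reads at all.
#'
#' @param ijc,sjc non-negative inclusion/skipping junction counts (vectors).
#' @param inc_form_len,skip_form_len positive effective form lengths.
#' @param normalized apply form-length normalization (default `TRUE`).
#' @return numeric vector of PSI values in `[0, 1]`, `NA` where `ijc+sjc = 0`.
#' @export
compute_psi <- function(ijc, sjc, inc_form_len, skip_form_len,
                        normalized = TRUE) {
  if (any(ijc < 0, na.rm = TRUE) || any(sjc < 0, na.rm = TRUE))
    stopf("junction counts must be non-negative")
  if (any(inc_form_len <= 0) || any(skip_form_len <= 0))
    stopf("form lengths must be positive")
  if (normalized) {
    inc <- ijc / inc_form_len
    skp <- sjc / skip_form_len
  } else {
    inc <- ijc
    skp <- sjc
  }
  psi <- inc / (inc + skp)
  psi[ijc + sjc == 0] <- NA_real_
  psi
}

#' Apply the retention filter per sample
#'
#' Retention is decided independently in every sample: an (event, sample) row
#' survives iff `psi_low < psi < psi_high` (both strict) and
#' `sjc >= min_sjc`. Events with missing PSI (zero junction coverage) are
#' dropped, never imputed. One event can therefore be retained in some
#' samples and dropped in others.
#'
#' @param events long events table (see [read_rmats_table()]).
#' @param config a [filter_config()].
#' @return the retained subset of `events` (same columns); with
#'   `config$normalized = FALSE` PSI is recomputed unnormalized first.
#' @export
filter_events <- function(events, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  ev <- as.data.table(events)
  if (!config$normalized)
    ev <- copy(ev)[, psi := compute_psi(ijc, sjc, inc_form_len, skip_form_len,
                                        normalized = FALSE)]
  keep <- !is.na(ev$psi) &
    ev$psi > config$psi_low & ev$psi < config$psi_high &
    ev$sjc >= config$min_sjc
  ev[keep]
}
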