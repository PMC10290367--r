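#' Torsional stiffness from a torque-rotation trace
#'
#' Ordinary least-squares slope of torque against rotation, restricted to
#' loading-ramp samples whose torque lies inside the regression window
#' (default 6-10 Nm, which excludes the settling toe region). Unloading
#' samples, if present, are discarded by truncating at the torque maximum.
#'
#' @param trace `ovtr_trace` (or list with `rotation`, `torque`).
#' @param window Torque window `c(low, high)` in Nm; default `c(6, 10)`.
#' @param fallback_window Optional window tried when the primary window is
#'   unreachable (off by default; its use is recorded in the
#'   `window_used` attribute).
#' @return Stiffness (Nm/deg) with attributes `window_used` and
#'   `n_points`.
#' @export
stiffness_from_trace <- function(trace, window = c(6, 10),
                                 fallback_window = NULL) {
  rot <- trace$rotation
  tq <- trace$torque
  stopifnot(length(rot) == length(tq), length(rot) >= 2)
  if (is.unsorted(rot)) stop("rotation samples must be non-decreasing")
  ramp <- seq_len(which.max(tq))     # loading ramp only
  rot <- rot[ramp]; tq <- tq[ramp]
  fit_in <- function(win) {
    sel <- tq >= win[1] & tq <= win[2]
    if (sum(sel) < 3) return(NULL)
    x <- rot[sel]; y <- tq[sel]
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    structure(slope, window_used = win, n_points = sum(sel))
  }
  res <- fit_in(window)
  if (is.null(res) && !is.null(fallback_window))
    res <- fit_in(fallback_window)
  if (is.null(res))
    stop_ovtr(sprintf(
      "regression window [%g, %g] Nm unreachable: trace maximum torque %.3g Nm",
      window[1], window[2], max(tq)), "ovtr_window_unreachable")
  res
}

#' Torsional rigidity from stiffness
#'
#' The Nm/deg to Nm^2/deg conversion multiplies by a physical gauge
#' length. The gauge is a required per-study configuration value, making
#' the unit system explicit and auditable.
#'
#' @param stiffness Torsional stiffness (Nm/deg).
#' @param gauge_length Gauge length (mm).
#' @return Rigidity (Nm^2/deg).
#' @export
rigidity_from_stiffness <- function(stiffness, gauge_length) {
  stopifnot(gauge_length > 0)
  as.numeric(stiffness) * gauge_length / 1000
}

#' Contralateral-normalised rigidity
#'
#' @param operated Operated-limb rigidity (Nm^2/deg).
#' @param contralateral Non-operated contralateral rigidity (Nm^2/deg),
#'   must be positive.
#' @return Percentage `100 * operated / contralateral`.
#' @export
normalize_rigidity <- function(operated, contralateral) {
  if (any(contralateral <= 0))
    stop_ovtr("contralateral rigidity must be positive", "ovtr_invalid_input")
  100 * operated / contralateral
}

#' Full biomechanical analysis of one torsion trace
#'
#' Convenience wrapper: stiffness from the regression window, rigidity via
#' the gauge length, and optional contralateral normalisation.
#'
#' @inheritParams stiffness_from_trace
#' @param gauge_length Gauge length (mm).
#' @param contralateral Optional contralateral rigidity (Nm^2/deg).
#' @return List with `stiffness`, `rigidity`, `normalized` (or `NA`),
#'   `window_used`, `n_points_in_window`.
#' @export
analyze_trace <- function(trace, gauge_length, window = c(6, 10),
                          contralateral = NULL, fallback_window = NULL) {
  k <- stiffness_from_trace(trace, window, fallback_window)
  rig <- rigidity_from_stiffness(k, gauge_length)
  list(stiffness = as.numeric(k), rigidity = rig,
       normalized = if (is.null(contralateral)) NA_real_ else
         normalize_rigidity(rig, contralateral),
       window_used = attr(k, "window_used"),
       n_points_in_window = attr(k, "n_points"))
}
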