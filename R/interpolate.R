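#' Interpolate slow-grid output observations onto the fast input grid
#'
#' Output variables assayed offline (e.g. hourly) are interpolated to the fast
#' sensor grid so that every input row has a matching output row. Observed
#' rows are preserved exactly; only unobserved rows are filled. The default is
#' piecewise linear interpolation; a cubic (natural spline) alternative is
#' available. Extrapolation beyond the first/last observation is refused
#' unless explicitly requested.
#'
#' @param batch A [batch_ts()] object.
#' @param method `"linear"` (default) or `"cubic"`.
#' @param extrapolate Allow filling rows outside the observed time range
#'   (constant for linear via `rule = 2`, spline extension for cubic).
#' @return The batch with `y` defined on the full grid; `y_observed` unchanged.
#' @export
interpolate_outputs <- function(batch, method = c("linear", "cubic"),
                                extrapolate = FALSE) {
  method <- match.arg(method)
  b <- batch
  obs <- which(b$y_observed)
  if (length(obs) < 2L) {
    stop("batch '", b$batch_id, "': need at least 2 observations to interpolate")
  }
  todo <- which(!b$y_observed)
  if (!length(todo)) return(b)
  if (!extrapolate && (min(todo) < min(obs) || max(todo) > max(obs))) {
    stop("batch '", b$batch_id, "': unobserved rows outside the observed ",
         "range; pass extrapolate = TRUE to allow extrapolation")
  }
  t_all <- seq_len(nrow(b$y))
  for (ch in colnames(b$y)) {
    fill <- if (method == "linear") {
      stats::approx(t_all[obs], b$y[obs, ch], xout = t_all[todo],
                    method = "linear", rule = if (extrapolate) 2 else 1)$y
    } else {
      stats::spline(t_all[obs], b$y[obs, ch], xout = t_all[todo],
                    method = "natural")$y
    }
    b$y[todo, ch] <- fill
  }
  b
}
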