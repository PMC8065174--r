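#' Time-dependent parameter schedules
#'
#' Schedules map time to per-neuron pump or bias values during a simulation.
#' Three shapes are supported: constant, linear ramp over the full run, and a
#' tabulated piecewise-linear curve. Values are held constant beyond the last
#' knot. Scalar values are recycled across neurons.
#'
#' @param value,from,to per-neuron values (scalars recycled).
#' @param times increasing knot times for [schedule_table()].
#' @param values numeric vector (one curve shared by all neurons) or
#'   n x length(times) matrix of knot values.
#' @return An object of class `dopo_schedule`.
#' @examples
#' schedule_linear(-0.5, 3.2)   # pump ramp across the spiking region
#' @export
schedule_constant <- function(value) {
  stopifnot(all(is.finite(value)))
  structure(list(kind = "constant", value = value), class = "dopo_schedule")
}

#' @rdname schedule_constant
#' @export
schedule_linear <- function(from, to) {
  stopifnot(all(is.finite(from)), all(is.finite(to)))
  structure(list(kind = "linear", from = from, to = to), class = "dopo_schedule")
}

#' @rdname schedule_constant
#' @export
schedule_table <- function(times, values) {
  times <- as.numeric(times)
  if (length(times) < 1 || is.unsorted(times, strictly = TRUE))
    stop("schedule times must be strictly increasing")
  if (is.matrix(values)) {
    if (ncol(values) != length(times)) stop("values must have one column per time")
  } else {
    if (length(values) != length(times)) stop("values must match times in length")
  }
  stopifnot(all(is.finite(values)))
  structure(list(kind = "table", times = times, values = values),
            class = "dopo_schedule")
}

# resolve a schedule to knot form (times vector, n x k value matrix) over
# [0, duration]; `fallback` is the constant per-neuron value used when sched
# is NULL.
resolve_schedule <- function(sched, n, duration, fallback) {
  if (is.null(sched)) sched <- schedule_constant(fallback)
  if (!inherits(sched, "dopo_schedule")) stop("not a dopo_schedule")
  switch(sched$kind,
    constant = list(times = 0,
                    values = matrix(rep_len(sched$value, n), n, 1)),
    linear = list(times = c(0, duration),
                  values = cbind(rep_len(sched$from, n), rep_len(sched$to, n))),
    table = {
      if (min(sched$times) > 0 || max(sched$times) < duration)
        stop("tabulated schedule must cover [0, duration]")
      v <- sched$values
      if (!is.matrix(v)) v <- matrix(v, n, length(sched$times), byrow = TRUE)
      if (nrow(v) != n) stop("schedule values have wrong number of neurons")
      list(times = sched$times, values = v)
    })
}

# evaluate resolved knots at arbitrary times -> n x length(t) matrix
eval_schedule_knots <- function(knots, t) {
  n <- nrow(knots$values)
  out <- matrix(NA_real_, n, length(t))
  for (i in seq_len(n)) {
    if (length(knots$times) == 1) out[i, ] <- knots$values[i, 1]
    else out[i, ] <- stats::approx(knots$times, knots$values[i, ], xout = t,
                                   rule = 2)$y
  }
  out
}
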