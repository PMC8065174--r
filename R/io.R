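#' Write simulation products as plain-text files
#'
#' Long-format CSV writers for trajectories (time, neuron, v, w), polar
#' trajectories (time, neuron, theta, R), spike trains (neuron, spike_time),
#' and annealing traces (time, E_Ising). Numbers are written with 9
#' significant digits.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "dopo_trajectory"))
  n <- nrow(x$v)
  df <- data.frame(time = rep(x$times, each = n),
                   neuron = rep(seq_len(n), length(x$times)),
                   v = as.vector(x$v), w = as.vector(x$w))
  write_csv9(df, path)
}

#' @rdname write_trajectory_csv
#' @export
write_polar_csv <- function(x, path) {
  stopifnot(inherits(x, "dopo_polar"))
  n <- nrow(x$theta)
  df <- data.frame(time = rep(x$times, each = n),
                   neuron = rep(seq_len(n), length(x$times)),
                   theta = as.vector(x$theta))
  if (!is.null(x$R)) df$R <- as.vector(x$R)
  write_csv9(df, path)
}

#' @rdname write_trajectory_csv
#' @export
write_spikes_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  df <- do.call(rbind, lapply(seq_along(x$spike_times), function(i) {
    if (length(x$spike_times[[i]]) == 0) return(NULL)
    data.frame(neuron = i, spike_time = x$spike_times[[i]])
  }))
  if (is.null(df)) df <- data.frame(neuron = integer(), spike_time = numeric())
  write_csv9(df, path)
}

#' @rdname write_trajectory_csv
#' @export
write_energy_csv <- function(x, path) {
  stopifnot(inherits(x, "dopo_anneal"))
  write_csv9(data.frame(time = x$energy_times, E_Ising = x$energy_trace),
             path)
}

#' Serialize a phase diagram
#'
#' The grid goes to CSV (P_tilde, I_ext_tilde, omega_tilde, region counts);
#' the bifurcation boundary point sets go to a JSON file.
#'
#' @param x a `dopo_phase_diagram`.
#' @param csv_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_phase_diagram <- function(x, csv_path, json_path) {
  stopifnot(inherits(x, "dopo_phase_diagram"))
  write_csv9(x$grid, csv_path)
  jsonlite::write_json(list(ah = x$ah_boundary, snlc = x$snlc_boundary),
                       json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}

write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @param params optional `dopo_params` to attach (defaults to unit-frequency
#'   neurons, which is correct for all default-unit runs).
#' @return a `dopo_trajectory`.
#' @export
read_trajectory_csv <- function(path, params = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "neuron", "v", "w") %in% names(df)))
  times <- sort(unique(df$time))
  n <- max(df$neuron)
  o <- order(df$time, df$neuron)
  df <- df[o, ]
  structure(list(times = times,
                 v = matrix(df$v, n, length(times)),
                 w = matrix(df$w, n, length(times)),
                 params = params %||% neuron_params(n),
                 coupling = NULL, config = NULL, schedules = NULL),
            class = "dopo_trajectory")
}
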