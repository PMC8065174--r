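#' Build a clustered Kuramoto-style DOPO network
#'
#' Constructs the clustered ensemble: `n_clusters` all-to-all connected
#' clusters of `cluster_size` neurons each, sparsely linked by a configurable
#' number of random inter-cluster edges. The coupling is encoded into both
#' the v- and w-equations (`gamma == gamma_prime == J_k`). Per-neuron pumps
#' come from [assign_pump_spread()]: clusters are labelled A, B, C, ... in
#' descending order of intrinsic firing rate (ascending pump, since the
#' spiking frequency decreases with pump).
#'
#' @param n_clusters number of clusters (default 4).
#' @param cluster_size neurons per cluster (default 15).
#' @param J_k coupling scale applied to the whole matrix.
#' @param inter_edges_per_pair random edges linking each pair of clusters
#'   (default 2; 0 for isolated clusters).
#' @param inter_strength relative weight of inter-cluster edges (default 1).
#' @param P_tilde_centers per-cluster centre of the dimensionless pump
#'   (default evenly spaced over \[0.6, 1.8\]).
#' @param P_tilde_spread within-cluster pump spread (default 0.22; neurons
#'   get evenly spaced values centre +/- spread/2).
#' @param omega0 natural frequency (default 1).
#' @param seed seed for the random inter-cluster edges.
#' @return list with `coupling` (a `dopo_coupling`), `params`
#'   (a `dopo_params`), and `membership` (cluster factor, levels A, B, ...).
#' @export
clustered_network <- function(n_clusters = 4, cluster_size = 15, J_k = 0.025,
                              inter_edges_per_pair = 2, inter_strength = 1,
                              P_tilde_centers = NULL, P_tilde_spread = 0.22,
                              omega0 = 1, seed = 1) {
  stopifnot(n_clusters >= 1, cluster_size >= 1)
  n <- n_clusters * cluster_size
  membership <- factor(rep(LETTERS[seq_len(n_clusters)], each = cluster_size))
  J <- matrix(0, n, n)
  for (c in seq_len(n_clusters)) {
    rows <- which(membership == levels(membership)[c])
    J[rows, rows] <- 1
  }
  diag(J) <- 0
  if (n_clusters > 1 && inter_edges_per_pair > 0) {
    with_seed(seed, {
      for (a in seq_len(n_clusters - 1)) for (b in (a + 1):n_clusters) {
        ra <- which(membership == levels(membership)[a])
        rb <- which(membership == levels(membership)[b])
        for (e in seq_len(inter_edges_per_pair)) {
          i <- sample(ra, 1)
          j <- sample(rb, 1)
          J[i, j] <- inter_strength
          J[j, i] <- inter_strength
        }
      }
    })
  }
  P_tilde <- assign_pump_spread(n, n_clusters = n_clusters,
                                P_tilde_centers = P_tilde_centers,
                                P_tilde_spread = P_tilde_spread)
  list(coupling = network_coupling(J, gamma = J_k, gamma_prime = J_k),
       params = neuron_params(n, P_tilde = P_tilde,
                              J_vw = -omega0, J_wv = omega0),
       membership = membership)
}

#' Per-neuron pump assignment controlling the firing-rate spread
#'
#' Distributes dimensionless pump values over clustered neurons so that the
#' intrinsic spiking frequencies `omega(P)` are spread by design: cluster
#' centres ascend in pump (hence descend in firing rate, labelling clusters
#' A, B, ... from fastest to slowest), and neurons within a cluster get
#' evenly spaced values around the centre.
#'
#' @param n_neurons total neuron count (multiple of `n_clusters`).
#' @param n_clusters number of clusters (default 4).
#' @param P_tilde_centers per-cluster centres; default evenly spaced over
#'   \[0.6, 1.8\] (single cluster: 1.0).
#' @param P_tilde_spread within-cluster spread (default 0.22; 0 for
#'   identical pumps).
#' @return numeric vector of per-neuron dimensionless pump values, grouped
#'   by cluster.
#' @export
assign_pump_spread <- function(n_neurons, n_clusters = 4,
                               P_tilde_centers = NULL,
                               P_tilde_spread = 0.22) {
  stopifnot(n_neurons %% n_clusters == 0)
  cluster_size <- n_neurons / n_clusters
  if (is.null(P_tilde_centers))
    P_tilde_centers <- if (n_clusters == 1) 1.0
      else seq(0.6, 1.8, length.out = n_clusters)
  stopifnot(length(P_tilde_centers) == n_clusters)
  P <- unlist(lapply(P_tilde_centers, function(mu) {
    if (cluster_size == 1) mu
    else seq(mu - P_tilde_spread / 2, mu + P_tilde_spread / 2,
             length.out = cluster_size)
  }))
  if (any(P <= 0 | P >= sqrt(8)))
    stop("requested pump values leave the spiking domain (0, sqrt(8))")
  P
}

#' Random Ising instance
#'
#' Erdos-Renyi-style symmetric instance: each of the C(n, 2) edges is
#' present independently with probability `density`; present edges get
#' weight +1/-1 equiprobably (default) or uniform on \[-1, 1\].
#' Reproducible from `seed`.
#'
#' @param n number of spins (>= 2).
#' @param density edge probability in (0, 1\].
#' @param weights `"pm1"` (default) or `"uniform"`.
#' @param seed integer seed.
#' @return An object of class `ising_instance`: list with `n`, `J` (n x n
#'   symmetric, zero diagonal), `density` (realized), `target_density`,
#'   `weights`, `seed`.
#' @export
random_ising_instance <- function(n, density = 0.5,
                                  weights = c("pm1", "uniform"), seed = 1) {
  weights <- match.arg(weights)
  stopifnot(n >= 2, density > 0, density <= 1)
  n <- as.integer(n)
  m_possible <- n * (n - 1) / 2
  J <- matrix(0, n, n)
  with_seed(seed, {
    up <- which(upper.tri(J))
    present <- up[stats::runif(length(up)) < density]
    if (length(present) == 0)
      stop("density too low: the sampled instance has no edges")
    w <- if (weights == "pm1") sample(c(-1, 1), length(present), replace = TRUE)
         else stats::runif(length(present), -1, 1)
    J[present] <- w
  })
  J <- J + t(J)
  structure(list(n = n, J = J,
                 density = sum(J[upper.tri(J)] != 0) / m_possible,
                 target_density = density, weights = weights, seed = seed),
            class = "ising_instance")
}

#' Wrap an explicit coupling matrix as an Ising instance
#'
#' @param J symmetric matrix with zero diagonal.
#' @return an `ising_instance`.
#' @export
ising_instance <- function(J) {
  J <- as.matrix(J)
  cp <- network_coupling(J)   # validation: square, symmetric, zero diagonal
  n <- cp$n_neurons
  structure(list(n = n, J = cp$J,
                 density = if (n > 1) sum(J[upper.tri(J)] != 0) /
                   (n * (n - 1) / 2) else 0,
                 target_density = NA_real_, weights = "explicit",
                 seed = NA_integer_),
            class = "ising_instance")
}

#' @export
print.ising_instance <- function(x, ...) {
  cat("Ising instance:", x$n, "spins,",
      sum(x$J[upper.tri(x$J)] != 0), "edges",
      sprintf("(density %.3f)\n", x$density))
  invisible(x)
}

#' Encode an Ising instance as a DOPO network
#'
#' Spin-spin interactions enter only the v-equations (`gamma_prime = 0`);
#' the external bias is zero. The binary sign of each v-DOPO represents the
#' Ising spin, and under a pump ramp the network relaxes toward low-energy
#' configurations of \eqn{E_{Ising} = -\sum_{i<j} J_{ij}\sigma_i\sigma_j}.
#'
#' The v-feedback is applied with gain `+J_k * J_ij`: this is the sign for
#' which aligned amplitudes are rewarded where `J_ij > 0` (a ferromagnetic
#' pair freezes aligned) and for which the rotating-frame average of the
#' coupling renormalizes the pump as
#' \eqn{P' = P_0 - \frac{1}{2} J_k E_{loc,i}} — energetically unstable
#' neurons get less effective pump, keep spiking, and preferentially flip.
#' Hardware descriptions that quote a negative gain measure the feedback
#' injection with the opposite sign convention; with the model equations as
#' written here, a negative gain would maximize the energy instead.
#'
#' @param instance an `ising_instance`.
#' @param J_k coupling strength (dimensionless when omega0 = 1).
#' @param omega0 natural frequency (default 1).
#' @return list with `coupling` (gamma = J_k, gamma_prime = 0) and `params`
#'   (I_ext = 0).
#' @export
ising_network <- function(instance, J_k, omega0 = 1) {
  stopifnot(inherits(instance, "ising_instance"))
  list(coupling = network_coupling(instance$J, gamma = J_k * omega0,
                                   gamma_prime = 0),
       params = neuron_params(instance$n, I_ext = 0,
                              J_vw = -omega0, J_wv = omega0))
}

#' Read and write Ising instances as edge lists
#'
#' Plain-text format: optional comment lines starting with `#`, a header
#' line `n m`, then `m` lines `i j w` with 1-based node indices and decimal
#' weights; each symmetric pair is stored once.
#'
#' @param instance an `ising_instance`.
#' @param path file path.
#' @return `write_ising_instance()`: the path, invisibly;
#'   `read_ising_instance()`: an `ising_instance`.
#' @export
write_ising_instance <- function(instance, path) {
  stopifnot(inherits(instance, "ising_instance"))
  up <- which(upper.tri(instance$J) & instance$J != 0, arr.ind = TRUE)
  lines <- c(sprintf("%d %d", instance$n, nrow(up)),
             sprintf("%d %d %.17g", up[, 1], up[, 2],
                     instance$J[up]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ising_instance
#' @export
read_ising_instance <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 2) stop("malformed header: expected 'n m'")
  n <- as.integer(hdr[1])
  m <- as.integer(hdr[2])
  if (length(lines) - 1 != m)
    stop(sprintf("header promises %d edges but file has %d", m,
                 length(lines) - 1))
  J <- matrix(0, n, n)
  if (m > 0) {
    e <- matrix(scan(text = lines[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    i <- as.integer(e[, 1]); j <- as.integer(e[, 2])
    if (any(i < 1 | i > n | j < 1 | j > n | i == j))
      stop("edge endpoints out of range")
    J[cbind(i, j)] <- e[, 3]
    J[cbind(j, i)] <- e[, 3]
  }
  ising_instance(J)
}
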