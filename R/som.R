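# Self-organizing map: 4x4 lattice, winner-take-most updates with the
# three-level neighborhood (1 at the winner, 0.5 at lattice distance 1, 0
# elsewhere), used to split each outcome class into homogeneous subgroups
# before rule mining.

#' Self-organizing map configuration
#'
#' The lattice and learning scheme used to cluster each outcome class: a 4x4
#' grid, learning rate 0.4, and a neighborhood function equal to 1 at the
#' winning neuron, 0.5 at lattice distance 1, and 0 otherwise. Lattice
#' distance is Chebyshev by default (distance 1 includes diagonals),
#' switchable to Manhattan.
#'
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param learning_rate Learning rate eta in (0, 1].
#' @param epochs Training passes over the data; presentation order is
#'   shuffled once from the seed and then fixed.
#' @param lattice Chebyshev or Manhattan lattice distance for the
#'   neighborhood.
#' @param seed Integer seed for weight initialisation and presentation order.
#' @return An object of class `som_config`.
#' @export
som_config <- function(grid_rows = 4, grid_cols = 4, learning_rate = 0.4,
                       epochs = 50, lattice = c("chebyshev", "manhattan"),
                       seed = 1L) {
  if (learning_rate <= 0 || learning_rate > 1) stop("learning_rate must be in (0, 1]")
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              lattice = match.arg(lattice), seed = as.integer(seed))
  class(cfg) <- "som_config"
  cfg
}

# neuron lattice coordinates, row-major: neuron i is (row, col)
.som_coords <- function(cfg) {
  cbind(row = rep(seq_len(cfg$grid_rows), each = cfg$grid_cols),
        col = rep(seq_len(cfg$grid_cols), times = cfg$grid_rows))
}

# neighborhood factor phi for every neuron given the winner index
.som_phi <- function(cfg, coords, winner) {
  dr <- abs(coords[, "row"] - coords[winner, "row"])
  dc <- abs(coords[, "col"] - coords[winner, "col"])
  d <- if (cfg$lattice == "chebyshev") pmax(dr, dc) else dr + dc
  ifelse(d == 0, 1, ifelse(d == 1, 0.5, 0))
}

#' Apply one SOM weight update
#'
#' The update rule `w_new = w_old + phi * eta * (x - w_old)` for a single
#' presented vector, applied to every neuron with its neighborhood factor.
#' Exposed separately so the arithmetic can be checked directly.
#'
#' @param weights Neuron-by-dimension weight matrix.
#' @param x Presented input vector.
#' @param winner Winning neuron index.
#' @param cfg A [som_config()].
#' @param coords Lattice coordinates (computed from `cfg` when omitted).
#' @return Updated weight matrix.
#' @export
som_update <- function(weights, x, winner, cfg, coords = .som_coords(cfg)) {
  phi <- .som_phi(cfg, coords, winner)
  weights + (phi * cfg$learning_rate) * (matrix(x, nrow(weights), length(x),
                                                byrow = TRUE) - weights)
}

#' Train a self-organizing map
#'
#' Online training of the lattice on encoded patient vectors: for each
#' presented vector the nearest neuron by Euclidean distance wins (ties to the
#' lowest index) and all neurons move toward the input by
#' `phi * eta * (x - w)`. Weights are initialised uniformly in `[0, 1]` from
#' the seed; the presentation order is one seeded shuffle, repeated every
#' epoch, so training is fully deterministic.
#'
#' @param x Numeric matrix of encoded records (rows = records).
#' @param cfg A [som_config()].
#' @return Object of class `som_grid` with `weights` (neurons x dims) and the
#'   config.
#' @export
train_som <- function(x, cfg = som_config()) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("no records to train the map on")
  if (!all(is.finite(x))) stop("encoded vectors must be finite")
  n_neurons <- cfg$grid_rows * cfg$grid_cols
  if (nrow(x) < n_neurons) {
    warning("fewer records (", nrow(x), ") than neurons (", n_neurons,
            "); clustering degenerates to fewer effective clusters")
  }
  set.seed(cfg$seed)
  w <- matrix(stats::runif(n_neurons * ncol(x)), n_neurons, ncol(x))
  colnames(w) <- colnames(x)
  coords <- .som_coords(cfg)
  order_idx <- sample(nrow(x))
  for (ep in seq_len(cfg$epochs)) {
    for (i in order_idx) {
      xi <- x[i, ]
      d2 <- rowSums((w - matrix(xi, n_neurons, ncol(x), byrow = TRUE))^2)
      winner <- which.min(d2) # which.min takes the lowest index on ties
      w <- som_update(w, xi, winner, cfg, coords)
    }
  }
  grid <- list(weights = w, config = cfg)
  class(grid) <- "som_grid"
  grid
}

#' Assign records to SOM clusters
#'
#' Maps each encoded record to its nearest neuron (Euclidean distance on the
#' encoded coordinates); ties break to the lowest neuron index.
#'
#' @param grid A trained [train_som()] grid.
#' @param x Numeric matrix of encoded records.
#' @return Integer vector of neuron indices (1-based, row-major lattice).
#' @export
assign_clusters <- function(grid, x) {
  stopifnot(inherits(grid, "som_grid"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(grid$weights)) {
    stop("dimensionality mismatch: records have ", ncol(x), " dims, grid has ",
         ncol(grid$weights))
  }
  w <- grid$weights
  # ||x - w||^2 = ||x||^2 - 2 x.w + ||w||^2; only the last two depend on w
  cross <- x %*% t(w)
  d2 <- -2 * cross + matrix(rowSums(w^2), nrow(x), nrow(w), byrow = TRUE)
  apply(d2, 1L, function(r) which(r <= min(r) + 1e-12)[1])
}
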