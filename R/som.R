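#' Euclidean distance between two vectors
#'
#' @param y,x Numeric vectors of equal length.
#' @return `sqrt(sum((y - x)^2))`.
#' @export
euclidean_distance <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch")
  sqrt(sum((y - x)^2))
}

#' Exponential decay of a learning parameter
#'
#' `value0 * exp(-t / lambda)`; used for both the neighborhood radius and
#' the learning rate of the self-organizing map.
#'
#' @param value0 Initial value at `t = 0`.
#' @param t Iteration (>= 0).
#' @param lambda Time constant (> 0).
#' @return Decayed value.
#' @export
decayed <- function(value0, t, lambda) {
  if (lambda <= 0) stop("`lambda` must be > 0")
  value0 * exp(-t / lambda)
}

#' Gaussian neighborhood function
#'
#' `exp(-e^2 / (2 * alpha_t^2))`: 1 at the best matching unit and
#' decreasing with lattice distance `e`.
#'
#' @param e Lattice distance between the BMU and a node (>= 0).
#' @param alpha_t Current neighborhood radius (> 0).
#' @return Value in (0, 1].
#' @export
neighborhood <- function(e, alpha_t) {
  if (alpha_t <= 0) stop("`alpha_t` must be > 0")
  exp(-e^2 / (2 * alpha_t^2))
}

#' Construct an untrained self-organizing map grid
#'
#' Nodes live on a rectangular `rows` x `cols` lattice; each node carries
#' a weight vector of the input dimension, initialized uniformly in the
#' per-dimension data range (or [0, 1] when no data are given).
#'
#' @param rows,cols Lattice dimensions (`rows * cols >= 4`).
#' @param input_dim Weight-vector dimension.
#' @param alpha0 Initial neighborhood radius (default `max(rows, cols)/2`).
#' @param beta0 Initial learning rate in (0, 1] (default 0.5).
#' @param iterations Total presentation budget `o` (default
#'   `1000 * rows`; overridden by [som_fit()]).
#' @param lambda Decay time constant (default `iterations / log(alpha0)`).
#' @param seed Seed for weight initialization.
#' @param init_range Per-dimension `c(lo, hi)` matrix (2 x input_dim) for
#'   weight initialization.
#' @return Object of class `som_grid` with a `(rows*cols) x input_dim`
#'   weight matrix (row-major node order).
#' @export
som_grid <- function(rows = 10L, cols = 10L, input_dim,
                     alpha0 = max(rows, cols) / 2, beta0 = 0.5,
                     iterations = 1000L * rows, lambda = NULL,
                     seed = 1L, init_range = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4) stop("grid must have at least 4 nodes")
  if (beta0 <= 0 || beta0 > 1) stop("`beta0` must be in (0, 1]")
  if (alpha0 <= 0) stop("`alpha0` must be > 0")
  if (is.null(lambda)) lambda <- iterations / max(log(alpha0), 1e-6)
  if (lambda <= 0) stop("`lambda` must be > 0")
  W <- with_seed(seed, {
    if (is.null(init_range))
      matrix(stats::runif(rows * cols * input_dim), rows * cols, input_dim)
    else {
      lo <- init_range[1, ]; hi <- init_range[2, ]
      matrix(stats::runif(rows * cols * input_dim), rows * cols,
             input_dim) * rep(hi - lo, each = rows * cols) +
        rep(lo, each = rows * cols)
    }
  })
  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  structure(list(rows = rows, cols = cols, input_dim = input_dim,
                 weights = W, coords = coords, alpha0 = alpha0,
                 beta0 = beta0, iterations = as.integer(iterations),
                 lambda = lambda, seed = seed, trained = FALSE,
                 qe_curve = numeric(0)),
            class = "som_grid")
}

#' Best matching unit of an input vector
#'
#' Returns the node minimizing the Euclidean distance to `y`; ties are
#' broken by the smallest (row, col) in row-major order.
#'
#' @param grid A `som_grid`.
#' @param y Input vector of length `grid$input_dim`.
#' @return List with `index` (row-major node index), `row`, `col`,
#'   `distance`.
#' @export
find_bmu <- function(grid, y) {
  if (is.null(grid$weights)) stop("grid is uninitialized")
  if (length(y) != grid$input_dim) stop("input dimension mismatch")
  d2 <- rowSums(sweep(grid$weights, 2, y)^2)
  i <- which.min(d2)   # first minimum = smallest row-major index
  list(index = i, row = grid$coords[i, "row"],
       col = grid$coords[i, "col"], distance = sqrt(d2[i]))
}

#' One neighborhood-weighted update of all node weights
#'
#' Applies `x_ij <- x_ij + beta_t * gamma_ij * (y - x_ij)` to every node,
#' where `gamma_ij` is the Gaussian neighborhood of the node's lattice
#' distance to the BMU at the current radius.  The neighborhood is
#' evaluated for all nodes (no hard cutoff); nodes far beyond the radius
#' receive vanishingly small updates.
#'
#' @param grid A `som_grid`.
#' @param y Input vector.
#' @param bmu Result of [find_bmu()] (or a row-major node index).
#' @param t Current iteration (0-based; `t < grid$iterations`).
#' @return The updated grid.
#' @export
update_weights <- function(grid, y, bmu, t) {
  if (is.list(bmu)) bmu <- bmu$index
  alpha_t <- max(decayed(grid$alpha0, t, grid$lambda), 1e-12)
  beta_t <- decayed(grid$beta0, t, grid$lambda)
  e2 <- (grid$coords[, "row"] - grid$coords[bmu, "row"])^2 +
    (grid$coords[, "col"] - grid$coords[bmu, "col"])^2
  gam <- exp(-e2 / (2 * alpha_t^2))
  grid$weights <- grid$weights +
    (beta_t * gam) * (rep(y, each = nrow(grid$weights)) - grid$weights)
  grid
}

som_quantization_error <- function(grid, X) {
  mean(apply(X, 1, function(y)
    sqrt(min(rowSums(sweep(grid$weights, 2, y)^2)))))
}

#' Train a self-organizing map
#'
#' Kohonen competitive learning: for each of `iterations` presentations,
#' one input vector is shown (seeded cyclic order with a reshuffle every
#' epoch), its best matching unit found, and all node weights pulled
#' toward the input with exponentially decaying learning rate and
#' neighborhood radius.  The quantization error (mean distance of inputs
#' to their BMUs) is recorded once per pass through the data.
#'
#' @param x Numeric input matrix (rows = input vectors), e.g. one
#'   emotion-fraction profile per organization.
#' @param rows,cols Lattice dimensions.
#' @param iterations Total presentations `o` (default `1000 * nrow(x)`).
#' @param alpha0,beta0,lambda,seed See [som_grid()].
#' @return A trained `som_grid` with `qe_curve` (per-epoch quantization
#'   error) and `bmu` (final BMU index per input row).
#' @examples
#' profs <- matrix(runif(40), 10, 4)
#' m <- som_fit(profs, rows = 4, cols = 4, iterations = 2000, seed = 2)
#' m$qe_curve[1] >= m$qe_curve[length(m$qe_curve)]
#' @export
som_fit <- function(x, rows = 10L, cols = 10L,
                    iterations = 1000L * nrow(x),
                    alpha0 = max(rows, cols) / 2, beta0 = 0.5,
                    lambda = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one input vector")
  if (iterations <= 0) stop("`iterations` must be > 0")
  grid <- som_grid(rows, cols, input_dim = ncol(x), alpha0 = alpha0,
                   beta0 = beta0, iterations = iterations,
                   lambda = lambda, seed = seed,
                   init_range = apply(x, 2, range))
  n <- nrow(x)
  qe <- numeric(0)
  with_seed(derive_seed(seed, 3L), {
    ord <- sample.int(n)
    pos <- 0L
    for (t in seq_len(iterations) - 1L) {
      pos <- pos + 1L
      if (pos > n) {          # new epoch: record QE, reshuffle
        qe <- c(qe, som_quantization_error(grid, x))
        ord <- sample.int(n)
        pos <- 1L
      }
      y <- x[ord[pos], ]
      bmu <- find_bmu(grid, y)
      grid <- update_weights(grid, y, bmu, t)
    }
  })
  qe <- c(qe, som_quantization_error(grid, x))
  grid$qe_curve <- qe
  grid$trained <- TRUE
  grid$bmu <- apply(x, 1, function(y) find_bmu(grid, y)$index)
  grid
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("self-organizing map: %d x %d lattice, input dim %d\n",
              x$rows, x$cols, x$input_dim))
  cat(sprintf("  alpha0 %.3g, beta0 %.3g, lambda %.3g, budget %d\n",
              x$alpha0, x$beta0, x$lambda, x$iterations))
  if (x$trained)
    cat(sprintf("  trained; final quantization error %.5f\n",
                x$qe_curve[length(x$qe_curve)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
plot.som_grid <- function(x, ...) {
  if (!x$trained) stop("untrained grid")
  graphics::plot(seq_along(x$qe_curve), x$qe_curve, type = "b",
                 xlab = "epoch", ylab = "quantization error",
                 main = "SOM quantization error", ...)
  invisible(x)
}

#' Partition the SOM codebook with K-means
#'
#' Clusters the trained node weight vectors into `k` groups (default 4)
#' with seeded multi-start K-means; exactly `k` non-empty clusters are
#' returned.
#'
#' @param grid A trained `som_grid`.
#' @param k Number of clusters (<= number of nodes).
#' @param seed Seed for the restarts.
#' @param nstart Random restarts (best within-cluster sum of squares
#'   kept).
#' @return List with `cluster` (node -> cluster id, row-major order) and
#'   `centers` (k x input_dim matrix).
#' @export
kmeans_partition <- function(grid, k = 4L, seed = 1L, nstart = 20L) {
  n_nodes <- nrow(grid$weights)
  if (k > n_nodes) stop("`k` exceeds the number of nodes")
  if (k == n_nodes)
    return(list(cluster = seq_len(n_nodes), centers = grid$weights))
  km <- with_seed(seed,
                  stats::kmeans(grid$weights, centers = k, nstart = nstart,
                                iter.max = 100))
  list(cluster = km$cluster, centers = km$centers)
}

#' Map an organizational rank to its competitiveness category
#'
#' Ranks 1-5 are highly competitive organizations, 6-8 moderate, and
#' 9-10 low.
#'
#' @param org_rank Integer rank(s) in 1..10.
#' @return Character vector in `{high, moderate, low}`.
#' @export
rank_to_category <- function(org_rank) {
  if (any(org_rank < 1 | org_rank > 10)) stop("rank out of range 1..10")
  ifelse(org_rank <= 5, "high", ifelse(org_rank <= 8, "moderate", "low"))
}

# Dominant-emotion -> category rule; ties resolved pessimistically
# (angry > neutral > happy > excited).
emotion_to_category <- function(fractions) {
  prio <- c(angry = 1L, neutral = 2L, happy = 3L, excited = 4L)
  f <- fractions[names(prio)]
  dominant <- names(prio)[order(-f, prio)][1]
  switch(dominant, angry = "low", neutral = "moderate",
         happy = "high", excited = "high")
}

#' Per-organization emotion profiles
#'
#' Aggregates (predicted or observed) emotion labels into one
#' emotion-fraction 4-vector per organizational rank.
#'
#' @param org_rank Integer vector of organization ranks per employee.
#' @param emotion Character (or factor) emotion labels per employee.
#' @return Data frame with org_rank, n_employees and one fraction column
#'   per emotion (fractions sum to 1 per row).
#' @export
org_profiles <- function(org_rank, emotion) {
  emotion <- factor(as.character(emotion), levels = emotion_levels())
  tab <- table(org_rank, emotion)
  fr <- tab / pmax(rowSums(tab), 1)
  out <- data.frame(org_rank = as.integer(rownames(tab)),
                    n_employees = as.integer(rowSums(tab)))
  for (em in emotion_levels()) out[[em]] <- as.numeric(fr[, em])
  out
}

#' Categorize organizational competitiveness from emotion profiles
#'
#' Each organization is mapped through a trained SOM: its profile's best
#' matching unit determines its codebook cluster, and the cluster
#' centroid's dominant emotion determines the category (angry-dominant ->
#' low, neutral -> moderate, happy/excited -> high).  Without a SOM the
#' dominant emotion of the organization's own profile is used directly.
#'
#' @param profiles Data frame from [org_profiles()].
#' @param som Optional trained `som_grid` fitted to the profile fractions.
#' @param partition Optional result of [kmeans_partition()] on `som`.
#' @return Data frame of class `competitiveness_report`: org_rank,
#'   n_employees, emotion fractions, cluster (NA without a SOM),
#'   dominant emotion and category.
#' @export
categorize_competitiveness <- function(profiles, som = NULL,
                                       partition = NULL) {
  if (nrow(profiles) == 0) stop("empty profile set")
  fr <- as.matrix(profiles[, emotion_levels()])
  if (!is.null(som)) {
    if (is.null(partition)) partition <- kmeans_partition(som)
    bmu <- apply(fr, 1, function(y) find_bmu(som, y)$index)
    cluster <- partition$cluster[bmu]
    cat_of_cluster <- apply(partition$centers, 1, function(ctr) {
      names(ctr) <- emotion_levels()
      emotion_to_category(ctr)
    })
    category <- cat_of_cluster[cluster]
    centers <- partition$centers
    dominant <- apply(centers[cluster, , drop = FALSE], 1, function(ctr) {
      names(ctr) <- emotion_levels()
      prio <- c(angry = 1L, neutral = 2L, happy = 3L, excited = 4L)
      names(prio)[order(-ctr[names(prio)], prio)][1]
    })
  } else {
    cluster <- rep(NA_integer_, nrow(profiles))
    category <- apply(fr, 1, function(f) {
      names(f) <- emotion_levels(); emotion_to_category(f)
    })
    dominant <- apply(fr, 1, function(f) {
      names(f) <- emotion_levels()
      prio <- c(angry = 1L, neutral = 2L, happy = 3L, excited = 4L)
      names(prio)[order(-f[names(prio)], prio)][1]
    })
  }
  out <- cbind(profiles,
               data.frame(cluster = cluster, dominant = dominant,
                          category = category))
  class(out) <- c("competitiveness_report", "data.frame")
  out
}

#' Export a trained SOM to a structured text container
#'
#' Dimensions, schedule and weights are written as JSON with full
#' precision; [read_som()] restores the grid.
#'
#' @param grid A `som_grid`.
#' @param path File path.
#' @export
write_som <- function(grid, path) {
  obj <- list(format = "emocomp-som", version = 1L,
              rows = grid$rows, cols = grid$cols,
              input_dim = grid$input_dim, alpha0 = grid$alpha0,
              beta0 = grid$beta0, lambda = grid$lambda,
              iterations = grid$iterations, seed = grid$seed,
              trained = grid$trained, qe_curve = grid$qe_curve,
              weights = grid$weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emocomp-som"))
    stop("not an emocomp som container")
  g <- som_grid(obj$rows, obj$cols, input_dim = obj$input_dim,
                alpha0 = obj$alpha0, beta0 = obj$beta0,
                iterations = obj$iterations, lambda = obj$lambda,
                seed = obj$seed)
  g$weights <- matrix(obj$weights, obj$rows * obj$cols, obj$input_dim)
  g$trained <- obj$trained
  g$qe_curve <- as.numeric(obj$qe_curve)
  g
}
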