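test_that("Euclidean distance is a metric on examples", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_gte(euclidean_distance(a, b), 0)
  }
  expect_error(euclidean_distance(1:2, 1:3), "mismatch")
})

test_that("decay and neighborhood follow their closed forms", {
  expect_equal(decayed(2, 0, 5), 2)
  expect_equal(decayed(2, 5, 5), 2 / exp(1), tolerance = 1e-12)
  v <- decayed(1, 0:20, 3)
  expect_true(all(diff(v) < 0))
  expect_error(decayed(1, 1, 0), "lambda")
  expect_equal(neighborhood(0, 2), 1)
  expect_equal(neighborhood(2, 2), exp(-0.5), tolerance = 1e-12)
  g <- neighborhood(seq(0, 5, by = 0.5), 1.5)
  expect_true(all(diff(g) < 0))
  expect_error(neighborhood(1, 0), "alpha")
})

test_that("the BMU equals an exhaustive scan and breaks ties row-major", {
  g <- som_grid(2, 2, input_dim = 3, seed = 1)
  g$weights <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(5, 5, 5))
  hit <- find_bmu(g, c(1, 1, 1))
  expect_equal(hit$index, 2L)
  expect_equal(hit$distance, 0)
  # two equidistant nodes: the smaller row-major index wins
  g$weights <- rbind(c(1, 0, 0), c(0, 1, 0), c(9, 9, 9), c(9, 9, 9))
  expect_equal(find_bmu(g, c(0.5, 0.5, 0))$index, 1L)
  expect_error(find_bmu(g, 1:2), "dimension")
  # brute-force oracle on random 6x6 grids
  set.seed(21)
  for (trial in 1:100) {
    gg <- som_grid(6, 6, input_dim = 4, seed = trial)
    y <- runif(4)
    d <- apply(gg$weights, 1, function(w) euclidean_distance(y, w))
    expect_equal(find_bmu(gg, y)$index, which.min(d))
  }
})

test_that("weight updates follow the neighborhood-weighted rule", {
  g <- som_grid(2, 2, input_dim = 2, beta0 = 1, alpha0 = 1, seed = 4)
  w0 <- g$weights
  y <- c(0.3, 0.9)
  bmu <- find_bmu(g, y)
  g2 <- update_weights(g, y, bmu, t = 0)
  # at the BMU, beta(0) * gamma(0) = 1: the node becomes exactly y
  expect_equal(unname(g2$weights[bmu$index, ]), y, tolerance = 1e-12)
  # an off-BMU node moves by beta * exp(-e^2 / (2 alpha^2)) of the gap
  i <- setdiff(1:4, bmu$index)[1]
  e2 <- sum((g$coords[i, ] - g$coords[bmu$index, ])^2)
  gam <- exp(-e2 / 2)
  expect_equal(unname(g2$weights[i, ]),
               unname(w0[i, ] + gam * (y - w0[i, ])), tolerance = 1e-12)
  # beta(t) ~ 0 for huge t: grid unchanged
  gl <- som_grid(2, 2, input_dim = 2, beta0 = 1, alpha0 = 1, lambda = 10,
                 seed = 4)
  g3 <- update_weights(gl, y, find_bmu(gl, y), t = 1e4)
  expect_equal(g3$weights, gl$weights, tolerance = 1e-10)
  # convex containment: updated weights stay inside [min, max] hull
  set.seed(5)
  gg <- som_grid(3, 3, input_dim = 2, seed = 6)
  for (t in 0:20) {
    yy <- runif(2)
    lo <- pmin(apply(gg$weights, 2, min), yy)
    hi <- pmax(apply(gg$weights, 2, max), yy)
    gg <- update_weights(gg, yy, find_bmu(gg, yy), t)
    expect_true(all(gg$weights >= rep(lo, each = 9) - 1e-12))
    expect_true(all(gg$weights <= rep(hi, each = 9) + 1e-12))
  }
})

test_that("SOM training converges and is deterministic", {
  # single input: the BMU weight converges to that vector
  y <- matrix(c(0.2, 0.8, 0.5, 0.1), 1)
  g <- som_fit(y, rows = 3, cols = 3, iterations = 3000, seed = 9)
  expect_lt(find_bmu(g, as.vector(y))$distance, 1e-3)
  g2 <- som_fit(y, rows = 3, cols = 3, iterations = 3000, seed = 9)
  expect_identical(g$weights, g2$weights)
  expect_error(som_fit(y, iterations = 0), "iterations")
  # quantization error decreases on blob data in >= 9/10 seeds
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    X <- rbind(matrix(rnorm(40, 0, 0.05), 10, 4),
               matrix(rnorm(40, 1, 0.05), 10, 4))
    gf <- som_fit(X, rows = 4, cols = 4, iterations = 4000, seed = s)
    if (gf$qe_curve[length(gf$qe_curve)] < gf$qe_curve[1]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("K-means partitions the codebook into k non-empty clusters", {
  g <- som_grid(3, 3, input_dim = 2, seed = 2)
  singletons <- kmeans_partition(g, k = 9)
  expect_equal(sort(unique(singletons$cluster)), 1:9)
  # four well-separated blobs of codebook vectors are recovered exactly
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  set.seed(3)
  g$weights <- centers[rep(1:4, length.out = 9), ] + rnorm(18, 0, 0.01)
  part <- kmeans_partition(g, k = 4, seed = 5)
  expect_equal(length(unique(part$cluster)), 4L)
  truth <- rep(1:4, length.out = 9)
  expect_equal(length(unique(paste(part$cluster, truth))), 4L)
  expect_error(kmeans_partition(g, k = 10), "exceeds")
})

test_that("rank maps to the published competitiveness bands", {
  expect_equal(rank_to_category(3), "high")
  expect_equal(rank_to_category(7), "moderate")
  expect_equal(rank_to_category(10), "low")
  expect_equal(rank_to_category(c(1, 5, 6, 8, 9)),
               c("high", "high", "moderate", "moderate", "low"))
  expect_error(rank_to_category(0), "range")
  expect_error(rank_to_category(11), "range")
})

test_that("emotion profiles categorize by dominant emotion", {
  profs <- data.frame(org_rank = 1:3, n_employees = c(10, 10, 10),
                      neutral = c(0, 0, 1), happy = c(0, 1, 0),
                      excited = c(0, 0, 0), angry = c(1, 0, 0))
  catrep <- categorize_competitiveness(profs)
  expect_s3_class(catrep, "competitiveness_report")
  expect_equal(catrep$category, c("low", "high", "moderate"))
  # ties resolve pessimistically: angry > neutral > happy > excited
  tie <- data.frame(org_rank = 1, n_employees = 4, neutral = 0.25,
                    happy = 0.25, excited = 0.25, angry = 0.25)
  expect_equal(categorize_competitiveness(tie)$category, "low")
  tie2 <- data.frame(org_rank = 1, n_employees = 4, neutral = 0.5,
                     happy = 0.5, excited = 0, angry = 0)
  expect_equal(categorize_competitiveness(tie2)$category, "moderate")
  expect_error(categorize_competitiveness(profs[0, ]), "empty")
})

test_that("org profiles aggregate to unit-sum fractions", {
  d <- small_dataset()
  profs <- org_profiles(d$org_rank, d$emotion)
  expect_true(all(abs(rowSums(profs[, emotion_levels()]) - 1) < 1e-9))
  expect_equal(sum(profs$n_employees), nrow(d))
  expect_equal(profs$org_rank, sort(unique(d$org_rank)))
})

test_that("SOM export round-trips through the JSON container", {
  X <- matrix(runif(20), 5, 4)
  g <- som_fit(X, rows = 2, cols = 3, iterations = 500, seed = 12)
  f <- tempfile(fileext = ".json")
  write_som(g, f)
  back <- read_som(f)
  expect_equal(back$weights, g$weights, tolerance = 1e-14)
  expect_equal(back$qe_curve, g$qe_curve, tolerance = 1e-14)
  expect_equal(back$rows, g$rows)
  unlink(f)
})
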