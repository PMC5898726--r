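# Deterministic hidden-node selectors: similarity k-means and SVDD/SVC

test_that("k-means degenerate cluster counts behave as defined", {
  X <- rand_bits(12, 32, p = 0.4, seed = 30)
  # k = n: every sample its own representative
  km <- kmeans_representatives(X, k = 12, coef = "C03", seed = 1)
  expect_equal(sort(km$representative_index), 1:12)
  expect_equal(length(unique(km$assignments)), 12)

  # k = 1: representative is the sample most similar to the global mean
  km1 <- kmeans_representatives(X, k = 1, coef = "C03", seed = 1)
  centroid <- matrix(colMeans(X), 1)
  sims <- similarity_matrix("C03", X, centroid)[, 1]
  expect_equal(km1$representative_index, which.max(sims))
  expect_equal(km1$assignments, rep(1L, 12))

  expect_error(kmeans_representatives(X, k = 13), "1..n")
})

test_that("k-means recovers two planted blobs with pure assignments", {
  pb <- planted_blobs(n_per = 12, m = 64, flip = 0.03, seed = 31)
  km <- kmeans_representatives(pb$bits, k = 2, coef = "C03", seed = 2)
  # each cluster contains exactly one blob
  tab <- table(km$assignments, pb$membership)
  expect_equal(sort(diag(tab[, order(tab[1, ], decreasing = TRUE)])),
               c(12, 12))
  # one representative from each blob
  expect_equal(sort(pb$membership[km$representative_index]), c(1, 2))
})

test_that("k-means objective trace is non-increasing and the run is seeded", {
  X <- rand_bits(40, 48, p = 0.3, seed = 33)
  km <- kmeans_representatives(X, k = 5, coef = "C10", seed = 4)
  expect_true(all(diff(km$objective) <= 1e-12))
  km_b <- kmeans_representatives(X, k = 5, coef = "C10", seed = 4)
  expect_identical(km$representative_index, km_b$representative_index)
  expect_identical(km$assignments, km_b$assignments)
  # representatives are actual samples
  expect_true(all(km$representatives %in% c(0, 1)))
  expect_equal(km$representatives, X[km$representative_index, ])
})

test_that("k-means under a correlation coefficient rescales its geometry", {
  pb <- planted_blobs(n_per = 8, m = 32, flip = 0.02, seed = 35)
  km <- kmeans_representatives(pb$bits, k = 2, coef = "C14", seed = 1)
  tab <- table(km$assignments, pb$membership)
  expect_equal(max(tab[1, ]) + max(tab[2, ]), 16)  # pure split
})

test_that("SVDD degenerate cases", {
  x1 <- matrix(c(1, 0, 1, 0), 1)
  f1 <- svdd_fit(x1, kernel = "C03", cs = 1)
  expect_equal(f1$multipliers, 1)
  expect_equal(f1$radius_sq, 0, tolerance = 1e-9)

  x2 <- rbind(c(1, 0, 1, 0), c(1, 0, 1, 0))
  f2 <- svdd_fit(x2, kernel = "C03", cs = 1)
  expect_equal(f2$radius_sq, 0, tolerance = 1e-9)

  expect_error(svdd_fit(rand_bits(3, 8, seed = 1), cs = 0.2),
               "infeasible")
})

test_that("SVDD dual matches a generic QP solver", {
  skip_if_not_installed("kernlab")
  X <- rand_bits(20, 32, p = 0.35, seed = 36)
  for (cs in c(0.15, 0.5)) {
    fit <- svdd_fit(X, kernel = "C03", cs = cs, tol = 1e-8)
    K <- pairwise_matrix("C03", X)
    K <- (K + t(K)) / 2
    # ipop minimises c'b + b'Hb/2 under b = A b' constraints and box
    qp <- kernlab::ipop(c = matrix(-diag(K)), H = 2 * K,
                        A = matrix(1, 1, 20), b = 1, r = 0,
                        l = matrix(0, 20), u = matrix(cs, 20),
                        sigf = 9, maxiter = 200)
    b_qp <- kernlab::primal(qp)
    dual_obj <- function(b) sum(b * diag(K)) - drop(t(b) %*% K %*% b)
    expect_equal(dual_obj(fit$multipliers), dual_obj(b_qp),
                 tolerance = 1e-6)
    expect_equal(fit$multipliers, as.numeric(b_qp), tolerance = 1e-3,
                 info = paste("cs =", cs))
  }
})

test_that("SVDD satisfies feasibility and KKT conditions", {
  X <- rand_bits(40, 48, p = 0.3, seed = 37)
  tol <- 1e-6
  for (cs in c(0.1, 0.3, 1.0)) {
    fit <- svdd_fit(X, kernel = "C03", cs = cs, tol = tol)
    b <- fit$multipliers
    expect_lt(abs(sum(b) - 1), 1e-8)
    expect_true(all(b >= -tol & b <= cs + tol))
    expect_true(length(intersect(fit$boundary_svs, fit$bounded_svs)) == 0)
    r2 <- sphere_distance_sq(fit, X)
    if (length(fit$boundary_svs)) {
      expect_true(all(abs(r2[fit$boundary_svs] - fit$radius_sq) <= 10 * tol))
    }
    interior <- which(b <= 1e-8)
    if (length(interior)) {
      expect_true(all(r2[interior] <= fit$radius_sq + 10 * tol))
    }
  }
})

test_that("decreasing cs cannot decrease the outlier count", {
  X <- rbind(planted_blobs(n_per = 15, m = 32, flip = 0.08, seed = 38)$bits)
  counts <- sapply(seq(1.0, 0.1, by = -0.1), function(cs) {
    length(svdd_fit(X, kernel = "C03", cs = cs)$bounded_svs)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("sphere distance matches a term-by-term brute force", {
  X <- rand_bits(15, 24, p = 0.4, seed = 39)
  fit <- svdd_fit(X, kernel = "C03", cs = 0.4)
  set.seed(40)
  z <- as.numeric(runif(24) < 0.4)
  brute <- similarity("C03", z, z) -
    2 * sum(sapply(1:15, function(i) {
      fit$multipliers[i] * similarity("C03", X[i, ], z)
    })) +
    sum(outer(fit$multipliers, fit$multipliers) *
          pairwise_matrix("C03", X))
  expect_equal(sphere_distance_sq(fit, z), brute, tolerance = 1e-8)

  # all-zero query: zero similarity to everything, so K(z,z) + offset
  z0 <- numeric(24)
  expect_equal(sphere_distance_sq(fit, z0), fit$offset, tolerance = 1e-10)
})

test_that("SVC labels a tight blob as one cluster and split blobs as two", {
  one <- generate_synthetic(n_active = 14, n_inactive = 0, m = 48,
                            n_scaffolds = 1, seed_density = 0.4,
                            flip_prob = 0.02, seed = 41)
  f_one <- svdd_fit(one$bits, kernel = "C03", cs = 1)
  lab_one <- svc_labels(f_one)
  expect_equal(length(unique(lab_one)), 1)

  pb <- planted_blobs(n_per = 8, m = 64, flip = 0.01, seed = 42)
  f_two <- svdd_fit(pb$bits, kernel = "C03", cs = 1)
  lab_two <- svc_labels(f_two)
  expect_equal(length(unique(lab_two)), 2)
  expect_equal(length(unique(lab_two[pb$membership == 1])), 1)
  expect_equal(length(unique(lab_two[pb$membership == 2])), 1)
})

test_that("SVC representatives are the boundary support vectors", {
  pb <- planted_blobs(n_per = 10, m = 64, flip = 0.04, seed = 43)
  fit <- svdd_fit(pb$bits, kernel = "C03", cs = 0.3)
  reps <- svc_representatives(fit)
  expect_equal(nrow(reps), length(fit$boundary_svs))
  expect_equal(reps, fit$X[fit$boundary_svs, , drop = FALSE])
  expect_lte(nrow(reps), nrow(pb$bits))
  # boundary SVs drawn from both blobs
  expect_setequal(unique(pb$membership[fit$boundary_svs]), c(1, 2))
  # definitional count from the multipliers
  b <- fit$multipliers
  expect_equal(length(fit$boundary_svs),
               sum(b > 1e-6 & b < fit$cs - 1e-6))
  # include_bounded adds the outliers
  reps_all <- svc_representative_index(fit, include_bounded = TRUE)
  expect_setequal(reps_all, union(fit$boundary_svs, fit$bounded_svs))
})

test_that("select_nodes honours the common contract for all methods", {
  fp <- separable_set(n_active = 8, n_inactive = 40, m = 64, seed = 44)
  for (m in c("random", "kmeans", "svc")) {
    sel <- select_nodes(fp, method = m, coef = "C03", l = 10, k = 10,
                        cs = 0.5, seed = 2)
    expect_true(all(sel$W %in% c(0, 1)))
    expect_equal(sel$W, fp$bits[sel$index, , drop = FALSE])
  }
  # identical contract to what wselm() trains with
  s1 <- select_nodes(fp, "random", l = 10, seed = 2)
  f1 <- wselm(fp, method = "random", l = 10, seed = 2)
  expect_identical(s1$index, f1$selection$index)
})
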