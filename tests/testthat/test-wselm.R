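# Weighted-similarity ELM: class weights, hidden matrix, ridge solve,
# training and prediction

test_that("class weights follow the imbalance rule", {
  y <- c(rep(1, 10), rep(-1, 160))
  cw <- class_weights(y)
  expect_equal(unique(cw$gamma[y == 1]), 16)
  expect_equal(unique(cw$gamma[y == -1]), 1)
  expect_equal(cw$n_active, 10)
  expect_equal(cw$n_inactive, 160)

  cw_bal <- class_weights(c(1, 1, -1, -1))
  expect_equal(cw_bal$gamma, rep(1, 4))

  cw_flip <- class_weights(c(rep(1, 150), rep(-1, 20)))
  expect_equal(unique(cw_flip$gamma[cw_flip$gamma != 1]), 7.5)
  expect_equal(unique(class_weights(c(rep(1, 150), rep(-1, 20)))$gamma[1:150]), 1)

  expect_error(class_weights(rep(1, 5)), "both classes")
  expect_error(class_weights(c(1, 0, -1)), "coded")
})

test_that("hidden matrix holds similarity activations", {
  X <- rand_bits(6, 32, seed = 5)
  W <- X[c(2, 4), , drop = FALSE]
  H <- hidden_matrix(X, W, "C03")
  expect_equal(dim(H), c(6, 2))
  expect_equal(H[2, 1], 1)
  expect_equal(H[4, 2], 1)
  for (i in 1:6) for (j in 1:2) {
    expect_equal(H[i, j], similarity("C03", X[i, ], W[j, ]))
  }
  # self-activation diagonal with W = X
  H2 <- hidden_matrix(X, X, "C03")
  expect_equal(diag(H2), rep(1, 6))
})

test_that("solve_beta solves its defining ridge system", {
  # identity hidden matrix: (I + I)^{-1} y = y/2
  y <- c(1, -1, 1, -1)
  expect_equal(solve_beta(diag(4), y, C = 1), y / 2)

  # large C: agrees with minimum-norm least squares (pseudo-inverse oracle)
  set.seed(10)
  H <- matrix(runif(30 * 8), 30, 8)
  y2 <- sign(rnorm(30))
  beta <- solve_beta(H, y2, C = 1e12)
  sv <- svd(H)
  beta_pinv <- sv$v %*% ((t(sv$u) %*% y2) / sv$d)
  expect_equal(beta, drop(beta_pinv), tolerance = 1e-5)

  # weighted case: matches a generic quadratic optimiser on the objective
  set.seed(11)
  H3 <- matrix(runif(20 * 5), 20, 5)
  y3 <- sign(rnorm(20))
  gam <- runif(20, 0.5, 4)
  C <- 3
  obj <- function(b) {
    r <- (gam * H3) %*% b - gam * y3
    sum(r^2) + sum(b^2) / C
  }
  beta3 <- solve_beta(H3, y3, gamma = gam, C = C)
  opt <- optim(rep(0, 5), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(beta3, opt$par, tolerance = 1e-4)
  expect_lte(obj(beta3), opt$value + 1e-10)
})

test_that("normal-equation residuals vanish over random instances", {
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    l <- sample(1:min(n, 15), 1)
    H <- matrix(runif(n * l), n, l)
    y <- sign(rnorm(n))
    gam <- runif(n, 0.5, 20)
    C <- 10^runif(1, -4, 4)
    beta <- solve_beta(H, y, gamma = gam, C = C)
    Hh <- gam * H
    lhs <- (diag(l) / C + crossprod(Hh)) %*% beta
    rhs <- crossprod(Hh, gam * y)
    expect_lt(sqrt(sum((lhs - rhs)^2)), 1e-8 * max(sqrt(sum(rhs^2)), 1))
  }
})

test_that("ridge shrinkage: ||beta|| non-increasing as C decreases", {
  set.seed(13)
  H <- matrix(runif(25 * 10), 25, 10)
  y <- sign(rnorm(25))
  gam <- runif(25, 1, 16)
  norms <- sapply(10^seq(-6, 6), function(C) {
    sqrt(sum(solve_beta(H, y, gamma = gam, C = C)^2))
  })
  expect_true(all(diff(norms) >= -1e-10))
})

test_that("row-scaled weighting equals pre-scaled data with unit weights", {
  set.seed(14)
  H <- matrix(runif(18 * 6), 18, 6)
  y <- sign(rnorm(18))
  gam <- runif(18, 0.5, 8)
  b1 <- solve_beta(H, y, gamma = gam, C = 2)
  # (gamma.H)'(gamma.H) identity: same solution from pre-scaled inputs
  b2 <- solve_beta(gam * H, gam * y, gamma = NULL, C = 2)
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("linear weighting variant solves the Gamma-linear system", {
  set.seed(15)
  H <- matrix(runif(20 * 6), 20, 6)
  y <- sign(rnorm(20))
  gam <- runif(20, 1, 10)
  beta <- solve_beta(H, y, gamma = gam, C = 5, weighting = "linear")
  lhs <- (diag(6) / 5 + crossprod(H, gam * H)) %*% beta
  rhs <- crossprod(H, gam * y)
  expect_equal(drop(lhs), drop(rhs), tolerance = 1e-8)
})

test_that("unweighted full-node model agrees with a spectral ridge oracle", {
  X <- rand_bits(30, 64, p = 0.3, seed = 16)
  y <- sign(rnorm(30))
  K <- pairwise_matrix("C03", X)
  C <- 7
  beta <- solve_beta(K, y, gamma = NULL, C = C)
  # independent spectral route through the eigendecomposition of K
  e <- eigen(K, symmetric = TRUE)
  beta_spec <- e$vectors %*% ((e$values * crossprod(e$vectors, y)) /
                                (e$values^2 + 1 / C))
  expect_equal(beta, drop(beta_spec), tolerance = 1e-8)
  # and the fitted scores agree on fresh molecules
  Xt <- rand_bits(12, 64, p = 0.3, seed = 17)
  Kt <- similarity_matrix("C03", Xt, X)
  expect_equal(drop(Kt %*% beta), drop(Kt %*% beta_spec), tolerance = 1e-8)
})

test_that("random training samples nodes without replacement and is seeded", {
  fp <- separable_set(n_active = 8, n_inactive = 40, m = 64, seed = 20)
  n <- nrow(fp$bits)
  fit_all <- wselm(fp, coef = "C03", method = "random", l = n, C = 1,
                   seed = 3)
  # l = n: the node set is a permutation of the training rows
  expect_equal(sort(fit_all$selection$index), 1:n)
  expect_equal(fit_all$W[order(fit_all$selection$index), ], fp$bits)

  f1 <- wselm(fp, coef = "C03", method = "random", l = 12, C = 1, seed = 5)
  f2 <- wselm(fp, coef = "C03", method = "random", l = 12, C = 1, seed = 5)
  f3 <- wselm(fp, coef = "C03", method = "random", l = 12, C = 1, seed = 6)
  expect_identical(f1$selection$index, f2$selection$index)
  expect_identical(f1$beta, f2$beta)
  expect_false(identical(f1$selection$index, f3$selection$index))
  expect_false(any(duplicated(f1$selection$index)))

  expect_error(wselm(fp, method = "random", l = n + 1), "1..n")
})

test_that("training on separable data reaches AUROC 1", {
  fp <- separable_set(n_active = 10, n_inactive = 80, m = 128, seed = 21)
  fit <- wselm(fp, coef = "C03", method = "random", l = 40, C = 100,
               seed = 1)
  expect_equal(auroc(fitted(fit), fp$labels), 1.0)
})

test_that("prediction is the hidden-activation projection and is equivariant", {
  fp <- separable_set(seed = 22)
  fit <- wselm(fp, coef = "C03", method = "random", l = 20, C = 1, seed = 2)

  # single molecule equal to the only hidden node, beta = 1 -> score 1
  one <- list(W = fp$bits[1, , drop = FALSE], beta = 1, coef = "C03")
  class(one) <- "wselm"
  expect_equal(predict(one, fp$bits[1, , drop = FALSE]), 1)

  # training-set prediction reproduces the stored fit
  expect_equal(predict(fit, fp), fitted(fit), tolerance = 1e-12)

  # permutation equivariance
  Xt <- rand_bits(15, 128, seed = 23)
  p <- sample(15)
  expect_equal(predict(fit, Xt)[p], predict(fit, Xt[p, ]))

  expect_error(predict(fit, rand_bits(3, 16, seed = 1)), "bit length")
})

test_that("models serialise to text and back losslessly", {
  fp <- separable_set(seed = 24)
  fit <- wselm(fp, coef = "C10", method = "random", l = 15, C = 0.5,
               seed = 9)
  path <- tempfile(fileext = ".txt")
  write_wselm(fit, path)
  back <- read_wselm(path)
  expect_equal(back$W, unname(fit$W))
  expect_equal(back$beta, fit$beta)
  expect_equal(back$C, fit$C)
  expect_identical(back$coef, fit$coef)
  Xt <- rand_bits(10, 128, seed = 25)
  expect_equal(predict(back, Xt), predict(fit, Xt), tolerance = 1e-12)
  unlink(path)
})
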