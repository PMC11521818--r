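test_that("varimax rotation separates two latent wavelength blocks", {
  set.seed(31)
  n <- 120
  f1 <- rnorm(n); f2 <- rnorm(n)
  block1 <- outer(f1, runif(15, 0.8, 1.2)) + matrix(rnorm(n * 15, sd = 0.05), n)
  block2 <- outer(f2, runif(15, 0.8, 1.2)) + matrix(rnorm(n * 15, sd = 0.05), n)
  X <- cbind(block1, block2)
  colnames(X) <- sprintf("wl_%.1f", seq(400, by = 10, length.out = 30))
  lm2 <- pca_varimax(X, n_components = 2)
  L <- abs(lm2$loadings)
  # each rotated component loads > 0.9 on exactly one block
  for (k in 1:2) {
    on_block1 <- mean(L[1:15, k]) > 0.9
    on_block2 <- mean(L[16:30, k]) > 0.9
    expect_true(xor(on_block1, on_block2))
  }
})

test_that("a single retained component is returned unrotated", {
  set.seed(32)
  f <- rnorm(80)
  X <- outer(f, runif(10, 0.9, 1.1)) + matrix(rnorm(800, sd = 0.05), 80)
  res <- pca_varimax(X, n_components = 1)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(abs(res$loadings[, 1]),
               abs(pc$rotation[, 1] * pc$sdev[1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$rotmat, diag(1))
})

test_that("varimax preserves communalities and total explained variance", {
  set.seed(33)
  X <- matrix(rnorm(200 * 12), 200, 12) +
    outer(rnorm(200), runif(12)) + outer(rnorm(200), runif(12))
  res <- pca_varimax(X, n_components = 3)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  unrot <- pc$rotation[, 1:3] %*% diag(pc$sdev[1:3])
  expect_equal(rowSums(res$loadings^2), rowSums(unrot^2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(res$explained_variance),
               sum(pc$sdev[1:3]^2) / ncol(X), tolerance = 1e-8)
})

test_that("degenerate inputs to pca_varimax are rejected", {
  expect_error(pca_varimax(matrix(1:4, 1)), class = "chlorospec_decomposition_error")
  X <- cbind(rnorm(10), rep(2, 10))
  expect_error(pca_varimax(X), class = "chlorospec_decomposition_error")
})

test_that("relative-SD profiles behave per group", {
  grid <- seq(400, 1000, by = 50)
  mk <- function(id, v, chl) toy_spectrum(grid, rep(v, 13), chl, id)
  # identical spectra in a group give zero relative SD
  set <- spectra_set(list(mk("a", 0.3, 1000), mk("b", 0.3, 1200),
                          mk("c", 0.4, 2000), mk("d", 0.5, 2600)))
  prof <- sd_profile(set, list(c(900, 1300), c(900, 3000)))
  expect_true(all(prof$relative_sd[, 1] == 0))
  # the wider, nested group is computed over the union sample set
  expect_equal(prof$n_per_group, c(2, 4))
  man <- apply(rbind(0.3, 0.3, 0.4, 0.5), 2, sd) / mean(c(0.3, 0.3, 0.4, 0.5))
  expect_equal(unname(prof$relative_sd[1, 2]), man[1])
  expect_error(sd_profile(set, list(c(5000, 6000))),
               class = "chlorospec_grouping_error")
})

test_that("the widest chlorophyll group peaks in relative SD near 670 nm", {
  set <- generate_dataset(fast_config(n_samples = 150, seed = 17))
  prof <- sd_profile(set)
  widest <- prof$relative_sd[, ncol(prof$relative_sd)]
  peak <- prof$wavelengths[which.max(widest)]
  expect_gte(peak, 655)
  expect_lte(peak, 685)
})

test_that("wavelength picking finds loading extrema with tie-break rules", {
  wl <- seq(400, 1000, by = 1)
  curve <- 0.2 +
    0.6 * exp(-0.5 * ((wl - 516) / 8)^2) +
    0.55 * exp(-0.5 * ((wl - 551) / 8)^2) -
    0.5 * exp(-0.5 * ((wl - 763) / 10)^2)
  lmx <- structure(list(wavelengths = wl,
                        loadings = matrix(curve, ncol = 1,
                                          dimnames = list(NULL, "RC1")),
                        explained_variance = 1, eigenvalues = 1,
                        rotmat = diag(1), n_components = 1L),
                   class = "loadings_matrix")
  ws <- pick_wavelengths(lmx, n_max = 2, n_min = 1)
  expect_equal(ws$maxima, c(516, 551))
  expect_equal(ws$minima, 763)
  # a single interior maximum (plus one dip) is returned as is
  single <- structure(list(wavelengths = wl,
                           loadings = matrix(exp(-0.5 * ((wl - 700) / 30)^2) -
                                               0.4 * exp(-0.5 * ((wl - 900) / 20)^2),
                                             ncol = 1),
                           explained_variance = 1, eigenvalues = 1,
                           rotmat = diag(1), n_components = 1L),
                      class = "loadings_matrix")
  expect_equal(pick_wavelengths(single, n_max = 1, n_min = 1)$maxima, 700)
  expect_equal(pick_wavelengths(single, n_max = 1, n_min = 1)$minima, 900)
  expect_error(pick_wavelengths(single, n_max = 5, n_min = 1),
               class = "chlorospec_selection_error")
})

test_that("selected wavelengths do not depend on sample order", {
  set <- generate_dataset(fast_config(n_samples = 80, seed = 23))
  X <- reflectance_matrix(set)
  perm <- sample(nrow(X))
  w1 <- pick_wavelengths(pca_varimax(X, n_components = 2))
  w2 <- pick_wavelengths(pca_varimax(X[perm, ], n_components = 2))
  expect_equal(w1$maxima, w2$maxima)
  expect_equal(w1$minima, w2$minima)
})

test_that("VIF and tolerance follow the closed form", {
  set.seed(41)
  # mean-zero, mutually orthogonal features: VIF exactly 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200, 3))))[, -1]
  rep1 <- collinearity(q)
  expect_equal(rep1$vif, rep(1, 3), tolerance = 1e-9)
  expect_equal(rep1$tolerance, rep(1, 3), tolerance = 1e-9)
  expect_false(any(rep1$flagged))

  # two features with empirical correlation exactly 0.9
  z <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 2), 100, 2))))[, -1]
  x1 <- z[, 1]
  x2 <- 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2]
  rep2 <- collinearity(cbind(a = x1, b = x2))
  expect_equal(rep2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_true(all(rep2$flagged))

  # an exact duplicate yields infinite VIF with a flag, not an error
  rep3 <- collinearity(cbind(x1, x1, z[, 2]))
  expect_true(is.infinite(rep3$vif[1]) && is.infinite(rep3$vif[2]))
  expect_equal(rep3$tolerance[1], 0)
  expect_true(all(rep3$flagged[1:2]))
})

test_that("VIF >= 1 and vif * tolerance = 1 on random full-rank designs", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 4), 60, 4) %*% (diag(4) + 0.3)
    rep <- collinearity(X)
    finite <- is.finite(rep$vif)
    expect_true(all(rep$vif[finite] >= 1 - 1e-12))
    expect_equal(rep$vif[finite] * rep$tolerance[finite],
                 rep(1, sum(finite)), tolerance = 1e-9)
  }
})
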