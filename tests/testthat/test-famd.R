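test_that("encoding reduces to PCA and MCA in the pure limits", {
  set.seed(1)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  m <- famd(X, ndim = 3)
  expect_equal(m$eigenvalues, eigen(cor(X))$values, tolerance = 1e-8)
  expect_equal(m$total_inertia, 3)

  # single binary categorical, balanced: one dimension of inertia K - 1 = 1
  Y <- data.frame(g = factor(rep(c("x", "y"), each = 10)))
  m2 <- famd(Y, ndim = 1)
  expect_equal(m2$eigenvalues, 1, tolerance = 1e-10)
  expect_equal(m2$total_inertia, 1)

  # all-categorical table: eigenvalues equal the independently coded
  # indicator-matrix decomposition, sum equals sum(K_j - 1)
  set.seed(2)
  C <- data.frame(u = factor(sample(letters[1:3], 30, TRUE)),
                  v = factor(sample(letters[4:5], 30, TRUE)))
  m3 <- famd(C, ndim = 2)
  o3 <- oracle_famd(NULL, C)
  expect_equal(m3$eigenvalues, o3$eigenvalues, tolerance = 1e-8)
  expect_equal(sum(m3$eigenvalues), (3 - 1) + (2 - 1), tolerance = 1e-8)
})

test_that("a toy mixed table encodes cell-by-cell as the formulas say", {
  d <- data.frame(x = c(1, 2, 3, 6), g = factor(c("a", "a", "b", "b")))
  enc <- encode_mixed(d)
  x <- d$x
  sx <- sqrt(mean((x - mean(x))^2))
  expect_equal(enc$X[, "x"], (x - mean(x)) / sx, tolerance = 1e-12,
               ignore_attr = TRUE)
  # binary categorical, p = 0.5 each: (y - p)/sqrt(p)
  ya <- c(1, 1, 0, 0)
  expect_equal(enc$X[, "g=a"], (ya - 0.5) / sqrt(0.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(enc$total_inertia, 1 + (2 - 1))
  # raw indicators sum to 1 across a variable's levels before weighting
  expect_error(encode_mixed(data.frame(x = rep(1, 4))), "zero variance")
  expect_error(encode_mixed(data.frame(g = factor(rep("a", 4)))),
               "fewer than 2 observed levels")
})

test_that("the mixed decomposition agrees with an independent oracle", {
  d <- data.frame(x = c(0.5, 1.9, 3.4, 2.2, 5.0, 4.1),
                  y = c(10, 12, 9, 14, 11, 13),
                  g = factor(c("a", "b", "a", "c", "b", "c")))
  m <- famd(d, ndim = 4)
  o <- oracle_famd(d[c("x", "y")], d["g"])
  expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-8)
  expect_equal(m$total_inertia, 2 + (3 - 1))
  expect_equal(sum(m$eigenvalues), m$total_inertia, tolerance = 1e-8)

  # individual coordinate variance (n denominator) equals the eigenvalue
  n <- nrow(d)
  v <- apply(m$ind_coords, 2, function(f) sum((f - mean(f))^2) / n)
  expect_equal(unname(v), m$eigenvalues[1:4], tolerance = 1e-8)

  # contributions sum to 100 per dimension
  expect_equal(unname(colSums(m$contrib)), rep(100, 4), tolerance = 1e-6)
  expect_equal(unname(colSums(m$var_contrib)), rep(100, 4),
               tolerance = 1e-6)

  # full-rank reconstruction of the weighted encoded matrix
  enc <- encode_mixed(d)
  fit <- famd_fit(enc, ndim = m$rank)
  S_rec <- (fit$ind_coords / sqrt(n)) %*%
    t(fit$col_coords %*% diag(1 / sqrt(fit$eigenvalues[1:fit$rank])))
  # F V' D^{-1} recovers U D V' = S
  expect_equal(unname(S_rec), unname(enc$X / sqrt(n)), tolerance = 1e-8)
})

test_that("row and column permutations behave as expected", {
  set.seed(5)
  d <- data.frame(x = rnorm(15), y = rnorm(15),
                  g = factor(sample(c("a", "b"), 15, TRUE)))
  m <- famd(d, ndim = 2)
  perm <- sample(15)
  mp <- famd(d[perm, ], ndim = 2)
  expect_equal(unname(mp$ind_coords), unname(m$ind_coords[perm, ]),
               tolerance = 1e-8)
  mc <- famd(d[c("g", "y", "x")], ndim = 2)
  expect_equal(mc$eigenvalues, m$eigenvalues, tolerance = 1e-10)
})

test_that("ndim above the rank is rejected with the attained rank", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))  # collinear
  expect_error(famd(d, ndim = 2), "rank \\(1\\)")
})

test_that("scree data reports exact monotone percentages", {
  set.seed(6)
  d <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  m <- famd(d, ndim = 3)
  sp <- screeplot_data(m)
  expect_equal(sp$percent, 100 * m$eigenvalues / 3)
  expect_true(all(diff(sp$cumulative) >= 0))
  expect_equal(sp$cumulative[nrow(sp)], 100, tolerance = 1e-8)

  one <- famd(data.frame(x = rnorm(10)), ndim = 1)
  expect_equal(screeplot_data(one)$percent, 100)
})

test_that("top contributors rank deterministically and find structure", {
  set.seed(7)
  base <- rnorm(60)
  d <- data.frame(lead = base + rnorm(60, 0, 0.05),
                  echo = base + rnorm(60, 0, 0.05),
                  noise1 = rnorm(60), noise2 = rnorm(60))
  m <- famd(d, ndim = 2)
  top <- top_contributors(m, dim = 1, k = 2)
  expect_setequal(top$variable, c("lead", "echo"))
  expect_error(top_contributors(m, dim = 5), "1\\.\\.2")

  # independent equal-variance variables: roughly equal average contributions
  set.seed(8)
  contribs <- rowMeans(vapply(1:30, function(i) {
    di <- as.data.frame(matrix(rnorm(200), 50, 4))
    famd(di, ndim = 4)$var_contrib[, 1]
  }, numeric(4)))
  expect_true(all(abs(contribs - 25) < 8))
})
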