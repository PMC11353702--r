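random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("Kabsch beats a dense random-rotation search and stays proper", {
  set.seed(41)
  for (rep in 1:3) {
    P <- matrix(rnorm(15), 5)
    Q <- matrix(rnorm(15), 5)
    k <- kabsch(P, Q)
    expect_equal(det(k$R), 1, tolerance = 1e-10)
    # no rotation from a large random sample does better
    P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
    best <- min(vapply(1:3000, function(i) {
      R <- random_rotation()
      sqrt(mean(rowSums((P0 %*% R - Q0)^2)))
    }, numeric(1)))
    expect_lte(k$rmsd, best + 1e-9)
  }
  # reflection-related structures cannot reach zero with proper rotations
  P <- matrix(rnorm(12), 4)
  Pm <- P %*% diag(c(-1, 1, 1))
  expect_gt(kabsch(P, Pm)$rmsd, 0.05)
})

test_that("aligning a rigidly moved trajectory collapses RMSD to zero", {
  set.seed(43)
  base <- matrix(rnorm(30, sd = 5), 10)
  coords <- array(NA_real_, dim = c(20, 10, 3))
  for (f in 1:20)
    coords[f, , ] <- base %*% t(random_rotation()) +
      matrix(rnorm(3, sd = 4), 10, 3, byrow = TRUE)
  tr <- new_trajectory(coords, c(500, 500, 500))
  al <- align_trajectory(tr, 1:10)
  expect_lt(max(al$rmsd), 1e-6)
  al2 <- align_trajectory(tr, 1:10, reference = "first_frame")
  expect_lt(max(al2$rmsd), 1e-6)
})

test_that("RMSD and RMSF closed forms hold", {
  base <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), 4, byrow = TRUE)
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- base
  moved <- base; moved[1, 3] <- 2   # one atom displaced 2 A
  coords[2, , ] <- moved
  tr <- new_trajectory(coords, c(100, 100, 100))
  al <- align_trajectory(tr, 1:4, reference = "first_frame")
  k <- kabsch(moved, base)
  # direct (unaligned) displacement: sqrt(2^2 / 4) = 1; Kabsch can only
  # reduce it
  expect_equal(sqrt(mean(rowSums((moved - base)^2))), 1)
  expect_lte(k$rmsd, 1)
  # identical frames: zero RMSD and RMSF
  tr0 <- pinned_trajectory(base, n_frames = 5)
  al0 <- align_trajectory(tr0, 1:4)
  expect_equal(al0$rmsd, rep(0, 5), tolerance = 1e-12)
  expect_equal(rmsf(al0, 1:4), rep(0, 4), tolerance = 1e-12)
})

test_that("RMSF of a Gaussian-mode ensemble matches the mode variances", {
  set.seed(47)
  mean_s <- matrix(rnorm(45, sd = 6), 15)
  g <- generate_gaussian_modes(mean_s, c(4, 1), n_frames = 4000, seed = 13)
  al <- align_trajectory(g$trajectory, 1:15, reference = "first_frame")
  f <- rmsf(al, 1:15)
  # per-atom variance: sum over modes of lambda_i * |mode_i(atom)|^2
  pred <- sqrt(vapply(1:15, function(a) {
    rows <- (3 * (a - 1) + 1):(3 * a)
    sum(g$eigenvalues[1] * g$modes[rows, 1]^2 +
        g$eigenvalues[2] * g$modes[rows, 2]^2)
  }, numeric(1)))
  expect_lt(max(abs(f - pred) / pred), 0.1)
})

test_that("PCA recovers injected eigenvalues and satisfies the trace identity", {
  set.seed(51)
  mean_s <- matrix(rnorm(60, sd = 8), 20)
  g <- generate_gaussian_modes(mean_s, c(4, 1), n_frames = 4000,
                               rigid_motion = TRUE, seed = 15)
  al <- align_trajectory(g$trajectory, 1:20)
  pca <- pca_ca(al, 1:20, n_components = 5)
  expect_lt(abs(pca$eigenvalues[1] - 4) / 4, 0.1)
  expect_lt(abs(pca$eigenvalues[2] - 1) / 1, 0.1)
  expect_gt(sum(pca$variance_explained[1:2]), 0.95)
  # eigenvalue sum equals total centred variance
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-8)
  # eigenvectors orthonormal
  k <- ncol(pca$eigenvectors)
  expect_equal(unname(crossprod(pca$eigenvectors)), diag(k), tolerance = 1e-8)
  # static trajectory: all eigenvalues zero
  tr0 <- pinned_trajectory(mean_s, n_frames = 10)
  pca0 <- pca_ca(align_trajectory(tr0, 1:20, reference = "first_frame"),
                 1:20)
  expect_lt(max(pca0$eigenvalues), 1e-12)
  # rigid-motion-only trajectory: alignment removes everything
  g0 <- generate_gaussian_modes(mean_s, 0, n_frames = 30,
                                rigid_motion = TRUE, seed = 2)
  pcar <- pca_ca(align_trajectory(g0$trajectory, 1:20), 1:20)
  expect_lt(max(pcar$eigenvalues), 1e-6)
})

test_that("free-energy landscapes pin the minimum at zero and obey limits", {
  set.seed(53)
  X <- matrix(rnorm(4e4), ncol = 2)
  fel <- fel_2d(X, bins = 20, temperature = 323.15)
  expect_equal(min(fel$F, na.rm = TRUE), 0)
  expect_true(all(fel$F >= 0, na.rm = TRUE))
  expect_true(all(is.na(fel$F[fel$mask])))
  # harmonic radial profile: F ~ 0.5 kB T r^2
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  rr2 <- outer(mid(fel$pc1_edges)^2, mid(fel$pc2_edges)^2, "+")
  ok <- !fel$mask & rr2 < 9
  fit <- stats::lm(fel$F[ok] ~ rr2[ok])
  expect_gt(summary(fit)$r.squared, 0.95)
  # sign-flip equivariance
  fel_flip <- fel_2d(cbind(-X[, 1], X[, 2]), bins = 20, temperature = 323.15)
  expect_equal(fel_flip$F[20:1, ], fel$F, tolerance = 1e-9)
  # translation invariance of the landscape shape
  fel_shift <- fel_2d(X + 5, bins = 20, temperature = 323.15)
  expect_equal(fel_shift$F, fel$F, tolerance = 1e-9)
  # all frames identical: one unmasked bin at F = 0
  fel1 <- fel_2d(matrix(1, 50, 2), bins = 5)
  expect_equal(sum(!fel1$mask), 1L)
  expect_equal(fel1$F[!fel1$mask], 0)
})

test_that("minima detection separates basins by barrier persistence", {
  kT <- kT_at()
  e <- seq(-5, 5, length.out = 41)
  mid <- (e[-1] + e[-length(e)]) / 2
  # single Gaussian: one minimum at any threshold
  d1 <- outer(mid, mid, function(x, y) exp(-(x^2 + y^2) / 2))
  f1 <- fel_from_probability(d1, e, e)
  expect_equal(nrow(find_minima(f1, 0.5 * kT)), 1L)
  # two Gaussians with a ~3 kT barrier
  d2 <- outer(mid, mid, function(x, y)
    exp(-((x + 2)^2 + y^2) / (2 * 0.7^2)) +
    exp(-((x - 2)^2 + y^2) / (2 * 0.7^2)))
  f2 <- fel_from_probability(d2, e, e)
  m_low <- find_minima(f2, 1 * kT)
  m_high <- find_minima(f2, 5 * kT)
  expect_equal(nrow(m_low), 2L)
  expect_equal(nrow(m_high), 1L)
  expect_equal(m_low$F[1], 0)
  # minima count is non-increasing in the threshold
  counts <- vapply(c(0.5, 1, 2, 3, 5, 8) * kT,
                   function(th) nrow(find_minima(f2, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(find_minima(fel_from_probability(
    matrix(c(1, rep(0, 24)), 5), seq(0, 5), seq(0, 5)), 1)$F,
    NA)  # masked-heavy grids are still valid
})
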