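test_that("directional gradients follow the neighbour-minus-centre convention with replicate borders", {
  img <- matrix(c(1, 3), 1, 2)  # [a, b] in one row
  g <- directional_gradients(img)
  expect_equal(g$east[1, 1], 2)   # b - a
  expect_equal(g$west[1, 1], 0)   # border
  expect_equal(g$west[1, 2], -2)
  expect_equal(g$east[1, 2], 0)

  const <- matrix(5, 6, 7)
  gc <- directional_gradients(const)
  for (d in gc) expect_true(all(d == 0))

  set.seed(10)
  m <- matrix(rnorm(48), 6, 8)
  gm <- directional_gradients(m)
  # antisymmetry: east at (r, c) = -west at (r, c+1)
  expect_equal(gm$east[, 1:7], -gm$west[, 2:8])
  expect_equal(gm$south[1:5, ], -gm$north[2:6, ])
})

test_that("conduction is the exponential edge-stopping function", {
  expect_equal(conduction(0, 30), 1)
  expect_equal(conduction(30, 30), exp(-1))
  expect_equal(conduction(60, 30), exp(-4))
  expect_error(conduction(matrix(1), 0), "positive")
  set.seed(11)
  g <- matrix(rnorm(100, sd = 50), 10)
  cc <- conduction(g, 25)
  expect_true(all(cc > 0 & cc <= 1))
})

test_that("diffuse_step matches the per-pixel scalar oracle", {
  p <- diffusion_params(kappa = 30, lambda = 0.25, iterations = 1)
  img <- matrix(0, 3, 3); img[2, 2] <- 100
  expect_equal(diffuse_step(img, p),
               oracle_diffuse_step(img, 30, 0.25), tolerance = 1e-14)

  set.seed(12)
  for (i in 1:10) {
    m <- matrix(rnorm(64, sd = 200), 8, 8)
    expect_equal(max(abs(diffuse_step(m, p) - oracle_diffuse_step(m, 30, 0.25))),
                 0, tolerance = 1e-12)
  }
})

test_that("a constant image is a fixed point and intensity is conserved", {
  p <- diffusion_params()
  const <- matrix(42, 9, 9)
  expect_equal(diffuse(const, p), const)

  set.seed(13)
  for (i in 1:10) {
    m <- matrix(rnorm(14 * 11, 100, 300), 14, 11)
    out <- diffuse_step(m, p)
    expect_equal(sum(out), sum(m), tolerance = 1e-9)
  }
})

test_that("the extremum principle holds for lambda <= 1/4", {
  set.seed(14)
  for (lam in c(0.1, 0.25)) {
    p <- diffusion_params(lambda = lam, iterations = 5)
    m <- matrix(rnorm(100, sd = 500), 10, 10)
    out <- diffuse(m, p)
    expect_gte(min(out), min(m))
    expect_lte(max(out), max(m))
  }
})

test_that("diffuse composes diffuse_step and reduces within-region variance on a noisy phantom", {
  p <- diffusion_params(iterations = 1)
  set.seed(15)
  m <- matrix(rnorm(64), 8, 8)
  expect_identical(diffuse(m, p), diffuse_step(m, p))

  case <- make_phantom(phantom_spec(seed = 7, dose_fraction = 0.5))
  den <- diffuse(case$image, diffusion_params(iterations = 15))
  liver <- case$liver_mask == 1 & case$lesion_mask == 0
  expect_lt(var(den[liver]), var(case$image[liver]))
})

test_that("larger kappa smooths at least as much (total variation sweep)", {
  # lambda 0.2 so every spatial frequency is strictly damped; at 0.25 the
  # conduction->1 limit is pure neighbour averaging, whose checkerboard mode
  # does not decay and breaks the monotone ordering
  for (s in 1:3) {
    set.seed(s)
    img <- matrix(50 + rnorm(40 * 40, 0, 15), 40)
    tvs <- vapply(c(5, 10, 20, 30, 50, 80),
                  function(k) total_variation(
                    diffuse(img, diffusion_params(kappa = k, lambda = 0.2,
                                                  iterations = 10))),
                  numeric(1))
    expect_false(is.unsorted(rev(tvs)))
  }
})

test_that("runtime grows roughly linearly in pixel count (O(T N^2))", {
  p <- diffusion_params(iterations = 8)
  set.seed(16)
  small <- matrix(rnorm(96^2), 96)
  big <- matrix(rnorm(192^2), 192)
  t_small <- system.time(for (i in 1:3) diffuse(small, p))[["elapsed"]]
  t_big <- system.time(for (i in 1:3) diffuse(big, p))[["elapsed"]]
  # 4x the pixels: allow a generous constant-factor margin, this is a
  # scaling sanity check, not a benchmark
  expect_lt(t_big, max(12 * t_small, 0.5))
})

test_that("diffusion parameter validation rejects unstable settings", {
  expect_error(diffusion_params(kappa = -1), "positive")
  expect_error(diffusion_params(lambda = 0.3), "0.25")
  expect_error(diffusion_params(lambda = 0), "0.25")
  expect_error(diffusion_params(iterations = 0), "positive integer")
})
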