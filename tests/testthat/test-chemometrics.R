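make_toy_cube <- function(data, wn = NULL) {
  d <- dim(data)
  lam <- seq(638, 752, length.out = d[3])
  hyperspec_cube(data, lam,
                 if (is.null(wn)) 1e7 / lam - 1e7 / 790 else wn)
}

test_that("additive averaging is the band mean with threshold masking", {
  cube <- make_toy_cube(array(3, c(4, 5, 10)))
  av <- additive_averaging(cube, bands = 1:10)
  expect_true(all(av$map == 3))
  ## S = 10 over n = 5 bands -> 2
  arr <- array(2, c(2, 2, 5))
  av2 <- additive_averaging(make_toy_cube(arr), bands = 1:5)
  expect_true(all(av2$map == 2))
  ## vacuous thresholds mask everything in
  expect_true(all(av2$mask))
  av3 <- additive_averaging(make_toy_cube(arr), bands = 1:5,
                            intensity_thresholds = c(3, 4))
  expect_false(any(av3$mask))
  expect_error(additive_averaging(cube, wavenumber_range = c(10, 20)),
               "empty band selection")
})

test_that("NDSI follows its defining arithmetic and bounds", {
  arr <- array(0, c(1, 3, 2))
  arr[1, , 1] <- c(3, 1, 1)     # I_1
  arr[1, , 2] <- c(1, 1, 0)     # I_2
  cube <- make_toy_cube(arr)
  nd <- ndsi_map(cube, 1, 2)
  expect_equal(nd$map[1, ], c(0.5, 0, 1))
  expect_warning(ndsi_map(cube, 1, 1), "identically zero")
  ## zero denominator flagged, set to zero
  arr0 <- array(0, c(1, 1, 2))
  nd0 <- ndsi_map(make_toy_cube(arr0), 1, 2)
  expect_equal(nd0$map[1, 1], 0)
  expect_true(nd0$flagged[1, 1])
})

test_that("NDSI is antisymmetric under band swap and within [-1, 1]", {
  arr <- withr::with_seed(5, array(stats::runif(4 * 5 * 3, 0, 100),
                                   c(4, 5, 3)))
  cube <- make_toy_cube(arr)
  a <- ndsi_map(cube, 1, 2)$map
  b <- ndsi_map(cube, 2, 1)$map
  expect_equal(a, -b)
  expect_true(all(a >= -1 & a <= 1))
})

test_that("teaching regions satisfy every strict inequality and are disjoint", {
  ## the full-scale sampling rule: 125 regions, 4 < x < 35, 3 < y < 55,
  ## 20 < x*y < 720, drawn over a 640 x 480 image
  rc <- region_constraint(4, 35, 3, 55, 20, 720, 125)
  labels <- matrix(1L, 480, 640)
  ts <- sample_teaching_regions(NULL, rc, seed = 21, label_map = labels,
                                legend = c(all = 1L))
  expect_equal(nrow(ts$regions), 125)
  with(ts$regions, {
    expect_true(all(width > 4 & width < 35))
    expect_true(all(height > 3 & height < 55))
    expect_true(all(width * height > 20 & width * height < 720))
  })
  ## disjoint: occupancy painted exactly once
  occ <- matrix(0L, 480, 640)
  for (i in seq_len(nrow(ts$regions))) {
    rg <- ts$regions[i, ]
    occ[rg$y0:(rg$y0 + rg$height - 1), rg$x0:(rg$x0 + rg$width - 1)] <-
      occ[rg$y0:(rg$y0 + rg$height - 1), rg$x0:(rg$x0 + rg$width - 1)] + 1L
  }
  expect_lte(max(occ), 1L)
  ## determinism
  ts2 <- sample_teaching_regions(NULL, rc, seed = 21, label_map = labels,
                                 legend = c(all = 1L))
  expect_identical(ts$regions, ts2$regions)
})

test_that("region constraints hold across random seeds (property)", {
  rc <- region_constraint(2, 8, 2, 8, 5, 40, 10)
  labels <- matrix(1L, 48, 64)
  for (seed in 1:8) {
    ts <- sample_teaching_regions(NULL, rc, seed = seed,
                                  label_map = labels)
    expect_true(all(ts$regions$width > 2 & ts$regions$width < 8))
    expect_true(all(ts$regions$height > 2 & ts$regions$height < 8))
    a <- ts$regions$width * ts$regions$height
    expect_true(all(a > 5 & a < 40))
  }
})

test_that("a forced single feasible region is found; infeasible errors", {
  rc <- region_constraint(2, 4, 2, 4, 8, 10, 1)   # only 3x3 = 9 qualifies
  labels <- matrix(1L, 3, 3)
  ts <- sample_teaching_regions(NULL, rc, seed = 1, label_map = labels)
  expect_equal(ts$regions$width, 3)
  expect_equal(ts$regions$height, 3)
  rc_many <- region_constraint(2, 4, 2, 4, 8, 10, 5)
  expect_error(sample_teaching_regions(NULL, rc_many, seed = 1,
                                       label_map = labels),
               "could only place")
})

test_that("SAM matches itself and is scale invariant", {
  spec <- withr::with_seed(3, matrix(stats::runif(3 * 20), 3, 20))
  rownames(spec) <- c("a", "b", "c")
  lab <- sam_classify(spec, spec)
  expect_equal(as.integer(lab), 1:3)
  lab5 <- sam_classify(5 * spec, spec)
  expect_equal(as.integer(lab5), 1:3)
  ## zero-norm pixel gets the unclassified label 0
  z <- rbind(spec, 0)
  expect_equal(as.integer(sam_classify(z, spec))[4], 0L)
})

test_that("SAM labels all channel interiors correctly without noise", {
  sim <- channel_sim(7, noise = FALSE)
  tr <- retrieve_cube(sim, xpm = FALSE)
  ts <- sample_teaching_regions(tr, channel_constraint(), seed = 3,
                                label_map = sim$labels,
                                legend = sim$legend)
  cm <- sam_classify(tr, ts)
  inch <- sim$labels > 0
  expect_equal(mean(cm[inch] == sim$labels[inch]), 1)
  expect_mapequal(attr(cm, "legend"), sim$legend)
})

test_that("two-class LDA matches the closed form", {
  set.seed(11)
  n <- 40; p <- 6
  x1 <- matrix(rnorm(n * p), n, p) + rep(c(2, 0, 0, 1, 0, 0), each = n)
  x2 <- matrix(rnorm(n * p), n, p)
  X <- rbind(x1, x2)
  cls <- rep(c("a", "b"), each = n)
  mdl <- lda_train(X, cls)
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  w_closed <- solve(mdl$S_W, mu1 - mu2)
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  cosang <- abs(sum(w_closed * mdl$w[, 1]))
  expect_gt(cosang, 1 - 1e-8)
})

test_that("identical class means give a zero Fisher criterion", {
  set.seed(4)
  X <- matrix(rnorm(60 * 4), 60, 4)
  cls <- rep(c("a", "b", "c"), each = 20)
  Xc <- X
  for (cn in unique(cls))
    Xc[cls == cn, ] <- sweep(X[cls == cn, ], 2,
                             colMeans(X[cls == cn, ]))  # all means 0
  mdl <- lda_train(Xc, cls)
  expect_lt(mdl$J, 1e-10)
})

test_that("the trained projection beats a 1e5 random-direction search", {
  set.seed(7)
  p <- 5
  mk <- function(mu) sweep(matrix(rnorm(30 * p), 30, p), 2, mu, `+`)
  X <- rbind(mk(c(3, 0, 0, 0, 0)), mk(c(0, 2, 0, 0, 0)),
             mk(c(0, 0, 1, 1, 0)))
  cls <- rep(c("a", "b", "c"), each = 30)
  mdl <- lda_train(X, cls)
  W <- matrix(rnorm(1e5 * p), 1e5, p)
  Jr <- rowSums((W %*% mdl$S_B) * W) / rowSums((W %*% mdl$S_W) * W)
  expect_gte(mdl$J, max(Jr))
})

test_that("the Fisher criterion is scale invariant", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3),
             matrix(rnorm(20 * 3, mean = 2), 20, 3))
  mdl <- lda_train(X, rep(c("a", "b"), each = 20))
  w <- mdl$w[, 1]
  for (c0 in c(-3, 0.01, 17))
    expect_equal(fisher_criterion(c0 * w, mdl$S_B, mdl$S_W),
                 fisher_criterion(w, mdl$S_B, mdl$S_W), tolerance = 1e-9)
})

test_that("LDA training rejects degenerate teaching sets", {
  X <- matrix(rnorm(10 * 3), 10, 3)
  expect_error(lda_train(X, rep("a", 10)), "two classes")
  expect_error(lda_train(X, c(rep("a", 9), "b")), "at least two")
})

test_that("a pixel at a class centroid is assigned to that class", {
  set.seed(9)
  X <- rbind(matrix(rnorm(20 * 4, 0), 20, 4),
             matrix(rnorm(20 * 4, 4), 20, 4))
  cls <- rep(c("lo", "hi"), each = 20)
  mdl <- lda_train(X, cls)
  cents <- rbind(colMeans(X[cls == "lo", ]), colMeans(X[cls == "hi", ]))
  lab <- lda_classify(cents, mdl)
  expect_equal(as.integer(lab), 1:2)
  expect_error(lda_classify(cents[, 1:3], mdl), "band count")
})

test_that("well-separated blob phantom is fully recovered by LDA", {
  sim <- .cached("blobsim", function() {
    simulate_cube(make_phantom("blobs", n_classes = 3, seed = 4),
                  default_species_library(),
                  optical_config(n_bands = 64), seed = 5, noise = FALSE)
  })
  tr <- retrieve_cube(sim, xpm = FALSE)
  X <- cube_spectra(tr)
  lab <- as.vector(sim$labels)
  sel <- lab > 0
  mdl <- suppressMessages(lda_train(X[sel, ], as.character(lab[sel])))
  cm <- lda_classify(tr, mdl)
  pred <- mdl$class_names[cm[sim$labels > 0]]
  expect_equal(mean(pred == as.character(sim$labels[sim$labels > 0])), 1)
})

test_that("edge response: ideal step is at the interpolation floor", {
  step <- c(rep(0, 10), rep(1, 10))
  expect_lte(edge_response_resolution(step, pixel_pitch_um = 2), 2)
})

test_that("a Gaussian-blurred edge gives 2.563 sigma within 2%", {
  sigma <- 4
  x <- seq(-40, 40)
  prof <- stats::pnorm(x / sigma)
  er <- edge_response_resolution(prof, pixel_pitch_um = 1)
  expect_equal(er, 2.5631 * sigma, tolerance = 0.02)
  ## decreasing edges work too
  expect_equal(edge_response_resolution(rev(prof)), er, tolerance = 1e-9)
})

test_that("non-monotone profiles are rejected", {
  bad <- c(0, 0.2, 0.8, 0.3, 1)
  expect_error(edge_response_resolution(bad), "not monotone")
})
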