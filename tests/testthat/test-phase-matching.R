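test_that("index ellipse identities hold at the principal angles", {
  cry0 <- gase_crystal(theta_deg = 0)
  cry90 <- gase_crystal(theta_deg = 90)
  lam <- c(700, 900, 5000)
  expect_equal(refractive_index(cry0, lam, "e"),
               refractive_index(cry0, lam, "o"), tolerance = 1e-12)
  n_e_principal <- sqrt(5.76 + 0.3879 / (lam / 1000)^2 -
                        0.2288 / (lam / 1000)^4 +
                        0.1223 / (lam / 1000)^6 +
                        1.8550 * (lam / 1000)^2 / ((lam / 1000)^2 - 1780.3))
  expect_equal(refractive_index(cry90, lam, "e"), n_e_principal,
               tolerance = 1e-12)
})

test_that("ordinary index matches direct Sellmeier evaluation", {
  cry <- gase_crystal()
  lam_um <- c(0.79, 1.5, 10)
  direct <- sqrt(7.443 + 0.4050 / lam_um^2 + 0.0186 / lam_um^4 +
                 0.0061 / lam_um^6 +
                 3.1485 * lam_um^2 / (lam_um^2 - 2193.8))
  expect_equal(refractive_index(cry, lam_um * 1000, "o"), direct,
               tolerance = 1e-12)
  expect_error(refractive_index(cry, 400, "o"), "validity")
  expect_error(refractive_index(cry, 25000, "o"), "validity")
})

test_that("a dispersionless crystal is exactly phase matched", {
  cry <- gase_crystal()
  ## flat indices: constant-A Sellmeier with all dispersion terms off
  flat <- c(A = 2.5^2, B2 = 0, B4 = 0, B6 = 0, C = 0, D = -1)
  cry$sellmeier <- list(o = flat, e = flat, validity_um = c(0.3, 30))
  expect_equal(delta_k(cry, c(800, 1500, 2500)), rep(0, 3),
               tolerance = 1e-10)
})

test_that("delta_k is symmetric under swapping the two ordinary inputs", {
  cry <- gase_crystal()
  wn_mir <- 1500                      # cm^-1
  lam_cp <- 790                       # nm
  ## swap: call the MIR wavelength the pump and the pump wavenumber the MIR
  wn_cp <- 1e7 / lam_cp
  lam_mir <- 1e7 / wn_mir
  expect_equal(delta_k(cry, wn_mir, lam_cp),
               delta_k(cry, wn_cp, lam_mir), tolerance = 1e-10)
})

test_that("the phase-matched wavenumber matches a dense sign-change scan", {
  cry <- gase_crystal()
  wn <- seq(640, 3015, by = 1)
  dk <- delta_k(cry, wn)
  flips <- which(diff(sign(dk)) != 0)
  expect_gte(length(flips), 1)
  wn_pm <- wn[flips[1]]
  ## efficiency is maximal within one grid step of the sign change
  eta <- conversion_efficiency(cry, wn)
  expect_lte(abs(wn[which.max(eta)] - wn_pm), 1)
})

test_that("sinc^2 law: unity at Delta_k 0, zero at Delta_k L/2 = pi", {
  cry <- gase_crystal(thickness_um = 100)
  wn <- seq(640, 3015, by = 1)
  dk <- delta_k(cry, wn)
  x <- dk * cry$thickness_um / 2
  eta <- conversion_efficiency(cry, wn, normalize = FALSE)
  ## exact zeros where x crosses multiples of pi
  zero_crossings <- which(diff(floor(x / pi)) != 0 & sign(x[-1]) ==
                            sign(x[-length(x)]))
  expect_gte(length(zero_crossings), 1)
  i <- zero_crossings[1]
  expect_lt(min(eta[i], eta[i + 1]), 1e-4 * max(eta))
})

test_that("thin film covers the band while a thick crystal fringes", {
  thin <- band_coverage(gase_crystal(thickness_um = 4.4),
                        band = c(640, 3015), threshold = 0)
  expect_true(thin$covered)
  expect_gt(thin$min_efficiency, 0)
  thick <- band_coverage(gase_crystal(thickness_um = 100),
                         band = c(640, 3015), threshold = 0)
  expect_false(thick$covered)
  ## degenerate band: min is the single-point efficiency
  single <- band_coverage(gase_crystal(4.4), band = c(1500, 1500))
  expect_equal(single$min_efficiency, 1)   # normalized to itself
  expect_equal(single$at_wavenumber, 1500)
})

test_that("efficiency scales as L^2 at small thickness where sinc ~ 1", {
  wn_pm <- 2030                        # near phase matching, sinc ~ 1
  e1 <- conversion_efficiency(gase_crystal(1), wn_pm, normalize = FALSE)
  e2 <- conversion_efficiency(gase_crystal(2), wn_pm, normalize = FALSE)
  expect_equal(e2 / e1, 4, tolerance = 0.02)
})

test_that("fringe spacing decreases with crystal thickness", {
  wn <- seq(640, 3015, by = 1)
  count_zeros <- function(L) {
    x <- delta_k(gase_crystal(L), wn) * L / 2
    sum(diff(floor(x / pi)) != 0)
  }
  expect_lt(count_zeros(50), count_zeros(100))
  expect_lt(count_zeros(100), count_zeros(200))
})

test_that("efficiency is continuous and non-negative over the band", {
  eta <- conversion_efficiency(gase_crystal(4.4), seq(640, 3015, by = 1))
  expect_true(all(eta >= 0))
  expect_lt(max(abs(diff(eta))), 0.01)
})
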