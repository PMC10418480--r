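make_pdf <- function(dens, normalized = FALSE, kind = "phi") {
  new("TorsionPDF", residue = 1L, kind = kind,
      grid = seq(-180, 180 - 360 / length(dens), by = 360 / length(dens)),
      density = dens, normalized = normalized,
      config = kernelConfig(w = pi / 2), exportable = TRUE)
}

test_that("Boltzmann inversion maps density to energy with a bounded floor", {
  u <- boltzmannInvert(make_pdf(rep(0.5, 36)))
  expect_equal(u$U, rep(-log(0.5), 36))          # uniform P -> constant U
  dens <- rep(exp(-1), 36); dens[10] <- 1
  u <- boltzmannInvert(make_pdf(dens))
  expect_equal(u$U[11], 1)                       # P = e^-1 -> U = 1
  expect_identical(which.min(u$U), which.max(dens))
  dens <- rep(1, 36); dens[1:5] <- 1e-12         # below the relative floor
  u <- boltzmannInvert(make_pdf(dens), floorEps = 1e-8)
  expect_true(all(u$floored[1:5]))
  expect_equal(u$U[1:5], rep(-log(1e-8), 5))
  expect_error(boltzmannInvert(make_pdf(rep(0, 36))), "all-zero")
})

test_that("reference-term standard deviation matches numerical integration", {
  expect_equal(referenceTermStd(data.frame(mult = integer(),
                                           halfAmp = numeric(),
                                           phase = numeric())[0, ]), 0)
  one <- data.frame(mult = 1, halfAmp = 1, phase = 0)
  expect_equal(referenceTermStd(one), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(referenceTermStd(one), oracle_term_std(one), tolerance = 1e-6)
  two <- data.frame(mult = c(1, 2), halfAmp = c(1, 1), phase = c(0, 0))
  expect_equal(referenceTermStd(two), 1, tolerance = 1e-9)
  expect_equal(referenceTermStd(two), oracle_term_std(two), tolerance = 1e-6)
  set.seed(14)
  for (i in 1:8) {
    nt <- sample(1:4, 1)
    terms <- data.frame(mult = sample(1:6, nt, replace = i %% 2 == 0),
                        halfAmp = stats::runif(nt, 0.1, 6),
                        phase = stats::runif(nt, 0, 360))
    expect_equal(referenceTermStd(terms), oracle_term_std(terms),
                 tolerance = 1e-6)
  }
  expect_error(referenceTermStd(data.frame(mult = 0, halfAmp = 1,
                                           phase = 0)), "positive")
})

test_that("scaling enforces the phi/psi standard-deviation ratios", {
  # profile with population sd exactly 1
  u <- c(rep(1, 18), rep(-1, 18))
  sc <- scalePEF(u, "phi", stdRef = 1)
  expect_equal(sc$f, 14.77)
  e <- sc$energy
  expect_equal(sqrt(mean((e - mean(e))^2)), 14.77, tolerance = 1e-12)
  expect_equal(min(e), 0)
  sc <- scalePEF(2 * u, "psi", stdRef = 1)
  expect_equal(sc$f, 2.65)
  expect_error(scalePEF(rep(3, 36), "phi", stdRef = 1), "degenerate")
})

test_that("degenerate (flat) profiles are skipped with a warning, not exported", {
  ens <- make_fixture_ensemble(nResidues = 3, nModels = 20, seed = 21)
  # a floor at the peak density flattens every profile: each residue is
  # degenerate, gets skipped, and the run yields no exportable potential
  w <- capture_warnings(
    pefs <- buildTorsionPEFs(ens, stdRef = 1, floorEps = 1))
  expect_gt(length(w), 0)
  expect_true(all(grepl("skipped", w)))
  expect_length(pefs, 0)
})

test_that("scaling postcondition holds across a randomized fixture suite", {
  for (seed in c(5, 17)) {
    ens <- make_fixture_ensemble(nResidues = 5, nModels = 40, seed = seed,
                                 kappa = 6)
    pefs <- buildTorsionPEFs(ens, stdRef = 2.1)
    expect_gt(length(pefs), 0)
    for (p in pefs) {
      e <- p@energy
      ratio <- sqrt(mean((e - mean(e))^2)) / p@stdRef
      expect_equal(ratio, unname(c(phi = 14.77, psi = 5.30)[p@kind]),
                   tolerance = 1e-9)
      expect_identical(which.min(p@energy),
                       which.max(densityValues(
                         ensemblePDFs(ens)[[sprintf("%d:%s", p@residue,
                                                    p@kind)]])))
    }
  }
})

test_that("analytic forces agree with numerical differentiation of the energy", {
  ens <- make_fixture_ensemble(nResidues = 4, nModels = 50, seed = 31,
                               kappa = 5)
  cfg <- kernelConfig(N = nModels(ens))
  ws <- scoreWeights(modelScores(ens))
  pefs <- buildTorsionPEFs(ens, stdRef = 1)
  h <- 1e-3  # degrees; FD truncation ~1e-9 relative at this step
  for (nm in c("2:phi", "3:psi")) {
    p <- pefs[[nm]]
    s <- dihedralSamples(ens, p@residue, p@kind)
    w <- exp(-modelScores(ens)[as.character(s$model)] / 10)
    floorAbs <- 0  # no floored points in this fixture
    expect_false(any(p@floored))
    eAt <- function(a) oracle_energy_at(a, s$angle, w, cfg@exponent, p@f,
                                        1e-300)
    fd <- -(eAt(p@grid + h) - eAt(p@grid - h)) / (2 * h) * 180 / pi
    expect_lt(max(abs(p@force - fd)) / max(abs(fd)), 1e-6)
    # force ~ 0 at the density argmax (grid resolution)
    imax <- which.min(p@energy)
    expect_lt(abs(p@force[imax]), max(abs(p@force)) * 0.05)
  }
})

test_that("force is antisymmetric for a symmetric single-kernel density", {
  cfg <- kernelConfig(w = pi / 3)
  p <- pefFromSamples(c(m = 0), NULL, cfg, residue = 1L, kind = "phi",
                      stdRef = 1)
  i0 <- which(p@grid == 0)
  ok <- !p@floored & !rev(p@floored)
  lhs <- p@force[i0 + 1:90]; rhs <- p@force[i0 - 1:90]
  expect_equal(lhs, -rhs, tolerance = 1e-9)
})

test_that("floored plateaus have exactly zero force and capped energy", {
  cfg <- kernelConfig(w = 0.2)  # very sharp kernel -> density underflows
  p <- pefFromSamples(c(m = 0), NULL, cfg, residue = 1L, kind = "phi",
                      stdRef = 1, floorEps = 1e-8)
  expect_gt(sum(p@floored), 0)
  expect_true(all(p@force[p@floored] == 0))
  expect_equal(max(p@energy), max(p@energy[p@floored]))
})

test_that("energy is normalization-invariant up to a constant; force exactly", {
  ens <- make_fixture_ensemble(nResidues = 3, nModels = 30, seed = 41)
  pN <- buildTorsionPEFs(ens, stdRef = 1, normalize = TRUE)[["2:phi"]]
  pU <- buildTorsionPEFs(ens, stdRef = 1, normalize = FALSE)[["2:phi"]]
  expect_equal(pN@energy, pU@energy, tolerance = 1e-9)  # same after shift
  expect_equal(pN@force, pU@force, tolerance = 1e-12)
  # monotone consistency between density and energy off the floor
  pdf <- ensemblePDFs(ens)[["2:phi"]]
  ord <- order(pdf@density)
  expect_true(all(diff(pN@energy[ord]) <= 1e-9))
})
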