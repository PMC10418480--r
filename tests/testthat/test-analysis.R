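rigid_move <- function(model, angleZ = 0.6, shift = c(3, -2, 7)) {
  R <- matrix(c(cos(angleZ), -sin(angleZ), 0,
                sin(angleZ), cos(angleZ), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]; a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  new("ModelRecord", modelId = model@modelId, atoms = a)
}

test_that("superposition recovers rigid-body transforms exactly", {
  ens <- make_fixture_ensemble(nResidues = 5, nModels = 1, seed = 61)
  ref <- ens@models[[1]]
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  expect_lt(superpose(rigid_move(ref), ref)$rmsd, 1e-9)
})

test_that("fitted RMSD matches a brute-force rotation-search oracle", {
  set.seed(62)
  ref4 <- matrix(stats::rnorm(12, sd = 2), 4, 3)      # asymmetric 4 points
  mob4 <- ref4 + matrix(stats::rnorm(12, sd = 0.3), 4, 3)
  refM <- new("ModelRecord", modelId = 1L, atoms = data.frame(
    name = "CA", resid = 1:4, resname = "ALA", chain = "A",
    x = ref4[, 1], y = ref4[, 2], z = ref4[, 3]))
  mobM <- new("ModelRecord", modelId = 2L, atoms = data.frame(
    name = "CA", resid = 1:4, resname = "ALA", chain = "A",
    x = mob4[, 1], y = mob4[, 2], z = mob4[, 3]))
  got <- superpose(mobM, refM, atomSelection(atoms = "CA"))$rmsd
  expect_equal(got, oracle_fit_rmsd(mob4, ref4), tolerance = 1e-3)
  # superposed RMSD never exceeds the unfitted RMSD
  expect_lte(got, sqrt(mean(rowSums((mob4 - ref4)^2))) + 1e-12)
})

test_that("superposition input validation catches bad selections", {
  ens <- make_fixture_ensemble(nResidues = 4, nModels = 2, seed = 63)
  expect_error(superpose(ens@models[[1]], ens@models[[2]],
                         atomSelection(resid = 2, atoms = "CA")),
               "fewer than 3")
  short <- ens@models[[2]]
  short@atoms <- short@atoms[short@atoms$resid < 4, ]
  expect_error(superpose(ens@models[[1]], short), "mismatch")
})

test_that("subset RMSD after fitting another subset behaves as constructed", {
  ens <- make_fixture_ensemble(nResidues = 6, nModels = 4, seed = 64)
  ref <- ens@models[[1]]
  fit <- atomSelection(resid = 1:4, atoms = c("N", "CA", "C"))
  meas <- atomSelection(resid = 6, atoms = "O")
  copies <- lapply(1:3, function(i) {
    m <- ref; m@modelId <- as.integer(i); m })
  r0 <- subsetRmsd(copies, ref, fit, meas)
  expect_equal(r0$mean, 0, tolerance = 1e-9)
  expect_equal(r0$sd, 0, tolerance = 1e-9)
  # rigid-body pre-transformation of any model does not change the result
  moved <- copies
  moved[[2]] <- rigid_move(moved[[2]])
  rM <- subsetRmsd(moved, ref, fit, meas)
  expect_equal(rM$values, r0$values, tolerance = 1e-9)
  # inject a known displacement d on the measured atom only
  d <- 1.7
  disp <- lapply(copies, function(m) {
    a <- m@atoms
    i <- a$resid == 6 & a$name == "O"
    a$z[i] <- a$z[i] + d
    new("ModelRecord", modelId = m@modelId, atoms = a)
  })
  rD <- subsetRmsd(disp, ref, fit, meas)
  expect_equal(rD$mean, d, tolerance = 1e-6)
  # centroid of a single-atom selection equals that atom's deviation
  rC <- subsetRmsd(disp, ref, fit, meas, centroid = TRUE)
  expect_equal(rC$values, rD$values, tolerance = 1e-9)
})

test_that("per-residue RMSF matches the jitter that generated it", {
  ens <- make_fixture_ensemble(nResidues = 4, nModels = 2, seed = 65)
  base <- ens@models[[1]]
  copies <- lapply(1:2, function(i) { m <- base; m@modelId <- as.integer(i); m })
  expect_equal(perResidueRmsf(copies)$rmsf, rep(0, 4), tolerance = 1e-9)
  expect_error(perResidueRmsf(copies[1]), "at least 2")
  # jitter the CA of residue 3 isotropically with known sigma
  sigma <- 0.25
  set.seed(66)
  nrep <- 400
  jit <- lapply(seq_len(nrep), function(i) {
    a <- base@atoms
    sel <- a$resid == 3 & a$name == "CA"
    a[sel, c("x", "y", "z")] <- a[sel, c("x", "y", "z")] +
      stats::rnorm(3, 0, sigma)
    new("ModelRecord", modelId = as.integer(i), atoms = a)
  })
  fit <- atomSelection(resid = c(1, 2, 4), atoms = c("N", "CA", "C"))
  rf <- perResidueRmsf(jit, fit = fit)
  expect_equal(rf$rmsf[rf$resid == 3], sigma * sqrt(3), tolerance = 0.1)
  # invariance under a global rigid-body motion of every model
  rfMoved <- perResidueRmsf(lapply(jit, rigid_move), fit = fit)
  expect_equal(rfMoved$rmsf, rf$rmsf, tolerance = 1e-9)
})

test_that("circular summaries report mean, spread and modes correctly", {
  s <- circularSummary(rep(42, 50))
  expect_equal(s$mean, 42)
  expect_equal(s$sd, 0, tolerance = 1e-9)
  expect_identical(s$nModes, 1L)
  expect_equal(s$modes, 42, tolerance = 1)
  # two equal-mass clusters at +/-90: resultant ~ 0, two modes
  s2 <- circularSummary(c(rep(-90, 100), rep(90, 100)))
  expect_lt(s2$resultantLength, 1e-8)
  expect_true(is.na(s2$mean))
  expect_identical(s2$nModes, 2L)
  # von Mises sample: Rbar consistent with I1(kappa)/I0(kappa)
  set.seed(67)
  kappa <- 4
  ang <- EnsemblePEF:::.rvonmises(4000, 10, kappa)
  s3 <- circularSummary(ang)
  expect_equal(s3$resultantLength,
               besselI(kappa, 1) / besselI(kappa, 0), tolerance = 0.02)
  expect_lt(circularDelta(s3$mean, 10), 3)
  expect_identical(s3$nModes, 1L)
})

test_that("weighted circular summaries shift toward favored samples", {
  ang <- c(rep(-60, 10), rep(60, 10))
  w <- c(rep(5, 10), rep(1, 10))
  s <- circularSummary(ang, weights = w)
  expect_lt(s$mean, 0)  # pulled toward the heavier cluster
})

test_that("combined chemical-shift perturbation follows the convention", {
  expect_equal(combinedCsp(0, 0), 0)
  expect_equal(combinedCsp(0.3, 0), 0.3)
  expect_equal(combinedCsp(-0.3, 0), 0.3)
  expect_equal(combinedCsp(0.1, 0.5, 0.2), sqrt(0.1^2 + 0.1^2))
  expect_equal(combinedCsp(0.1, 0.5, 0.2), 0.14142, tolerance = 1e-5)
})

test_that("KRAS region presets partition the sequence", {
  r <- krasRegions()
  expect_identical(r$ploop, 10:17)
  expect_identical(r$switch1, 28:40)
  expect_identical(r$switch2, 60:76)
  expect_identical(sort(c(r$ploop, r$switch1, r$switch2, r$nonSwitch)),
                   1:169)
})
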