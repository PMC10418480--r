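# Independent plain-loop oracles and small fixture builders shared by the
# tests. Everything here is deliberately coded from the defining formulas,
# scalar loops and all, so it shares no code path with the package.

# circular distance of two angles, scalar
oracle_delta <- function(a, b) {
  a <- ((a + 180) %% 360) - 180
  b <- ((b + 180) %% 360) - 180
  d <- abs(a - b)
  if (d < 180) d else 360 - d
}

# power-raised cosine kernel, scalar
oracle_kernel <- function(alpha, alpha_ij, k) {
  cos(oracle_delta(alpha, alpha_ij) * pi / 360)^k
}

# score-weighted circular KDE on a grid, plain double loop
oracle_kde <- function(grid, angles, scores, s_ref, k, normalize = FALSE,
                       step = NULL) {
  cj <- exp(-scores / s_ref)
  C <- sum(cj)
  p <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    acc <- 0
    for (j in seq_along(angles))
      acc <- acc + cj[j] * oracle_kernel(grid[gi], angles[j], k)
    p[gi] <- acc / C
  }
  if (normalize) p <- p / (sum(p) * step)
  p
}

# scaled energy at arbitrary angles from the weighted kernel sum
# (un-normalized scale; the scaling factor f and floor are passed in).
# Coded from the defining formulas with its own wrap/min construction,
# independent of the package's outer/matrix-product path.
oracle_energy_at <- function(alpha, angles, weights, k, f, floorAbs) {
  aw <- ((angles + 180) %% 360) - 180
  vapply(alpha, function(a) {
    d <- abs(((a + 180) %% 360) - 180 - aw)
    d <- pmin(d, 360 - d)
    acc <- sum(weights * cos(d * pi / 360)^k)
    -f * log(max(acc / sum(weights), floorAbs))
  }, numeric(1))
}

# numerical sd of a cosine-series dihedral term over a dense uniform grid
oracle_term_std <- function(terms, npts = 1e6) {
  th <- seq(0, 2 * pi, length.out = npts + 1)[-(npts + 1)]
  v <- rep(0, npts)
  for (i in seq_len(nrow(terms)))
    v <- v + terms$halfAmp[i] *
      (1 + cos(terms$mult[i] * th - terms$phase[i] * pi / 180))
  sqrt(mean((v - mean(v))^2))
}

# brute-force proper-rotation search: coarse Euler grid then Nelder-Mead
# refinement; returns the minimal RMSD of mobile onto ref (centroids
# aligned, rotations only)
oracle_fit_rmsd <- function(mobile, ref) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(ref, 2, colMeans(ref))
  rot <- function(e) {
    cz <- cos(e[1]); sz <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cx <- cos(e[3]); sx <- sin(e[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(e) sqrt(mean(rowSums((mc %*% t(rot(e)) - rc)^2)))
  g <- seq(0, 2 * pi - pi / 6, by = pi / 6)
  best <- Inf; bestE <- c(0, 0, 0)
  for (a in g) for (b in g) for (cc in g) {
    v <- obj(c(a, b, cc))
    if (v < best) { best <- v; bestE <- c(a, b, cc) }
  }
  for (i in 1:3) {
    o <- stats::optim(bestE, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    bestE <- o$par
  }
  obj(bestE)
}

# small synthetic scored ensemble, in memory
make_fixture_ensemble <- function(nResidues = 4, nModels = 30, seed = 1,
                                  kappa = 8, coupling = 0, ...) {
  spec <- generatorSpec(
    nResidues = nResidues, nModels = nModels,
    phi = data.frame(mode = -63, kappa = kappa, mass = 1),
    psi = data.frame(mode = -43, kappa = kappa, mass = 1),
    score = list(base = -100, sd = 5, coupling = coupling),
    seed = seed, ...)
  ens <- generateEnsemble(spec)
  scoredEnsemble(ens$models, ens$scores)
}

# toy preprocessed GROMACS-style topology: backbone-only peptide with two
# multiplicity lines per phi/psi proper plus one improper
make_toy_topology <- function(nres = 3) {
  atoms <- sprintf("%6d   amber  %4d   ALA  %-4s  %d  0.0000  12.0000",
                   seq_len(3 * nres), rep(seq_len(nres), each = 3),
                   rep(c("N", "CA", "C"), nres),
                   rep(seq_len(nres), each = 3))
  quad <- function(i) paste(i, collapse = " ")
  dih <- character()
  for (r in 2:nres) {  # phi: C(r-1) N(r) CA(r) C(r)
    q <- c(3 * (r - 1), 3 * r - 2, 3 * r - 1, 3 * r)
    dih <- c(dih, paste(quad(q), "9 180.0 4.60240 1"),
             paste(quad(q), "9 180.0 0.75312 2"))
  }
  for (r in seq_len(nres - 1)) {  # psi: N(r) CA(r) C(r) N(r+1)
    q <- c(3 * r - 2, 3 * r - 1, 3 * r, 3 * r + 1)
    dih <- c(dih, paste(quad(q), "9 0.0 1.75728 1"),
             paste(quad(q), "9 0.0 1.00416 2"))
  }
  c("[ moleculetype ]", "PROT    3", "[ atoms ]", atoms,
    "[ bonds ]", "     1      2     1",
    "[ dihedrals ]", dih,
    "[ dihedrals ]", "     1      3      2      4     4  180.0  4.0  2")
}
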