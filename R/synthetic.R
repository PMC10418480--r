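#' Specification for a synthetic scored ensemble
#'
#' Defines per-residue circular mixture distributions for phi and psi, the
#' number of models, and a score model, all under one mandatory seed. Each
#' distribution is a data.frame with columns \code{mode} (degrees),
#' \code{kappa} (von Mises concentration > 0) and \code{mass} (mixture
#' weights summing to 1); a single data.frame is recycled across residues.
#' phi is generated for residues 2..n and psi for residues 1..(n-1) (the
#' chain termini lack the respective angle).
#'
#' The score model is \code{list(base, sd, coupling)}: per-model scores are
#' base + N(0, sd) noise, minus \code{coupling} times the model's fraction
#' of angles drawn from the first mixture component -- so with coupling > 0
#' the first component's conformers score better (lower).
#'
#' @param nResidues number of residues.
#' @param nModels number of models.
#' @param phi,psi mixture data.frame, or list of one per residue.
#' @param score list(base, sd, coupling).
#' @param seed mandatory integer seed.
#' @return an object of class "GeneratorSpec".
#' @export
generatorSpec <- function(nResidues, nModels,
                          phi = data.frame(mode = -63, kappa = 8, mass = 1),
                          psi = data.frame(mode = -43, kappa = 8, mass = 1),
                          score = list(base = -100, sd = 5, coupling = 0),
                          seed) {
  if (missing(seed)) stop("seed is mandatory in a generator spec")
  norm <- function(d, kind) {
    if (is.data.frame(d)) d <- rep(list(d), nResidues)
    if (length(d) != nResidues)
      stop(kind, " mixture list must have one entry per residue")
    for (x in d) {
      if (!all(c("mode", "kappa", "mass") %in% names(x)))
        stop(kind, " mixtures need columns mode, kappa, mass")
      if (any(x$kappa <= 0)) stop("kappa must be > 0")
      if (abs(sum(x$mass) - 1) > 1e-9)
        stop("mixture masses must sum to 1")
    }
    d
  }
  structure(list(nResidues = nResidues, nModels = nModels,
                 phi = norm(phi, "phi"), psi = norm(psi, "psi"),
                 score = score, seed = as.integer(seed)),
            class = "GeneratorSpec")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa -> 0 falls
# back to the circular uniform. Returns degrees in [-180, 180).
.rvonmises <- function(n, muDeg, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(wrapAngle(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    acc <- theta[ok]
    take <- min(length(acc), m)
    if (take > 0) out[(got + 1):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  wrapAngle(muDeg + out * 180 / pi)
}

#' Sample per-model dihedral angles from a generator spec
#'
#' Draws every defined (residue, kind) angle of every model from its
#' circular mixture, wrapped to [-180, 180). Deterministic for a fixed
#' seed.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @return list with \code{phi}, \code{psi}: matrices (nModels x
#'   nResidues, NA where the angle is undefined), and \code{component}:
#'   matching matrices of 1-based mixture-component labels.
#' @export
sampleDihedrals <- function(spec) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  set.seed(spec$seed)
  nM <- spec$nModels; nR <- spec$nResidues
  draw <- function(mix, defined) {
    ang <- matrix(NA_real_, nM, nR)
    comp <- matrix(NA_integer_, nM, nR)
    for (ri in which(defined)) {
      m <- mix[[ri]]
      ci <- sample.int(nrow(m), nM, replace = TRUE, prob = m$mass)
      a <- numeric(nM)
      for (cc in unique(ci)) {
        sel <- ci == cc
        a[sel] <- .rvonmises(sum(sel), m$mode[cc], m$kappa[cc])
      }
      ang[, ri] <- a
      comp[, ri] <- ci
    }
    list(angle = ang, component = comp)
  }
  phiDef <- c(FALSE, rep(TRUE, nR - 1))
  psiDef <- c(rep(TRUE, nR - 1), FALSE)
  ph <- draw(spec$phi, phiDef)
  ps <- draw(spec$psi, psiDef)
  list(phi = ph$angle, psi = ps$angle,
       component = list(phi = ph$component, psi = ps$component))
}

# ideal backbone geometry (Angstrom / degrees) used for reconstruction;
# only the dihedrals matter downstream, so fixed ideal values suffice
IDEAL_GEOMETRY <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8)

# place D given A, B, C with bond length |C-D|, angle B-C-D and torsion
# A-B-C-D (NeRF construction)
.placeAtom <- function(A, B, C, dist, angleDeg, torsionDeg) {
  th <- angleDeg * pi / 180
  chi <- torsionDeg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  nrm <- .cross3(ab, bc)
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-12) stop("degenerate geometry in backbone construction")
  nrm <- nrm / nl
  m <- .cross3(nrm, bc)
  d2 <- c(-dist * cos(th), dist * sin(th) * cos(chi),
          dist * sin(th) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * nrm
}

#' Build backbone coordinates from dihedral angles
#'
#' Sequential internal-coordinate construction of an N/CA/C/O backbone with
#' fixed ideal bond lengths and angles and planar trans peptide bonds
#' (omega = 180). Re-extracting phi/psi from the result reproduces the
#' inputs to well under 0.1 degrees.
#'
#' @param phi numeric length n; phi[1] is ignored (undefined).
#' @param psi numeric length n; psi[n] is ignored for the chain (used only
#'   to orient the final carbonyl; NA falls back to 180).
#' @param modelId integer id for the resulting model.
#' @param chain chain id.
#' @param omega peptide-bond torsion (default 180).
#' @return a \linkS4class{ModelRecord} with atoms N, CA, C, O per residue.
#' @export
buildBackbone <- function(phi, psi, modelId = 1L, chain = "A", omega = 180) {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  g <- IDEAL_GEOMETRY
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  th <- g$a_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    psiI <- if (is.na(psi[i])) 180 else psi[i]
    N[i + 1, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$b_C_N, g$a_CA_C_N,
                             psiI)
    CA[i + 1, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1, ], g$b_N_CA,
                              g$a_C_N_CA, omega)
    phiI <- if (is.na(phi[i + 1])) -60 else phi[i + 1]
    C[i + 1, ] <- .placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CA_C,
                             g$a_N_CA_C, phiI)
  }
  for (i in seq_len(n)) {
    psiI <- if (is.na(psi[i])) 180 else psi[i]
    # carbonyl O opposite the next amide N: torsion N-CA-C-O = psi + 180
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$b_C_O, g$a_CA_C_O,
                         psiI + 180)
  }
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), n),
    resid = rep(seq_len(n), each = 4),
    resname = "ALA", chain = chain,
    x = as.vector(rbind(N[, 1], CA[, 1], C[, 1], O[, 1])),
    y = as.vector(rbind(N[, 2], CA[, 2], C[, 2], O[, 2])),
    z = as.vector(rbind(N[, 3], CA[, 3], C[, 3], O[, 3])),
    stringsAsFactors = FALSE)
  new("ModelRecord", modelId = as.integer(modelId), atoms = atoms)
}

#' Generate a synthetic scored ensemble in memory
#'
#' Samples dihedrals, reconstructs backbone models and assigns scores
#' according to the spec's score model.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @return list with \code{models} (list of \linkS4class{ModelRecord}),
#'   \code{scores} (named numeric), \code{angles} (the
#'   \code{\link{sampleDihedrals}} output).
#' @export
generateEnsemble <- function(spec) {
  ang <- sampleDihedrals(spec)
  nM <- spec$nModels
  models <- vector("list", nM)
  for (j in seq_len(nM))
    models[[j]] <- buildBackbone(ang$phi[j, ], ang$psi[j, ], modelId = j)
  sc <- spec$score
  noise <- stats::rnorm(nM, 0, sc$sd)
  frac1 <- rowMeans(cbind(ang$component$phi == 1L, ang$component$psi == 1L),
                    na.rm = TRUE)
  scores <- sc$base + noise - (sc$coupling %||% 0) * frac1
  names(scores) <- sprintf("m_%04d", seq_len(nM))
  list(models = models, scores = scores, angles = ang)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic scored ensemble to disk
#'
#' Emits a multi-model PDB, a Rosetta-style score table and a JSON manifest
#' recording the spec, the seed and an md5 hash of the canonical spec JSON.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @param prefix output path prefix; writes <prefix>.pdb, <prefix>.sc,
#'   <prefix>_manifest.json.
#' @return invisibly, list of the three paths plus the in-memory ensemble.
#' @export
emitScoredEnsemble <- function(spec, prefix) {
  ens <- generateEnsemble(spec)
  pdb <- paste0(prefix, ".pdb")
  sc <- paste0(prefix, ".sc")
  man <- paste0(prefix, "_manifest.json")
  writeEnsemble(ens$models, pdb)
  writeLines(c("SCORE: total_score description",
               sprintf("SCORE: %.3f %s", unname(ens$scores),
                       names(ens$scores))), sc)
  jsonlite::write_json(
    list(spec = .specAsList(spec), seed = spec$seed,
         spec_hash = specHash(spec), n_models = spec$nModels),
    man, auto_unbox = TRUE, digits = NA)
  invisible(list(pdb = pdb, scores = sc, manifest = man, ensemble = ens))
}

.specAsList <- function(spec) {
  list(nResidues = spec$nResidues, nModels = spec$nModels,
       phi = lapply(spec$phi, as.list), psi = lapply(spec$psi, as.list),
       score = spec$score, seed = spec$seed)
}

#' Hash of a generator spec
#'
#' md5 of the canonical JSON serialization; lets a manifest's provenance be
#' re-verified against a recomputed spec.
#'
#' @param spec a \code{\link{generatorSpec}}.
#' @return character md5 hash.
#' @export
specHash <- function(spec) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(.specAsList(spec), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
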