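#' Atom selection predicate
#'
#' A lightweight selection: any combination of residue indices, atom names
#' and chain ids; NULL means "no restriction".
#'
#' @param resid integer vector of residue indices, or NULL.
#' @param atoms character vector of atom names (e.g. backbone
#'   c("N","CA","C","O")), or NULL.
#' @param chain character vector of chain ids, or NULL.
#' @return an object of class "AtomSelection".
#' @export
atomSelection <- function(resid = NULL, atoms = NULL, chain = NULL) {
  structure(list(resid = resid, atoms = atoms, chain = chain),
            class = "AtomSelection")
}

.selectRows <- function(a, sel) {
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$resid)) keep <- keep & a$resid %in% sel$resid
  if (!is.null(sel$atoms)) keep <- keep & a$name %in% sel$atoms
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  keep
}

#' KRAS region presets
#'
#' Residue ranges of the functionally flexible segments of KRAS (1-169):
#' P-loop 10-17, Switch-I 28-40, Switch-II 60-76, and the complementary
#' "non-Switch" set commonly used as the fitting selection when measuring
#' cofactor deviations.
#'
#' @param nRes protein length (default 169).
#' @return named list of integer vectors: ploop, switch1, switch2,
#'   nonSwitch.
#' @export
krasRegions <- function(nRes = 169) {
  ploop <- 10:17; sw1 <- 28:40; sw2 <- 60:76
  list(ploop = ploop, switch1 = sw1, switch2 = sw2,
       nonSwitch = setdiff(seq_len(nRes), c(ploop, sw1, sw2)))
}

# match atoms of two models 1:1 by (chain, resid, name) within a selection;
# returns the two coordinate matrices in a common order
.matchedCoords <- function(mobile, reference, sel) {
  am <- mobile@atoms[.selectRows(mobile@atoms, sel), , drop = FALSE]
  ar <- reference@atoms[.selectRows(reference@atoms, sel), , drop = FALSE]
  keym <- paste(am$chain, am$resid, am$name)
  keyr <- paste(ar$chain, ar$resid, ar$name)
  if (anyDuplicated(keym) || anyDuplicated(keyr))
    stop("selection is ambiguous (duplicate atoms)")
  common <- intersect(keym, keyr)
  if (!setequal(keym, keyr))
    stop(sprintf("selection mismatch between models: %d vs %d atoms, %d common",
                 length(keym), length(keyr), length(common)))
  im <- match(common, keym); ir <- match(common, keyr)
  list(mobile = as.matrix(am[im, c("x", "y", "z")]),
       reference = as.matrix(ar[ir, c("x", "y", "z")]),
       keys = common)
}

#' Rigid-body least-squares superposition
#'
#' Superposes \code{mobile} onto \code{reference} using the optimal
#' rotation + translation (no reflection) over the fit selection
#' (least-squares fitting via bio3d). All atoms of the mobile model are
#' transformed.
#'
#' @param mobile,reference \linkS4class{ModelRecord} objects.
#' @param fit an \code{\link{atomSelection}} describing the fitted atoms
#'   (default: backbone N, CA, C).
#' @return list with \code{model} (the transformed
#'   \linkS4class{ModelRecord}) and \code{rmsd} (fit RMSD, Angstrom).
#' @export
superpose <- function(mobile, reference,
                      fit = atomSelection(atoms = c("N", "CA", "C"))) {
  mc <- .matchedCoords(mobile, reference, fit)
  if (nrow(mc$mobile) < 3) stop("fit selection has fewer than 3 atoms")
  if (qr(sweep(mc$mobile, 2, colMeans(mc$mobile)))$rank < 2)
    stop("fit selection atoms are collinear")
  full <- as.matrix(mobile@atoms[, c("x", "y", "z")])
  fitIdxMobile <- match(mc$keys, paste(mobile@atoms$chain,
                                       mobile@atoms$resid,
                                       mobile@atoms$name))
  nFull <- nrow(full)
  fixedFull <- matrix(0, nFull, 3)
  fixedFull[seq_len(nrow(mc$reference)), ] <- mc$reference
  xyzFixed <- as.vector(t(fixedFull))
  xyzMobile <- as.vector(t(full))
  refInds <- bio3d::atom2xyz(seq_len(nrow(mc$reference)))
  mobInds <- bio3d::atom2xyz(fitIdxMobile)
  moved <- bio3d::fit.xyz(fixed = xyzFixed, mobile = xyzMobile,
                          fixed.inds = refInds, mobile.inds = mobInds)
  newAtoms <- mobile@atoms
  movedMat <- matrix(moved, ncol = 3, byrow = TRUE)
  newAtoms$x <- movedMat[, 1]; newAtoms$y <- movedMat[, 2]
  newAtoms$z <- movedMat[, 3]
  fitted <- movedMat[fitIdxMobile, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - mc$reference)^2)))
  list(model = new("ModelRecord", modelId = mobile@modelId,
                   atoms = newAtoms),
       rmsd = rmsd)
}

#' Deviation of a subset after fitting a different subset
#'
#' For every model: superpose on the fit selection, then report the
#' deviation of the measure selection from the reference -- either the RMSD
#' over the matched atoms or, with \code{centroid = TRUE}, the distance
#' between centroids (the convention for ions and ligand centers).
#'
#' @param models list of \linkS4class{ModelRecord}.
#' @param reference \linkS4class{ModelRecord} reference structure.
#' @param fit \code{\link{atomSelection}} for the superposition.
#' @param measure \code{\link{atomSelection}} whose deviation is reported.
#' @param centroid logical; measure the centroid displacement instead of
#'   the per-atom RMSD.
#' @return list with \code{mean}, \code{sd} and \code{values} (per model,
#'   Angstrom).
#' @export
subsetRmsd <- function(models, reference, fit, measure, centroid = FALSE) {
  vals <- vapply(models, function(m) {
    sp <- superpose(m, reference, fit)
    mc <- .matchedCoords(sp$model, reference, measure)
    if (nrow(mc$mobile) == 0) stop("empty measure selection")
    if (centroid) {
      sqrt(sum((colMeans(mc$mobile) - colMeans(mc$reference))^2))
    } else {
      sqrt(mean(rowSums((mc$mobile - mc$reference)^2)))
    }
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Per-residue RMSF of an ensemble
#'
#' Superposes every model onto the first via the fit selection, then
#' computes each selected atom's root-mean-square fluctuation about the
#' ensemble-mean coordinates, averaged per residue.
#'
#' @param models list of at least two \linkS4class{ModelRecord}.
#' @param fit \code{\link{atomSelection}} for the superposition.
#' @param atoms \code{\link{atomSelection}} of the atoms whose fluctuation
#'   is reported (default CA).
#' @return data.frame with columns \code{chain}, \code{resid}, \code{rmsf}
#'   (Angstrom).
#' @export
perResidueRmsf <- function(models,
                           fit = atomSelection(atoms = c("N", "CA", "C")),
                           atoms = atomSelection(atoms = "CA")) {
  if (length(models) < 2) stop("RMSF needs at least 2 models")
  ref <- models[[1]]
  fitted <- lapply(models, function(m) superpose(m, ref, fit)$model)
  sel <- lapply(fitted, function(m) {
    a <- m@atoms[.selectRows(m@atoms, atoms), , drop = FALSE]
    a[order(a$chain, a$resid, a$name), , drop = FALSE]
  })
  key <- paste(sel[[1]]$chain, sel[[1]]$resid, sel[[1]]$name)
  for (s in sel)
    if (!identical(paste(s$chain, s$resid, s$name), key))
      stop("atom selection not identical across models")
  arr <- vapply(sel, function(s) as.matrix(s[, c("x", "y", "z")]),
                matrix(0, length(key), 3))
  meanC <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - array(meanC, dim(arr)))^2, c(1, 3), sum)
  rmsfAtom <- sqrt(rowMeans(dev2))
  agg <- stats::aggregate(rmsfAtom,
                          by = list(chain = sel[[1]]$chain,
                                    resid = sel[[1]]$resid), FUN = mean)
  names(agg)[3] <- "rmsf"
  agg[order(agg$chain, agg$resid), ]
}

#' Circular summary of a dihedral sample set
#'
#' Weighted circular mean and standard deviation (sd = sqrt(-2 ln Rbar) of
#' the mean resultant length, in degrees) plus the modes of the circular
#' KDE: local maxima whose topographic prominence exceeds a fraction of the
#' peak density (default 5%, suppressing grid noise).
#'
#' @param angles numeric angles in degrees.
#' @param weights optional numeric weights (same length), e.g. score
#'   weights.
#' @param config optional \linkS4class{CircularKernelConfig}; derived from
#'   the sample size when NULL.
#' @param gridStep KDE grid spacing in degrees.
#' @param prominence mode-detection prominence threshold as a fraction of
#'   the peak density.
#' @return list with \code{mean} (degrees, NA when the resultant length is
#'   ~0 and the mean is undefined), \code{resultantLength}, \code{sd}
#'   (degrees), \code{modes} (degrees), \code{nModes}.
#' @export
circularSummary <- function(angles, weights = NULL, config = NULL,
                            gridStep = 1, prominence = 0.05) {
  if (!length(angles)) stop("empty sample set")
  if (is.null(weights)) weights <- rep(1, length(angles))
  th <- wrapAngle(angles) * pi / 180
  w <- weights / sum(weights)
  cbar <- sum(w * cos(th)); sbar <- sum(w * sin(th))
  rbar <- sqrt(cbar^2 + sbar^2)
  mu <- if (rbar < 1e-8) NA_real_ else wrapAngle(atan2(sbar, cbar) * 180 / pi)
  sdv <- if (rbar <= 0) Inf else sqrt(-2 * log(min(rbar, 1))) * 180 / pi
  if (is.null(config)) config <- kernelConfig(N = length(angles))
  ws <- new("WeightSet", sRef = 1, weights = stats::setNames(
    weights, as.character(seq_along(angles))), total = sum(weights))
  pdf <- weightedPDF(stats::setNames(angles, as.character(seq_along(angles))),
                     ws, config, gridStep = gridStep, normalize = TRUE)
  modes <- .circularModes(pdf@density, pdf@grid, prominence)
  list(mean = mu, resultantLength = rbar, sd = sdv, modes = modes,
       nModes = length(modes))
}

# local maxima of a periodic density with topographic prominence above
# frac * max(density)
.circularModes <- function(dens, grid, frac) {
  n <- length(dens)
  lft <- dens[c(n, seq_len(n - 1))]
  rgt <- dens[c(seq_len(n - 1) + 1, 1)]
  peaks <- which(dens > lft & dens >= rgt)
  if (!length(peaks)) return(numeric(0))
  thr <- frac * max(dens)
  keep <- vapply(peaks, function(p) {
    h <- dens[p]
    if (h == max(dens)) return(h - min(dens) >= thr)
    walk <- function(step) {
      i <- p; lo <- h
      repeat {
        i <- ((i - 1 + step) %% n) + 1
        if (dens[i] > h) return(lo)
        lo <- min(lo, dens[i])
        if (i == p) return(lo)
      }
    }
    h - max(walk(1), walk(-1)) >= thr
  }, logical(1))
  sort(grid[peaks[keep]])
}

#' Combined chemical-shift perturbation
#'
#' Conventional combined amide CSP: sqrt(dH^2 + (nScale * dN)^2). The
#' nitrogen scale factor defaults to 0.2, a common convention for amide
#' groups; it is configurable and recorded by callers.
#'
#' @param deltaH 1H shift difference (ppm).
#' @param deltaN 15N shift difference (ppm).
#' @param nScale nitrogen scaling factor.
#' @return combined shift difference (ppm), vectorized.
#' @export
combinedCsp <- function(deltaH, deltaN, nScale = 0.2) {
  sqrt(deltaH^2 + (nScale * deltaN)^2)
}
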