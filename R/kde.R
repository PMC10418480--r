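#' Kernel width from ensemble size
#'
#' Scott-rule-like bandwidth for the circular kernel: w = 2*pi*N^(-1/3)
#' radians, shrinking with the number of models.
#'
#' @param N positive integer ensemble size.
#' @return width in radians.
#' @export
#' @examples
#' widthFromEnsembleSize(8)  # pi
widthFromEnsembleSize <- function(N) {
  if (length(N) != 1 || is.na(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  2 * pi * N^(-1 / 3)
}

#' Kernel exponent from width
#'
#' k = 1 + 1/tan^2(w/2); the exponent of the power-raised cosine kernel
#' that realises width w.
#'
#' @param w width in radians, in (0, pi].
#' @return exponent k >= 1.
#' @export
#' @examples
#' exponentFromWidth(pi / 2)  # 2
exponentFromWidth <- function(w) {
  if (length(w) != 1 || is.na(w) || w <= 0) stop("width must be > 0")
  if (w > pi) stop("width must be <= pi")
  if (w == pi) return(1)   # tan(pi/2) -> Inf, limit k = 1
  1 + 1 / tan(w / 2)^2
}

#' Kernel width from exponent
#'
#' Inverse of \code{\link{exponentFromWidth}}: w = 2*atan(1/sqrt(k - 1)).
#'
#' @param k exponent >= 1.
#' @return width in radians.
#' @export
widthFromExponent <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1) stop("exponent must be >= 1")
  if (k == 1) return(pi)
  2 * atan(1 / sqrt(k - 1))
}

#' Build a circular kernel configuration
#'
#' Either give the ensemble size \code{N} (width auto-derived via
#' \code{\link{widthFromEnsembleSize}}) or the width \code{w} directly.
#' One global width is used per run even when some models lack a given
#' dihedral.
#'
#' @param N ensemble size (used if \code{w} is missing).
#' @param w width in radians (overrides \code{N}-derived width).
#' @return a \linkS4class{CircularKernelConfig}.
#' @export
kernelConfig <- function(N = NULL, w = NULL) {
  if (is.null(w)) {
    if (is.null(N)) stop("give N or w")
    w <- widthFromEnsembleSize(N)
    if (w > pi) w <- pi  # N < 8 would give w > pi; cap at the half-circle
  }
  new("CircularKernelConfig", width = w, exponent = exponentFromWidth(w),
      N = if (is.null(N)) NA_integer_ else as.integer(N))
}

#' Power-raised cosine kernel value
#'
#' K(alpha, alpha_ij) = cos^k(Delta * pi/360) with Delta the circular
#' distance in degrees; 1 at Delta = 0, 0 at Delta = 180, bounded in [0, 1].
#'
#' @param alpha,alphaIJ angles in degrees (vectorized).
#' @param k kernel exponent >= 1.
#' @return kernel values in [0, 1].
#' @export
kernelValue <- function(alpha, alphaIJ, k) {
  if (any(k < 1)) stop("kernel exponent must be >= 1")
  cos(circularDelta(alpha, alphaIJ) * pi / 360)^k
}

#' Score weights for ensemble models
#'
#' Boltzmann-like weights c_j = exp(-s_j/s_ref) from total scores (lower
#' score, larger weight; an e-fold change per s_ref score units). The
#' reference score defaults to 10.
#'
#' @param scores named numeric vector of total scores.
#' @param sRef reference score > 0.
#' @return a \linkS4class{WeightSet}.
#' @export
scoreWeights <- function(scores, sRef = 10) {
  if (length(sRef) != 1 || is.na(sRef) || sRef <= 0)
    stop("sRef must be a positive number")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(abs(scores) / sRef > 700))
    stop("|score|/sRef exceeds 700: exp() would overflow/underflow; ",
         "rescale the scores or increase sRef")
  w <- exp(-scores / sRef)
  new("WeightSet", sRef = sRef, weights = w, total = sum(w))
}

.uniformGrid <- function(step) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("grid step must evenly divide 360 degrees")
  seq(-180, 180 - step, by = step)
}

#' Score-weighted circular kernel density estimate
#'
#' P(alpha) = (1/C) * sum_j c_j K(alpha, alpha_ij) on a uniform grid over
#' [-180, 180). With \code{normalize = TRUE} the density is rescaled so its
#' trapezoidal integral over the circle is 1 (unit 1/degree); the flag is
#' recorded on the result. Energies derived later differ only by an
#' additive constant between the two modes.
#'
#' @param angles numeric vector of sampled angles (degrees) for one
#'   (residue, kind); names, if present, are model ids.
#' @param weights a \linkS4class{WeightSet} covering the samples' models,
#'   or NULL for equal weights.
#' @param config a \linkS4class{CircularKernelConfig}.
#' @param gridStep grid spacing in degrees (default 1).
#' @param normalize logical; normalize to unit circular integral.
#' @param residue,kind metadata stored on the result.
#' @return a \linkS4class{TorsionPDF}.
#' @export
weightedPDF <- function(angles, weights = NULL, config, gridStep = 1,
                        normalize = TRUE, residue = NA_integer_,
                        kind = "phi") {
  if (!length(angles)) stop("empty sample set")
  if (is.null(weights)) {
    w <- rep(1, length(angles))
  } else {
    if (is.null(names(angles))) {
      if (length(weights@weights) != length(angles))
        stop("weights/sample length mismatch and samples carry no model ids")
      w <- unname(weights@weights)
    } else {
      miss <- setdiff(names(angles), names(weights@weights))
      if (length(miss))
        stop("no weight for model(s): ", paste(miss, collapse = ", "))
      w <- unname(weights@weights[names(angles)])
    }
  }
  grid <- .uniformGrid(gridStep)
  k <- config@exponent
  delta <- outer(grid, wrapAngle(angles), circularDelta)
  dens <- as.vector(cos(delta * pi / 360)^k %*% w) / sum(w)
  if (normalize) {
    tot <- sum(dens) * gridStep
    if (tot <= 0) stop("density integrates to zero; cannot normalize")
    dens <- dens / tot
  }
  new("TorsionPDF", residue = as.integer(residue), kind = kind, grid = grid,
      density = dens, normalized = normalize, config = config,
      exportable = kind %in% EXPORTABLE_KINDS)
}

#' Per-residue torsion densities for a scored ensemble
#'
#' Runs \code{\link{weightedPDF}} for every (residue, kind) sample set of
#' the ensemble using score weights exp(-s/sRef) and a kernel width derived
#' from the global ensemble size.
#'
#' @param ensemble a \linkS4class{ScoredEnsemble}.
#' @param sRef reference score (default 10).
#' @param gridStep grid spacing in degrees.
#' @param normalize normalize densities to unit circular integral.
#' @param config optional \linkS4class{CircularKernelConfig}; derived from
#'   the ensemble size when NULL.
#' @param kinds angle kinds to include (omega is never included here; it is
#'   diagnostic only).
#' @return named list of \linkS4class{TorsionPDF} ("<residue>:<kind>").
#' @export
ensemblePDFs <- function(ensemble, sRef = 10, gridStep = 1, normalize = TRUE,
                         config = NULL, kinds = c("phi", "psi")) {
  kinds <- intersect(kinds, EXPORTABLE_KINDS)
  if (is.null(config)) config <- kernelConfig(N = nModels(ensemble))
  ws <- scoreWeights(modelScores(ensemble), sRef = sRef)
  s <- ensemble@samples[ensemble@samples$kind %in% kinds, , drop = FALSE]
  keys <- unique(s[, c("residue", "kind")])
  keys <- keys[order(keys$residue, match(keys$kind, ANGLE_KINDS)), ]
  out <- vector("list", nrow(keys))
  nm <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- s$residue == keys$residue[i] & s$kind == keys$kind[i]
    ang <- stats::setNames(s$angle[sel], as.character(s$model[sel]))
    out[[i]] <- weightedPDF(ang, ws, config, gridStep = gridStep,
                            normalize = normalize,
                            residue = keys$residue[i], kind = keys$kind[i])
    nm[i] <- sprintf("%d:%s", keys$residue[i], keys$kind[i])
  }
  stats::setNames(out, nm)
}

#' Write a torsion density as a two-column text table
#'
#' Columns: angle_deg, density.
#'
#' @param pdf a \linkS4class{TorsionPDF}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDFTable <- function(pdf, path) {
  utils::write.table(
    data.frame(angle_deg = pdf@grid, density = pdf@density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
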