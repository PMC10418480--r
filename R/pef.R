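DEFAULT_RATIOS <- c(phi = 14.77, psi = 5.30)

#' Boltzmann inversion of a torsion density
#'
#' U(alpha) = -ln(max(P, floor)) with a relative density floor: the floor is
#' \code{floorEps * max(P)}, which bounds the energy (and zeroes the force)
#' in unsampled regions instead of letting it diverge. The argmin of U is
#' the argmax of P.
#'
#' @param pdf a \linkS4class{TorsionPDF}.
#' @param floorEps relative density floor (> 0), default 1e-8 of the peak.
#' @return list with \code{grid}, \code{U} (unscaled energy, dimensionless),
#'   \code{floored} (logical mask of floored grid points).
#' @export
boltzmannInvert <- function(pdf, floorEps = 1e-8) {
  if (floorEps <= 0) stop("floorEps must be > 0")
  p <- pdf@density
  if (all(p == 0)) stop("all-zero density cannot be inverted")
  floorAbs <- floorEps * max(p)
  floored <- p < floorAbs
  list(grid = pdf@grid, U = -log(pmax(p, floorAbs)), floored = floored)
}

#' Standard deviation of a cosine-series dihedral term
#'
#' For a force-field proper-dihedral potential
#' sum_n (V_n/2)(1 + cos(n*theta - gamma_n)) the standard deviation over a
#' uniformly distributed angle is computed in closed form:
#' Var = 1/2 * sum over term pairs with equal multiplicity of
#' (V_a/2)(V_b/2) cos(gamma_a - gamma_b). For distinct multiplicities this
#' reduces to sqrt(sum (V_n/2)^2 / 2).
#'
#' @param terms data.frame with columns \code{mult} (positive integer
#'   multiplicity n), \code{halfAmp} (V_n/2 in kJ/mol), \code{phase}
#'   (gamma_n in degrees). May have zero rows.
#' @return standard deviation in kJ/mol.
#' @export
referenceTermStd <- function(terms) {
  if (is.null(terms) || nrow(terms) == 0) return(0)
  if (!all(c("mult", "halfAmp", "phase") %in% names(terms)))
    stop("terms needs columns mult, halfAmp, phase")
  if (any(terms$mult <= 0) || any(terms$mult != round(terms$mult)))
    stop("multiplicities must be positive integers")
  v <- 0
  for (n in unique(terms$mult)) {
    t <- terms[terms$mult == n, , drop = FALSE]
    g <- t$phase * pi / 180
    # |sum halfAmp * e^{i gamma}|^2 / 2 for this multiplicity
    v <- v + (sum(t$halfAmp * cos(g))^2 + sum(t$halfAmp * sin(g))^2) / 2
  }
  sqrt(v)
}

#' Scale an unscaled torsion energy profile to force-field magnitude
#'
#' The scaling factor f = ratio * stdRef / sd(U) makes the population
#' standard deviation of the scaled energy over the uniform grid equal to
#' ratio * stdRef; the profile is then shifted so its minimum is 0. The
#' default ratios are 14.77 for phi and 5.30 for psi.
#'
#' @param U numeric unscaled energy profile on a uniform grid.
#' @param kind "phi" or "psi" (selects the default ratio).
#' @param stdRef reference standard deviation in kJ/mol (e.g. from
#'   \code{\link{referenceTermStd}}).
#' @param ratio override the kind-specific default ratio.
#' @param label used in the degenerate-profile error message.
#' @return list with \code{f} (scaling factor) and \code{energy} (kJ/mol,
#'   min 0).
#' @export
scalePEF <- function(U, kind = c("phi", "psi"), stdRef, ratio = NULL,
                     label = NULL) {
  kind <- match.arg(kind)
  if (is.null(ratio)) ratio <- DEFAULT_RATIOS[[kind]]
  if (stdRef <= 0) stop("stdRef must be > 0")
  sdU <- stats::sd(U) * sqrt((length(U) - 1) / length(U))  # population sd
  if (sdU <= 0)
    stop("degenerate (flat) energy profile",
         if (!is.null(label)) paste0(" for ", label) else "",
         ": cannot scale a uniform density")
  f <- ratio * stdRef / sdU
  e <- f * U
  list(f = f, energy = e - min(e))
}

# dP/dalpha (per degree) of the weighted kernel sum, same scale as the
# un-normalized weighted mean of kernels. The sign of d(Delta)/d(alpha) is
# sign(wrap(alpha - alpha_ij)); the kernel derivative vanishes smoothly at
# Delta = 0 and (for k > 1) at Delta = 180.
.kdeDerivative <- function(grid, angles, w, k) {
  d <- outer(grid, wrapAngle(angles), function(a, b) wrapAngle(a - b))
  x <- abs(d) * pi / 360
  dk <- -k * cos(x)^(k - 1) * sin(x) * (pi / 360) * sign(d)
  as.vector(dk %*% w) / sum(w)
}

#' Build one torsion potential from raw samples
#'
#' Full pipeline for a single (residue, kind): score-weighted circular KDE,
#' Boltzmann inversion with a density floor, force-field scaling, and the
#' analytic force from the closed-form kernel-sum derivative. Because the
#' energy is -f ln P + const, the force f * P'/P is exactly invariant to
#' density normalization; it is set to 0 on floored plateaus and converted
#' to kJ/mol/rad.
#'
#' @param angles sampled angles in degrees (names = model ids, optional).
#' @param weights a \linkS4class{WeightSet} or NULL for equal weights.
#' @param config a \linkS4class{CircularKernelConfig}.
#' @param residue,kind metadata; kind also selects the scaling ratio.
#' @param stdRef reference standard deviation (kJ/mol).
#' @param ratio override the default kind ratio.
#' @param gridStep grid spacing in degrees.
#' @param floorEps relative density floor.
#' @param normalize normalize the intermediate density (affects the energy
#'   only through the shift; recorded for provenance).
#' @return a \linkS4class{TorsionPEF}.
#' @export
pefFromSamples <- function(angles, weights = NULL, config,
                           residue = NA_integer_, kind = c("phi", "psi"),
                           stdRef = 1, ratio = NULL, gridStep = 1,
                           floorEps = 1e-8, normalize = TRUE) {
  kind <- match.arg(kind)
  pdf <- weightedPDF(angles, weights, config, gridStep = gridStep,
                     normalize = normalize, residue = residue, kind = kind)
  inv <- boltzmannInvert(pdf, floorEps = floorEps)
  sc <- scalePEF(inv$U, kind = kind, stdRef = stdRef, ratio = ratio,
                 label = sprintf("residue %s %s", residue, kind))
  if (is.null(weights)) w <- rep(1, length(angles))
  else if (is.null(names(angles))) w <- unname(weights@weights)
  else w <- unname(weights@weights[names(angles)])
  # force f * P'/P is invariant to density normalization, so both the
  # derivative and the density here are on the raw (weighted-mean) scale
  raw <- weightedPDF(angles, weights, config, gridStep = gridStep,
                     normalize = FALSE, residue = residue, kind = kind)@density
  dPd <- .kdeDerivative(pdf@grid, angles, w, config@exponent)
  force <- ifelse(inv$floored, 0,
                  sc$f * dPd / pmax(raw, floorEps * max(raw)))
  force <- force * 180 / pi   # per-degree -> per-radian
  new("TorsionPEF", residue = as.integer(residue), kind = kind,
      grid = pdf@grid, energy = sc$energy, force = force, f = sc$f,
      stdRef = stdRef, ratio = if (is.null(ratio)) DEFAULT_RATIOS[[kind]]
               else ratio,
      floorEps = floorEps, floored = inv$floored)
}

#' Build all torsion potentials of a scored ensemble
#'
#' Runs \code{\link{pefFromSamples}} for every (residue, phi/psi) sample
#' set. Residues whose profile is degenerate (flat density) are skipped
#' with a warning so that the force field's own term stays in place for
#' them; chain termini lack one of the angles and are naturally absent.
#'
#' @param ensemble a \linkS4class{ScoredEnsemble}.
#' @param stdRef reference standard deviation in kJ/mol, or a named list
#'   with entries \code{phi} and \code{psi} of data.frames understood by
#'   \code{\link{referenceTermStd}}.
#' @param ratios named numeric, default c(phi = 14.77, psi = 5.30).
#' @param sRef reference score for the weights.
#' @param gridStep grid spacing in degrees.
#' @param floorEps relative density floor.
#' @param config optional \linkS4class{CircularKernelConfig}.
#' @param normalize normalize intermediate densities.
#' @return named list of \linkS4class{TorsionPEF} ("<residue>:<kind>").
#' @export
buildTorsionPEFs <- function(ensemble, stdRef = 1, ratios = DEFAULT_RATIOS,
                             sRef = 10, gridStep = 1, floorEps = 1e-8,
                             config = NULL, normalize = TRUE) {
  if (is.null(config)) config <- kernelConfig(N = nModels(ensemble))
  ws <- scoreWeights(modelScores(ensemble), sRef = sRef)
  stdRefOf <- function(kind) {
    if (is.list(stdRef) && !is.data.frame(stdRef))
      referenceTermStd(stdRef[[kind]])
    else stdRef
  }
  s <- ensemble@samples[ensemble@samples$kind %in% EXPORTABLE_KINDS, ,
                        drop = FALSE]
  keys <- unique(s[, c("residue", "kind")])
  keys <- keys[order(keys$residue, match(keys$kind, ANGLE_KINDS)), ]
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- s$residue == keys$residue[i] & s$kind == keys$kind[i]
    ang <- stats::setNames(s$angle[sel], as.character(s$model[sel]))
    pef <- tryCatch(
      pefFromSamples(ang, ws, config, residue = keys$residue[i],
                     kind = keys$kind[i], stdRef = stdRefOf(keys$kind[i]),
                     ratio = unname(ratios[[keys$kind[i]]]),
                     gridStep = gridStep, floorEps = floorEps,
                     normalize = normalize),
      error = function(e) {
        warning(sprintf("residue %d %s skipped (force-field term kept): %s",
                        keys$residue[i], keys$kind[i], conditionMessage(e)))
        NULL
      })
    if (!is.null(pef))
      out[[sprintf("%d:%s", keys$residue[i], keys$kind[i])]] <- pef
  }
  out
}

#' Write torsion potentials and a run manifest
#'
#' One text table per potential (columns angle_deg, energy_kJ_mol,
#' force_kJ_mol_rad) plus a JSON manifest recording N, w, k, sRef, ratios,
#' stdRef and floorEps.
#'
#' @param pefs named list of \linkS4class{TorsionPEF}.
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{CircularKernelConfig} used.
#' @param sRef,seed provenance entries for the manifest.
#' @return invisibly, the manifest path.
#' @export
writePEFBundle <- function(pefs, dir, config = NULL, sRef = 10, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(pefs))
  for (i in seq_along(pefs)) {
    p <- pefs[[i]]
    fn <- sprintf("pef_res%04d_%s.tsv", p@residue, p@kind)
    utils::write.table(
      data.frame(angle_deg = p@grid, energy_kJ_mol = p@energy,
                 force_kJ_mol_rad = p@force),
      file.path(dir, fn), sep = "\t", quote = FALSE, row.names = FALSE)
    files[i] <- fn
  }
  manifest <- list(
    n_pefs = length(pefs), files = files,
    N = if (!is.null(config)) config@N else NA,
    w_rad = if (!is.null(config)) config@width else NA,
    k = if (!is.null(config)) config@exponent else NA,
    s_ref = sRef,
    ratios = as.list(DEFAULT_RATIOS),
    std_ref = if (length(pefs)) pefs[[1]]@stdRef else NA,
    floor_eps = if (length(pefs)) pefs[[1]]@floorEps else NA,
    seed = seed)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mp)
}

#' Read back a potential bundle written by writePEFBundle
#'
#' Reconstructs \linkS4class{TorsionPEF} objects from the per-residue text
#' tables and the manifest (the floored mask is not serialized; it is
#' restored as the zero-force region).
#'
#' @param dir bundle directory.
#' @return named list of \linkS4class{TorsionPEF}.
#' @export
readPEFBundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  out <- list()
  for (fn in man$files) {
    t <- utils::read.table(file.path(dir, fn), header = TRUE, sep = "\t")
    m <- regmatches(fn, regexec("pef_res(\\d+)_(phi|psi)\\.tsv", fn))[[1]]
    if (length(m) != 3) stop("unrecognized bundle file name: ", fn)
    res <- as.integer(m[2]); kind <- m[3]
    en <- t$energy_kJ_mol
    out[[sprintf("%d:%s", res, kind)]] <-
      new("TorsionPEF", residue = res, kind = kind, grid = t$angle_deg,
          energy = en, force = t$force_kJ_mol_rad,
          f = NA_real_, stdRef = man$std_ref %||% NA_real_,
          ratio = unname(DEFAULT_RATIOS[[kind]]),
          floorEps = man$floor_eps %||% NA_real_,
          floored = t$force_kJ_mol_rad == 0 & en == max(en))
  }
  out
}
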