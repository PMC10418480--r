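#' Number of models in an object
#' @param x an object with models
#' @return integer count
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Total scores of an ensemble
#' @param x a ScoredEnsemble
#' @return named numeric vector of per-model total scores
#' @export
setGeneric("modelScores", function(x) standardGeneric("modelScores"))

#' Long table of dihedral samples
#' @param x a ScoredEnsemble
#' @param residue optional residue filter
#' @param kind optional angle-kind filter
#' @return data.frame with columns residue, kind, model, angle
#' @export
setGeneric("dihedralSamples",
           function(x, residue = NULL, kind = NULL)
             standardGeneric("dihedralSamples"))

#' Angle grid of a torsion density or potential
#' @param x a TorsionPDF or TorsionPEF
#' @return numeric grid in degrees
#' @export
setGeneric("angleGrid", function(x) standardGeneric("angleGrid"))

#' Density values of a torsion density
#' @param x a TorsionPDF
#' @return numeric density vector
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' Energy values of a torsion potential
#' @param x a TorsionPEF
#' @return numeric vector, kJ/mol
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' Force values of a torsion potential
#' @param x a TorsionPEF
#' @return numeric vector, -dE/dalpha in kJ/mol/rad
#' @export
setGeneric("forceValues", function(x) standardGeneric("forceValues"))

setMethod("nModels", "ScoredEnsemble", function(x) length(x@models))

setMethod("modelScores", "ScoredEnsemble", function(x) x@scores)

setMethod("dihedralSamples", "ScoredEnsemble",
  function(x, residue = NULL, kind = NULL) {
    s <- x@samples
    if (!is.null(residue)) s <- s[s$residue %in% residue, , drop = FALSE]
    if (!is.null(kind)) s <- s[s$kind %in% kind, , drop = FALSE]
    rownames(s) <- NULL
    s
  })

setMethod("angleGrid", "TorsionPDF", function(x) x@grid)
setMethod("angleGrid", "TorsionPEF", function(x) x@grid)
setMethod("densityValues", "TorsionPDF", function(x) x@density)
setMethod("energyValues", "TorsionPEF", function(x) x@energy)
setMethod("forceValues", "TorsionPEF", function(x) x@force)

setMethod("show", "ModelRecord", function(object) {
  cat(sprintf("ModelRecord %d: %d atoms, %d residues, chain(s) %s\n",
              object@modelId, nrow(object@atoms),
              length(unique(paste(object@atoms$chain, object@atoms$resid))),
              paste(unique(object@atoms$chain), collapse = ",")))
})

setMethod("show", "ScoredEnsemble", function(object) {
  cat(sprintf("ScoredEnsemble: %d models, kinds {%s}, %d dihedral samples\n",
              length(object@models), paste(object@kinds, collapse = ", "),
              nrow(object@samples)))
  if (length(object@scores))
    cat(sprintf("  scores: min %.2f, median %.2f, max %.2f\n",
                min(object@scores), stats::median(object@scores),
                max(object@scores)))
})

setMethod("show", "CircularKernelConfig", function(object) {
  cat(sprintf("CircularKernelConfig: w = %.5f rad (%.2f deg), k = %.4f, N = %s\n",
              object@width, object@width * 180 / pi, object@exponent,
              ifelse(is.na(object@N), "<given width>", object@N)))
})

setMethod("show", "TorsionPDF", function(object) {
  cat(sprintf("TorsionPDF: residue %d %s, %d grid points, %s%s\n",
              object@residue, object@kind, length(object@grid),
              if (object@normalized) "normalized" else "un-normalized",
              if (object@exportable) "" else " (diagnostic only)"))
})

setMethod("show", "TorsionPEF", function(object) {
  cat(sprintf(
    "TorsionPEF: residue %d %s, f = %.4f, sd(E) = %.3f kJ/mol, %d floored points\n",
    object@residue, object@kind, object@f,
    sqrt(mean((object@energy - mean(object@energy))^2)), sum(object@floored)))
})

setMethod("show", "TopologyPatch", function(object) {
  cat(sprintf("TopologyPatch: %d proper lines removed, %d tabulated lines added\n",
              nrow(object@removed), nrow(object@added)))
})
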