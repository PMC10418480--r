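#' @import methods
NULL

ANGLE_KINDS <- c("phi", "psi", "omega")
EXPORTABLE_KINDS <- c("phi", "psi")

#' ModelRecord: one structural model of an ensemble
#'
#' Holds the atoms of a single model from a multi-model PDB file. Atoms are
#' stored as a data.frame with columns \code{name}, \code{resid} (1-based
#' residue number), \code{resname}, \code{chain}, \code{x}, \code{y},
#' \code{z} (coordinates in Angstrom).
#'
#' @slot modelId integer label of the model (from the MODEL record).
#' @slot atoms data.frame of atoms as described above.
#' @exportClass ModelRecord
setClass("ModelRecord",
  representation(modelId = "integer", atoms = "data.frame"),
  validity = function(object) {
    msg <- character()
    req <- c("name", "resid", "resname", "chain", "x", "y", "z")
    if (!all(req %in% names(object@atoms)))
      msg <- c(msg, paste("atoms must have columns:", paste(req, collapse = ", ")))
    else {
      for (ch in unique(object@atoms$chain)) {
        r <- object@atoms$resid[object@atoms$chain == ch]
        if (is.unsorted(r))
          msg <- c(msg, sprintf("residue indices not non-decreasing in chain '%s'", ch))
      }
      if (any(!is.finite(object@atoms$x)) || any(!is.finite(object@atoms$y)) ||
          any(!is.finite(object@atoms$z)))
        msg <- c(msg, "non-finite coordinates")
    }
    if (length(object@modelId) != 1L) msg <- c(msg, "modelId must be length 1")
    if (length(msg)) msg else TRUE
  }
)

#' ScoredEnsemble: models, scores and their dihedral samples
#'
#' The canonical in-memory dataset: a list of \linkS4class{ModelRecord}
#' objects, one total score per model (Rosetta convention, lower is better),
#' and the long table of backbone dihedral samples extracted from them.
#'
#' @slot models list of \linkS4class{ModelRecord}.
#' @slot scores named numeric; names are model ids as character.
#' @slot samples data.frame with columns \code{residue}, \code{kind}
#'   (\code{"phi"}, \code{"psi"} or \code{"omega"}), \code{model},
#'   \code{angle} (degrees in [-180, 180)).
#' @slot kinds character; the angle kinds that were extracted.
#' @exportClass ScoredEnsemble
setClass("ScoredEnsemble",
  representation(models = "list", scores = "numeric", samples = "data.frame",
                 kinds = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@models)
    if (length(object@scores) != n)
      msg <- c(msg, sprintf("%d models but %d scores", n, length(object@scores)))
    ids <- vapply(object@models, function(m) m@modelId, integer(1))
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate model ids")
    if (!setequal(names(object@scores), as.character(ids)))
      msg <- c(msg, "score names do not match model ids")
    if (any(!is.finite(object@scores))) msg <- c(msg, "non-finite scores")
    if (nrow(object@samples) &&
        !all(object@samples$model %in% ids))
      msg <- c(msg, "sample model ids not a subset of ensemble model ids")
    if (nrow(object@samples) &&
        (any(object@samples$angle < -180) || any(object@samples$angle >= 180)))
      msg <- c(msg, "sample angles outside [-180, 180)")
    if (length(msg)) msg else TRUE
  }
)

#' CircularKernelConfig: kernel width, exponent and ensemble size
#'
#' Width \code{w} (radians) and exponent \code{k} of the power-raised cosine
#' kernel are tied by k = 1 + 1/tan^2(w/2); when derived from the ensemble
#' size, w = 2*pi*N^(-1/3) (a Scott-rule-like bandwidth).
#'
#' @slot width numeric, kernel width w in radians, in (0, pi].
#' @slot exponent numeric, kernel exponent k >= 1.
#' @slot N integer, ensemble size the width was derived from (NA if the
#'   width was given directly).
#' @exportClass CircularKernelConfig
setClass("CircularKernelConfig",
  representation(width = "numeric", exponent = "numeric", N = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@width <= 0 || object@width > pi)
      msg <- c(msg, "width must be in (0, pi]")
    if (object@exponent < 1) msg <- c(msg, "exponent must be >= 1")
    kk <- 1 + 1 / tan(object@width / 2)^2
    if (abs(kk - object@exponent) > 1e-6 * max(1, kk))
      msg <- c(msg, "exponent inconsistent with width (k = 1 + 1/tan^2(w/2))")
    if (length(msg)) msg else TRUE
  }
)

#' WeightSet: per-model Boltzmann-like score weights
#'
#' Weights c_j = exp(-s_j / s_ref) computed from total scores; C is their sum.
#'
#' @slot sRef numeric reference score (> 0, default 10).
#' @slot weights named numeric, one weight per model, all > 0.
#' @slot total numeric, sum of the weights.
#' @exportClass WeightSet
setClass("WeightSet",
  representation(sRef = "numeric", weights = "numeric", total = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sRef <= 0) msg <- c(msg, "sRef must be > 0")
    if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
    if (abs(object@total - sum(object@weights)) >
        1e-9 * max(1, object@total))
      msg <- c(msg, "total != sum(weights)")
    if (length(msg)) msg else TRUE
  }
)

#' TorsionPDF: score-weighted circular density of one dihedral
#'
#' Density of one residue's phi/psi/omega angle on a uniform grid over
#' [-180, 180). The density unit is 1/degree when normalized (the
#' circular trapezoidal integral is 1).
#'
#' @slot residue integer, 1-based residue index.
#' @slot kind character, "phi", "psi" or "omega".
#' @slot grid numeric, uniform grid in degrees over [-180, 180).
#' @slot density numeric, nonnegative density values on the grid.
#' @slot normalized logical, whether the density integrates to 1.
#' @slot config \linkS4class{CircularKernelConfig} used.
#' @slot exportable logical; FALSE for omega (diagnostic only, never
#'   exported as a potential).
#' @exportClass TorsionPDF
setClass("TorsionPDF",
  representation(residue = "integer", kind = "character", grid = "numeric",
                 density = "numeric", normalized = "logical",
                 config = "CircularKernelConfig", exportable = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% ANGLE_KINDS) msg <- c(msg, "unknown angle kind")
    if (length(object@grid) != length(object@density))
      msg <- c(msg, "grid/density length mismatch")
    if (any(object@density < 0)) msg <- c(msg, "negative density")
    if (length(object@grid) > 1) {
      st <- diff(object@grid)
      if (max(abs(st - st[1])) > 1e-9) msg <- c(msg, "grid not uniform")
    }
    if (isTRUE(object@normalized)) {
      step <- object@grid[2] - object@grid[1]
      if (abs(sum(object@density) * step - 1) > 1e-9)
        msg <- c(msg, "normalized density does not integrate to 1")
    }
    if (length(msg)) msg else TRUE
  }
)

#' TorsionPEF: Boltzmann-inverted, force-field-scaled torsion potential
#'
#' Energy E(alpha) = -f * ln max(P(alpha), floor) shifted so min(E) = 0, and
#' the analytic force -dE/dalpha, on the same grid as the source density.
#' The scaling factor f is chosen so that sd(E)/stdRef equals the
#' kind-specific ratio (14.77 for phi, 5.30 for psi by default).
#'
#' @slot residue integer residue index.
#' @slot kind character angle kind ("phi" or "psi").
#' @slot grid numeric grid in degrees over [-180, 180).
#' @slot energy numeric, kJ/mol.
#' @slot force numeric, -dE/dalpha in kJ/mol/rad.
#' @slot f numeric, applied scaling factor f_i.
#' @slot stdRef numeric, reference standard deviation (kJ/mol).
#' @slot ratio numeric, target sd(E)/stdRef ratio.
#' @slot floorEps numeric, relative density floor applied.
#' @slot floored logical vector, TRUE where the density was floored.
#' @exportClass TorsionPEF
setClass("TorsionPEF",
  representation(residue = "integer", kind = "character", grid = "numeric",
                 energy = "numeric", force = "numeric", f = "numeric",
                 stdRef = "numeric", ratio = "numeric", floorEps = "numeric",
                 floored = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% ANGLE_KINDS) msg <- c(msg, "unknown angle kind")
    n <- length(object@grid)
    if (length(object@energy) != n || length(object@force) != n ||
        length(object@floored) != n)
      msg <- c(msg, "grid/energy/force/floored length mismatch")
    if (n && abs(min(object@energy)) > 1e-9 * max(1, max(object@energy)))
      msg <- c(msg, "energy minimum not shifted to 0")
    if (length(msg)) msg else TRUE
  }
)

#' TopologyPatch: record of a topology dihedral replacement
#'
#' Bookkeeping for swapping backbone proper dihedrals for tabulated ones:
#' the removed proper lines (with their original positions, so the patch is
#' reversible) and the added tabulated lines.
#'
#' @slot removed data.frame with columns \code{line} (1-based index in the
#'   original file), \code{text}, \code{residue}, \code{kind}.
#' @slot added data.frame with columns \code{text}, \code{residue},
#'   \code{kind}, \code{table}.
#' @slot marker character, comment marker delimiting the added block.
#' @exportClass TopologyPatch
setClass("TopologyPatch",
  representation(removed = "data.frame", added = "data.frame",
                 marker = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(c("line", "text", "residue", "kind") %in% names(object@removed)))
      msg <- c(msg, "removed must have columns line, text, residue, kind")
    if (!all(c("text", "residue", "kind", "table") %in% names(object@added)))
      msg <- c(msg, "added must have columns text, residue, kind, table")
    both <- intersect(object@removed$text, object@added$text)
    if (length(both)) msg <- c(msg, "a line is both removed and added")
    if (length(msg)) msg else TRUE
  }
)
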