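#' Extract backbone dihedral samples from an ensemble of models
#'
#' Computes phi (C[i-1]-N[i]-CA[i]-C[i]), psi (N[i]-CA[i]-C[i]-N[i+1]) and,
#' on request, omega (CA[i]-C[i]-N[i+1]-CA[i+1]) for every residue of every
#' model. phi is undefined for the first residue of a chain and psi/omega
#' for the last. omega is diagnostic only (the planar peptide bond keeps it
#' nearly constant) and is flagged non-exportable downstream.
#'
#' Residues missing a required backbone atom in a model are skipped in that
#' model with a warning. Models must share one sequence/chain layout.
#'
#' @param models list of \linkS4class{ModelRecord}.
#' @param kinds character subset of c("phi", "psi", "omega").
#' @return data.frame with columns \code{residue}, \code{kind},
#'   \code{model}, \code{angle} (degrees in [-180, 180)), \code{chain}.
#' @export
extractDihedrals <- function(models, kinds = c("phi", "psi")) {
  kinds <- match.arg(kinds, ANGLE_KINDS, several.ok = TRUE)
  ref <- .sequenceLayout(models[[1]])
  for (m in models[-1]) {
    lay <- .sequenceLayout(m)
    if (!identical(dim(ref), dim(lay)) ||
        !all(ref$chain == lay$chain & ref$resid == lay$resid &
             ref$resname == lay$resname)) {
      bad <- which(!(paste(ref$chain, ref$resid, ref$resname) %in%
                     paste(lay$chain, lay$resid, lay$resname)))[1]
      if (is.na(bad)) bad <- 1L
      stop(sprintf(
        "inconsistent sequences across models: model %d differs from model %d first at chain %s residue %d (%s)",
        m@modelId, models[[1]]@modelId,
        ref$chain[bad], ref$resid[bad], ref$resname[bad]))
    }
  }
  out <- vector("list", length(models))
  skipped <- character()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    a <- m@atoms
    rows <- list()
    for (ch in unique(a$chain)) {
      ac <- a[a$chain == ch & a$name %in% c("N", "CA", "C"), , drop = FALSE]
      resids <- sort(unique(ac$resid))
      co <- function(rid, nm) {
        i <- which(ac$resid == rid & ac$name == nm)[1]
        if (is.na(i)) return(NULL)
        c(ac$x[i], ac$y[i], ac$z[i])
      }
      for (ri in seq_along(resids)) {
        rid <- resids[ri]
        prev <- if (ri > 1 && resids[ri - 1] == rid - 1) resids[ri - 1] else NA
        nxt <- if (ri < length(resids) && resids[ri + 1] == rid + 1)
          resids[ri + 1] else NA
        need <- list()
        if ("phi" %in% kinds && !is.na(prev))
          need$phi <- list(co(prev, "C"), co(rid, "N"), co(rid, "CA"), co(rid, "C"))
        if ("psi" %in% kinds && !is.na(nxt))
          need$psi <- list(co(rid, "N"), co(rid, "CA"), co(rid, "C"), co(nxt, "N"))
        if ("omega" %in% kinds && !is.na(nxt))
          need$omega <- list(co(rid, "CA"), co(rid, "C"), co(nxt, "N"), co(nxt, "CA"))
        for (kd in names(need)) {
          pts <- need[[kd]]
          if (any(vapply(pts, is.null, logical(1)))) {
            skipped <- c(skipped,
                         sprintf("model %d chain %s residue %d %s", m@modelId,
                                 ch, rid, kd))
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            residue = rid, kind = kd, model = m@modelId,
            angle = computeDihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
            chain = ch, stringsAsFactors = FALSE)
        }
      }
    }
    out[[mi]] <- do.call(rbind, rows)
  }
  if (length(skipped))
    warning("skipped dihedrals with missing backbone atoms: ",
            paste(utils::head(skipped, 5), collapse = "; "),
            if (length(skipped) > 5) sprintf(" (and %d more)", length(skipped) - 5))
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no dihedral could be extracted from the ensemble")
  res <- res[order(res$chain, res$residue, match(res$kind, ANGLE_KINDS),
                   res$model), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.sequenceLayout <- function(m) {
  # keyed on any backbone atom so that a single missing atom in one model
  # does not masquerade as a sequence mismatch
  a <- m@atoms[m@atoms$name %in% c("N", "CA", "C"),
               c("chain", "resid", "resname")]
  a <- unique(a)
  a[order(a$chain, a$resid), , drop = FALSE]
}

#' Assemble a scored ensemble
#'
#' Bundles models, their total scores and the extracted dihedral samples
#' into the canonical \linkS4class{ScoredEnsemble} dataset. Scores are
#' matched to models by name when the score table carries names that embed
#' the model number (e.g. "m_0003"), otherwise by file order.
#'
#' @param models list of \linkS4class{ModelRecord}.
#' @param scores named numeric from \code{\link{readScores}}, or bare
#'   numeric in model order.
#' @param kinds angle kinds to extract (default phi and psi).
#' @param topFraction keep only this fraction of best-scoring (lowest score)
#'   models before extraction; default 1 (use all models).
#' @return a \linkS4class{ScoredEnsemble}.
#' @export
scoredEnsemble <- function(models, scores, kinds = c("phi", "psi"),
                           topFraction = 1) {
  if (length(scores) != length(models))
    stop(sprintf("%d models but %d scores", length(models), length(scores)))
  ids <- vapply(models, function(m) m@modelId, integer(1))
  if (!is.null(names(scores))) {
    num <- suppressWarnings(as.integer(gsub("\\D", "", names(scores))))
    if (!any(is.na(num)) && setequal(num, ids))
      scores <- scores[match(ids, num)]
  }
  names(scores) <- as.character(ids)
  if (topFraction < 1) {
    if (topFraction <= 0) stop("topFraction must be in (0, 1]")
    keep <- order(scores)[seq_len(max(1L, ceiling(topFraction * length(models))))]
    keep <- sort(keep)
    models <- models[keep]
    scores <- scores[keep]
  }
  samples <- extractDihedrals(models, kinds)
  new("ScoredEnsemble", models = models, scores = scores,
      samples = samples[, c("residue", "kind", "model", "angle")],
      kinds = kinds)
}

#' Read a scored ensemble from a PDB file and a score table
#'
#' Convenience wrapper around \code{\link{readEnsemble}},
#' \code{\link{readScores}} and \code{\link{scoredEnsemble}}.
#'
#' @param pdbPath multi-model PDB file.
#' @param scorePath Rosetta-style score table.
#' @param kinds angle kinds to extract.
#' @param topFraction see \code{\link{scoredEnsemble}}.
#' @return a \linkS4class{ScoredEnsemble}.
#' @export
readScoredEnsemble <- function(pdbPath, scorePath, kinds = c("phi", "psi"),
                               topFraction = 1) {
  scoredEnsemble(readEnsemble(pdbPath), readScores(scorePath),
                 kinds = kinds, topFraction = topFraction)
}

#' Write the canonical dihedral dataset as a tab-separated table
#'
#' Columns: residue_index, angle_kind, model_id, angle_deg, score.
#'
#' @param ensemble a \linkS4class{ScoredEnsemble}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeDihedralDataset <- function(ensemble, path) {
  s <- ensemble@samples
  out <- data.frame(residue_index = s$residue, angle_kind = s$kind,
                    model_id = s$model, angle_deg = s$angle,
                    score = unname(ensemble@scores[as.character(s$model)]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a dihedral dataset written by writeDihedralDataset
#'
#' @param path TSV file path.
#' @return data.frame with the written columns.
#' @export
readDihedralDataset <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
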