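PATCH_MARKER_BEGIN <- "; tabulated-backbone-dihedrals begin"
PATCH_MARKER_END <- "; tabulated-backbone-dihedrals end"

#' Write tabulated dihedral table files
#'
#' One three-column table (angle_deg, energy kJ/mol, minus-derivative
#' kJ/mol/rad) per potential, covering [-180, 180] inclusive (the +180 row
#' repeats the -180 values, closing the period). Table indices are assigned
#' deterministically, sorted by residue then kind (phi before psi), and
#' files are named \code{table_d<index>.xvg}.
#'
#' @param pefs named list of \linkS4class{TorsionPEF}.
#' @param dir output directory.
#' @param spacing table spacing in degrees; must divide 360 evenly and
#'   match the potentials' grid.
#' @return data.frame with columns \code{residue}, \code{kind},
#'   \code{table} (0-based index), \code{file}.
#' @export
writeDihedralTables <- function(pefs, dir, spacing = 1) {
  if (abs(360 / spacing - round(360 / spacing)) > 1e-9)
    stop("spacing must evenly divide 360 degrees")
  kinds <- vapply(pefs, function(p) p@kind, character(1))
  if (any(!kinds %in% EXPORTABLE_KINDS))
    stop("only phi/psi potentials are exportable (omega is diagnostic only)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ord <- order(vapply(pefs, function(p) p@residue, integer(1)),
               match(vapply(pefs, function(p) p@kind, character(1)),
                     EXPORTABLE_KINDS))
  pefs <- pefs[ord]
  out <- data.frame(residue = integer(), kind = character(),
                    table = integer(), file = character())
  for (i in seq_along(pefs)) {
    p <- pefs[[i]]
    st <- p@grid[2] - p@grid[1]
    if (abs(st - spacing) > 1e-9)
      stop(sprintf("potential grid step %.4f does not match spacing %.4f",
                   st, spacing))
    idx <- i - 1L
    fn <- sprintf("table_d%d.xvg", idx)
    ang <- c(p@grid, 180)
    en <- c(p@energy, p@energy[1])
    fo <- c(p@force, p@force[1])
    writeLines(sprintf("%12.6f %20.12e %20.12e", ang, en, fo),
               file.path(dir, fn))
    out <- rbind(out, data.frame(residue = p@residue, kind = p@kind,
                                 table = idx, file = fn))
  }
  rownames(out) <- NULL
  out
}

#' Read a tabulated dihedral table file
#'
#' @param path path to a table written by \code{\link{writeDihedralTables}}.
#' @return data.frame with columns \code{angle_deg}, \code{energy},
#'   \code{minus_derivative}.
#' @export
readDihedralTable <- function(path) {
  t <- utils::read.table(path, col.names = c("angle_deg", "energy",
                                             "minus_derivative"))
  st <- diff(t$angle_deg)
  if (max(abs(st - st[1])) > 1e-9) stop("non-uniform table spacing in ", path)
  if (abs(t$energy[1] - t$energy[nrow(t)]) > 1e-9)
    stop("table not periodic (first/last energies differ) in ", path)
  t
}

#' Parse a pre-processed GROMACS-dialect topology
#'
#' Supports plain, include-expanded topology text: \code{[ atoms ]} and
#' \code{[ dihedrals ]} sections of the first moleculetype are parsed.
#' Preprocessor macros (#include, #define, #ifdef) are not expanded here;
#' their presence is an error rather than a silent pass-through.
#'
#' @param topology path to a .top/.itp file, or its lines as a character
#'   vector.
#' @return list with \code{lines}, \code{atoms} (data.frame index, name,
#'   resnr, resname) and \code{dihedrals} (data.frame line, ai, aj, ak, al,
#'   funct).
#' @export
parseTopology <- function(topology) {
  lines <- if (length(topology) == 1 && file.exists(topology))
    readLines(topology) else topology
  if (any(grepl("^\\s*#(include|define|ifdef|ifndef)", lines)))
    stop("topology contains preprocessor macros; run it through the ",
         "engine's preprocessor (grompp -pp) first")
  section <- ""
  atoms <- list(); dihed <- list()
  nAtomSections <- 0L
  for (i in seq_along(lines)) {
    ln <- sub(";.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[\\s*(\\S+)\\s*\\]$", ln))[[1]]
    if (length(m)) {
      section <- tolower(m[2])
      if (section == "atoms") {
        nAtomSections <- nAtomSections + 1L
        if (nAtomSections > 1L) break  # only the first moleculetype
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (section == "atoms") {
      if (length(tok) < 5)
        stop(sprintf("malformed [ atoms ] line %d", i))
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(tok[1]), name = tok[5],
        resnr = as.integer(tok[3]), resname = tok[4],
        stringsAsFactors = FALSE)
    } else if (section == "dihedrals") {
      if (length(tok) < 5)
        stop(sprintf("malformed [ dihedrals ] line %d", i))
      dihed[[length(dihed) + 1L]] <- data.frame(
        line = i, ai = as.integer(tok[1]), aj = as.integer(tok[2]),
        ak = as.integer(tok[3]), al = as.integer(tok[4]),
        funct = as.integer(tok[5]), stringsAsFactors = FALSE)
    }
  }
  list(lines = lines,
       atoms = if (length(atoms)) do.call(rbind, atoms) else
         data.frame(index = integer(), name = character(),
                    resnr = integer(), resname = character()),
       dihedrals = if (length(dihed)) do.call(rbind, dihed) else
         data.frame(line = integer(), ai = integer(), aj = integer(),
                    ak = integer(), al = integer(), funct = integer()))
}

#' Backbone phi/psi atom-index quadruplets of a topology
#'
#' Resolves, per residue, the phi quadruplet C(i-1)-N(i)-CA(i)-C(i) and the
#' psi quadruplet N(i)-CA(i)-C(i)-N(i+1) to topology atom indices. Termini
#' lacking an angle are omitted; angles spanning a chain break (gap in the
#' residue numbering, or a non-peptide residue) are omitted with a warning.
#'
#' @param top parsed topology from \code{\link{parseTopology}} (or a path /
#'   lines, parsed on the fly).
#' @return data.frame with columns \code{residue}, \code{kind}, \code{ai},
#'   \code{aj}, \code{ak}, \code{al}.
#' @export
identifyBackboneQuadruplets <- function(top) {
  if (!is.list(top) || is.null(top$atoms)) top <- parseTopology(top)
  a <- top$atoms
  resnrs <- sort(unique(a$resnr))
  idx <- function(r, nm) {
    i <- a$index[a$resnr == r & a$name == nm]
    if (length(i)) i[1] else NA_integer_
  }
  bb <- lapply(resnrs, function(r)
    c(N = idx(r, "N"), CA = idx(r, "CA"), C = idx(r, "C")))
  names(bb) <- as.character(resnrs)
  peptide <- vapply(bb, function(x) !all(is.na(x)), logical(1))
  for (r in resnrs[peptide]) {
    x <- bb[[as.character(r)]]
    if (any(is.na(x)))
      stop(sprintf("residue %d is missing backbone atom(s): %s", r,
                   paste(names(x)[is.na(x)], collapse = ", ")))
  }
  out <- list(); broken <- integer()
  for (r in resnrs[peptide]) {
    x <- bb[[as.character(r)]]
    prevOk <- (r - 1) %in% resnrs && peptide[[as.character(r - 1)]]
    nextOk <- (r + 1) %in% resnrs && peptide[[as.character(r + 1)]]
    if (r > min(resnrs[peptide]) && !prevOk) broken <- c(broken, r)
    if (prevOk)
      out[[length(out) + 1L]] <- data.frame(
        residue = r, kind = "phi", ai = bb[[as.character(r - 1)]]["C"],
        aj = x["N"], ak = x["CA"], al = x["C"])
    if (nextOk)
      out[[length(out) + 1L]] <- data.frame(
        residue = r, kind = "psi", ai = x["N"], aj = x["CA"], ak = x["C"],
        al = bb[[as.character(r + 1)]]["N"])
  }
  if (length(broken))
    warning("chain break: omitted angles spanning residue(s) ",
            paste(unique(broken), collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Patch a topology: replace backbone propers with tabulated dihedrals
#'
#' Removes every proper-dihedral line (funct 1 or 9, including multiple
#' multiplicity lines for the same quadruplet, in either atom order) of the
#' targeted phi/psi quadruplets and appends one tabulated-dihedral line
#' (funct 8, per-line table number, scale factor 1.0 -- the magnitude
#' already lives inside the potential) per quadruplet, in a marked block at
#' the end of the molecule's dihedral section. Impropers (funct 2/4),
#' Ryckaert-Bellemans terms (funct 3), omega and every other dihedral are
#' untouched. Applying the patch to an already-patched topology is a no-op
#' with a warning; \code{\link{unpatchTopology}} restores the original from
#' the patch record.
#'
#' @param topology path, lines, or parsed topology.
#' @param tables data.frame from \code{\link{writeDihedralTables}} (columns
#'   residue, kind, table).
#' @param quadruplets data.frame from
#'   \code{\link{identifyBackboneQuadruplets}}; defaults to identifying
#'   them from the topology. Only rows whose (residue, kind) has a table
#'   are targeted.
#' @return list with \code{lines} (patched topology text) and \code{patch}
#'   (a \linkS4class{TopologyPatch}).
#' @export
patchTopology <- function(topology, tables, quadruplets = NULL) {
  top <- if (is.list(topology) && !is.null(topology$lines)) topology
         else parseTopology(topology)
  lines <- top$lines
  if (any(grepl(PATCH_MARKER_BEGIN, lines, fixed = TRUE))) {
    warning("topology already patched; no-op")
    return(list(lines = lines,
                patch = new("TopologyPatch",
                            removed = data.frame(line = integer(),
                                                 text = character(),
                                                 residue = integer(),
                                                 kind = character()),
                            added = data.frame(text = character(),
                                               residue = integer(),
                                               kind = character(),
                                               table = integer()),
                            marker = PATCH_MARKER_BEGIN)))
  }
  if (is.null(quadruplets)) quadruplets <- identifyBackboneQuadruplets(top)
  targets <- merge(quadruplets, tables[, c("residue", "kind", "table")],
                   by = c("residue", "kind"))
  if (nrow(targets) < nrow(tables))
    stop("some tables have no matching backbone quadruplet in the topology")
  d <- top$dihedrals
  removed <- list(); added <- list()
  for (i in seq_len(nrow(targets))) {
    q <- unlist(targets[i, c("ai", "aj", "ak", "al")])
    hit <- d$funct %in% c(1L, 9L) &
      ((d$ai == q[1] & d$aj == q[2] & d$ak == q[3] & d$al == q[4]) |
       (d$ai == q[4] & d$aj == q[3] & d$ak == q[2] & d$al == q[1]))
    if (!any(hit))
      stop(sprintf(
        "no proper dihedral found for residue %d %s (atoms %s); refusing to add a tabulated term on top",
        targets$residue[i], targets$kind[i], paste(q, collapse = "-")))
    removed[[i]] <- data.frame(line = d$line[hit], text = lines[d$line[hit]],
                               residue = targets$residue[i],
                               kind = targets$kind[i],
                               stringsAsFactors = FALSE)
    added[[i]] <- data.frame(
      text = sprintf("%6d %6d %6d %6d     8 %5d   1.0", q[1], q[2], q[3],
                     q[4], targets$table[i]),
      residue = targets$residue[i], kind = targets$kind[i],
      table = targets$table[i], stringsAsFactors = FALSE)
  }
  removed <- do.call(rbind, removed)
  added <- do.call(rbind, added)
  if (anyDuplicated(removed$line))
    stop("internal error: a proper line matched two quadruplets")
  insertAt <- max(d$line)  # after the last dihedral line of the molecule
  block <- c(PATCH_MARKER_BEGIN, "[ dihedrals ]", added$text,
             PATCH_MARKER_END)
  keep <- setdiff(seq_along(lines), removed$line)
  before <- keep[keep <= insertAt]
  after <- keep[keep > insertAt]
  patched <- c(lines[before], block, lines[after])
  patch <- new("TopologyPatch", removed = removed, added = added,
               marker = PATCH_MARKER_BEGIN)
  list(lines = patched, patch = patch)
}

#' Reverse a topology patch
#'
#' Restores the original topology (byte-identical, comments included) from
#' a patched topology and its \linkS4class{TopologyPatch} record: the
#' marked tabulated block is dropped and the removed proper lines are
#' reinserted at their original positions.
#'
#' @param lines patched topology lines.
#' @param patch the \linkS4class{TopologyPatch} returned when patching.
#' @return character vector of the restored topology lines.
#' @export
unpatchTopology <- function(lines, patch) {
  b <- which(lines == PATCH_MARKER_BEGIN)
  e <- which(lines == PATCH_MARKER_END)
  if (length(b) != 1 || length(e) != 1 || e < b)
    stop("patched block markers not found or malformed")
  base <- lines[-(b:e)]
  rem <- patch@removed[order(patch@removed$line), , drop = FALSE]
  for (i in seq_len(nrow(rem)))
    base <- append(base, rem$text[i], after = rem$line[i] - 1L)
  base
}

#' Write a topology patch report
#'
#' @param patch a \linkS4class{TopologyPatch}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writePatchReport <- function(patch, path) {
  jsonlite::write_json(
    list(removed = patch@removed, added = patch@added,
         n_removed = nrow(patch@removed), n_added = nrow(patch@added)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
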