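#' Read a multi-model PDB ensemble
#'
#' Parses MODEL/ENDMDL blocks into a list of \linkS4class{ModelRecord}
#' objects. A file without MODEL records but with ATOM records is read as a
#' single model (id 1). ATOM and HETATM records are kept (NMR-style
#' ensembles may carry ions or ligands); for alternate locations only the
#' first (blank or "A") is kept; insertion codes are rejected, since
#' ensemble generators such as CS-Rosetta emit neither.
#'
#' @param path path to a PDB file.
#' @return list of \linkS4class{ModelRecord}, file order preserved.
#' @export
readEnsemble <- function(path) {
  lines <- readLines(path)
  recs <- list()
  cur <- NULL          # data accumulators for the open model
  curId <- NA_integer_
  inModel <- FALSE
  sawModelKw <- FALSE
  finish <- function(cur, curId, lineNo) {
    if (is.null(cur) || length(cur$name) == 0L)
      stop(sprintf("empty model (no ATOM records) ending at line %d", lineNo))
    atoms <- data.frame(name = cur$name, resid = cur$resid,
                        resname = cur$resname, chain = cur$chain,
                        x = cur$x, y = cur$y, z = cur$z,
                        stringsAsFactors = FALSE)
    new("ModelRecord", modelId = curId, atoms = atoms)
  }
  newAcc <- function() list(name = character(), resid = integer(),
                            resname = character(), chain = character(),
                            x = numeric(), y = numeric(), z = numeric())
  for (i in seq_along(lines)) {
    ln <- lines[i]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "MODEL")) {
      sawModelKw <- TRUE
      inModel <- TRUE
      cur <- newAcc()
      id <- suppressWarnings(as.integer(trimws(substr(ln, 7, 80))))
      curId <- if (is.na(id)) length(recs) + 1L else id
    } else if (startsWith(rec, "ENDMDL")) {
      recs[[length(recs) + 1L]] <- finish(cur, curId, i)
      cur <- NULL
      inModel <- FALSE
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (is.null(cur)) {            # unlabelled single-model file
        cur <- newAcc()
        curId <- 1L
      }
      if (nchar(ln) < 54)
        stop(sprintf("malformed ATOM record at line %d: too short", i))
      alt <- substr(ln, 17, 17)
      if (!alt %in% c(" ", "", "A")) next   # keep first altloc only
      icode <- substr(ln, 27, 27)
      if (icode != " " && icode != "")
        stop(sprintf("insertion code '%s' at line %d not supported", icode, i))
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      resid <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
      if (any(is.na(xyz)) || is.na(resid))
        stop(sprintf("malformed ATOM record at line %d: non-numeric field", i))
      n <- length(cur$name) + 1L
      cur$name[n] <- trimws(substr(ln, 13, 16))
      cur$resid[n] <- resid
      cur$resname[n] <- trimws(substr(ln, 18, 20))
      cur$chain[n] <- substr(ln, 22, 22)
      cur$x[n] <- xyz[1]; cur$y[n] <- xyz[2]; cur$z[n] <- xyz[3]
    }
  }
  if (!is.null(cur) && length(cur$name)) {
    if (sawModelKw && inModel)
      warning("final MODEL block not closed by ENDMDL; kept")
    recs[[length(recs) + 1L]] <- finish(cur, curId, length(lines))
  }
  if (!length(recs))
    stop("empty ensemble: no models with ATOM records found in ", path)
  recs
}

#' Write models to a multi-model PDB file
#'
#' Coordinates are written with the standard 3-decimal PDB precision, each
#' model wrapped in MODEL/ENDMDL records.
#'
#' @param models list of \linkS4class{ModelRecord}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEnsemble <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(sprintf("MODEL     %4d", m@modelId), con)
    a <- m@atoms
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       seq_len(nrow(a)), nm, a$resname, a$chain, a$resid,
                       a$x, a$y, a$z, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a Rosetta-style score table
#'
#' Accepts the header-labelled whitespace-delimited ".sc" dialect (a header
#' naming a total-score column, e.g. \code{total_score} or \code{score},
#' and a \code{description} column; optional leading \code{SCORE:} tags) or
#' a plain two-column (id, score) table.
#'
#' @param path path to the score file.
#' @return named numeric vector of total scores; names are the model
#'   descriptions/ids.
#' @export
readScores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty score table: ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  tagged <- vapply(tok, function(t) identical(t[1], "SCORE:"), logical(1))
  if (any(tagged)) tok <- lapply(tok[tagged], function(t) t[-1])
  header <- tok[[1]]
  rows <- tok[-1]
  scoreCol <- which(tolower(header) %in% c("total_score", "score", "total"))
  descCol <- which(tolower(header) %in% c("description", "model", "id", "tag"))
  if (length(scoreCol) && length(descCol)) {
    scoreCol <- scoreCol[1]; descCol <- descCol[1]
    if (!length(rows)) stop("score table has a header but no rows: ", path)
    ids <- vapply(rows, `[`, character(1), descCol)
    sc <- vapply(rows, `[`, character(1), scoreCol)
  } else if (all(lengths(tok) == 2L)) {
    # two-column fallback; drop a non-numeric header row if present
    if (is.na(suppressWarnings(as.numeric(header[2])))) {
      if (!length(rows)) stop("score table has a header but no rows: ", path)
    } else rows <- tok
    ids <- vapply(rows, `[`, character(1), 1L)
    sc <- vapply(rows, `[`, character(1), 2L)
  } else {
    stop("cannot locate a total-score and a description column in ", path)
  }
  val <- suppressWarnings(as.numeric(sc))
  if (any(is.na(val)))
    stop("non-numeric score for model(s): ",
         paste(ids[is.na(val)], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate model id(s) in score table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(val, ids)
}
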