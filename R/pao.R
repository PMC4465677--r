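## Plain-text PAO-style detection-history files.
##
## Grammar (one item per line unless noted; whitespace-delimited):
##   occucam-pao 1                         magic + format version
##   sites: <n>
##   occasions: <n>
##   type: single|multistate|twospecies
##   seasons: <k>                          then k lines "label year start nWeeks"
##   observations:                         then n lines "siteId code ..."
##                                         codes are integers, "-" = missing
##   effort:                               then n lines "siteId days ..."
##   sitecovs: <name> ... | none           then (if any) n lines "siteId value ..."
##   end
## Numeric covariates are printed with %.15g so that write -> read -> write
## is byte-identical.

fmtNum <- function(x) formatC(x, format = "g", digits = 15)

#' Write a detection history (and optional covariates) to a PAO-style file
#'
#' Serialises a [DetectionHistory-class] plus optional
#' [SiteCovariates-class] to the plain-text PAO dialect documented in the
#' package (header lines declaring dimensions and season layout, a
#' whitespace-delimited observation matrix with \code{"-"} for missing
#' site-weeks, an effort block, and named site-covariate columns). Output is
#' deterministic: writing the same object twice yields identical bytes, and
#' [readPAO()] restores the object exactly.
#'
#' @param history a [DetectionHistory-class].
#' @param path output file path.
#' @param covariates optional [SiteCovariates-class] (raw scale is written).
#' @return Invisibly, \code{path}.
#' @seealso [readPAO()]
#' @export
writePAO <- function(history, path, covariates = NULL) {
  o <- history@observations; e <- history@effort
  s <- history@layout@seasons
  lines <- c("occucam-pao 1",
             paste0("sites: ", nrow(o)),
             paste0("occasions: ", ncol(o)),
             paste0("type: ", history@type),
             paste0("seasons: ", nrow(s)),
             sprintf("%s %d %s %d", s$label, s$year, format(s$start), s$nWeeks),
             "observations:")
  oChr <- matrix(as.character(o), nrow(o)); oChr[o == OBS_MISSING] <- "-"
  lines <- c(lines, paste(history@siteIds, apply(oChr, 1L, paste, collapse = " ")))
  lines <- c(lines, "effort:",
             paste(history@siteIds, apply(e, 1L, paste, collapse = " ")))
  if (is.null(covariates)) {
    lines <- c(lines, "sitecovs: none")
  } else {
    cd <- covariates@raw
    cd <- cd[match(history@siteIds, cd$site), , drop = FALSE]
    if (any(is.na(cd$site))) stop("covariates missing for some history sites")
    covNames <- setdiff(names(cd), "site")
    lines <- c(lines, paste("sitecovs:", paste(covNames, collapse = " ")))
    vals <- vapply(seq_len(nrow(cd)), function(i)
      paste(fmtNum(unlist(cd[i, covNames])), collapse = " "), character(1))
    lines <- c(lines, paste(cd$site, vals))
  }
  lines <- c(lines, "end")
  writeLines(lines, path)
  invisible(path)
}

paoStop <- function(lineNo, msg) stop(sprintf("PAO parse error at line %d: %s", lineNo, msg),
                                      call. = FALSE)

#' Read a PAO-style detection-history file
#'
#' Parses the plain-text dialect written by [writePAO()]. Ragged rows,
#' non-numeric cells and dimension mismatches raise an error naming the
#' offending line. Files may or may not embed site covariates; the second
#' list element is \code{NULL} when they are absent.
#'
#' @param path file path.
#' @return \code{list(history = DetectionHistory, covariates =
#'   SiteCovariates or NULL)}.
#' @export
readPAO <- function(path) {
  lines <- readLines(path)
  ln <- 0L
  nextLine <- function() {
    ln <<- ln + 1L
    if (ln > length(lines)) paoStop(ln, "unexpected end of file")
    lines[ln]
  }
  expectKey <- function(key) {
    l <- nextLine()
    if (!startsWith(l, paste0(key, ":")) && l != key)
      paoStop(ln, paste0("expected '", key, "'"))
    trimws(sub(paste0("^", key, ":?"), "", l))
  }
  if (nextLine() != "occucam-pao 1") paoStop(1L, "bad magic header")
  nSites <- as.integer(expectKey("sites"))
  nOcc <- as.integer(expectKey("occasions"))
  if (is.na(nSites) || is.na(nOcc)) paoStop(ln, "non-numeric dimension")
  type <- expectKey("type")
  nSeas <- as.integer(expectKey("seasons"))
  if (is.na(nSeas) || nSeas < 1) paoStop(ln, "bad season count")
  sdf <- lapply(seq_len(nSeas), function(i) {
    f <- strsplit(nextLine(), "[ \t]+")[[1]]
    if (length(f) != 4) paoStop(ln, "season line needs: label year start nWeeks")
    f
  })
  layout <- seasonLayout(vapply(sdf, `[`, "", 1L),
                         as.integer(vapply(sdf, `[`, "", 2L)),
                         vapply(sdf, `[`, "", 3L),
                         as.integer(vapply(sdf, `[`, "", 4L)))
  if (layout@totalWeeks != nOcc)
    paoStop(ln, sprintf("season weeks sum to %d but occasions: %d", layout@totalWeeks, nOcc))
  readBlock <- function(key, parse) {
    expectKey(key)
    rows <- vector("list", nSites); ids <- character(nSites)
    for (i in seq_len(nSites)) {
      f <- strsplit(nextLine(), "[ \t]+")[[1]]
      ids[i] <- f[1L]
      rows[[i]] <- parse(f[-1L])
    }
    list(ids = ids, m = do.call(rbind, rows))
  }
  parseCodes <- function(f) {
    if (length(f) != nOcc) paoStop(ln, sprintf("row has %d cells, expected %d", length(f), nOcc))
    v <- suppressWarnings(as.integer(ifelse(f == "-", OBS_MISSING, f)))
    if (any(is.na(v))) paoStop(ln, "non-numeric observation cell")
    v
  }
  parseEffort <- function(f) {
    if (length(f) != nOcc) paoStop(ln, sprintf("row has %d cells, expected %d", length(f), nOcc))
    v <- suppressWarnings(as.integer(f))
    if (any(is.na(v))) paoStop(ln, "non-numeric effort cell")
    v
  }
  ob <- readBlock("observations", parseCodes)
  eb <- readBlock("effort", parseEffort)
  if (!identical(ob$ids, eb$ids)) paoStop(ln, "site ids differ between blocks")
  covHead <- expectKey("sitecovs")
  covariates <- NULL
  if (covHead != "none") {
    covNames <- strsplit(covHead, "[ \t]+")[[1]]
    cm <- vector("list", nSites); ids <- character(nSites)
    for (i in seq_len(nSites)) {
      f <- strsplit(nextLine(), "[ \t]+")[[1]]
      if (length(f) != length(covNames) + 1L)
        paoStop(ln, sprintf("covariate row has %d cells, expected %d",
                            length(f) - 1L, length(covNames)))
      ids[i] <- f[1L]
      v <- suppressWarnings(as.numeric(f[-1L]))
      if (any(is.na(v))) paoStop(ln, "non-numeric covariate cell")
      cm[[i]] <- v
    }
    if (!identical(ids, ob$ids)) paoStop(ln, "covariate site ids differ")
    df <- as.data.frame(do.call(rbind, cm))
    names(df) <- covNames
    covariates <- siteCovariates(cbind(site = ids, df))
  }
  if (nextLine() != "end") paoStop(ln, "expected 'end'")
  history <- detectionHistory(ob$m, eb$m, layout, siteIds = ob$ids, type = type)
  list(history = history, covariates = covariates)
}
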