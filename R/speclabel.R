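## Compact model-notation labels, e.g.
##   "psi(Season + Direct) p(Season x Direct + Number)"
##   "psi(Season) R(.) p(State + Season) delta(Season)"
##   "psi(Species) p(Species x Direct + Number)"

covTerm <- function(covariate, mode, factorName) {
  disp <- COV_DISPLAY[[covariate]]
  switch(mode,
         none = factorName,
         additive = paste(factorName, "+", disp),
         interaction = paste(factorName, "x", disp))
}

#' Compact text label of a model specification
#'
#' Mirrors the field's customary notation: the occupancy and detection
#' linear predictors in parentheses, \code{+} for additive covariate
#' effects, \code{x} for season- (or species-) specific slopes,
#' \code{Number} for the camera-effort term and \code{.} for a constant
#' parameter.
#'
#' @param spec an [OccuModelSpec-class].
#' @return character(1) label.
#' @seealso [parseModelSpec()] for the inverse.
#' @export
specLabel <- function(spec) {
  fac <- if (spec@family == "twospecies") "Species" else "Season"
  if (spec@family == "multistate") {
    pLab <- switch(spec@pStateTerms,
                   season = "Season",
                   state_add = "State + Season",
                   state_int = "State x Season")
    return(sprintf("psi(Season) R(%s) p(%s) delta(%s)",
                   if (spec@rTerms == "season") "Season" else ".",
                   pLab,
                   if (spec@deltaTerms == "season") "Season" else "."))
  }
  psiLab <- if (is.na(spec@covariate)) fac
            else covTerm(spec@covariate, spec@psiMode, fac)
  pLab <- if (is.na(spec@covariate)) fac
          else covTerm(spec@covariate, spec@pMode, fac)
  if (spec@effortTerm) pLab <- paste(pLab, "+ Number")
  sprintf("psi(%s) p(%s)", psiLab, pLab)
}

#' Parse a compact model label into an OccuModelSpec
#'
#' Inverse of [specLabel()]; accepts labels such as
#' \code{"psi(Season + Direct) p(Season x Direct + Number)"} or
#' \code{"psi(Season) R(.) p(State + Season) delta(Season)"}.
#'
#' @param label character(1) model label.
#' @param family model family the label belongs to.
#' @param etaFree passed through for the two-species family.
#' @return An [OccuModelSpec-class].
#' @export
parseModelSpec <- function(label, family = c("multiseason", "multistate", "twospecies"),
                           etaFree = FALSE) {
  family <- match.arg(family)
  grab <- function(key) {
    m <- regmatches(label, regexec(paste0(key, "\\(([^)]*)\\)"), label))[[1]]
    if (length(m) < 2) stop("label lacks a ", key, "(...) term: ", label)
    trimws(m[2])
  }
  if (family == "multistate") {
    pIn <- grab("p")
    pStateTerms <- if (grepl("State x Season", pIn, fixed = TRUE)) "state_int"
                   else if (grepl("State", pIn)) "state_add" else "season"
    return(modelSpec(family,
                     rTerms = if (grab("R") == "Season") "season" else "constant",
                     pStateTerms = pStateTerms,
                     deltaTerms = if (grab("delta") == "Season") "season" else "constant"))
  }
  effortTerm <- grepl("Number", label)
  parseSide <- function(txt) {
    txt <- gsub("\\+ *Number", "", txt)
    hit <- which(vapply(COV_DISPLAY, function(d)
      grepl(d, txt, fixed = TRUE), logical(1)))
    ## "Total" also contains no other display name; "P" would substring-match
    ## "pH", so test pH before P by preferring the longest match
    if (length(hit) > 1) hit <- hit[which.max(nchar(COV_DISPLAY[hit]))]
    if (length(hit) == 0) return(list(cov = NA_character_, mode = "none"))
    list(cov = names(COV_DISPLAY)[hit],
         mode = if (grepl(" x ", txt, fixed = TRUE)) "interaction" else "additive")
  }
  psi <- parseSide(grab("psi"))
  p <- parseSide(grab("p"))
  cov <- if (!is.na(psi$cov)) psi$cov else p$cov
  if (!is.na(psi$cov) && !is.na(p$cov) && psi$cov != p$cov)
    stop("a model carries at most one habitat covariate: ", label)
  modelSpec(family, covariate = cov, psiMode = psi$mode, pMode = p$mode,
            etaFree = etaFree, effortTerm = effortTerm)
}
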