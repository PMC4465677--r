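#' Read raw camera-trap image records from CSV
#'
#' Expects columns \code{site_id}, \code{datetime} (ISO-8601), \code{species}
#' (\code{rusa}/\code{red}), \code{age} (\code{adult}/\code{juvenile}) and
#' \code{sex} (\code{male}/\code{female}/\code{unknown}). Rows with an
#' unparseable timestamp or a value outside the closed enumerations are
#' rejected with a warning naming the offending rows.
#'
#' @param path CSV file path.
#' @param tz timezone for timestamps (default UTC).
#' @return data.frame with columns \code{site}, \code{timestamp}
#'   (\code{POSIXct}), \code{species}, \code{age}, \code{sex}.
#' @export
readImageRecords <- function(path, tz = "UTC") {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "datetime", "species", "age", "sex")
  if (!all(need %in% names(raw)))
    stop("image CSV must have columns: ", paste(need, collapse = ", "))
  ts <- as.POSIXct(raw$datetime, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  bad <- is.na(ts) | !raw$species %in% c("rusa", "red") |
    !raw$age %in% c("adult", "juvenile") |
    !raw$sex %in% c("male", "female", "unknown")
  if (any(bad))
    warning(sum(bad), " record(s) rejected (bad timestamp or enumeration): rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "))
  data.frame(site = as.character(raw$site_id[!bad]), timestamp = ts[!bad],
             species = raw$species[!bad], age = raw$age[!bad],
             sex = raw$sex[!bad], stringsAsFactors = FALSE)
}

#' Drop non-independent consecutive images
#'
#' Camera traps fire repeatedly while an animal lingers; consecutive images
#' of the same species at the same camera within a short window are treated
#' as one event and only the first is retained. Filtering runs per
#' (site, species) stream, anchored to the last \emph{retained} record: a
#' record is dropped when its timestamp is less than \code{window} after the
#' previously retained record of its stream. The operation is idempotent and
#' preserves the input row order of the survivors.
#'
#' @param records image-record data.frame (see [readImageRecords()]).
#' @param window independence window in seconds (default 300 = 5 minutes).
#' @return The retained subset of \code{records}.
#' @examples
#' recs <- data.frame(site = "s1",
#'   timestamp = as.POSIXct("2010-07-01 12:00:00", tz = "UTC") + c(0, 180, 480),
#'   species = "rusa", age = "adult", sex = "female")
#' nrow(filterIndependentImages(recs))  # 2: the 3-minute follow-up is dropped
#' @export
filterIndependentImages <- function(records, window = 300) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$timestamp))) stop("records contain unparseable timestamps")
  keep <- logical(nrow(records))
  for (key in unique(paste(records$site, records$species))) {
    idx <- which(paste(records$site, records$species) == key)
    idx <- idx[order(records$timestamp[idx])]
    lastKept <- -Inf
    for (i in idx) {
      t <- as.numeric(records$timestamp[i])
      if (t - lastKept >= window || !is.finite(lastKept)) {
        keep[i] <- TRUE
        lastKept <- t
      }
    }
  }
  records[keep, , drop = FALSE]
}

## week index (or NA) of each timestamp under a layout
weekOfTimestamp <- function(timestamp, layout) {
  d <- as.Date(timestamp)
  s <- layout@seasons
  wk <- rep(NA_integer_, length(d))
  for (i in seq_len(nrow(s))) {
    off <- as.integer(d - s$start[i])
    inSeason <- off >= 0L & off < 7L * s$nWeeks[i]
    wk[inSeason] <- s$firstWeek[i] + off[inSeason] %/% 7L
  }
  wk
}

#' Aggregate image records to weekly detection histories
#'
#' Builds the site x week observation matrix from independence-filtered
#' records. For a single-species history the weekly code is 1 when at least
#' one record of \code{species} falls in the site-week. For a multistate
#' history the code is 2 when at least one adult-male record of the species
#' falls in the week (the male state subsumes the species state), 1 when
#' only other records do, 0 otherwise. For a two-species history the weekly
#' code is \code{yA + 2*yB} over species \code{c("rusa", "red")}. Weeks with
#' zero effort are coded -1 regardless of records; records dated outside the
#' layout are discarded with a warning.
#'
#' @param records filtered image records (see [filterIndependentImages()]).
#' @param layout a [SeasonLayout-class].
#' @param effort integer site x week matrix of active camera days; rownames
#'   are site ids.
#' @param type history type to build.
#' @param species focal species ("rusa" or "red") for single/multistate
#'   histories.
#' @return A [DetectionHistory-class].
#' @export
aggregateWeekly <- function(records, layout, effort,
                            type = c("single", "multistate", "twospecies"),
                            species = "rusa") {
  type <- match.arg(type)
  effort <- as.matrix(effort); storage.mode(effort) <- "integer"
  sites <- rownames(effort)
  if (is.null(sites)) stop("effort matrix must have site ids as rownames")
  if (ncol(effort) != layout@totalWeeks)
    stop("effort must have one column per weekly occasion")
  wk <- weekOfTimestamp(records$timestamp, layout)
  out <- is.na(wk) | !records$site %in% sites
  if (any(out)) {
    warning(sum(out), " record(s) outside the season layout or site list discarded")
    records <- records[!out, , drop = FALSE]; wk <- wk[!out]
  }
  obs <- matrix(0L, nrow(effort), ncol(effort), dimnames = dimnames(effort))
  mark <- function(sp, code, onlyAdultMale = FALSE) {
    sel <- records$species == sp
    if (onlyAdultMale) sel <- sel & records$age == "adult" & records$sex == "male"
    if (!any(sel)) return(invisible())
    i <- match(records$site[sel], sites); j <- wk[sel]
    for (k in seq_along(i)) obs[i[k], j[k]] <<- bitwOr(obs[i[k], j[k]], code)
  }
  if (type == "single") {
    mark(species, 1L)
  } else if (type == "multistate") {
    mark(species, 1L)
    mark(species, 2L, onlyAdultMale = TRUE)
    obs[obs == 3L] <- 2L  # male detection subsumes the species state
  } else {
    mark("rusa", 1L)
    mark("red", 2L)
  }
  obs[effort == 0L] <- OBS_MISSING
  detectionHistory(obs, effort, layout, siteIds = sites, type = type)
}

#' Naive occupancy of a season
#'
#' Proportion of sites with at least one detection (any positive code)
#' during the given season, uncorrected for detectability. Invariant to the
#' ordering of sites.
#'
#' @param history a [DetectionHistory-class].
#' @param season season index into the layout, or \code{NULL} to pool all
#'   seasons (site-union detection across the study).
#' @return Proportion in [0, 1].
#' @export
naiveOccupancy <- function(history, season = NULL) {
  obs <- history@observations
  if (!is.null(season)) {
    s <- history@layout@seasons
    if (season < 1 || season > nrow(s)) stop("invalid season index")
    cols <- s$firstWeek[season] + seq_len(s$nWeeks[season]) - 1L
    obs <- obs[, cols, drop = FALSE]
  }
  if (all(obs == OBS_MISSING)) stop("all weeks missing in the requested season")
  mean(apply(obs, 1L, function(r) any(r > 0L)))
}
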