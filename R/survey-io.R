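## Survey I/O: two dialects.
##  - "csv": long table, one row per (ping, depth bin), columns
##    ping_index, time_utc, lat, lon, depth_m (bin top; uniform bin height),
##    sv38_db, sv120_db; empty = missing. dB written with 6 decimals.
##  - "json": self-describing gridded container (dimensions, coordinates
##    including full depth edges, variables with units/convention attributes).
## The JSON container is lossless for arbitrary bin spacing; the CSV dialect
## assumes uniform bins (validated on read).

.CSV_COLS <- c("ping_index", "time_utc", "lat", "lon", "depth_m",
               "sv38_db", "sv120_db")

#' Read / write a two-frequency survey
#'
#' `writeSurvey()` serializes a 38/120 kHz [SvGrid-class] pair;
#' `readSurvey()` restores it. Values, missing flags and geometry round-trip
#' losslessly (dB values carry >= 4 decimal places in the CSV dialect).
#'
#' @param survey list with elements `sv38` and `sv120` ([SvGrid-class]).
#' @param path file path.
#' @param dialect `"csv"` (long table) or `"json"` (gridded self-describing
#'   container).
#' @return `readSurvey()` returns `list(sv38 =, sv120 =)`.
#' @export
writeSurvey <- function(survey, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  g38 <- survey$sv38; g120 <- survey$sv120
  stopifnot(is(g38, "SvGrid"), is(g120, "SvGrid"))
  if (!identical(dim(g38@sv), dim(g120@sv)) ||
      !isTRUE(all.equal(g38@depthEdges, g120@depthEdges)))
    stop("sv38 and sv120 must share one lattice")
  if (dialect == "csv") .writeSurveyCsv(g38, g120, path) else
    .writeSurveyJson(g38, g120, path)
  invisible(path)
}

#' @rdname writeSurvey
#' @export
readSurvey <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") .readSurveyCsv(path) else .readSurveyJson(path)
}

.fmtDb <- function(x) ifelse(is.na(x), "", sprintf("%.10f", x))

.writeSurveyCsv <- function(g38, g120, path) {
  np <- nrow(g38@sv); nb <- ncol(g38@sv)
  tops <- g38@depthEdges[-(nb + 1L)]
  df <- data.frame(
    ping_index = rep(g38@pings$ping_index, times = nb),
    time_utc = rep(format(g38@pings$time_utc, "%Y-%m-%dT%H:%M:%OS3",
                          tz = "UTC"), times = nb),
    lat = rep(sprintf("%.8f", g38@pings$lat), times = nb),
    lon = rep(sprintf("%.8f", g38@pings$lon), times = nb),
    depth_m = rep(sprintf("%.6f", tops), each = np),
    sv38_db = .fmtDb(as.vector(linearToDb(g38@sv))),
    sv120_db = .fmtDb(as.vector(linearToDb(g120@sv))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.readSurveyCsv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (!setequal(names(df), .CSV_COLS))
    stop("unknown or missing columns: expected ",
         paste(.CSV_COLS, collapse = ", "))
  df$ping_index <- as.integer(df$ping_index)
  df$depth_m <- as.numeric(df$depth_m)

  tops <- unique(df$depth_m)
  pidx <- unique(df$ping_index)
  if (any(diff(tops) <= 0))
    stop("non-monotone depth column")
  key <- paste(df$ping_index, df$depth_m)
  if (anyDuplicated(key)) stop("duplicate (ping, depth) keys")
  nb <- length(tops); np <- length(pidx)
  if (nrow(df) != nb * np) stop("ragged (ping, depth) lattice")

  if (nb > 1) {
    h <- diff(tops)
    if (max(h) - min(h) > 1e-6)
      stop("csv dialect requires uniform depth bins; use the json container")
    edges <- c(tops, tops[nb] + h[1])
  } else edges <- c(tops, tops + 1)

  ord <- order(match(df$depth_m, tops), match(df$ping_index, pidx))
  df <- df[ord, ]
  toMat <- function(col) {
    x <- suppressWarnings(as.numeric(col))
    matrix(dbToLinear(x), np, nb)
  }
  first <- df[seq_len(np), ]
  pings <- data.frame(
    ping_index = first$ping_index,
    time_utc = as.POSIXct(first$time_utc, format = "%Y-%m-%dT%H:%M:%OS",
                          tz = "UTC"),
    lat = as.numeric(first$lat), lon = as.numeric(first$lon))
  list(sv38 = new("SvGrid", frequency = 38, sv = toMat(df$sv38_db),
                  depthEdges = edges, pings = pings),
       sv120 = new("SvGrid", frequency = 120, sv = toMat(df$sv120_db),
                   depthEdges = edges, pings = pings))
}

.writeSurveyJson <- function(g38, g120, path) {
  toList <- function(g) {
    m <- linearToDb(g@sv)
    list(units = "dB re 1 m-1", data = unname(apply(m, 1, as.list,
                                                    simplify = FALSE)))
  }
  obj <- list(
    container = "zoosonde-survey-grid",
    version = 1L,
    dimensions = list(ping = nrow(g38@sv), depth = ncol(g38@sv)),
    coordinates = list(
      ping_index = g38@pings$ping_index,
      time_utc = format(g38@pings$time_utc, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
      lat = g38@pings$lat, lon = g38@pings$lon,
      depth_edges_m = g38@depthEdges),
    variables = list(sv38_db = toList(g38), sv120_db = toList(g120)),
    attributes = list(convention = "Sv re 1 m-1; depth positive down",
                      frequencies_khz = c(g38@frequency, g120@frequency)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
}

.readSurveyJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "zoosonde-survey-grid"))
    stop("not a zoosonde survey container")
  np <- obj$dimensions$ping; nb <- obj$dimensions$depth
  edges <- as.numeric(obj$coordinates$depth_edges_m)
  if (any(diff(edges) <= 0)) stop("non-monotone depth edges")
  pings <- data.frame(
    ping_index = as.integer(obj$coordinates$ping_index),
    time_utc = as.POSIXct(obj$coordinates$time_utc,
                          format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
    lat = as.numeric(obj$coordinates$lat),
    lon = as.numeric(obj$coordinates$lon))
  toMat <- function(v) {
    if (is.matrix(v$data)) return(dbToLinear(v$data))
    m <- matrix(NA_real_, np, nb)
    for (i in seq_len(np)) m[i, ] <- as.numeric(unlist(
      lapply(v$data[[i]], function(x) if (is.null(x)) NA_real_ else x)))
    dbToLinear(m)
  }
  fr <- obj$attributes$frequencies_khz
  list(sv38 = new("SvGrid", frequency = fr[1], sv = toMat(obj$variables$sv38_db),
                  depthEdges = edges, pings = pings),
       sv120 = new("SvGrid", frequency = fr[2],
                   sv = toMat(obj$variables$sv120_db),
                   depthEdges = edges, pings = pings))
}

#' Export a classification mask as a long table
#'
#' @param mask a [ClassMask-class].
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame with `ping_block`, `depth_cell`, `label`, `provenance`.
#' @export
maskToDataFrame <- function(mask, path = NULL) {
  stopifnot(is(mask, "ClassMask"))
  d <- dim(mask@labels)
  df <- data.frame(ping_block = rep(seq_len(d[1]), times = d[2]),
                   depth_cell = rep(seq_len(d[2]), each = d[1]),
                   label = as.vector(mask@labels),
                   provenance = as.vector(mask@provenance))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
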