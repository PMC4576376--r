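# Delimited sensor-log import/export, channel schema and the time index.

.roles <- c("time-day", "time-hour", "time-min", "time-sec", "time-ms",
            "accel-x", "accel-y", "accel-z", "mag-x", "mag-y", "mag-z",
            "pressure", "temperature", "latitude", "longitude",
            "derived", "other")
.types <- c("integer", "real", "text")

#' Channel schema for a sensor log
#'
#' Describes each column of a tag log: its name, its semantic role (time
#' fields, accelerometer/magnetometer axes, environmental channels, derived
#' outputs) and its value type. The roles drive every downstream step: the
#' five `time-*` fields are combined into the millisecond time index, and the
#' `accel-*`/`mag-*` roles locate the tri-axial sensor channels.
#'
#' @param name character vector of unique column names.
#' @param role character vector of roles, one of
#'   `r paste0('"', .roles, '"', collapse = ", ")`.
#' @param type value types, one of `"integer"`, `"real"`, `"text"`.
#' @return a `channel_schema` data frame.
#' @export
channel_schema <- function(name, role = "other",
                           type = ifelse(role == "text", "text", "real")) {
  n <- length(name)
  role <- rep_len(role, n)
  type <- rep_len(type, n)
  if (anyDuplicated(name)) stop("channel names must be unique")
  bad <- setdiff(role, .roles)
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(type, .types)
  if (length(bad)) stop("unknown value type(s): ", paste(bad, collapse = ", "))
  timeroles <- role[startsWith(role, "time-")]
  if (anyDuplicated(timeroles)) stop("at most one channel per time-* role")
  sens <- startsWith(role, "accel-") | startsWith(role, "mag-")
  if (any(sens & type != "real")) {
    stop("accelerometer/magnetometer channels must be real-valued")
  }
  out <- data.frame(name = name, role = role, type = type,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_schema", "data.frame")
  out
}

# guess roles from conventional column names when no schema is given
guess_role <- function(nm) {
  lut <- c(day = "time-day", d = "time-day",
           hour = "time-hour", h = "time-hour", hrs = "time-hour",
           min = "time-min", m = "time-min", mins = "time-min",
           sec = "time-sec", s = "time-sec", secs = "time-sec",
           ms = "time-ms", msec = "time-ms",
           ax = "accel-x", ay = "accel-y", az = "accel-z",
           accx = "accel-x", accy = "accel-y", accz = "accel-z",
           mx = "mag-x", my = "mag-y", mz = "mag-z",
           magx = "mag-x", magy = "mag-y", magz = "mag-z",
           pressure = "pressure", press = "pressure",
           temperature = "temperature", temp = "temperature",
           lat = "latitude", latitude = "latitude",
           lon = "longitude", long = "longitude", longitude = "longitude")
  key <- tolower(gsub("[^a-z]", "", tolower(nm)))
  out <- unname(lut[key])
  out[is.na(out)] <- "other"
  out
}

ms_per <- c("time-day" = 86400000, "time-hour" = 3600000,
            "time-min" = 60000, "time-sec" = 1000, "time-ms" = 1)

# combine the time-* fields into milliseconds
combine_time_ms <- function(df, schema) {
  tms <- numeric(nrow(df))
  found <- FALSE
  for (r in names(ms_per)) {
    i <- which(schema$role == r)
    if (length(i)) {
      tms <- tms + as.numeric(df[[schema$name[i]]]) * ms_per[[r]]
      found <- TRUE
    }
  }
  if (!found) return(NULL)
  tms
}

new_sensor_table <- function(df, schema, rate, time_ms) {
  stopifnot(nrow(df) >= 1)
  if (!is.null(time_ms) && is.unsorted(time_ms)) {
    stop("timestamps must be non-decreasing")
  }
  structure(df, schema = schema, rate = rate, time_ms = time_ms,
            class = c("sensor_table", "data.frame"))
}

#' The millisecond time index of a sensor table
#' @param table a `sensor_table`.
#' @return numeric vector of per-sample timestamps (ms), combined from the
#'   `time-*` fields as `day*86400000 + h*3600000 + min*60000 + s*1000 + ms`.
#'   The value is the raw combination, not re-based to zero, so that external
#'   fixes stamped on the same clock align exactly.
#' @export
time_ms <- function(table) attr(table, "time_ms")

#' The channel schema of a sensor table
#' @param table a `sensor_table`.
#' @return the [channel_schema] describing the table's columns.
#' @export
schema <- function(table) attr(table, "schema")

#' Load a delimited sensor log
#'
#' Reads a comma- or tab-delimited tag log with a header row into a typed
#' [sensor_table]. Malformed numeric cells become missing values and their
#' count is recorded; a row with the wrong number of fields is an error that
#' names the offending row.
#'
#' @param path file to read.
#' @param delimiter `"comma"` or `"tab"`.
#' @param schema optional [channel_schema] covering all columns; when `NULL`
#'   names are taken from the header and roles guessed from conventional
#'   column names (`ax`, `my`, `day`, ...).
#' @param rate nominal sampling rate in Hz; when `NULL` it is inferred from
#'   the median time-index step.
#' @param require_time error when no `time-*` channel is present (set `FALSE`
#'   for auxiliary tables such as calibration snippets).
#' @return a `sensor_table` with attributes `schema`, `rate` and `time_ms`,
#'   plus `n_malformed`, the count of unparseable numeric cells.
#' @export
load_table <- function(path, delimiter = c("comma", "tab"), schema = NULL,
                       rate = NULL, require_time = TRUE) {
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "comma") "," else "\t"
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  ncol <- length(header)
  nf <- lengths(fields[-1])
  bad <- which(nf != ncol)
  if (length(bad)) {
    stop("row ", bad[1] + 1, " has ", nf[bad[1]], " fields, expected ", ncol)
  }
  if (is.null(schema)) {
    schema <- channel_schema(header, guess_role(header))
  } else {
    if (!inherits(schema, "channel_schema")) stop("'schema' must be a channel_schema")
    if (nrow(schema) != ncol) {
      stop("schema covers ", nrow(schema), " columns but file has ", ncol)
    }
  }
  raw <- matrix(unlist(fields[-1], use.names = FALSE), ncol = ncol, byrow = TRUE)
  df <- vector("list", ncol)
  names(df) <- schema$name
  n_malformed <- 0L
  for (j in seq_len(ncol)) {
    col <- trimws(raw[, j])
    if (schema$type[j] == "text") {
      df[[j]] <- col
    } else {
      v <- suppressWarnings(as.numeric(col))
      n_malformed <- n_malformed + sum(is.na(v) & nzchar(col) & col != "NA")
      if (schema$type[j] == "integer") v <- as.integer(round(v))
      df[[j]] <- v
    }
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  tms <- combine_time_ms(df, schema)
  if (is.null(tms) && require_time) {
    stop("no time-* channels found and a time index is required")
  }
  if (is.null(rate) && !is.null(tms) && nrow(df) > 1) {
    step <- stats::median(diff(tms))
    rate <- if (step > 0) 1000 / step else NA_real_
  }
  out <- new_sensor_table(df, schema, rate, tms)
  attr(out, "n_malformed") <- n_malformed
  out
}

#' A set of time-stamped positional fixes
#'
#' Ground-truth positions (typically GPS) used to merge into the sensor log
#' and to correct dead-reckoned tracks.
#'
#' @param time_ms strictly increasing timestamps (ms, same clock as the log).
#' @param lat,lon coordinates in decimal degrees.
#' @param source free-text label for the fix source.
#' @return a `fix_set` data frame.
#' @export
fix_set <- function(time_ms, lat, lon, source = "gps") {
  stopifnot(length(time_ms) == length(lat), length(lat) == length(lon))
  if (length(time_ms) > 1 && any(diff(time_ms) <= 0)) {
    stop("fix timestamps must be strictly increasing")
  }
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("|latitude| must be <= 90")
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("|longitude| must be <= 180")
  structure(data.frame(time_ms = time_ms, lat = lat, lon = lon),
            source = source, class = c("fix_set", "data.frame"))
}

#' Read positional fixes from a delimited file
#'
#' @inheritParams load_table
#' @param schema optional schema; the file must expose `time-*` fields plus
#'   `latitude` and `longitude` roles.
#' @export
load_fixes <- function(path, delimiter = c("comma", "tab"), schema = NULL,
                       source = "gps") {
  tbl <- load_table(path, delimiter, schema, require_time = TRUE)
  sc <- schema(tbl)
  lat <- sc$name[sc$role == "latitude"]
  lon <- sc$name[sc$role == "longitude"]
  if (!length(lat) || !length(lon)) stop("fix file needs latitude and longitude columns")
  fix_set(time_ms(tbl), tbl[[lat[1]]], tbl[[lon[1]]], source = source)
}

#' Merge positional fixes into a sensor table
#'
#' Appends `latitude` and `longitude` columns to the log. A row receives a
#' fix's coordinates only when the fix shares its exact timestamp (both
#' streams are assumed time-synchronised); every other row gets a missing
#' value, which downstream steps skip. No interpolation is performed at merge
#' time. An optional tolerance (off by default) admits nearest-neighbour
#' matching for fixes whose clock ticks fall between samples.
#'
#' @param table a [sensor_table] with a time index.
#' @param fixes a [fix_set].
#' @param tolerance_ms match a fix to the nearest sample within this many
#'   milliseconds; `0` (the default) requires exact timestamp equality.
#' @param names names for the two appended columns.
#' @return the table with two appended columns; all pre-existing columns are
#'   untouched.
#' @export
merge_fixes <- function(table, fixes, tolerance_ms = 0,
                        names = c("fix_lat", "fix_lon")) {
  tms <- time_ms(table)
  if (is.null(tms)) stop("table has no time index")
  lat <- rep(NA_real_, nrow(table))
  lon <- rep(NA_real_, nrow(table))
  if (nrow(fixes) > 0) {
    if (tolerance_ms > 0) {
      idx <- vapply(fixes$time_ms, function(ft) {
        d <- abs(tms - ft)
        i <- which.min(d)
        if (d[i] <= tolerance_ms) i else NA_integer_
      }, integer(1))
    } else {
      idx <- match(fixes$time_ms, tms)
    }
    ok <- !is.na(idx)
    if (!any(ok)) {
      warning("no fix timestamp matches the table's time span; columns are all null")
    }
    lat[idx[ok]] <- fixes$lat[ok]
    lon[idx[ok]] <- fixes$lon[ok]
  }
  append_channels(table, stats::setNames(list(lat, lon), names))
}

#' Append derived channels to a sensor table
#'
#' @param table a [sensor_table].
#' @param channels named list of vectors, each of `nrow(table)` values.
#' @return the table with the new columns appended (roles `derived`, or
#'   `latitude`/`longitude` when so named); existing columns and the row
#'   count are never modified.
#' @export
append_channels <- function(table, channels) {
  stopifnot(is.list(channels), !is.null(names(channels)))
  sc <- schema(table)
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (length(v) != nrow(table)) {
      stop("channel '", nm, "' has ", length(v), " values, table has ", nrow(table), " rows")
    }
    if (nm %in% sc$name) stop("channel '", nm, "' already exists")
    table[[nm]] <- v
    role <- if (grepl("lat", nm)) "latitude" else if (grepl("lon", nm)) "longitude" else "derived"
    sc <- rbind(sc, data.frame(name = nm, role = role,
                               type = if (is.numeric(v)) "real" else "text"))
  }
  class(sc) <- c("channel_schema", "data.frame")
  attr(table, "schema") <- sc
  table
}

#' Fetch the tri-axial channels for a sensor role
#' @param table a [sensor_table].
#' @param what `"accel"` or `"mag"`.
#' @return an N x 3 numeric matrix in x, y, z order.
#' @export
sensor_matrix <- function(table, what = c("accel", "mag")) {
  what <- match.arg(what)
  sc <- schema(table)
  cols <- vapply(c("x", "y", "z"), function(ax) {
    i <- which(sc$role == paste0(what, "-", ax))
    if (!length(i)) stop("table has no ", what, "-", ax, " channel")
    sc$name[i[1]]
  }, character(1))
  as.matrix(as.data.frame(table)[, cols])
}

#' Export a merged sensor table with behaviour codes
#'
#' Writes the table (original plus derived channels) to CSV with one extra
#' `behaviour` column: rows inside a labelled interval carry that class's
#' integer code, all other rows carry 0 (reserved for "unlabelled").
#' Numeric cells are written with 15 significant digits so that
#' export -> [load_table] -> export reproduces the file byte-identically.
#'
#' @param table a [sensor_table].
#' @param path output file.
#' @param labels optional [label_set]; overlapping intervals of different
#'   classes are an error naming the conflict.
#' @return `path`, invisibly.
#' @export
export_merged <- function(table, path, labels = NULL) {
  codes <- behaviour_codes(labels, nrow(table))
  df <- as.data.frame(table)
  df$behaviour <- codes
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  mat <- do.call(cbind, cols)
  lines <- c(paste(names(df), collapse = ","),
             apply(mat, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sensor_table <- function(x, ...) {
  cat("<sensor_table> ", nrow(x), " samples x ", ncol(x), " channels",
      if (!is.null(attr(x, "rate"))) paste0(" @ ", signif(attr(x, "rate"), 4), " Hz"),
      "\n", sep = "")
  sc <- schema(x)
  cat("channels:", paste0(sc$name, " [", sc$role, "]", collapse = ", "), "\n")
  if (!is.null(time_ms(x))) {
    cat("time index: ", time_ms(x)[1], " .. ", time_ms(x)[nrow(x)], " ms\n", sep = "")
  }
  invisible(x)
}
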