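# Persistent template store: a directory of plain-text template files with
# a JSON index, keyed animal -> behaviour. A database back-end without a
# server: templates saved from one deployment can be queried and reused on
# any other file.

#' Write / read a single template file
#'
#' Plain-text format: a metadata header (`animal`, `behaviour`, `p`, `q`,
#' `channels`) followed by one space-separated sample line per channel.
#'
#' @param template a [dd_template].
#' @param path file path.
#' @return `write_template` returns `path` invisibly; `read_template` the
#'   template (lossless round trip).
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "dd_template"))
  lines <- c(paste("animal:", template$animal),
             paste("behaviour:", template$behaviour),
             paste("p:", template$p),
             paste("q:", template$q),
             paste("channels:", paste(names(template$channels), collapse = ",")))
  for (ch in names(template$channels)) {
    lines <- c(lines, paste0(ch, ": ",
                             paste(fmt_num(template$channels[[ch]]), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("cannot read template file: ", path)
  lines <- readLines(path, warn = FALSE)
  val <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) stop("malformed template file: missing '", key, "'")
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  chans <- strsplit(val("channels"), ",")[[1]]
  waves <- lapply(chans, function(ch) {
    v <- suppressWarnings(as.numeric(strsplit(val(ch), "\\s+")[[1]]))
    if (anyNA(v)) stop("malformed template file: channel '", ch, "'")
    v
  })
  dd_template(stats::setNames(waves, chans),
              animal = val("animal"), behaviour = val("behaviour"),
              p = as.integer(val("p")), q = as.integer(val("q")))
}

store_index_path <- function(dir) file.path(dir, "index.json")

read_store_index <- function(dir) {
  p <- store_index_path(dir)
  if (!file.exists(p)) {
    return(data.frame(animal = character(0), behaviour = character(0),
                      file = character(0)))
  }
  as.data.frame(jsonlite::fromJSON(p))
}

#' Save a template into a template store
#'
#' @param dir store directory (created if absent).
#' @param template a [dd_template]; its `animal`/`behaviour` metadata form
#'   the key. Saving under an existing key replaces the stored template.
#' @return the stored file path, invisibly.
#' @export
store_template <- function(dir, template) {
  stopifnot(inherits(template, "dd_template"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- read_store_index(dir)
  slug <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)
  fn <- paste0(slug(template$animal), "__", slug(template$behaviour), ".tpl")
  write_template(template, file.path(dir, fn))
  idx <- idx[!(idx$animal == template$animal &
                 idx$behaviour == template$behaviour), , drop = FALSE]
  idx <- rbind(idx, data.frame(animal = template$animal,
                               behaviour = template$behaviour, file = fn))
  jsonlite::write_json(idx, store_index_path(dir), auto_unbox = FALSE,
                       digits = NA)
  invisible(file.path(dir, fn))
}

#' Query a template store
#'
#' @param dir store directory.
#' @param animal animal key.
#' @param behaviour optional behaviour name; when `NULL` all of the animal's
#'   stored behaviours are returned.
#' @return a list of [dd_template]s (empty when the animal is unknown); with
#'   `behaviour` given, an error if that key is missing.
#' @export
query_store <- function(dir, animal, behaviour = NULL) {
  idx <- read_store_index(dir)
  sub <- idx[idx$animal == animal, , drop = FALSE]
  if (!is.null(behaviour)) {
    sub <- sub[sub$behaviour == behaviour, , drop = FALSE]
    if (!nrow(sub)) {
      stop("no stored template for animal '", animal, "', behaviour '",
           behaviour, "'")
    }
  }
  lapply(sub$file, function(f) read_template(file.path(dir, f)))
}
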