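# CSV dialect used throughout: comma-separated, UTF-8, "." decimal,
# no thousands separators, always a header row.

#' Write / read a screen table in the package's CSV dialect
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_screen_csv` returns a data.frame; `write_screen_csv`
#'   returns `path` invisibly.
#' @export
write_screen_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read and validate a plate map
#'
#' A plate map assigns each well its role (`sample`, `vector`, `mock`,
#' `empty`) and optional gene metadata. Validation rejects missing
#' required columns, malformed well labels, duplicated wells within a
#' plate, and roles outside the vocabulary, naming the offending row.
#'
#' @param path CSV with required columns `plate_id, well, role` and
#'   optional `gene_id, insert_bp, dna_ng_ul`.
#' @param require_full demand exactly 96 wells per plate (default TRUE).
#' @return Validated data.frame (class `plate_layout`).
#' @export
read_plate_map <- function(path, require_full = TRUE) {
  x <- read_screen_csv(path)
  req <- c("plate_id", "well", "role")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("parse error: missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is_well_label(x$well))
  if (length(bad))
    stop("parse error: malformed well label '", x$well[bad[1]],
         "' at row ", bad[1])
  bad_role <- which(!x$role %in% WELL_ROLES)
  if (length(bad_role))
    stop("parse error: unknown role '", x$role[bad_role[1]],
         "' at row ", bad_role[1])
  key <- paste(x$plate_id, x$well)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("parse error: duplicate well ", x$well[dup[1]], " on plate ",
         x$plate_id[dup[1]], " at row ", dup[1])
  if (require_full) {
    counts <- table(x$plate_id)
    short <- names(counts)[counts != 96L]
    if (length(short))
      stop("parse error: plate ", short[1], " has ", counts[short[1]],
           " wells (expected 96)")
  }
  class(x) <- c("plate_layout", class(x))
  x
}

#' @rdname read_plate_map
#' @param layout data.frame to write.
#' @export
write_plate_map <- function(layout, path) {
  write_screen_csv(as.data.frame(layout), path)
}

sidecar_path <- function(path) paste0(path, ".channels.csv")

#' Write a multi-channel image stack as 16-bit TIFF with a channel sidecar
#'
#' One TIFF page per channel, 16-bit unsigned; channel order is recorded
#' in a sidecar CSV (`<path>.channels.csv` with columns `page, channel`)
#' so intensities and labels round-trip bit-exactly.
#'
#' @param channels named list of integer matrices (0..65535).
#' @param path output TIFF path.
#' @return `path` invisibly.
#' @export
write_channel_stack <- function(channels, path) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("input error: channels must be a named list")
  pages <- lapply(channels, function(m) {
    if (any(m < 0 | m > 65535)) stop("input error: intensities outside 16-bit range")
    matrix(as.numeric(m) / 65535, nrow(m), ncol(m))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_screen_csv(data.frame(page = seq_along(channels),
                              channel = names(channels)),
                   sidecar_path(path))
  invisible(path)
}

#' Read a multi-channel TIFF stack with its channel sidecar
#'
#' @param path TIFF written by [write_channel_stack()] (sidecar
#'   `<path>.channels.csv` must exist and list one channel per page).
#' @return Named list of integer matrices.
#' @export
read_channel_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("input error: missing channel sidecar ", sc)
  map <- read_screen_csv(sc)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != nrow(map))
    stop("input error: ", length(pages), " TIFF pages but ", nrow(map),
         " sidecar channels")
  pages <- lapply(pages, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  names(pages) <- map$channel[order(map$page)]
  pages
}

#' Write / read a flat key=value run configuration
#'
#' Every pipeline run writes its resolved configuration (seed, package
#' version, stage parameters) next to its outputs in a flat
#' `key = value` text format; the reader rejects unknown keys so stale
#' or misspelled configurations fail loudly.
#'
#' @param config named list of atomic scalars.
#' @param path file path.
#' @param allowed for `read_run_config`, the permitted key vocabulary
#'   (`NULL` accepts any).
#' @return `read_run_config` returns a named list of strings.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(names(config) != ""))
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", format(config[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path, allowed = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    stop("parse error: malformed config line: ",
         lines[which(lengths(kv) != 3L)[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  if (anyDuplicated(keys))
    stop("parse error: duplicate config key ", keys[duplicated(keys)][1])
  if (!is.null(allowed)) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown))
      stop("parse error: unknown config key(s): ",
           paste(unknown, collapse = ", "))
  }
  stats::setNames(as.list(vals), keys)
}
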