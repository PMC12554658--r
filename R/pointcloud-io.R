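# Colored single-plant point clouds are plain tibbles with columns
# x, y, z (double, model units; y is the vertical/growth axis after
# coordinate correction) and r, g, b (integer, 0-255).

#' Construct or validate a point-cloud tibble
#'
#' A point cloud is a tibble with coordinate columns `x`, `y`, `z` and 8-bit
#' color columns `r`, `g`, `b`. `as_point_cloud()` coerces a data frame
#' (filling missing color columns with 0) and checks the invariants: equal
#' column lengths, finite coordinates, integer colors in \[0, 255\].
#'
#' @param data A data frame with at least `x`, `y`, `z` columns.
#' @param name Optional free-text identifier stored in the `"name"` attribute.
#' @return A validated point-cloud tibble.
#' @examples
#' as_point_cloud(data.frame(x = 0:1, y = 0, z = 0))
#' @export
as_point_cloud <- function(data, name = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  missing_xyz <- setdiff(c("x", "y", "z"), names(data))
  if (length(missing_xyz) > 0) {
    abort(paste0("point cloud is missing column(s): ",
                 paste(missing_xyz, collapse = ", ")))
  }
  cloud <- tibble::as_tibble(data)
  for (ch in c("r", "g", "b")) {
    if (!ch %in% names(cloud)) cloud[[ch]] <- 0L
  }
  cloud <- cloud[, c("x", "y", "z", "r", "g", "b")]
  for (co in c("x", "y", "z")) {
    if (!is.numeric(cloud[[co]]) || anyNA(cloud[[co]]) ||
        any(!is.finite(cloud[[co]]))) {
      abort(paste0("coordinate column `", co, "` must be finite numeric."))
    }
    cloud[[co]] <- as.double(cloud[[co]])
  }
  for (ch in c("r", "g", "b")) {
    v <- cloud[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 255) ||
        any(v != round(v))) {
      abort(paste0("color column `", ch,
                   "` must contain integers in [0, 255]."))
    }
    cloud[[ch]] <- as.integer(round(v))
  }
  if (!is.null(name)) attr(cloud, "name") <- name
  cloud
}

check_cloud <- function(cloud, min_points = 0L,
                        arg = deparse(substitute(cloud))) {
  cloud <- as_point_cloud(cloud, name = attr(cloud, "name", exact = TRUE))
  if (nrow(cloud) < min_points) {
    abort(paste0("`", arg, "` must contain at least ", min_points,
                 " points (has ", nrow(cloud), ")."))
  }
  cloud
}

parse_error <- function(path, line, msg) {
  abort(paste0("parse error in '", path, "' at line ", line, ": ", msg),
        class = "planthull_parse_error")
}

#' Read a colored point cloud from ASCII PLY or XYZRGB text
#'
#' Supported formats: ASCII PLY (`element vertex` with `x`, `y`, `z`
#' properties and optional `red`, `green`, `blue` colors; binary PLY files
#' are rejected) and whitespace-delimited XYZRGB text with one `x y z [r g
#' b]` record per line and `#` comment lines ignored. Missing color columns
#' default to `(0, 0, 0)`. Float PLY color properties in \[0, 1\] are scaled
#' by 255 and rounded to the internal 8-bit convention.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by file extension, `.ply` vs anything else),
#'   `"ply"`, or `"xyzrgb"`.
#' @return A point-cloud tibble (see [as_point_cloud()]) with the file's
#'   base name in the `"name"` attribute; one row per record, in file order.
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyzrgb")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  cloud <- switch(format,
    ply = read_ply_ascii(path),
    xyzrgb = read_xyzrgb(path)
  )
  attr(cloud, "name") <- sub("\\.[^.]*$", "", basename(path))
  cloud
}

read_xyzrgb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(toks) %in% c(3L, 6L)) {
      parse_error(path, i, paste0("expected 3 or 6 fields, found ",
                                  length(toks)))
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) parse_error(path, i, "non-numeric field")
    if (length(vals) == 3L) vals <- c(vals, 0, 0, 0)
    if (any(vals[4:6] < 0 | vals[4:6] > 255)) {
      parse_error(path, i, "color channel out of [0, 255]")
    }
    recs[[j]] <- vals
  }
  m <- if (length(recs) > 0) do.call(rbind, recs) else
    matrix(numeric(), ncol = 6)
  as_point_cloud(tibble::tibble(
    x = m[, 1], y = m[, 2], z = m[, 3],
    r = round(m[, 4]), g = round(m[, 5]), b = round(m[, 6])
  ))
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    parse_error(path, 1, "not a PLY file (missing 'ply' magic)")
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) parse_error(path, length(lines), "missing 'end_header'")
  header <- trimws(lines[2:(end - 1)])
  fmt <- grep("^format\\b", header, value = TRUE)
  if (length(fmt) != 1) parse_error(path, 2, "missing format line")
  if (!grepl("^format\\s+ascii\\b", fmt)) {
    abort(paste0("'", path, "': only ASCII PLY is supported (found '",
                 fmt, "')"))
  }
  # walk elements; only 'vertex' may carry data
  n_vertex <- NA_integer_
  props <- character()
  prop_types <- character()
  current <- ""
  for (i in seq_along(header)) {
    h <- header[i]
    if (grepl("^element\\b", h)) {
      toks <- strsplit(h, "\\s+")[[1]]
      current <- toks[2]
      cnt <- suppressWarnings(as.integer(toks[3]))
      if (is.na(cnt)) parse_error(path, i + 1, "bad element count")
      if (current == "vertex") {
        n_vertex <- cnt
      } else if (cnt > 0) {
        abort(paste0("'", path, "': unsupported PLY element '", current,
                     "' with ", cnt, " entries (only vertex data supported)"))
      }
    } else if (grepl("^property\\b", h) && current == "vertex") {
      toks <- strsplit(h, "\\s+")[[1]]
      if (toks[2] == "list") {
        abort(paste0("'", path, "': list properties are not supported"))
      }
      prop_types <- c(prop_types, toks[2])
      props <- c(props, toks[3])
    }
  }
  if (is.na(n_vertex)) parse_error(path, end, "no 'element vertex' in header")
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) parse_error(path, end, "vertex element lacks x/y/z")
  col_idx <- match(c("red", "green", "blue"), props)
  body <- if (end < length(lines)) lines[(end + 1):length(lines)] else character()
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < n_vertex) {
    parse_error(path, length(lines),
                paste0("header declares ", n_vertex, " vertices but body has ",
                       length(body)))
  }
  coords <- matrix(0, nrow = n_vertex, ncol = 3)
  cols <- matrix(0, nrow = max(n_vertex, 1), ncol = 3)
  for (j in seq_len(n_vertex)) {
    lineno <- end + j
    toks <- strsplit(trimws(body[j]), "\\s+")[[1]]
    if (length(toks) < length(props)) {
      parse_error(path, lineno, paste0("expected ", length(props),
                                       " fields, found ", length(toks)))
    }
    vals <- suppressWarnings(as.numeric(toks[seq_along(props)]))
    if (anyNA(vals)) parse_error(path, lineno, "non-numeric field")
    coords[j, ] <- vals[need]
    if (!anyNA(col_idx)) {
      cv <- vals[col_idx]
      # float color convention: [0, 1] scaled to 8-bit
      if (all(prop_types[col_idx] %in% c("float", "float32", "double",
                                         "float64"))) {
        cv <- cv * 255
      }
      cv <- round(cv)
      if (any(cv < 0 | cv > 255)) {
        parse_error(path, lineno, "color channel out of range")
      }
      cols[j, ] <- cv
    }
  }
  if (n_vertex == 0) cols <- cols[0, , drop = FALSE]
  as_point_cloud(tibble::tibble(
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    r = cols[, 1], g = cols[, 2], b = cols[, 3]
  ))
}

#' Write a colored point cloud to ASCII PLY or XYZRGB text
#'
#' Round-trips with [read_point_cloud()]: coordinates within 1e-6 and colors
#' exactly.
#'
#' @param cloud A point-cloud tibble.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"ply"`, or `"xyzrgb"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "ply", "xyzrgb")) {
  cloud <- check_cloud(cloud)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyzrgb"
  }
  body <- sprintf("%.9g %.9g %.9g %d %d %d",
                  cloud$x, cloud$y, cloud$z, cloud$r, cloud$g, cloud$b)
  out <- if (format == "ply") {
    c("ply", "format ascii 1.0",
      paste("element vertex", nrow(cloud)),
      "property float x", "property float y", "property float z",
      "property uchar red", "property uchar green", "property uchar blue",
      "end_header", body)
  } else {
    body
  }
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write to '", path, "'"))
  invisible(path)
}
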