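#' Read a PLY mesh
#'
#' Supports `ascii` and `binary_little_endian` PLY files with a `vertex`
#' element carrying `x`, `y`, `z` (and optionally `nx`, `ny`, `nz`) and a
#' `face` element with a `vertex_indices`/`vertex_index` list property.
#' Vertex order is preserved exactly (the order carries the dense
#' correspondence of statistical shape models). PLY face indices are 0-based
#' and converted to 1-based.
#'
#' @param path file path.
#' @return a [trimesh()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file must contain vertex and face elements")

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    data <- list()
    for (el in elements) {
      if (el$count == 0L) { data[[el$name]] <- NULL; next }
      lines <- body[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      toks <- strsplit(trimws(lines), "\\s+")
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        data[[el$name]] <- lapply(toks, as.numeric)
      } else {
        vals <- matrix(as.numeric(unlist(toks)), nrow = el$count, byrow = TRUE)
        colnames(vals) <- vapply(el$props, `[[`, "", "name")
        data[[el$name]] <- vals
      }
    }
  } else {
    data <- list()
    for (el in elements) {
      if (any(vapply(el$props, `[[`, TRUE, "list"))) {
        rows <- vector("list", el$count)
        p <- el$props[[1]]
        for (i in seq_len(el$count)) {
          cnt <- read_scalar(con, p$count_type)
          rows[[i]] <- c(cnt, read_scalar(con, p$type, cnt))
        }
        data[[el$name]] <- rows
      } else {
        types <- vapply(el$props, `[[`, "", "type")
        vals <- matrix(NA_real_, el$count, length(types))
        for (i in seq_len(el$count))
          for (j in seq_along(types))
            vals[i, j] <- read_scalar(con, types[j])
        colnames(vals) <- vapply(el$props, `[[`, "", "name")
        data[[el$name]] <- vals
      }
    }
  }

  v <- data$vertex
  verts <- unname(v[, c("x", "y", "z"), drop = FALSE])
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% colnames(v))) {
    normals <- unname(v[, c("nx", "ny", "nz"), drop = FALSE])
    len <- sqrt(rowSums(normals^2))
    if (any(len == 0)) normals <- NULL else normals <- normals / len
  }
  faces <- t(vapply(data$face, function(r) {
    if (r[1] != 3) stop("only triangular faces are supported")
    r[2:4] + 1
  }, numeric(3)))
  trimesh(verts, faces, normals = normals)
}

read_scalar <- function(con, type, n = 1L) {
  switch(type,
    "char" = , "int8" = readBin(con, "integer", n, size = 1L, signed = TRUE),
    "uchar" = , "uint8" = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "short" = , "int16" = readBin(con, "integer", n, size = 2L, signed = TRUE,
                                  endian = "little"),
    "ushort" = , "uint16" = readBin(con, "integer", n, size = 2L,
                                    signed = FALSE, endian = "little"),
    "int" = , "int32" = , "uint" = , "uint32" =
      readBin(con, "integer", n, size = 4L, endian = "little"),
    "float" = , "float32" = readBin(con, "numeric", n, size = 4L,
                                    endian = "little"),
    "double" = , "float64" = readBin(con, "numeric", n, size = 8L,
                                     endian = "little"),
    stop("unsupported PLY scalar type: ", type))
}

#' Write a PLY mesh
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param format `"ascii"` (default; coordinates printed at full precision)
#'   or `"binary_little_endian"` (double precision coordinates).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "trimesh"))
  has_n <- !is.null(mesh$normals)
  vtype <- if (format == "ascii") "double" else "double"
  header <- c(
    "ply",
    paste("format", format, "1.0"),
    "comment written by scalpfit",
    paste("element vertex", nrow(mesh$vertices)),
    paste("property", vtype, c("x", "y", "z")),
    if (has_n) paste("property", vtype, c("nx", "ny", "nz")),
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header")
  vmat <- if (has_n) cbind(mesh$vertices, mesh$normals) else mesh$vertices
  if (format == "ascii") {
    vlines <- apply(vmat, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " "))
    flines <- apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " "))
    writeLines(c(header, vlines, flines), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.vector(t(vmat)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nrow(f0))) {
      writeBin(3L, con, size = 1L)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Reads `v` and triangular `f` records; `f` entries of the form `a/b/c`
#' keep only the vertex index. OBJ indices are 1-based already.
#'
#' @param path file path.
#' @return a [trimesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file has no vertices or no faces")
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(flines), "\\s+"), function(t) {
    if (length(t) != 4L) stop("only triangular faces are supported")
    as.integer(vapply(strsplit(t[2:4], "/"), `[[`, "", 1L))
  }, integer(3)))
  trimesh(verts, faces)
}

#' Write a Wavefront OBJ mesh
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "trimesh"))
  v <- apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
                     collapse = " ")))
  f <- apply(mesh$faces, 1, function(r) paste("f", paste(r, collapse = " ")))
  writeLines(c(v, f), path)
  invisible(path)
}

#' Read / write an ordered sample trajectory as CSV
#'
#' The CSV carries one ordered sample per row with columns
#' `x,y,z[,nx,ny,nz][,step_index]`. [write_trajectory_csv()] also writes a
#' JSON sidecar (`<path>.json`) recording the sampling strategy and seed for
#' reproducibility when those are known.
#'
#' @param path CSV path.
#' @return for the reader, a `trajectory` object (see [sample_strategy()]);
#'   metadata from a sidecar is restored when present.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("trajectory CSV needs x,y,z columns")
  points <- unname(as.matrix(df[, c("x", "y", "z")]))
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names(df)))
    normals <- unname(as.matrix(df[, c("nx", "ny", "nz")]))
  step <- if ("step_index" %in% names(df)) df$step_index else NULL
  meta <- list(strategy = NA_character_, seed = NA_integer_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_trajectory(points = points, normals = normals, step_index = step,
                 vertex_ids = NULL, geodesic_length = meta$geodesic_length,
                 strategy = meta$strategy, seed = meta$seed)
}

#' @rdname read_trajectory_csv
#' @param trajectory a `trajectory` object.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(x = trajectory$points[, 1], y = trajectory$points[, 2],
                   z = trajectory$points[, 3])
  if (!is.null(trajectory$normals)) {
    df$nx <- trajectory$normals[, 1]
    df$ny <- trajectory$normals[, 2]
    df$nz <- trajectory$normals[, 3]
  }
  if (!is.null(trajectory$step_index)) df$step_index <- trajectory$step_index
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(strategy = trajectory$strategy, seed = trajectory$seed,
         geodesic_length = trajectory$geodesic_length),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
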