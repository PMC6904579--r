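# Mesh and parameter-file input/output: binary and ASCII STL, OBJ, ASCII
# PLY (the interchange formats of the printing pipeline; binary STL is the
# default), and JSON/YAML parameter files with schema validation. Units
# are millimetres throughout; one solid per file.

abort_io <- function(msg) {
  stop(structure(class = c("chiton_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Write a mesh to STL, OBJ or PLY
#'
#' @param mesh A `scale_mesh`.
#' @param path Output file path; the format is inferred from the extension
#'   unless `format` is given.
#' @param format One of `"stl"` (binary, default), `"stla"` (ASCII STL),
#'   `"obj"`, `"ply"` (ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format == "stl") format <- "stl"
  }
  format <- match.arg(format, c("stl", "stla", "obj", "ply"))
  v <- mesh$vertices; f <- mesh$faces
  fc <- face_corners(mesh)
  e1 <- fc$b - fc$a; e2 <- fc$c - fc$a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nl <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  nrm <- cbind(nx, ny, nz) / nl
  if (format == "stl") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("chitonarmor binary STL (mm)", width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # 50 bytes per facet: 12 floats + uint16 attribute
    dat <- t(cbind(nrm, fc$a, fc$b, fc$c))
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else if (format == "stla") {
    con <- file(path, "w")
    on.exit(close(con))
    cat("solid scale\n", file = con)
    tri <- sprintf(
      "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet\n",
      nrm[, 1], nrm[, 2], nrm[, 3],
      fc$a[, 1], fc$a[, 2], fc$a[, 3],
      fc$b[, 1], fc$b[, 2], fc$b[, 3],
      fc$c[, 1], fc$c[, 2], fc$c[, 3])
    cat(tri, file = con, sep = "")
    cat("endsolid scale\n", file = con)
  } else if (format == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else {
    lines <- c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a mesh from STL (binary or ASCII), OBJ or ASCII PLY
#'
#' STL facet soup is welded back into an indexed mesh by exact coordinate
#' matching (binary STL stores float32, so a write/read round trip
#' preserves vertices to about 1e-6 mm at these coordinate magnitudes).
#'
#' @param path Input file path.
#' @return A `scale_mesh` with provenance `"external"`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    head <- readBin(path, "raw", n = 84)
    if (length(head) < 84) abort_io("malformed STL: truncated header")
    is_ascii <- identical(rawToChar(head[1:5]), "solid") && {
      txt <- suppressWarnings(readLines(path, n = 2, warn = FALSE))
      length(txt) >= 2 && grepl("facet|endsolid", txt[2])
    }
    if (is_ascii) return(read_stl_ascii(path))
    return(read_stl_binary(path))
  }
  if (ext == "obj") return(read_obj(path))
  if (ext == "ply") return(read_ply_ascii(path))
  abort_io(paste0("unsupported mesh format: .", ext))
}

weld_facets <- function(tris) {
  # tris: 3n x 3 matrix of facet corners in order
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "_")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- tris[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  scale_mesh(verts, faces, provenance = "external")
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0 || sz < 84 + 50 * ntri)
    abort_io("malformed STL: truncated or inconsistent facet count")
  raw <- readBin(con, "raw", n = 50 * ntri)
  m <- matrix(raw, nrow = 50)
  fl <- readBin(as.raw(m[1:48, ]), "numeric", n = 12L * ntri, size = 4,
                endian = "little")
  fm <- matrix(fl, nrow = 12)
  tris <- rbind(t(fm[4:6, , drop = FALSE]),
                t(fm[7:9, , drop = FALSE]),
                t(fm[10:12, , drop = FALSE]))
  # interleave corners per facet
  ord <- as.vector(rbind(seq_len(ntri), seq_len(ntri) + ntri,
                         seq_len(ntri) + 2L * ntri))
  weld_facets(tris[ord, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vl) || length(vl) %% 3 != 0)
    abort_io("malformed ASCII STL: vertex count not a multiple of 3")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  if (anyNA(nums)) abort_io("malformed ASCII STL: unparsable vertex")
  weld_facets(nums)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v ", txt, value = TRUE)
  fl <- grep("^f ", txt, value = TRUE)
  if (!length(vl) || !length(fl)) abort_io("malformed OBJ: missing v/f records")
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  if (anyNA(v) || anyNA(f)) abort_io("malformed OBJ: unparsable record")
  scale_mesh(v, f, provenance = "external")
}

read_ply_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || txt[1] != "ply") abort_io("malformed PLY: missing magic")
  hend <- match("end_header", txt)
  if (is.na(hend)) abort_io("malformed PLY: no end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", txt, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) abort_io("malformed PLY: missing element counts")
  if (length(txt) < hend + nv + nf) abort_io("malformed PLY: truncated body")
  v <- do.call(rbind, lapply(strsplit(trimws(txt[hend + seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(txt[hend + nv + seq_len(nf)]), "\\s+"),
                             function(x) as.integer(x[2:4]) + 1L))
  scale_mesh(v, f, provenance = "external")
}

# ---- parameter files ----------------------------------------------------

#' Load scale parameters from a JSON or YAML file
#'
#' The file must contain exactly the 17 named free parameters (see
#' [scale_param_names()]) plus optionally `species`; unknown keys are
#' rejected with a listing. Parse errors, schema violations and invariant
#' violations raise distinct condition classes (`chiton_parse_error`,
#' `chiton_validation_error`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `scale_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  vals <- tryCatch({
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
  }, error = function(e) abort_parse(paste0("cannot parse ", path, ": ",
                                            conditionMessage(e))))
  if (!is.list(vals) || is.null(names(vals)) || !length(vals))
    abort_parse(paste0("parameter file ", path,
                       " does not contain a key-value mapping"))
  known <- c(unlist(scale_param_names()), "species")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    abort_validation(paste0("unknown parameter keys: ",
                            paste(unknown, collapse = ", ")))
  missing <- setdiff(unlist(scale_param_names()), names(vals))
  if (length(missing))
    abort_validation(paste0("missing parameters: ",
                            paste(missing, collapse = ", ")))
  do.call(scale_params, vals)
}

#' Write scale parameters to a JSON or YAML file
#'
#' @param params A `scale_params` object.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_scale_params(params)
  vals <- params[unlist(scale_param_names())]
  if (!is.null(params$species)) vals$species <- params$species
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
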