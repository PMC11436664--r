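#' Read an STL file into a cleaned triangle mesh
#'
#' Both STL dialects are supported. With `format_hint = "auto"` the dialect
#' is sniffed: a file whose first bytes spell `solid` and whose body parses
#' as ASCII facets is treated as ASCII, anything else as little-endian
#' binary. Vertices are de-duplicated within an absolute tolerance of
#' `1e-8`, degenerate faces are removed, coordinates are multiplied by
#' `unit_scale`, and stored facet normals are discarded (normals are always
#' recomputed from the vertex winding). If more than 10% of adjacent-face
#' windings disagree, the mesh is re-oriented by propagation from the
#' largest face.
#'
#' STL files carry no unit; this package interprets coordinates as
#' centimetres by default so that the default sampling resolution of
#' 1 point/cm^2 is meaningful. Use `unit_scale` to convert (e.g. 100 for a
#' model authored in metres).
#'
#' @param path path to an STL file.
#' @param format_hint `"auto"`, `"binary-stl"` or `"ascii-stl"`.
#' @param unit_scale multiplicative factor applied to coordinates to bring
#'   them to cm.
#' @param name model identifier; defaults to the file name without
#'   extension.
#' @return a [reef_mesh()] with attribute `n_degenerate_removed`.
#' @export
read_mesh <- function(path, format_hint = c("auto", "binary-stl", "ascii-stl"),
                      unit_scale = 1, name = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  fmt <- if (format_hint == "auto") sniff_stl_dialect(path) else format_hint
  raw_tri <- if (fmt == "ascii-stl") read_stl_ascii(path) else read_stl_binary(path)
  verts <- raw_tri * unit_scale
  nf <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  cl <- clean_mesh(verts, faces, name = name)
  mesh <- cl$mesh
  if (winding_disagreement(mesh) > 0.10) mesh <- orient_mesh(mesh)
  attr(mesh, "n_degenerate_removed") <- cl$n_degenerate_removed
  mesh
}

sniff_stl_dialect <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 1024L)
  printable <- head >= as.raw(0x20) & head <= as.raw(0x7e) |
    head %in% as.raw(c(0x09, 0x0a, 0x0d))
  head[!printable] <- as.raw(0x3f)   # '?': binary junk never matches below
  txt <- rawToChar(head)
  if (grepl("^\\s*solid", txt) && grepl("facet", txt, fixed = TRUE))
    "ascii-stl" else "binary-stl"
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop(sprintf("format error in '%s': expected vertex triples, found %d vertex lines",
                 path, length(vlines)))
  nums <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vlines)), "\\s+")))
  )
  if (anyNA(nums) || length(nums) != 3L * length(vlines))
    stop(sprintf("format error in '%s': unparsable vertex coordinates", path))
  matrix(nums, ncol = 3L, byrow = TRUE)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 84) stop(sprintf("format error in '%s': truncated header at byte %d", path, sz))
  invisible(readBin(con, "raw", n = 80L))
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.double(n_tri)
  if (sz < expected)
    stop(sprintf("format error in '%s': truncated at byte %.0f (expected %.0f bytes for %d facets)",
                 path, sz, expected, n_tri))
  body <- readBin(con, "raw", n = 50L * n_tri)
  # facet layout: 12 bytes normal (ignored), 36 bytes vertices, 2 bytes attr
  off <- rep(seq(0L, by = 50L, length.out = n_tri), each = 36L)
  idx <- off + rep(13:48, times = n_tri)
  verts <- readBin(body[idx], "numeric", size = 4L, n = 9L * n_tri,
                   endian = "little")
  matrix(verts, ncol = 3L, byrow = TRUE)
}

#' Write a mesh to binary STL
#'
#' Facet normals are recomputed from the winding before writing.
#'
#' @param mesh a [reef_mesh()].
#' @param path output path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC(paste0("reefcomplexity ", mesh$name),
                              width = -80))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- face_normals(mesh)
  co <- face_corners(mesh)
  # 12 floats per facet: normal, v1, v2, v3
  block <- rbind(t(nrm), t(co$a), t(co$b), t(co$c))   # 12 x nf
  flo <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  flo <- matrix(flo, nrow = 48L)
  attr_bytes <- matrix(as.raw(0L), nrow = 2L, ncol = nf)
  writeBin(as.vector(rbind(flo, attr_bytes)), con)
  invisible(path)
}
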