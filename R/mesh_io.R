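#' Read a triangular surface mesh
#'
#' Parses VTK legacy ASCII (`.vtk`, POLYDATA or UNSTRUCTURED_GRID), PLY
#' ASCII (`.ply`), OFF (`.off`) and ASCII STL (`.stl`). Per-cell arrays named
#' `fiber`, `region` and `conductive` in a VTK file populate the mesh
#' attributes; a missing fiber array yields an isotropic mesh and a missing
#' conductive array marks everything conductive. Non-triangle cells are
#' rejected with the offending cell index.
#'
#' @param path file path.
#' @param format one of `"vtk"`, `"ply"`, `"off"`, `"stl"`; inferred from the
#'   extension when `NULL`.
#' @return a validated [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         vtk = read_vtk(path),
         ply = read_ply(path),
         off = read_off(path),
         stl = read_stl(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangular surface mesh
#'
#' Writes VTK legacy ASCII (with point- and cell-data arrays), PLY ASCII,
#' OFF, or ASCII STL. Only the VTK dialect carries attribute arrays; the
#' mesh's own `fiber`, `region` (as integer codes, labels recorded on the
#' VTK comment line) and `conductive` arrays are always included there.
#'
#' @param mesh a `tri_mesh`.
#' @param path output file path.
#' @param point_data named list of per-node numeric vectors or 3-column
#'   matrices.
#' @param cell_data named list of per-triangle numeric vectors or 3-column
#'   matrices.
#' @param format as in [read_mesh()].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, point_data = list(), cell_data = list(),
                       format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  for (nm in names(point_data)) {
    len <- NROW(point_data[[nm]])
    if (len != n) stop("point_data field '", nm, "' has length ", len,
                       ", expected ", n)
  }
  for (nm in names(cell_data)) {
    len <- NROW(cell_data[[nm]])
    if (len != m) stop("cell_data field '", nm, "' has length ", len,
                       ", expected ", m)
  }
  switch(format,
         vtk = write_vtk(mesh, path, point_data, cell_data),
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stl = write_stl(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_vtk <- function(mesh, path, point_data, cell_data) {
  con <- file(path, "w")
  on.exit(close(con))
  regs <- sort(unique(mesh$region))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("aflutmap surface regions=", paste(regs, collapse = ",")),
               "ASCII", "DATASET POLYDATA"), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  cd <- cell_data
  cd$region <- match(mesh$region, regs)
  cd$conductive <- as.integer(mesh$conductive)
  if (!is.null(mesh$fiber)) cd$fiber <- mesh$fiber
  write_vtk_data(con, "CELL_DATA", m, cd)
  if (length(point_data)) write_vtk_data(con, "POINT_DATA", n, point_data)
}

write_vtk_data <- function(con, what, count, fields) {
  if (!length(fields)) return(invisible())
  writeLines(sprintf("%s %d", what, count), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (is.matrix(v) && ncol(v) == 3L) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(v, 1L, function(r) paste(fmt_num(r), collapse = " ")),
                 con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(as.numeric(v)), con)
    }
  }
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  regs <- NULL
  if (length(lines) >= 2 && grepl("regions=", lines[2], fixed = TRUE)) {
    regs <- strsplit(sub(".*regions=", "", lines[2]), ",", fixed = TRUE)[[1]]
  }
  toks <- scan(text = paste(lines[-(1:2)], collapse = "\n"), what = "",
               quiet = TRUE)
  i <- 1L
  nodes <- NULL; tris <- NULL
  pdata <- list(); cdata <- list()
  n_pts <- 0L; n_cells <- 0L
  section <- ""
  while (i <= length(toks)) {
    tk <- toupper(toks[i])
    if (tk == "POINTS") {
      n_pts <- as.integer(toks[i + 1L])
      vals <- as.numeric(toks[(i + 3L):(i + 2L + 3L * n_pts)])
      nodes <- matrix(vals, ncol = 3L, byrow = TRUE)
      i <- i + 3L + 3L * n_pts
    } else if (tk %in% c("POLYGONS", "CELLS")) {
      nc <- as.integer(toks[i + 1L])
      sz <- as.integer(toks[i + 2L])
      vals <- as.integer(toks[(i + 3L):(i + 2L + sz)])
      tris <- parse_vtk_cells(vals, nc)
      n_cells <- nc
      i <- i + 3L + sz
    } else if (tk == "CELL_TYPES") {
      nc <- as.integer(toks[i + 1L])
      ct <- as.integer(toks[(i + 2L):(i + 1L + nc)])
      bad <- which(!ct %in% c(5L))
      if (length(bad)) stop("non-triangle cell type at cell ", bad[1L])
      i <- i + 2L + nc
    } else if (tk == "POINT_DATA") {
      section <- "point"; i <- i + 2L
    } else if (tk == "CELL_DATA") {
      section <- "cell"; i <- i + 2L
    } else if (tk == "SCALARS") {
      nm <- toks[i + 1L]
      count <- if (section == "point") n_pts else n_cells
      j <- i + 4L  # SCALARS name type ncomp / LOOKUP_TABLE default
      if (toupper(toks[j]) == "LOOKUP_TABLE") j <- j + 2L
      vals <- as.numeric(toks[j:(j + count - 1L)])
      if (section == "point") pdata[[nm]] <- vals else cdata[[nm]] <- vals
      i <- j + count
    } else if (tk == "VECTORS") {
      nm <- toks[i + 1L]
      count <- if (section == "point") n_pts else n_cells
      vals <- as.numeric(toks[(i + 3L):(i + 2L + 3L * count)])
      vmat <- matrix(vals, ncol = 3L, byrow = TRUE)
      if (section == "point") pdata[[nm]] <- vmat else cdata[[nm]] <- vmat
      i <- i + 3L + 3L * count
    } else {
      i <- i + 1L
    }
  }
  if (is.null(nodes) || is.null(tris)) stop("not a parsable VTK surface mesh")
  region <- if (!is.null(cdata$region)) {
    codes <- as.integer(round(cdata$region))
    if (!is.null(regs) && max(codes) <= length(regs)) regs[codes]
    else as.character(codes)
  } else "default"
  conductive <- if (!is.null(cdata$conductive)) cdata$conductive > 0.5 else TRUE
  fiber <- cdata$fiber
  if (!is.null(fiber)) {
    fiber <- fiber / sqrt(rowSums(fiber^2))
  }
  mesh <- tri_mesh(nodes, tris, fiber = fiber, region = region,
                   conductive = conductive)
  attr(mesh, "point_data") <- pdata
  attr(mesh, "cell_data") <- cdata
  mesh
}

parse_vtk_cells <- function(vals, nc) {
  tris <- matrix(0L, nc, 3L)
  p <- 1L
  for (ci in seq_len(nc)) {
    k <- vals[p]
    if (k != 3L) stop("non-triangle cell (", k, " vertices) at cell index ",
                      ci)
    tris[ci, ] <- vals[(p + 1L):(p + 3L)] + 1L
    p <- p + 1L + k
  }
  tris
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$nodes)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endh)) stop("not an ASCII PLY file")
  hdr <- lines[seq_len(endh)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex +", "", grep("element vertex", hdr,
                                                      value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face +", "", grep("element face", hdr,
                                                    value = TRUE)[1L]))
  body <- lines[(endh + 1L):length(lines)]
  vl <- body[seq_len(nv)]
  nodes <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[1:3])
  }))
  fl <- body[nv + seq_len(nf)]
  tris <- matrix(0L, nf, 3L)
  for (ci in seq_len(nf)) {
    x <- as.integer(strsplit(trimws(fl[ci]), "\\s+")[[1]])
    if (x[1] != 3L) stop("non-triangle face (", x[1], " vertices) at face ",
                         ci)
    tris[ci, ] <- x[2:4] + 1L
  }
  tri_mesh(nodes, tris)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", paste(nrow(mesh$nodes), nrow(mesh$triangles), 0L)), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
}

read_off <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  if (toupper(toks[1]) != "OFF") stop("not an OFF file")
  nv <- as.integer(toks[2]); nf <- as.integer(toks[3])
  p <- 5L
  nodes <- matrix(as.numeric(toks[p:(p + 3L * nv - 1L)]), ncol = 3L,
                  byrow = TRUE)
  p <- p + 3L * nv
  tris <- matrix(0L, nf, 3L)
  for (ci in seq_len(nf)) {
    k <- as.integer(toks[p])
    if (k != 3L) stop("non-triangle face (", k, " vertices) at face ", ci)
    tris[ci, ] <- as.integer(toks[(p + 1L):(p + 3L)]) + 1L
    p <- p + 1L + k
  }
  tri_mesh(nodes, tris)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- triangle_normals(mesh)
  writeLines("solid aflutmap", con)
  for (ci in seq_len(nrow(mesh$triangles))) {
    writeLines(sprintf("facet normal %s", paste(fmt_num(nv[ci, ]),
                                                collapse = " ")), con)
    writeLines("  outer loop", con)
    for (v in mesh$triangles[ci, ]) {
      writeLines(sprintf("    vertex %s",
                         paste(fmt_num(mesh$nodes[v, ]), collapse = " ")), con)
    }
    writeLines(c("  endloop", "endfacet"), con)
  }
  writeLines("endsolid aflutmap", con)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("not an ASCII STL file")
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  if (nrow(coords) %% 3L != 0L) stop("malformed STL facet list")
  key <- apply(coords, 1L, function(r) paste(sprintf("%.9f", r),
                                             collapse = "_"))
  uk <- !duplicated(key)
  nodes <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(nodes, tris)
}
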