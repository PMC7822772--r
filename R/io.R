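# Plain-text mesh I/O: Gmsh MSH v2 ASCII and legacy VTK unstructured
# grids. Node-set membership travels as integer node tags (MSH physical
# point entities / VTK point-data arrays): 1 = fixed, 2 = load.

node_tags <- function(mesh) {
  tg <- integer(nrow(mesh$nodes))
  tg[mesh$fixed_nodes] <- 1L
  tg[mesh$load_nodes] <- 2L
  tg
}

mesh_from_tags <- function(nodes, tets, tags, tissue, density = 1000) {
  tet_mesh(nodes, tets, fixed_nodes = which(tags == 1L),
           load_nodes = which(tags == 2L), tissue = tissue, density = density)
}

#' Write / read a mesh as Gmsh MSH (v2.2 ASCII)
#'
#' Tetrahedra are written as element type 4 with two integer tags:
#' (tissue id, 0). Node-set membership is written as point elements
#' (type 15) with the physical tag 1 (fixed) or 2 (load).
#'
#' @param mesh a [tet_mesh()].
#' @param path file path.
#' @return `write_mesh_msh` returns `path` invisibly; `read_mesh_msh` a
#'   [tet_mesh()].
#' @export
write_mesh_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  tiss <- factor(mesh$tissue)
  tags <- node_tags(mesh)
  tagged <- which(tags > 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines(c("$PhysicalNames", as.character(nlevels(tiss))), con)
  writeLines(sprintf("3 %d \"%s\"", seq_len(nlevels(tiss)), levels(tiss)), con)
  writeLines("$EndPhysicalNames", con)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(m + length(tagged))), con)
  if (length(tagged))
    writeLines(sprintf("%d 15 2 %d 0 %d", seq_along(tagged), tags[tagged],
                       tagged), con)
  writeLines(sprintf("%d 4 2 %d 0 %d %d %d %d",
                     length(tagged) + seq_len(m), as.integer(tiss),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_mesh_msh
#' @param density mass density assigned on read (kg/m^3).
#' @export
read_mesh_msh <- function(path, density = 1000) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), ln); i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1)) stop("MSH file lacks a $", name, " section")
    ln[(i0 + 1L):(i1 - 1L)]
  }
  nm <- sec("PhysicalNames")
  phys <- if (length(nm) > 1) {
    f <- do.call(rbind, strsplit(nm[-1], " ", fixed = TRUE))
    setNames(gsub('"', "", apply(f[, -(1:2), drop = FALSE], 1, paste,
                                 collapse = " ")), f[, 2])
  } else character(0)
  nd <- sec("Nodes")
  nodes <- do.call(rbind, lapply(strsplit(nd[-1], " +"), function(v)
    as.numeric(v[2:4])))
  el <- sec("Elements")
  rows <- strsplit(el[-1], " +")
  tags <- integer(nrow(nodes)); tets <- list(); tiss <- character(0); k <- 0L
  for (v in rows) {
    v <- as.integer(v)
    type <- v[2]; ntag <- v[3]
    body <- v[(4 + ntag):length(v)]
    if (type == 15L) tags[body[1]] <- v[4]
    if (type == 4L) {
      k <- k + 1L; tets[[k]] <- body
      tiss[k] <- if (length(phys)) phys[[as.character(v[4])]] else "single"
    }
  }
  if (!k) stop("MSH file contains no tetrahedra")
  mesh_from_tags(nodes, do.call(rbind, tets), tags, tiss, density)
}

#' Write / read a mesh as legacy VTK unstructured grid (ASCII)
#'
#' Cell data `tissue` (integer codes with a comment-free lookup written
#' as field data is avoided; codes follow factor order of the labels) and
#' point data `node_tag` (0 free / 1 fixed / 2 load) are attached.
#' Displacement fields can be written as additional point data via `u`.
#'
#' @param mesh a [tet_mesh()].
#' @param path file path.
#' @param u optional displacement vector (3n) written as a point-data
#'   vector field `displacement`.
#' @return `write_mesh_vtk` returns `path` invisibly; `read_mesh_vtk` a
#'   list `mesh` plus `u` (NULL if absent).
#' @export
write_mesh_vtk <- function(mesh, path, u = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  tiss <- factor(mesh$tissue)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("tissue:", paste(levels(tiss), collapse = ",")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS tissue int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(tiss)), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS node_tag int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(node_tags(mesh)), con)
  if (!is.null(u)) {
    stopifnot(length(u) == 3L * n)
    um <- matrix(u, ncol = 3, byrow = TRUE)
    writeLines("VECTORS displacement double", con)
    writeLines(sprintf("%.17g %.17g %.17g", um[, 1], um[, 2], um[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @param density mass density assigned on read (kg/m^3).
#' @export
read_mesh_vtk <- function(path, density = 1000) {
  ln <- readLines(path)
  labels <- if (grepl("^tissue:", ln[2]))
    strsplit(sub("^tissue: *", "", ln[2]), ",")[[1]] else NULL
  ip <- grep("^POINTS", ln)[1]
  n <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  nodes <- do.call(rbind, lapply(strsplit(ln[ip + seq_len(n)], " +"),
                                 as.numeric))
  ic <- grep("^CELLS", ln)[1]
  m <- as.integer(strsplit(ln[ic], " +")[[1]][2])
  cells <- do.call(rbind, lapply(strsplit(ln[ic + seq_len(m)], " +"),
                                 as.integer))
  stopifnot(all(cells[, 1] == 4L))
  tets <- cells[, 2:5, drop = FALSE] + 1L
  grab_scalar <- function(name, count) {
    i <- grep(paste0("^SCALARS ", name), ln)
    if (!length(i)) return(NULL)
    as.integer(ln[i[1] + 1L + seq_len(count)])
  }
  tcode <- grab_scalar("tissue", m)
  tissue <- if (is.null(tcode)) rep("single", m) else {
    if (is.null(labels)) as.character(tcode) else labels[tcode]
  }
  tags <- grab_scalar("node_tag", n)
  if (is.null(tags)) tags <- integer(n)
  u <- NULL
  iv <- grep("^VECTORS displacement", ln)
  if (length(iv)) {
    um <- do.call(rbind, lapply(strsplit(ln[iv[1] + seq_len(n)], " +"),
                                as.numeric))
    u <- as.vector(t(um))
  }
  list(mesh = mesh_from_tags(nodes, tets, tags, tissue, density), u = u)
}
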