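#' Triangulated synaptic apposition surface (SAS) mesh
#'
#' A minimal triangle-mesh container for open surfaces: vertex coordinates in
#' nm and 1-based vertex index triplets. The mesh may have several connected
#' components (fragmented junctions) and interior holes (perforated
#' junctions); it must be an orientable surface with boundary, i.e. every
#' edge belongs to at most two triangles and no triangle is degenerate.
#'
#' @param vertices numeric matrix (n x 3) of coordinates in nm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices.
#' @return an object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3 || !is.numeric(vertices))
    stop("'vertices' must be an n x 3 numeric matrix", call. = FALSE)
  if (nrow(triangles) < 1)
    stop("mesh has no triangles", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  m <- structure(list(vertices = vertices, triangles = triangles),
                 class = "tri_mesh")
  a <- triangle_areas(m)
  if (any(a <= 0))
    stop("mesh contains degenerate (zero-area) triangles", call. = FALSE)
  cnt <- edge_use_counts(m)
  if (any(cnt > 2L))
    stop("non-manifold mesh: an edge is shared by more than two triangles",
         call. = FALSE)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles, %d component(s), %d hole(s)\n",
              nrow(x$vertices), nrow(x$triangles),
              mesh_n_components(x), mesh_n_holes(x)))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# undirected edge keys and their use counts across triangles
edge_table <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  data.frame(lo = lo, hi = hi, key = paste(lo, hi))
}

edge_use_counts <- function(mesh) {
  et <- edge_table(mesh)
  table(et$key)
}

# boundary edges: used by exactly one triangle
mesh_boundary_edges <- function(mesh) {
  et <- edge_table(mesh)
  cnt <- table(et$key)
  keys <- names(cnt)[cnt == 1L]
  et <- et[!duplicated(et$key), ]
  as.matrix(et[match(keys, et$key), c("lo", "hi")])
}

# connected-component label per vertex (via triangle connectivity, union-find)
mesh_vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tr <- mesh$triangles
  for (r in seq_len(nrow(tr))) {
    a <- find(tr[r, 1]); b <- find(tr[r, 2]); c <- find(tr[r, 3])
    parent[b] <- a; parent[find(c)] <- find(a)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Number of connected components of a mesh
#' @param mesh a \code{tri_mesh}.
#' @return integer count of components that contain at least one triangle.
#' @export
mesh_n_components <- function(mesh) {
  comp <- mesh_vertex_components(mesh)
  used <- unique(as.vector(mesh$triangles))
  length(unique(comp[used]))
}

#' Boundary loops of a mesh
#'
#' Chains the boundary edges (edges used by exactly one triangle) into closed
#' vertex loops. For a synaptic apposition surface every component has at
#' least one loop (the outer outline); additional loops are interior holes.
#'
#' @param mesh a \code{tri_mesh}.
#' @return list of integer vectors of vertex indices, one per loop.
#' @export
mesh_boundary_loops <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited_key <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (r in seq_len(nrow(be))) {
    k0 <- ekey(be[r, 1], be[r, 2])
    if (!is.null(visited_key[[k0]])) next
    start <- be[r, 1]
    loop <- c(start, be[r, 2])
    visited_key[[k0]] <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (nb in nbrs) {
        k <- ekey(cur, nb)
        if (is.null(visited_key[[k]])) { nxt <- nb; visited_key[[k]] <- TRUE; break }
      }
      if (is.na(nxt)) break
      if (nxt == start) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Number of interior holes of a mesh
#'
#' Counted as boundary loops in excess of one per connected component (each
#' component's largest-perimeter loop is taken to be its outer outline).
#'
#' @param mesh a \code{tri_mesh}.
#' @return integer >= 0.
#' @export
mesh_n_holes <- function(mesh) {
  loops <- mesh_boundary_loops(mesh)
  if (!length(loops)) return(0L)
  comp <- mesh_vertex_components(mesh)
  loop_comp <- vapply(loops, function(l) comp[l[1]], integer(1))
  sum(vapply(split(loops, loop_comp), length, integer(1)) - 1L)
}

#' Read or write a mesh in ASCII PLY format
#'
#' Minimal PLY support sufficient for exchanging SAS meshes: ASCII format,
#' vertex properties x/y/z first, triangular faces. Binary PLY is rejected.
#'
#' @param path file path.
#' @return \code{read_ply} returns a \code{tri_mesh}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ply")) stop("not a PLY file", call. = FALSE)
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported", call. = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(s) as.numeric(s[1:3])))
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(s) {
    s <- as.integer(s)
    if (s[1] != 3L) stop("only triangular faces are supported", call. = FALSE)
    s[2:4] + 1L
  }))
  tri_mesh(verts, faces)
}

#' @rdname read_ply
#' @param mesh a \code{tri_mesh} to write.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}

#' Read or write a mesh in OFF format
#' @param path file path.
#' @return \code{read_off} returns a \code{tri_mesh}.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                                 function(s) as.numeric(s[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"),
                                 function(s) {
    s <- as.integer(s)
    if (s[1] != 3L) stop("only triangular faces are supported", call. = FALSE)
    s[2:4] + 1L
  }))
  tri_mesh(verts, faces)
}

#' @rdname read_off
#' @param mesh a \code{tri_mesh} to write.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}
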