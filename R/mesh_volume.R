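# Triangle-mesh enclosed-volume kernel: the measurement endpoint of the
# 3-D scanning route to object volume. Only the mesh -> volume step lives
# here; surface reconstruction from depth sensors is out of scope.

#' Construct a triangle mesh
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates (cm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices, counter-
#'   clockwise when viewed from outside for outward orientation.
#' @return A list of class `triangle_mesh` with elements `vertices`, `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3", call. = FALSE)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinate", call. = FALSE)
  if (nrow(faces) == 0) stop("mesh has no faces", call. = FALSE)
  if (any(faces < 1) || any(faces > nrow(vertices))) {
    stop("face index out of range", call. = FALSE)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3])) {
    stop("degenerate face (repeated vertex index)", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

# m x 3 matrices of directed edge endpoints, one row per half-edge
.half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(from = c(f[, 1], f[, 2], f[, 3]),
        to   = c(f[, 2], f[, 3], f[, 1]))
}

#' Test whether a mesh is watertight and consistently oriented
#'
#' Watertight here means every undirected edge is shared by exactly two
#' faces that traverse it in opposite directions. Multiple disjoint closed
#' components are allowed.
#'
#' @param mesh A `triangle_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  he <- .half_edges(mesh)
  key_dir <- paste(he[, 1], he[, 2])
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und_counts <- table(key_und)
  if (any(und_counts != 2)) return(FALSE)
  # exactly two per undirected edge; orientation consistent iff the two
  # directed copies differ, i.e. no directed edge repeats
  !anyDuplicated(key_dir)
}

# first edge violating the two-faces rule, for error messages
.bad_edge <- function(mesh) {
  he <- .half_edges(mesh)
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key_und)
  bad <- names(cnt)[cnt != 2]
  if (length(bad)) bad[1] else {
    key_dir <- paste(he[, 1], he[, 2])
    key_und[duplicated(key_dir)][1]
  }
}

#' Enclosed volume of a watertight triangle mesh
#'
#' Sums signed tetrahedron volumes `det(v0, v1, v2) / 6` over faces
#' (divergence theorem); the result is translation-invariant and positive
#' for outward orientation. A globally inward-oriented mesh yields the
#' absolute value with a warning. Non-watertight meshes are refused, never
#' silently hole-filled.
#'
#' @param mesh A `triangle_mesh` in cm.
#' @return Enclosed volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is_watertight(mesh)) {
    stop(sprintf("mesh is not watertight/consistently oriented (edge %s)",
                 .bad_edge(mesh)), call. = FALSE)
  }
  v <- signed_mesh_volume(mesh)
  if (v < 0) {
    warning("mesh is inward-oriented; reporting |volume|", call. = FALSE)
    v <- -v
  }
  v
}

#' Signed volume (no watertightness check, no sign fix)
#'
#' Exposed for testing orientation behaviour; prefer [mesh_volume()].
#'
#' @param mesh A `triangle_mesh`.
#' @return Signed enclosed volume in cm^3.
#' @export
signed_mesh_volume <- function(mesh) {
  V <- mesh$vertices
  f <- mesh$faces
  a <- V[f[, 1], , drop = FALSE]
  b <- V[f[, 2], , drop = FALSE]
  c <- V[f[, 3], , drop = FALSE]
  # a . (b x c) per face
  triple <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
            a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
            a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(triple) / 6
}

#' Load a triangle mesh from OFF, ASCII PLY or OBJ
#'
#' Faces with more than three vertices are fan-triangulated. If face
#' orientations are inconsistent but repairable (a flood fill over shared
#' edges can make all adjacent faces traverse shared edges oppositely),
#' orientation is normalized with a message.
#'
#' @param path Mesh file; format from extension (`.off`, `.ply`, `.obj`).
#' @return A `triangle_mesh`.
#' @export
load_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    off = .read_off(path),
    ply = .read_ply(path),
    obj = .read_obj(path),
    stop(sprintf("unsupported mesh format '.%s'", ext), call. = FALSE))
  normalize_orientation(mesh)
}

.tokenize <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

.fan_triangulate <- function(poly_list) {
  do.call(rbind, lapply(poly_list, function(p) {
    if (length(p) < 3) stop("face with fewer than 3 vertices", call. = FALSE)
    cbind(p[1], p[2:(length(p) - 1)], p[3:length(p)])
  }))
}

.read_off <- function(path) {
  lines <- .tokenize(readLines(path, warn = FALSE))
  if (!grepl("^OFF", lines[1])) stop("not an OFF file", call. = FALSE)
  header <- as.numeric(strsplit(lines[2], "\\s+")[[1]])
  nv <- header[1]; nf <- header[2]
  verts <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])))
  polys <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- as.numeric(strsplit(l, "\\s+")[[1]])
    x[2:(1 + x[1])] + 1L
  })
  triangle_mesh(verts, .fan_triangulate(polys))
}

.read_ply <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (raw[1] != "ply") stop("not a PLY file", call. = FALSE)
  if (!any(grepl("format ascii", raw))) stop("only ascii PLY supported", call. = FALSE)
  end <- which(raw == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", raw, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", raw, value = TRUE)[1]))
  body <- .tokenize(raw[(end + 1):length(raw)])
  verts <- do.call(rbind, lapply(body[1:nv], function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])))
  polys <- lapply(body[(nv + 1):(nv + nf)], function(l) {
    x <- as.numeric(strsplit(l, "\\s+")[[1]])
    x[2:(1 + x[1])] + 1L
  })
  triangle_mesh(verts, .fan_triangulate(polys))
}

.read_obj <- function(path) {
  lines <- .tokenize(readLines(path, warn = FALSE))
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(vlines, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  polys <- lapply(flines, function(l) {
    toks <- strsplit(l, "\\s+")[[1]][-1]
    as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
  })
  triangle_mesh(verts, .fan_triangulate(polys))
}

#' Normalize face orientation by flood fill over shared edges
#'
#' Within each edge-connected component, faces are flipped so adjacent faces
#' traverse their shared edge in opposite directions; each component is then
#' globally flipped outward (positive signed volume) if needed. Meshes whose
#' orientation cannot be made consistent (e.g. non-manifold edges) are
#' returned unchanged.
#'
#' @param mesh A `triangle_mesh`.
#' @return A `triangle_mesh` with normalized orientation where repairable.
#' @export
normalize_orientation <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  he <- .half_edges(mesh)          # 3m half-edges, face id = (row - 1) %% m + 1
  face_of <- rep(seq_len(m), 3)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  groups <- split(seq_len(3 * m), key)
  if (any(lengths(groups) != 2)) return(mesh)  # open or non-manifold: leave as-is
  # adjacency with "same direction" flag per shared edge
  i1 <- vapply(groups, `[`, 0L, 1); i2 <- vapply(groups, `[`, 0L, 2)
  fa <- face_of[i1]; fb <- face_of[i2]
  same_dir <- he[i1, 1] == he[i2, 1]           # same traversal => one must flip
  adj <- split(data.frame(nb = c(fb, fa), same = c(same_dir, same_dir)),
               c(fa, fb))
  flip <- rep(NA, m)
  for (root in seq_len(m)) {
    if (!is.na(flip[root])) next
    flip[root] <- FALSE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      a <- adj[[as.character(cur)]]
      if (is.null(a)) next
      want <- ifelse(a$same, !flip[cur], flip[cur])
      unseen <- is.na(flip[a$nb])
      conflict <- !unseen & flip[a$nb] != want
      if (any(conflict)) return(mesh)          # Moebius-like: unrepairable
      flip[a$nb[unseen]] <- want[unseen]
      queue <- c(queue, a$nb[unseen])
    }
  }
  if (any(flip)) {
    f[flip, c(2, 3)] <- f[flip, c(3, 2)]
    message(sprintf("normalized orientation of %d face(s)", sum(flip)))
  }
  out <- triangle_mesh(mesh$vertices, f)
  # flip whole components that ended up inward
  comp <- .edge_components(out)
  for (k in unique(comp)) {
    sub <- triangle_mesh(out$vertices, out$faces[comp == k, , drop = FALSE])
    if (signed_mesh_volume(sub) < 0) {
      idx <- comp == k
      out$faces[idx, c(2, 3)] <- out$faces[idx, c(3, 2)]
    }
  }
  out
}

# face-connected component labels via shared undirected edges
.edge_components <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  he <- .half_edges(mesh)
  face_of <- rep(seq_len(m), 3)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  groups <- split(face_of, key)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in groups) {
    if (length(g) >= 2) {
      r <- find(g[1])
      for (o in g[-1]) parent[find(o)] <- r
    }
  }
  vapply(seq_len(m), find, 0L)
}

#' Axis-aligned box mesh
#'
#' @param edges Length-3 edge lengths (cm); a scalar gives a cube.
#' @param origin Minimum-corner coordinates.
#' @return A watertight, outward-oriented `triangle_mesh` (12 faces).
#' @export
mesh_box <- function(edges = 1, origin = c(0, 0, 0)) {
  e <- rep_len(edges, 3)
  v <- as.matrix(expand.grid(x = c(0, e[1]), y = c(0, e[2]), z = c(0, e[3])))
  v <- sweep(v, 2, origin, `+`)
  # outward CCW triangles of the unit-cube corner ordering above
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (down)
    c(5, 6, 7), c(6, 8, 7),   # z = e3 (up)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = e2
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = e1
  )
  triangle_mesh(v, f)
}

#' Icosphere mesh by repeated subdivision of an icosahedron
#'
#' Vertices lie exactly on the sphere, so enclosed volume is that of an
#' inscribed polyhedron: it converges to `4/3 pi r^3` from below as `depth`
#' grows.
#'
#' @param radius Sphere radius (cm).
#' @param depth Subdivision depth (0 = icosahedron, 20 faces; each level
#'   quadruples the face count).
#' @return A watertight `triangle_mesh`.
#' @export
mesh_icosphere <- function(radius = 1, depth = 2) {
  stopifnot(radius > 0, depth >= 0, depth <= 6)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (iter in seq_len(depth)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                          cbind(f[, 3], f[, 1])))
    keys <- edge_key(edges[, 1], edges[, 2])
    keep <- !duplicated(keys)
    edges <- edges[keep, , drop = FALSE]; keys <- keys[keep]
    mid <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_id <- stats::setNames(nv + seq_len(nrow(mid)), keys)
    v <- rbind(v, mid)
    a <- f[, 1]; b <- f[, 2]; c_ <- f[, 3]
    ab <- mid_id[edge_key(a, b)]; bc <- mid_id[edge_key(b, c_)]
    ca <- mid_id[edge_key(c_, a)]
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab), cbind(c_, ca, bc),
               cbind(ab, bc, ca))
  }
  triangle_mesh(v * radius, f)
}

#' Write a mesh as OFF (for fixtures and round trips)
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  invisible(path)
}
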