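# Void geometry: clearance-annotated Voronoi void graph of a structure.
# One vertex per Delaunay tetrahedron (at its circumcenter = Voronoi vertex),
# edges between face-adjacent tetrahedra, everything annotated with clearance
# (distance to the nearest atom's van der Waals surface).

#' Brute-force clearance of points against a structure
#'
#' Distance from each query point to the nearest atom surface,
#' `min_i(||p - x_i|| - r_i)`; negative inside an atom. This is the
#' definitional oracle for every clearance value stored in a void graph
#' (which uses a grid-accelerated equivalent).
#'
#' @param p Numeric 3-vector or n x 3 matrix of query points (A).
#' @param s A `chan_structure` with radii assigned.
#' @return Numeric vector of clearances (A).
#' @export
point_clearance <- function(p, s) {
  stopifnot(inherits(s, "chan_structure"))
  if (nrow(s$atoms) == 0) chan_error("chanatomy_value_error", "empty structure")
  if (any(is.na(s$atoms$radius)))
    chan_error("chanatomy_value_error", "radii not assigned; call assign_radii()")
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  ax <- s$atoms$x; ay <- s$atoms$y; az <- s$atoms$z; r <- s$atoms$radius
  vapply(seq_len(nrow(p)), function(i) {
    min(sqrt((ax - p[i, 1])^2 + (ay - p[i, 2])^2 + (az - p[i, 3])^2) - r)
  }, numeric(1))
}

atom_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Build the clearance-annotated void graph of a structure
#'
#' Computes the Delaunay tetrahedralization of the atomic centers, places one
#' void vertex at each tetrahedron circumcenter, connects face-adjacent
#' tetrahedra, annotates vertices and edges with clearance, and prunes edges
#' whose clearance falls below `params$interior_threshold` (they are kept in
#' the edge table with `kept = FALSE` for diagnostics). Edge clearance is the
#' minimum of the clearance sampled every 0.5 A along the connecting segment
#' (endpoints included); the Dijkstra edge weight is
#' `length / (clearance^2 + 0.01)`, so traversal prefers short and wide
#' corridors.
#'
#' @param s Sanitized `chan_structure` with radii assigned.
#' @param params A [channel_params()] object.
#' @return A `void_graph`: list with `vertices` (index, x, y, z, clearance,
#'   hull, status, depth), `edges` (from, to, length, clearance, weight,
#'   kept), `structure_id` and `params`. Status and depth are filled by
#'   [mark_exterior()].
#' @export
build_void_graph <- function(s, params = channel_params()) {
  stopifnot(inherits(s, "chan_structure"))
  if (any(is.na(s$atoms$radius)))
    chan_error("chanatomy_value_error", "radii not assigned; call assign_radii()")
  xyz <- atom_xyz(s)
  tet <- delaunay_tets(xyz)
  cc <- tet_circumcenters(xyz, tet$simplices)
  clr <- cpp_point_clearance(cc, xyz, s$atoms$radius)
  nv <- nrow(cc)
  hull <- rowSums(is.na(tet$neighbors)) > 0L
  # undirected face edges, each once
  from <- rep.int(seq_len(nv), 4L)
  to <- as.vector(tet$neighbors)
  ok <- !is.na(to) & from < to
  from <- from[ok]; to <- to[ok]
  elen <- sqrt(rowSums((cc[from, , drop = FALSE] - cc[to, , drop = FALSE])^2))
  # endpoint clearance bounds the segment minimum from above; edges already
  # below the interior threshold at an endpoint need no sampling (they are
  # pruned either way), which skips the bulk of a dense packing's edges
  minend <- pmin(clr[from], clr[to])
  eclr <- minend
  si <- which(minend >= params$interior_threshold)
  if (length(si)) {
    samp <- cpp_segment_clearance(cc[from[si], , drop = FALSE],
                                  cc[to[si], , drop = FALSE],
                                  0.5, xyz, s$atoms$radius)
    eclr[si] <- pmin(samp, minend[si])
  }
  weight <- pmax(elen, 1e-9) / (eclr^2 + 0.01)
  vertices <- data.frame(index = seq_len(nv), x = cc[, 1], y = cc[, 2],
                         z = cc[, 3], clearance = clr, hull = hull,
                         status = NA_character_, depth = NA_real_)
  edges <- data.frame(from = from, to = to, length = elen, clearance = eclr,
                      weight = weight, kept = eclr >= params$interior_threshold)
  structure(list(vertices = vertices, edges = edges, structure_id = s$id,
                 params = params),
            class = "void_graph")
}

#' @export
print.void_graph <- function(x, ...) {
  cat(sprintf("<void_graph> %s: %d vertices, %d/%d traversable edges",
              x$structure_id, nrow(x$vertices), sum(x$edges$kept), nrow(x$edges)))
  if (!all(is.na(x$vertices$status)))
    cat(sprintf("; %d exterior, %d boundary, %d interior",
                sum(x$vertices$status == "exterior"),
                sum(x$vertices$status == "boundary"),
                sum(x$vertices$status == "interior")))
  cat("\n")
  invisible(x)
}

# full face-adjacency igraph (used by the exterior peel)
full_graph <- function(g) {
  igraph::make_graph(rbind(g$edges$from, g$edges$to),
                     n = nrow(g$vertices), directed = FALSE)
}

# traversable graph: kept edges not touching exterior vertices, weights set
traversal_graph <- function(g) {
  keep <- g$edges$kept &
    g$vertices$status[g$edges$from] != "exterior" &
    g$vertices$status[g$edges$to] != "exterior"
  tg <- igraph::make_graph(rbind(g$edges$from[keep], g$edges$to[keep]),
                           n = nrow(g$vertices), directed = FALSE)
  igraph::E(tg)$weight <- g$edges$weight[keep]
  igraph::E(tg)$length <- g$edges$length[keep]
  tg
}

#' Classify void vertices as exterior, boundary or interior
#'
#' Iterative probe peel in the style of alpha shapes: a tetrahedron lying on
#' the current outer boundary (a convex-hull face, or a face shared with an
#' already peeled tetrahedron) is peeled when its vertex clearance is at
#' least `probe_radius`, so bulk solvent is removed but the probe cannot
#' descend into openings narrower than itself. Peeled vertices are
#' `exterior`; remaining vertices with a hull face or a face to a peeled
#' tetrahedron are `boundary` (the molecular surface, where channels end);
#' the rest are `interior`. Burial depth (unweighted hop distance to the
#' nearest boundary vertex over traversable edges) is stored in
#' `vertices$depth`.
#'
#' @param g A `void_graph` from [build_void_graph()].
#' @param probe_radius Peel probe radius (A); default from `g$params`.
#' @return The graph with `vertices$status` and `vertices$depth` filled.
#' @export
mark_exterior <- function(g, probe_radius = g$params$probe_radius) {
  stopifnot(inherits(g, "void_graph"))
  v <- g$vertices
  eligible <- v$clearance >= probe_radius
  fg <- full_graph(g)
  exterior <- rep(FALSE, nrow(v))
  seeds <- which(v$hull & eligible)
  if (length(seeds)) {
    # peel = connected components of eligible vertices reachable from a
    # hull-adjacent eligible vertex (equivalent to the iterative face peel)
    sub <- igraph::subgraph_from_edges(
      fg, igraph::E(fg)[eligible[g$edges$from] & eligible[g$edges$to]],
      delete.vertices = FALSE)
    comp <- igraph::components(sub)$membership
    exterior <- eligible & comp %in% unique(comp[seeds])
  }
  v$status <- ifelse(exterior, "exterior", "interior")
  # boundary: non-peeled vertices exposed to the hull or to a peeled vertex
  adj_ext <- rep(FALSE, nrow(v))
  ef <- g$edges$from; et <- g$edges$to
  adj_ext[ef[exterior[et]]] <- TRUE
  adj_ext[et[exterior[ef]]] <- TRUE
  v$status[!exterior & (v$hull | adj_ext)] <- "boundary"
  g$vertices <- v
  g$vertices$depth <- burial_depth(g)
  g
}

# hop distance to the nearest boundary vertex over kept, non-exterior edges
# (Inf for sealed voids, 0 on the boundary itself)
burial_depth <- function(g) {
  v <- g$vertices
  nv <- nrow(v)
  bnd <- which(v$status == "boundary")
  depth <- rep(Inf, nv)
  depth[v$status == "exterior"] <- NA_real_
  if (!length(bnd)) return(depth)
  keep <- g$edges$kept &
    v$status[g$edges$from] != "exterior" & v$status[g$edges$to] != "exterior"
  src <- nv + 1L
  el <- cbind(c(g$edges$from[keep], rep.int(src, length(bnd))),
              c(g$edges$to[keep], bnd))
  bg <- igraph::make_graph(t(el), n = nv + 1L, directed = FALSE)
  d <- as.vector(igraph::distances(bg, v = src, weights = NA))[seq_len(nv)]
  ok <- is.finite(d) & !is.na(depth)
  depth[ok] <- d[ok] - 1
  depth
}

#' Connected cavities of the interior void
#'
#' Components of strictly interior, traversable vertices (clearance at or
#' above `interior_threshold`) lying at least `min_solvent_depth` away from
#' bulk solvent (the empty balls around exterior vertices), over the kept
#' edges. The solvent-depth requirement excludes the shallow groove network
#' just under the molecular surface, which would otherwise string distinct
#' cavities together into one component. Each cavity reports its deepest
#' vertex (maximal burial depth; ties broken by larger clearance, then lower
#' index) and whether it can reach the surface (finite burial depth).
#'
#' @param g A `void_graph` with exterior marked.
#' @param min_solvent_depth Minimum distance (A) from a cavity vertex to the
#'   nearest exterior empty ball; defaults to half the probe radius.
#' @return List of cavities: `vertices`, `deepest`, `touches_surface`.
#' @export
cavity_components <- function(g, min_solvent_depth = g$params$probe_radius / 2) {
  stopifnot(inherits(g, "void_graph"))
  v <- g$vertices
  if (all(is.na(v$status)))
    chan_error("chanatomy_value_error", "call mark_exterior() first")
  core <- v$status == "interior" & v$clearance >= g$params$interior_threshold
  if (any(core)) {
    ext <- which(v$status == "exterior")
    if (length(ext)) {
      ex <- as.matrix(v[ext, c("x", "y", "z")])
      ecl <- v$clearance[ext]
      ci <- which(core)
      sdist <- vapply(ci, function(i)
        min(sqrt((ex[, 1] - v$x[i])^2 + (ex[, 2] - v$y[i])^2 +
                 (ex[, 3] - v$z[i])^2) - ecl), numeric(1))
      core[ci[sdist < min_solvent_depth]] <- FALSE
    }
  }
  if (!any(core)) return(list())
  keep <- g$edges$kept & core[g$edges$from] & core[g$edges$to]
  cg <- igraph::make_graph(rbind(g$edges$from[keep], g$edges$to[keep]),
                           n = nrow(v), directed = FALSE)
  memb <- igraph::components(cg)$membership
  out <- lapply(unique(memb[core]), function(m) {
    idx <- which(core & memb == m)
    ord <- order(-v$depth[idx], -v$clearance[idx], idx)
    list(vertices = idx, deepest = idx[ord[1]],
         touches_surface = any(is.finite(v$depth[idx])))
  })
  # deterministic cavity order: by lowest contained vertex index
  out[order(vapply(out, function(cv) min(cv$vertices), numeric(1)))]
}

#' Dump a void graph to JSON for external inspection
#'
#' @param g A `void_graph`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_void_graph_json <- function(g, file) {
  jsonlite::write_json(
    list(structure_id = g$structure_id,
         params = unclass(g$params),
         vertices = g$vertices,
         edges = g$edges),
    file, dataframe = "columns", digits = NA, auto_unbox = TRUE, na = "null")
  invisible(file)
}
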