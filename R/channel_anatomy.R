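# Channel anatomy: centerline measurement, bottleneck and local minima,
# layered lining residues.

#' Measure a raw path into a channel
#'
#' The centerline is the sequence of void-vertex positions along the path,
#' the radius at each point is the vertex clearance, and the channel length
#' is the polyline length. Single-vertex paths are flagged degenerate.
#'
#' @param path A raw path from [shortest_channels()] (list with `vertices`,
#'   `cost`) or a bare integer vector of vertex indices.
#' @param g The `void_graph` the path lives in.
#' @param s The `chan_structure` (kept for interface symmetry; radii come
#'   from the graph).
#' @return A `channel`: centerline (n x 3), radii, length, vertices, cost,
#'   site_id, generic, sub_threshold, degenerate.
#' @export
measure_channel <- function(path, g, s = NULL) {
  vs <- if (is.list(path)) path$vertices else as.integer(path)
  cost <- if (is.list(path)) path$cost else NA_real_
  centerline <- as.matrix(g$vertices[vs, c("x", "y", "z")])
  rownames(centerline) <- NULL
  structure(list(
    centerline = centerline,
    radii = g$vertices$clearance[vs],
    length = polyline_length(centerline),
    vertices = vs,
    cost = cost,
    site_id = NA_character_,
    generic = FALSE,
    sub_threshold = FALSE,
    degenerate = length(vs) < 2L
  ), class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  bn <- if (x$degenerate) NA else find_bottleneck(x)$radius
  cat(sprintf("<channel> %d points, length %.1f A, bottleneck %.2f A%s%s\n",
              nrow(x$centerline), x$length, bn,
              if (isTRUE(x$generic)) ", generic" else "",
              if (isTRUE(x$sub_threshold)) ", sub-threshold" else ""))
  invisible(x)
}

#' Bottleneck of a channel
#'
#' The bottleneck is where the channel radius is a minimum; ties resolve to
#' the index closest to the start.
#'
#' @param c A non-degenerate `channel`.
#' @return List with `index` (1-based position on the centerline) and
#'   `radius` (A).
#' @export
find_bottleneck <- function(c) {
  stopifnot(inherits(c, "channel"))
  if (c$degenerate)
    chan_error("chanatomy_value_error", "degenerate channel has no bottleneck")
  i <- which.min(c$radii) # which.min returns the first minimum
  list(index = i, radius = c$radii[i])
}

#' Local minima of the radius profile (channel narrowings)
#'
#' Indices i with `radii[i] < radii[i-1]` and `radii[i] < radii[i+1]`;
#' a plateau flanked by larger values reports its first index only, and the
#' two endpoints are never minima.
#'
#' @param c A `channel` with at least 3 centerline points.
#' @return Integer vector of 1-based centerline indices (possibly empty).
#' @export
find_local_minima <- function(c) {
  stopifnot(inherits(c, "channel"))
  r <- c$radii
  if (length(r) < 3) return(integer(0))
  runs <- rle(r)
  k <- length(runs$lengths)
  if (k < 3) return(integer(0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  inner <- 2:(k - 1)
  mins <- inner[runs$values[inner] < runs$values[inner - 1] &
                runs$values[inner] < runs$values[inner + 1]]
  starts[mins]
}

#' Residues lining a channel wall
#'
#' A residue lines the channel when some atom lies within
#' `radii[i] + vdw(atom) + contact_tolerance` of some centerline point i.
#' The residue weight is the fraction of the channel arc length whose
#' centerline points it touches; flags record whether it touches the
#' bottleneck or a local minimum.
#'
#' @param c A measured `channel`.
#' @param s Sanitized `chan_structure` with radii.
#' @param contact_tolerance Extra contact margin (A); atoms just beyond the
#'   probe surface still shape the wall.
#' @return Data frame, one row per lining residue: chain, resno, icode,
#'   resname, copy, weight, closest_index (the touched centerline point
#'   nearest to the residue), touches_bottleneck, touches_local_minimum.
#' @export
lining_residues <- function(c, s, contact_tolerance = 1.0) {
  stopifnot(inherits(c, "channel"), inherits(s, "chan_structure"))
  empty <- data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), resname = character(0),
                      copy = integer(0), weight = numeric(0),
                      closest_index = integer(0),
                      touches_bottleneck = logical(0),
                      touches_local_minimum = logical(0))
  if (c$degenerate || nrow(c$centerline) == 0) return(empty)
  at <- s$atoms
  axyz <- atom_xyz(s)
  n <- nrow(c$centerline)
  share <- point_arc_share(c$centerline)
  bni <- find_bottleneck(c)$index
  minima <- find_local_minima(c)
  # pair (centerline point, atom) contacts; points are few, atoms many
  pair_pt <- integer(0); pair_at <- integer(0); pair_d <- numeric(0)
  for (i in seq_len(n)) {
    thr <- c$radii[i] + at$radius + contact_tolerance
    d2 <- (axyz[, 1] - c$centerline[i, 1])^2 +
          (axyz[, 2] - c$centerline[i, 2])^2 +
          (axyz[, 3] - c$centerline[i, 3])^2
    hit <- which(d2 <= thr * thr)
    if (length(hit)) {
      pair_pt <- c(pair_pt, rep.int(i, length(hit)))
      pair_at <- c(pair_at, hit)
      pair_d <- c(pair_d, sqrt(d2[hit]))
    }
  }
  if (!length(pair_at)) return(empty)
  key <- paste(at$copy[pair_at], at$chain[pair_at], at$resno[pair_at],
               at$icode[pair_at], sep = "|")
  out <- lapply(split(seq_along(pair_at), key), function(ii) {
    a1 <- pair_at[ii[1]]
    touched <- unique(pair_pt[ii])
    best <- ii[which.min(pair_d[ii])]
    data.frame(chain = at$chain[a1], resno = at$resno[a1],
               icode = at$icode[a1], resname = at$resname[a1],
               copy = at$copy[a1],
               weight = min(1, sum(share[touched]) / max(c$length, 1e-12)),
               closest_index = pair_pt[best],
               touches_bottleneck = bni %in% touched,
               touches_local_minimum = any(minima %in% touched),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$copy, out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign internal/middle/external layers to lining residues
#'
#' Each residue is classified through its closest touched centerline point:
#' within `layer_distance` (Euclidean) of the channel start it is internal;
#' else within `layer_distance` of the end, external; otherwise middle. A
#' residue within range of both zones is internal (start precedence).
#'
#' @param lining Data frame from [lining_residues()].
#' @param c The corresponding `channel`.
#' @param params A [channel_params()] (uses `layer_distance`).
#' @return The lining data frame with a `layer` column.
#' @export
assign_layers <- function(lining, c, params = channel_params()) {
  stopifnot(inherits(c, "channel"))
  if (!nrow(lining)) {
    lining$layer <- character(0)
    return(lining)
  }
  pts <- c$centerline[lining$closest_index, , drop = FALSE]
  p0 <- c$centerline[1, ]
  p1 <- c$centerline[nrow(c$centerline), ]
  d_start <- sqrt(rowSums(sweep(pts, 2, p0)^2))
  d_end <- sqrt(rowSums(sweep(pts, 2, p1)^2))
  lining$layer <- ifelse(d_start <= params$layer_distance, "internal",
                         ifelse(d_end <= params$layer_distance, "external",
                                "middle"))
  lining
}

#' Export channel centerlines as PDB pseudo-atoms
#'
#' Writes one HETATM pseudo-atom per centerline point (element X, residue
#' CTR), one chain per channel, with the point radius in the occupancy
#' column, for visualization alongside the structure.
#'
#' @param channels List of `channel` objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_centerline_pdb <- function(channels, file) {
  con <- file(file, "w")
  on.exit(close(con))
  serial <- 0L
  chains <- c(LETTERS, letters, 0:9)
  for (k in seq_along(channels)) {
    ch <- channels[[k]]
    for (i in seq_len(nrow(ch$centerline))) {
      serial <- serial + 1L
      writeLines(sprintf("HETATM%5d  X   CTR %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           X",
                         serial %% 100000L, chains[(k - 1L) %% length(chains) + 1L],
                         i %% 10000L, ch$centerline[i, 1], ch$centerline[i, 2],
                         ch$centerline[i, 3], min(ch$radii[i], 99.99), 0), con)
    }
  }
  writeLines("END", con)
  invisible(file)
}
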