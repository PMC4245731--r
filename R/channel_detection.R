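# Channel detection: active-site start points, surface exits, Dijkstra
# extraction and channel-level filtering.

#' Channel detection parameters
#'
#' Defaults follow the standard Voronoi tunnel-finding setup: probe and
#' origin radius 5 A, interior threshold 1.1 A, and the customary defaults
#' for the bottleneck, cutoff-ratio and surface-cover parameters. Channels
#' shorter than `min_report_length` (15 A) are flagged sub-threshold rather
#' than deleted, so occurrence counts at 5/10/15/20 A are all computable
#' from one run.
#'
#' @param probe_radius Exterior peel probe (A).
#' @param origin_radius Search radius around the active-site centroid for the
#'   start vertex (A); expanded once by x1.5 if empty.
#' @param interior_threshold Minimum edge clearance for traversable void (A).
#' @param bottleneck_radius Channels narrower than this over more than
#'   `bottleneck_length` of arc are discarded (A).
#' @param bottleneck_length See `bottleneck_radius` (A).
#' @param cutoff_ratio Maximum fraction of vertices a channel may share with
#'   an already-kept, lower-cost channel.
#' @param surface_cover_radius Exits within this distance of a kept,
#'   lower-cost exit are merged away (A).
#' @param min_report_length Channels below this length are flagged
#'   sub-threshold (A).
#' @param layer_distance Lining residues whose contact point lies within this
#'   distance of the start/end are internal/external (A).
#' @return A `channel_params` object.
#' @export
channel_params <- function(probe_radius = 5, origin_radius = 5,
                           interior_threshold = 1.1, bottleneck_radius = 1.25,
                           bottleneck_length = 3.0, cutoff_ratio = 0.7,
                           surface_cover_radius = 10.0, min_report_length = 15,
                           layer_distance = 5) {
  p <- list(probe_radius = probe_radius, origin_radius = origin_radius,
            interior_threshold = interior_threshold,
            bottleneck_radius = bottleneck_radius,
            bottleneck_length = bottleneck_length, cutoff_ratio = cutoff_ratio,
            surface_cover_radius = surface_cover_radius,
            min_report_length = min_report_length,
            layer_distance = layer_distance)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0 || !is.finite(x),
                logical(1))
  bad["min_report_length"] <- !is.numeric(p$min_report_length) || p$min_report_length < 0
  if (any(bad))
    chan_error("chanatomy_value_error",
               paste0("invalid channel parameter(s): ", paste(names(p)[bad], collapse = ", ")))
  structure(p, class = "channel_params")
}

# atoms of a structure belonging to the residues of one site annotation,
# restricted to one assembly copy
site_atoms <- function(s, site, copy = 0L) {
  at <- s$atoms
  res <- site$residues
  key_at <- paste(at$chain, at$resno, sep = "|")
  key_res <- paste(res$chain, res$resno, sep = "|")
  hit <- at$copy == copy & key_at %in% key_res
  if (any(hit)) {
    expected <- setNames(res$resname, key_res)
    if (any(at$resname[hit] != expected[key_at[hit]], na.rm = TRUE))
      warning(sprintf("site %s: residue name mismatch against structure %s",
                      site$site_id, s$id), call. = FALSE)
  }
  which(hit)
}

#' Locate the channel start vertex for an active site
#'
#' Computes the centroid of the site-residue heavy atoms, then picks, among
#' traversable non-exterior vertices within `origin_radius` of the centroid,
#' the one with maximal clearance -- the apex chamber of the active-site
#' cavity (ties: larger burial depth, then closer to the centroid, then
#' lower index; clearance is compared before depth because hop depth is
#' mesh-sensitive and would favour narrow interstitial pockets over the
#' cavity apex). If none is found the search radius is expanded once by
#' x1.5; failing that, a `chanatomy_site_unreachable` error is raised (the
#' structure counts as "no channel").
#'
#' @param g A `void_graph` with exterior marked.
#' @param s The corresponding `chan_structure`.
#' @param site A site annotation (see [load_sites()]), optionally with a
#'   `$copy` element selecting the assembly copy (default 0).
#' @param params A [channel_params()].
#' @return A `start_point`: list(vertex, site_id, copy, centroid).
#' @export
locate_start <- function(g, s, site, params = g$params) {
  copy <- site$copy %||% 0L
  idx <- site_atoms(s, site, copy)
  if (!length(idx))
    chan_error("chanatomy_site_unreachable",
               sprintf("site %s: no residue resolvable in structure %s (copy %d)",
                       site$site_id, s$id, copy))
  centroid <- colMeans(s$atoms[idx, c("x", "y", "z")])
  v <- g$vertices
  cand_ok <- v$status %in% c("interior", "boundary") &
    v$clearance >= params$interior_threshold
  pick <- function(radius) {
    d2 <- (v$x - centroid[1])^2 + (v$y - centroid[2])^2 + (v$z - centroid[3])^2
    cand <- which(cand_ok & d2 <= radius^2)
    if (!length(cand)) return(NULL)
    cand[order(-v$clearance[cand], -v$depth[cand], d2[cand], cand)][1]
  }
  vert <- pick(params$origin_radius)
  if (is.null(vert)) vert <- pick(params$origin_radius * 1.5)
  if (is.null(vert))
    chan_error("chanatomy_site_unreachable",
               sprintf("site %s: no traversable void vertex within %.1f A of the site centroid",
                       site$site_id, params$origin_radius * 1.5))
  list(vertex = vert, site_id = site$site_id, copy = copy, centroid = centroid)
}

#' Candidate channel exits
#'
#' All boundary vertices of the void graph (surface end points). An empty
#' result is valid (fully sealed or fully exposed structures).
#'
#' @param g A `void_graph` with exterior marked.
#' @return Integer vector of vertex indices.
#' @export
candidate_exits <- function(g) {
  which(g$vertices$status == "boundary")
}

#' Shortest void paths from a start vertex to the surface
#'
#' Single-source Dijkstra over the traversable void graph (edge weight
#' `length / (clearance^2 + 0.01)`). One minimal-cost path is produced per
#' reachable exit. Paths that pass through an earlier boundary vertex are
#' discarded (a channel ends at its first surface contact; such paths are a
#' cheaper exit's channel plus a redundant near-surface crawl), and the
#' remaining exits are greedily clustered so that any exit lying within
#' `surface_cover_radius` of a kept, lower-cost exit is discarded. Ties are
#' broken by vertex index, making the result deterministic.
#'
#' @param g A `void_graph` with exterior marked.
#' @param start A `start_point` from [locate_start()] (or a vertex index).
#' @param exits Integer vertex indices; defaults to [candidate_exits()].
#' @param params A [channel_params()].
#' @return List of raw paths: `vertices` (ordered indices), `cost`.
#' @export
shortest_channels <- function(g, start, exits = candidate_exits(g),
                              params = g$params) {
  sv <- if (is.list(start)) start$vertex else start
  if (!length(exits)) return(list())
  tg <- traversal_graph(g)
  cost <- suppressWarnings(
    as.vector(igraph::distances(tg, v = sv, to = exits,
                                weights = igraph::E(tg)$weight)))
  ok <- is.finite(cost)
  exits <- exits[ok]; cost <- cost[ok]
  if (!length(exits)) return(list())
  ord <- order(cost, exits)
  exits <- exits[ord]; cost <- cost[ord]
  vp <- suppressWarnings(
    igraph::shortest_paths(tg, from = sv, to = exits,
                           weights = igraph::E(tg)$weight, output = "vpath")$vpath)
  vp <- lapply(vp, as.integer)
  # first-surface-contact rule
  bnd <- g$vertices$status == "boundary"
  clean <- vapply(vp, function(p)
    length(p) >= 1 && !any(bnd[p[-length(p)]]), logical(1))
  exits <- exits[clean]; cost <- cost[clean]; vp <- vp[clean]
  if (!length(exits)) return(list())
  v <- g$vertices
  keep_i <- integer(0)
  for (i in seq_along(exits)) {
    if (length(keep_i)) {
      d2 <- (v$x[exits[keep_i]] - v$x[exits[i]])^2 +
        (v$y[exits[keep_i]] - v$y[exits[i]])^2 +
        (v$z[exits[keep_i]] - v$z[exits[i]])^2
      if (any(d2 <= params$surface_cover_radius^2)) next
    }
    keep_i <- c(keep_i, i)
  }
  mapply(function(p, co) list(vertices = p, cost = co),
         vp[keep_i], cost[keep_i], SIMPLIFY = FALSE)
}

# Trim the trailing centerline points that lie inside some exterior
# vertex's empty ball (a sphere around an exterior Voronoi vertex with its
# clearance as radius contains no atom and belongs to bulk solvent): the
# channel ends where it meets the solvent, not at the outermost unpeeled
# vertex of the mouth vestibule.
trim_solvent <- function(ch, g) {
  if (ch$degenerate) return(ch)
  v <- g$vertices
  ext <- which(v$status == "exterior")
  if (!length(ext)) return(ch)
  ex <- cbind(v$x[ext], v$y[ext], v$z[ext])
  ecl <- v$clearance[ext]
  n <- nrow(ch$centerline)
  exposed <- vapply(seq_len(n), function(i) {
    d2 <- (ex[, 1] - ch$centerline[i, 1])^2 + (ex[, 2] - ch$centerline[i, 2])^2 +
      (ex[, 3] - ch$centerline[i, 3])^2
    any(d2 < ecl^2)
  }, logical(1))
  if (!exposed[n]) return(ch)
  inside <- which(!exposed)
  last <- if (length(inside)) max(inside) else 0L
  if (last < 2L) {
    ch$degenerate <- TRUE
    return(ch)
  }
  ch$centerline <- ch$centerline[seq_len(last), , drop = FALSE]
  ch$radii <- ch$radii[seq_len(last)]
  ch$vertices <- ch$vertices[seq_len(last)]
  ch$length <- polyline_length(ch$centerline)
  ch
}

# arc length of the longest contiguous run of centerline points with radius
# below `radius`
longest_narrow_run <- function(centerline, radii, radius) {
  narrow <- radii < radius
  if (!any(narrow)) return(0)
  runs <- rle(narrow)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                       centerline[-nrow(centerline), , drop = FALSE])^2))
  best <- 0
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    arc <- if (i1 > i0) sum(seg[i0:(i1 - 1L)]) else 0
    best <- max(best, arc)
  }
  best
}

#' Measure raw paths and apply channel-level filters
#'
#' Each raw path is measured into a channel ([measure_channel()]) and
#' trimmed to the surface; then, in order of increasing path cost, a channel
#' is dropped when (a) a contiguous centerline arc longer than
#' `bottleneck_length` stays narrower than `bottleneck_radius`, (b) it
#' shares more than `cutoff_ratio` of its vertices with an already-kept
#' channel, or (c) its surface endpoint lies within `surface_cover_radius`
#' of an already-kept channel's endpoint (the two cover the same surface
#' patch; wide mouths otherwise yield duplicate channels through parallel
#' void corridors). Surviving channels shorter than
#' `min_report_length` are flagged `sub_threshold` (retained, since
#' occurrence is also counted at 5/10/20 A).
#'
#' @param paths List of raw paths from [shortest_channels()].
#' @param g A `void_graph`.
#' @param s The `chan_structure`.
#' @param params A [channel_params()].
#' @param site_id Site label attached to the channels (NA for generic).
#' @param generic Flag channels as generic (cavity-to-surface) channels.
#' @return List of `channel` objects.
#' @export
refine_and_filter <- function(paths, g, s, params = g$params,
                              site_id = NA_character_, generic = FALSE) {
  if (!length(paths)) return(list())
  chans <- lapply(paths, function(p) trim_solvent(measure_channel(p, g, s), g))
  ord <- order(vapply(paths, `[[`, numeric(1), "cost"))
  kept <- list()
  kept_verts <- list()
  for (i in ord) {
    ch <- chans[[i]]
    if (ch$degenerate) next
    if (longest_narrow_run(ch$centerline, ch$radii, params$bottleneck_radius) >
        params$bottleneck_length) next
    vs <- ch$vertices
    dup <- any(vapply(kept_verts, function(kv)
      length(intersect(vs, kv)) / length(vs) > params$cutoff_ratio, logical(1)))
    if (dup) next
    endp <- ch$centerline[nrow(ch$centerline), ]
    same_patch <- any(vapply(kept, function(kc) {
      ke <- kc$centerline[nrow(kc$centerline), ]
      sum((endp - ke)^2) <= params$surface_cover_radius^2
    }, logical(1)))
    if (same_patch) next
    ch$site_id <- site_id
    ch$generic <- generic
    ch$sub_threshold <- ch$length < params$min_report_length
    kept[[length(kept) + 1L]] <- ch
    kept_verts[[length(kept_verts) + 1L]] <- vs
  }
  kept
}

#' Choose the active site with the most channels
#'
#' Given per-site channel lists, returns the site with the largest number of
#' qualifying (non-sub-threshold) channels; ties are broken by the largest
#' total qualifying channel length, then lexicographic site id.
#'
#' @param per_site_channels Named list: site id -> list of channels.
#' @return The chosen site id (character).
#' @export
select_site <- function(per_site_channels) {
  if (!length(per_site_channels))
    chan_error("chanatomy_value_error", "no sites supplied")
  ids <- names(per_site_channels)
  n_q <- vapply(per_site_channels, function(chs)
    sum(!vapply(chs, `[[`, logical(1), "sub_threshold")), numeric(1))
  tot <- vapply(per_site_channels, function(chs) {
    q <- !vapply(chs, `[[`, logical(1), "sub_threshold")
    sum(vapply(chs[q], `[[`, numeric(1), "length"))
  }, numeric(1))
  ids[order(-n_q, -tot, ids)][1]
}

#' Generic channels: cavity-to-surface paths irrespective of annotation
#'
#' For every cavity, runs [shortest_channels()] from its deepest vertex and
#' pools the results through [refine_and_filter()], labelling the survivors
#' as generic.
#'
#' @param g A `void_graph` with exterior marked.
#' @param s The `chan_structure`.
#' @param params A [channel_params()].
#' @return List of generic `channel` objects.
#' @export
generic_channels <- function(g, s, params = g$params) {
  cavs <- cavity_components(g)
  paths <- list()
  for (cv in cavs) {
    paths <- c(paths, shortest_channels(g, cv$deepest, params = params))
  }
  refine_and_filter(paths, g, s, params, site_id = NA_character_, generic = TRUE)
}
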