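# Shared fixtures: in-code structures, hand-made void graphs, and the
# brute-force oracles the geometric tests check against.

# Build a chan_structure from raw coordinates by round-tripping PDB text
# through the parser (radii assigned, element C unless given).
make_test_structure <- function(xyz, element = "C", resname = "ALA",
                                resno = seq_len(nrow(xyz)), chain = "A",
                                id = "test") {
  xyz <- as.matrix(xyz)
  element <- rep_len(element, nrow(xyz))
  resname <- rep_len(resname, nrow(xyz))
  chain <- rep_len(chain, nrow(xyz))
  lines <- sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(nrow(xyz)), resname, chain, resno,
                   xyz[, 1], xyz[, 2], xyz[, 3], element)
  s <- parse_pdb(text = paste(c(lines, "END"), collapse = "\n"), id = id)
  assign_radii(s)
}

# vertices of a regular tetrahedron with the given edge length
regular_tetrahedron <- function(edge) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v * edge / (2 * sqrt(2))
}

# random protein-like blob: n atoms, coordinates roughly packed
random_blob <- function(n, seed, spread = 12) {
  withr::with_seed(seed, matrix(stats::rnorm(n * 3, sd = spread / 2), ncol = 3))
}

# Hand-made void graph (bypasses triangulation) for path-level tests.
# vertices: data.frame or matrix of positions; edges: data.frame(from, to,
# weight); clearance/status/depth optional.
fake_void_graph <- function(pos, edges, clearance = NULL, status = NULL,
                            depth = NULL, params = channel_params()) {
  pos <- as.matrix(pos)
  nv <- nrow(pos)
  clearance <- clearance %||% rep(2, nv)
  status <- status %||% rep("interior", nv)
  depth <- depth %||% rep(1, nv)
  len <- sqrt(rowSums((pos[edges$from, , drop = FALSE] -
                       pos[edges$to, , drop = FALSE])^2))
  structure(list(
    vertices = data.frame(index = seq_len(nv), x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], clearance = clearance, hull = FALSE,
                          status = status, depth = depth),
    edges = data.frame(from = edges$from, to = edges$to, length = len,
                       clearance = pmin(clearance[edges$from], clearance[edges$to]),
                       weight = edges$weight %||% pmax(len, 1e-9),
                       kept = rep(TRUE, length(len))),
    structure_id = "fake", params = params),
    class = "void_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# channels above the report-length threshold
qualifying <- function(chs) {
  chs[!vapply(chs, `[[`, logical(1), "sub_threshold")]
}

# exhaustive-enumeration shortest path cost (independent Dijkstra oracle)
brute_force_cost <- function(nv, edges, from, to) {
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- Inf
  visit <- function(v, cost, seen) {
    if (cost >= best) return()
    if (v == to) { best <<- cost; return() }
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (j in seq_len(nrow(nb))) {
      if (!(nb[j, 1] %in% seen))
        visit(nb[j, 1], cost + nb[j, 2], c(seen, nb[j, 1]))
    }
  }
  visit(from, 0, from)
  best
}

# a measured channel object built directly from a centerline + radii
fake_channel <- function(centerline, radii, site_id = "S", generic = FALSE) {
  centerline <- as.matrix(centerline)
  structure(list(centerline = centerline, radii = radii,
                 length = sum(sqrt(rowSums((centerline[-1, , drop = FALSE] -
                   centerline[-nrow(centerline), , drop = FALSE])^2))),
                 vertices = seq_len(nrow(centerline)), cost = NA_real_,
                 site_id = site_id, generic = generic, sub_threshold = FALSE,
                 degenerate = nrow(centerline) < 2),
            class = "channel")
}

# minimal enzyme_record for cohort statistics tests
fake_record <- function(id, ec, n_atoms, channel_lengths,
                        hydropathy = NULL, polarity = NULL,
                        composition = c(ALA = 10), min_report = 15) {
  chans <- lapply(seq_along(channel_lengths), function(i) {
    L <- channel_lengths[i]
    ch <- fake_channel(cbind(seq(0, L, length.out = max(2, round(L))), 0, 0),
                       rep(2, max(2, round(L))))
    ch$sub_threshold <- L < min_report
    ch$physchem <- list(hydropathy = (hydropathy %||% rep(0, length(channel_lengths)))[i],
                        polarity = (polarity %||% rep(10, length(channel_lengths)))[i],
                        n_positive = 0, n_negative = 0, net_charge = 0)
    ch$lining <- data.frame(chain = "A", resno = 1, icode = "", resname = "ALA",
                            copy = 0L, weight = 1, closest_index = 1L,
                            touches_bottleneck = TRUE,
                            touches_local_minimum = FALSE, layer = "middle")
    ch
  })
  structure(list(structure_id = id, ec_class = ec, n_atoms = n_atoms,
                 site_id = "S", channels = chans, site_unreachable = FALSE,
                 residue_composition = as.table(composition), status = "ok"),
            class = "enzyme_record")
}

# straight-tunnel synthetic structure, small, for fast end-to-end tests
quick_tunnel <- function(seed = 5, length = 22, radius = 2.5,
                         bottleneck = 1.8, id = "quick") {
  make_tunnel_structure(
    tunnel_spec(direction = c(1, 0, 0), length = length, radius = radius,
                bottleneck_radius = bottleneck, cavity_radius = 5),
    seed = seed, id = id)
}
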