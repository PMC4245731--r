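# Synthetic structures: protein-like jittered FCC sphere packings with
# planted cavities, tunnels of known geometry, and planted lining
# compositions, plus machine-readable ground truth.

#' Specification of one planted tunnel
#'
#' The tunnel runs from the cavity's deepest apex (`cavity_center`) along
#' `direction`; `length` is the full planted channel length from the apex to
#' the packing surface. The radius profile is `radius` with an optional
#' plateau constriction to `bottleneck_radius` at fraction `bottleneck_t` of
#' the length (plateau half-width `bottleneck_halfwidth`, 2 A ramps).
#'
#' @param direction 3-vector, normalized internally.
#' @param length Planted channel length, apex to surface (A).
#' @param radius Base tunnel radius (A).
#' @param bottleneck_radius Dip radius (A); `NA` for a uniform profile.
#' @param bottleneck_t Fractional arc position of the dip (0-1).
#' @param bottleneck_halfwidth Plateau half-width of the constriction (A).
#' @param cavity_radius Radius of the cavity carved at the apex (A).
#' @param cavity_center Apex position (A).
#' @param lining Optional named list of planted residue pools per layer:
#'   `internal`, `middle`, `external`, and optionally `bottleneck`. Each
#'   entry is either a character vector sampled uniformly (length 1 =
#'   constant) or a named probability vector (multinomial draw).
#' @param annotate Emit a site annotation for this tunnel's cavity.
#' @return A `tunnel_spec` object.
#' @export
tunnel_spec <- function(direction = c(1, 0, 0), length = 30, radius = 2.5,
                        bottleneck_radius = NA, bottleneck_t = 0.5,
                        bottleneck_halfwidth = 3, cavity_radius = 6,
                        cavity_center = c(0, 0, 0), lining = NULL,
                        annotate = TRUE) {
  direction <- direction / sqrt(sum(direction^2))
  if (!is.na(bottleneck_radius) && bottleneck_radius < 1.2)
    chan_error("chanatomy_value_error",
               "bottleneck radius below 1.2 A would not be traversable")
  if (radius < 1.2)
    chan_error("chanatomy_value_error", "tunnel radius must be >= 1.2 A")
  structure(list(direction = direction, length = length, radius = radius,
                 bottleneck_radius = bottleneck_radius,
                 bottleneck_t = bottleneck_t,
                 bottleneck_halfwidth = bottleneck_halfwidth,
                 cavity_radius = cavity_radius,
                 cavity_center = cavity_center, lining = lining,
                 annotate = annotate),
            class = "tunnel_spec")
}

# radius profile: flat plateau at the bottleneck radius over
# +/- bottleneck_halfwidth, ramping back to the base radius over 2 A on
# either side. A plateau (rather than a sharp dip) is required for the
# constriction to be realizable by a union-of-spheres carve: a V-shaped dip
# narrower than the carve radius is swallowed by the neighbouring spheres.
tunnel_radius_at <- function(spec, t_abs) {
  r <- rep(spec$radius, length(t_abs))
  if (!is.na(spec$bottleneck_radius)) {
    t_bn <- spec$bottleneck_t * spec$length
    ramp <- 2
    excess <- pmax(0, abs(t_abs - t_bn) - spec$bottleneck_halfwidth)
    dip <- pmax(0, 1 - excess / ramp)
    r <- r - (spec$radius - spec$bottleneck_radius) * dip
  }
  r
}

# FCC packing of a ball: checkerboard lattice with nearest-neighbour
# distance `spacing`
fcc_ball <- function(ball_radius, spacing) {
  cell <- spacing / sqrt(2)
  k <- ceiling(ball_radius / cell)
  g <- expand.grid(i = -k:k, j = -k:k, l = -k:k)
  g <- g[(g$i + g$j + g$l) %% 2 == 0, ]
  pts <- as.matrix(g) * cell
  pts[rowSums(pts^2) <= ball_radius^2, , drop = FALSE]
}

#' Generate a synthetic structure with planted tunnels
#'
#' Builds a jittered FCC packing of single-heavy-atom pseudo-residues
#' (carbon spheres; spacing ~3.6 A matches protein heavy-atom density, the
#' jitter breaks Delaunay degeneracies deterministically), carves the
#' cavities and tunnels of the given specs, renames the surviving atoms that
#' line each tunnel according to its lining plan, and returns the structure
#' together with ground truth.
#'
#' @param tunnels List of [tunnel_spec()]s (a single spec is accepted).
#' @param spacing Nearest-neighbour atom spacing (A).
#' @param jitter Maximum displacement of an atom from its lattice site (A).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param ball_radius Packing radius (A); default: largest apex-to-surface
#'   requirement of the specs.
#' @param filler_composition Named probability vector over 3-letter residue
#'   names for atoms not lining any tunnel; default uniform over the 20
#'   standard amino acids.
#' @param atoms_per_residue 1 (default; exact lining bookkeeping) or 4
#'   (three satellite atoms per residue, stressing lining detection).
#' @param min_exit_separation Planted exits closer than this raise a
#'   generation error (channels would merge); default 2 x the surface-cover
#'   dedup radius.
#' @param id Structure identifier.
#' @return List with `structure` (a sanitized `chan_structure`, radii
#'   assigned), `sites` (site annotations for annotated cavities), and
#'   `truth` (per-tunnel planted length, bottleneck, exit point, per-layer
#'   planted lining composition).
#' @export
make_tunnel_structure <- function(tunnels, spacing = 3.6, jitter = 0.3,
                                  seed = 1, ball_radius = NULL,
                                  filler_composition = NULL,
                                  atoms_per_residue = 1,
                                  min_exit_separation = 20, id = "synth") {
  if (inherits(tunnels, "tunnel_spec")) tunnels <- list(tunnels)
  stopifnot(length(tunnels) >= 1, all(vapply(tunnels, inherits, logical(1), "tunnel_spec")))
  need_R <- max(vapply(tunnels, function(tp)
    sqrt(sum(tp$cavity_center^2)) + tp$length, numeric(1)))
  ball_radius <- ball_radius %||% need_R
  # exit points (where the tunnel axis crosses the ball surface)
  exits <- lapply(tunnels, function(tp) {
    ctr <- tp$cavity_center; d <- tp$direction
    # |ctr + t d| = ball_radius
    b <- sum(ctr * d); cq <- sum(ctr^2) - ball_radius^2
    t_exit <- -b + sqrt(b^2 - cq)
    list(t_exit = t_exit, point = ctr + t_exit * d)
  })
  if (length(tunnels) > 1) {
    ep <- do.call(rbind, lapply(exits, `[[`, "point"))
    dd <- as.matrix(dist(ep))
    if (any(dd[upper.tri(dd)] <= min_exit_separation))
      chan_error("chanatomy_generation_error",
                 sprintf("planted exits closer than %.1f A would merge", min_exit_separation))
  }
  aa20 <- property_scales()$aa
  filler_composition <- filler_composition %||% setNames(rep(1 / 20, 20), aa20)
  fp <- filler_composition[aa20]
  fp[is.na(fp)] <- 0
  vdw <- 1.70 # carbon pseudo-atoms
  res <- withr::with_seed(seed, {
    pts <- fcc_ball(ball_radius, spacing)
    pts <- pts + matrix(stats::runif(length(pts), -jitter / sqrt(3), jitter / sqrt(3)),
                        ncol = 3)
    # carve cavities and tunnels
    removed <- rep(FALSE, nrow(pts))
    wall <- vector("list", length(tunnels)) # per tunnel: layer info
    gates <- vector("list", length(tunnels)) # per tunnel: bottleneck ring
    for (k in seq_along(tunnels)) {
      tp <- tunnels[[k]]
      ctr <- tp$cavity_center
      dcav <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 +
                   (pts[, 3] - ctr[3])^2)
      removed <- removed | dcav < tp$cavity_radius + vdw
      ts <- seq(tp$cavity_radius - 1, exits[[k]]$t_exit + 8, by = 0.5)
      rt <- tunnel_radius_at(tp, ts)
      lining_of <- rep(NA_character_, nrow(pts))
      near_d <- rep(Inf, nrow(pts))
      for (j in seq_along(ts)) {
        p <- ctr + ts[j] * tp$direction
        d <- sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2)
        removed <- removed | d < rt[j] + vdw
        # wall shell: atoms whose center sits within 2.2 A of the carved wall
        shell <- d < rt[j] + vdw + 2.2 & ts[j] <= exits[[k]]$t_exit
        lay <- if (ts[j] >= exits[[k]]$t_exit - 5) "external"
               else if (!is.na(tp$bottleneck_radius) &&
                        abs(ts[j] - tp$bottleneck_t * tp$length) <= tp$bottleneck_halfwidth)
                 "bottleneck"
               else "middle"
        upd <- shell & d < near_d
        lining_of[upd] <- lay
        near_d[upd] <- d[upd]
      }
      # cavity wall = internal layer (takes precedence near the apex)
      cav_wall <- dcav >= tp$cavity_radius + vdw & dcav < tp$cavity_radius + vdw + 2.2
      lining_of[cav_wall] <- "internal"
      wall[[k]] <- lining_of
      # gate atoms: a lattice carve cannot realize a precise constriction
      # radius (the nearest surviving atom falls wherever the lattice puts
      # it), so the bottleneck is built the way real bottlenecks are - a
      # ring of residues protruding into the channel at exactly
      # bottleneck_radius + vdw from the axis
      if (!is.na(tp$bottleneck_radius)) {
        t_bn <- tp$bottleneck_t * tp$length
        pbn <- ctr + t_bn * tp$direction
        dirn <- tp$direction
        ref <- if (abs(dirn[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u <- ref - sum(ref * dirn) * dirn
        u <- u / sqrt(sum(u^2))
        v <- c(dirn[2] * u[3] - dirn[3] * u[2],
               dirn[3] * u[1] - dirn[1] * u[3],
               dirn[1] * u[2] - dirn[2] * u[1])
        # two rings of six, rotated a half step and offset axially: the
        # second ring closes the off-axis pockets between the gates of the
        # first, so the constriction radius is realized all around
        ng <- 6L
        th0 <- stats::runif(1, 0, 2 * pi / ng)
        rr <- tp$bottleneck_radius + vdw
        ring <- function(offset, rot) {
      th <- 2 * pi * (seq_len(ng) - 1) / ng + th0 + rot
      ax <- stats::runif(ng, -0.15, 0.15) + offset
      t(vapply(seq_len(ng), function(i)
        pbn + rr * (cos(th[i]) * u + sin(th[i]) * v) + ax[i] * dirn,
        numeric(3)))
        }
        gates[[k]] <- rbind(ring(-0.9, 0), ring(0.9, pi / ng))
      }
    }
    keep <- which(!removed)
    pts <- pts[keep, , drop = FALSE]
    gate_n <- vapply(gates, function(gm) if (is.null(gm)) 0L else nrow(gm),
                     integer(1))
    if (sum(gate_n)) pts <- rbind(pts, do.call(rbind, gates[gate_n > 0]))
    n <- nrow(pts)
    resname <- sample(aa20, n, replace = TRUE, prob = fp)
    planted <- vector("list", length(tunnels))
    for (k in seq_along(tunnels)) {
      tp <- tunnels[[k]]
      lin <- c(wall[[k]][keep],
               unlist(lapply(seq_along(tunnels), function(j)
                 rep(if (j == k) "bottleneck" else NA_character_, gate_n[j]))))
      plan <- tp$lining
      comp <- list()
      for (lay in c("internal", "middle", "external", "bottleneck")) {
        idx <- which(lin == lay)
        if (!length(idx)) next
        pool <- if (!is.null(plan)) plan[[lay]] %||% plan[["middle"]] else NULL
        if (!is.null(pool)) {
          resname[idx] <- if (is.numeric(pool))
            sample(names(pool), length(idx), replace = TRUE, prob = pool)
          else if (length(pool) == 1) pool
          else sample(pool, length(idx), replace = TRUE)
        }
        comp[[lay]] <- table(resname[idx])
      }
      planted[[k]] <- list(layers = lin, composition = comp)
    }
    list(pts = pts, resname = resname, planted = planted)
  })
  pts <- res$pts
  n <- nrow(pts)
  if (atoms_per_residue == 4) {
    off <- rbind(c(0, 0, 0), c(0.9, 0.9, 0.9), c(-0.9, 0.9, -0.9),
                 c(0.9, -0.9, -0.9)) / sqrt(3) * 1.3
    pts <- pts[rep(seq_len(n), each = 4), ] + off[rep(1:4, n), ]
    res$resname <- rep(res$resname, each = 4)
    resno <- rep(seq_len(n), each = 4)
    name <- rep(c("CA", "CB", "CG", "CD"), n)
  } else {
    resno <- seq_len(n)
    name <- rep("CA", n)
  }
  atoms <- data.frame(serial = seq_len(nrow(pts)), name = name, element = "C",
                      resname = res$resname, chain = "A", resno = resno,
                      icode = "", x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      occ = 1, het = FALSE, copy = 0L, radius = vdw,
                      stringsAsFactors = FALSE)
  s <- new_structure(atoms, id = id)
  # site annotations: a handful of cavity-wall residues per annotated tunnel
  sites <- list()
  for (k in seq_along(tunnels)) {
    if (!isTRUE(tunnels[[k]]$annotate)) next
    # lattice-site index == resno in both residue modes
    wall_res <- which(res$planted[[k]]$layers == "internal")
    if (!length(wall_res)) next
    # greedy farthest-point pick spreads the annotated residues around the
    # cavity so their centroid lands near the apex
    pickn <- min(6L, length(wall_res))
    wp <- pts[match(wall_res, resno), , drop = FALSE]
    pick_i <- 1L
    while (length(pick_i) < pickn) {
      dmin <- rep(Inf, nrow(wp))
      for (j in pick_i) {
        dj <- sqrt(rowSums((wp - matrix(wp[j, ], nrow(wp), 3, byrow = TRUE))^2))
        dmin <- pmin(dmin, dj)
      }
      pick_i <- c(pick_i, which.max(dmin))
    }
    pick <- wall_res[sort(pick_i)]
    sid <- sprintf("SITE%d", k)
    sites[[sid]] <- list(site_id = sid,
                         residues = data.frame(
                           chain = "A", resno = pick,
                           resname = atoms$resname[match(pick, atoms$resno)],
                           stringsAsFactors = FALSE))
  }
  truth <- list(
    n_tunnels = length(tunnels),
    seed = seed, spacing = spacing, ball_radius = ball_radius,
    tunnels = lapply(seq_along(tunnels), function(k) {
      tp <- tunnels[[k]]
      list(length = exits[[k]]$t_exit,
           tunnel_arc = exits[[k]]$t_exit - tp$cavity_radius,
           radius = tp$radius,
           bottleneck_radius = if (is.na(tp$bottleneck_radius)) tp$radius
                               else tp$bottleneck_radius,
           bottleneck_position = tp$bottleneck_t * tp$length,
           cavity_center = tp$cavity_center,
           cavity_radius = tp$cavity_radius,
           exit_point = exits[[k]]$point,
           annotated = isTRUE(tp$annotate),
           composition = lapply(res$planted[[k]]$composition, function(tb)
             as.list(setNames(as.integer(tb), names(tb)))))
    }))
  list(structure = s, sites = sites, truth = truth)
}

#' Generate a synthetic cohort with per-class lining compositions
#'
#' Structures get EC labels round-robin (EC1..EC6); each class draws its
#' lining residues from a stated multinomial. The default compositions make
#' EC1 markedly hydrophobic (Ile/Leu/Val/Phe-rich) and EC6 markedly
#' hydrophilic (Arg/Lys/Asp/Glu-rich), with the remaining classes mixed, so
#' that class-level physico-chemical orderings are recoverable from the
#' pipeline output. Geometry is drawn per structure: 1-2 tunnels, planted
#' channel length 20-34 A (comfortably above the 15 A report threshold, so
#' ground-truth occurrence is unambiguous under the measurement tolerance),
#' radius 2-3.5 A, with a bottleneck constriction on the first tunnel.
#'
#' @param n Number of structures.
#' @param seed Integer seed.
#' @param out_dir Directory to write PDB files, site CSVs, the manifest and
#'   ground-truth JSON into.
#' @param class_compositions Named list EC1..EC6 of named probability
#'   vectors over residue names (lining draw).
#' @param length_range,radius_range Uniform draw ranges for tunnel geometry.
#' @return List: `manifest` (path to manifest CSV), `entries` (data frame),
#'   `truths` (list of per-structure ground truths).
#' @export
make_cohort <- function(n, seed = 1, out_dir = tempfile("cohort"),
                        class_compositions = default_class_compositions(),
                        length_range = c(20, 34), radius_range = c(2, 3.5)) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ecs <- paste0("EC", 1:6)
  entries <- list()
  truths <- list()
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(k = sample(1:2, 1), len = stats::runif(2, length_range[1], length_range[2]),
           rad = stats::runif(2, radius_range[1], radius_range[2]),
           bnt = stats::runif(1, 0.35, 0.65),
           u = matrix(stats::rnorm(6), 2, 3),
           seed_i = sample.int(2^30, 1))
    })
  })
  for (i in seq_len(n)) {
    ec <- ecs[(i - 1L) %% 6L + 1L]
    comp <- class_compositions[[ec]]
    dr <- draws[[i]]
    dirs <- dr$u / sqrt(rowSums(dr$u^2))
    if (dr$k == 2 && sum(dirs[1, ] * dirs[2, ]) > 0.3) dirs[2, ] <- -dirs[2, ]
    specs <- lapply(seq_len(dr$k), function(j) {
      tunnel_spec(direction = dirs[j, ], length = dr$len[j], radius = dr$rad[j],
                  bottleneck_radius = if (j == 1) max(1.3, dr$rad[j] - 0.8) else NA,
                  bottleneck_t = dr$bnt,
                  lining = list(internal = comp, middle = comp, external = comp),
                  annotate = (j == 1))
    })
    sid <- sprintf("SYN%03d", i)
    synth <- make_tunnel_structure(specs, seed = dr$seed_i, id = sid)
    pdb <- file.path(out_dir, paste0(sid, ".pdb"))
    write_pdb(synth$structure, pdb)
    sites_csv <- file.path(out_dir, paste0(sid, "_sites.csv"))
    sdf <- do.call(rbind, lapply(synth$sites, function(st)
      cbind(structure_id = sid, site_id = st$site_id, st$residues)))
    write.csv(sdf, sites_csv, row.names = FALSE)
    entries[[i]] <- data.frame(structure_id = sid, ec = sub("EC", "", ec),
                               structure_path = basename(pdb),
                               sites_path = basename(sites_csv),
                               stringsAsFactors = FALSE)
    truths[[sid]] <- c(synth$truth, list(ec_class = ec))
  }
  entries <- do.call(rbind, entries)
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(entries, manifest, row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, entries = entries, truths = truths, dir = out_dir)
}

#' Default per-class lining compositions for synthetic cohorts
#'
#' @return Named list EC1..EC6 of named probability vectors.
#' @export
default_class_compositions <- function() {
  list(
    EC1 = c(ILE = .22, LEU = .20, VAL = .15, PHE = .12, ALA = .10, MET = .06,
            GLY = .05, SER = .05, TRP = .05),
    EC2 = c(GLY = .15, SER = .15, THR = .12, ALA = .12, ASN = .10, LEU = .10,
            HIS = .08, TYR = .08, ASP = .10),
    EC3 = c(HIS = .15, TYR = .15, TRP = .10, SER = .12, THR = .12, GLY = .12,
            ASN = .12, CYS = .12),
    EC4 = c(ALA = .15, GLY = .15, GLU = .12, LEU = .12, THR = .12, LYS = .12,
            PHE = .10, ASN = .12),
    EC5 = c(SER = .14, THR = .14, ASN = .14, GLN = .14, GLY = .14, ALA = .10,
            HIS = .10, TYR = .10),
    EC6 = c(ARG = .22, LYS = .20, ASP = .16, GLU = .16, ASN = .10, GLN = .06,
            SER = .05, GLY = .05)
  )
}
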