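# Internal helpers: python bridge, small geometry utilities, error builders.

chan_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "chanatomy_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Locate the python interpreter used for the Delaunay backend
#'
#' The triangulation step is delegated to Qhull through
#' `scipy.spatial.Delaunay`, run in a subprocess. The interpreter is taken
#' from the `CHANATOMY_PYTHON` environment variable when set, otherwise the
#' first of `python`/`python3` found on the `PATH`.
#'
#' @return Path to the interpreter executable.
#' @export
find_python <- function() {
  env <- Sys.getenv("CHANATOMY_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  chan_error("chanatomy_backend_error", "no python interpreter found on PATH")
}

# Delaunay tetrahedralization of an n x 3 coordinate matrix.
# Returns list(simplices = n_tet x 4 (1-based), neighbors = n_tet x 4
# (1-based, NA = convex hull face)), rows sorted deterministically by the
# sorted vertex-index quadruple.
delaunay_tets <- function(xyz) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  if (nrow(xyz) < 4)
    chan_error("chanatomy_triangulation_error", "need at least 4 atoms")
  ptf <- tempfile("pts", fileext = ".txt")
  otf <- tempfile("tet", fileext = ".txt")
  on.exit(unlink(c(ptf, otf)), add = TRUE)
  data.table::fwrite(data.table::as.data.table(xyz), ptf,
                     col.names = FALSE, sep = " ")
  script <- system.file("python", "delaunay.py", package = "chanatomy")
  err <- tempfile("delaunay_err")
  status <- system2(find_python(), c(shQuote(script), shQuote(ptf), shQuote(otf)),
                    stdout = FALSE, stderr = err)
  if (status != 0) {
    msg <- paste(readLines(err, warn = FALSE), collapse = "; ")
    chan_error("chanatomy_triangulation_error",
               paste0("Delaunay triangulation failed (degenerate input?): ", msg))
  }
  m <- as.matrix(data.table::fread(otf, header = FALSE))
  simp <- m[, 1:4, drop = FALSE] + 1L
  nbr <- m[, 5:8, drop = FALSE] + 1L
  nbr[nbr == 0L] <- NA_integer_
  # deterministic vertex ordering: sort tetrahedra by their sorted vertex ids
  key <- t(apply(simp, 1L, sort))
  ord <- do.call(order, as.data.frame(key))
  remap <- integer(nrow(simp))
  remap[ord] <- seq_len(nrow(simp))
  simp <- simp[ord, , drop = FALSE]
  nbr <- nbr[ord, , drop = FALSE]
  nbr[] <- remap[nbr]
  list(simplices = simp, neighbors = nbr)
}

# Circumcenters of tetrahedra (rows of simp index into xyz). Near-degenerate
# slivers fall back to the centroid; their clearance is still computed from
# the returned position, so the clearance/position invariant holds regardless.
tet_circumcenters <- function(xyz, simp) {
  a <- xyz[simp[, 1], , drop = FALSE]
  b <- xyz[simp[, 2], , drop = FALSE] - a
  c_ <- xyz[simp[, 3], , drop = FALSE] - a
  d <- xyz[simp[, 4], , drop = FALSE] - a
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  sq <- function(u) rowSums(u * u)
  cd <- cross(c_, d)
  db <- cross(d, b)
  bc <- cross(b, c_)
  det2 <- 2 * rowSums(b * cd)
  num <- sq(b) * cd + sq(c_) * db + sq(d) * bc
  scale <- pmax(sq(b), sq(c_), sq(d))
  bad <- !is.finite(det2) | abs(det2) < 1e-9 * scale
  det2[bad] <- 1 # placeholder, overwritten below
  cc <- a + num / det2
  # near-flat slivers put the circumcenter astronomically far out; cap at a
  # generous multiple of the local tetrahedron size (these vertices sit in
  # bulk solvent or junk space and never carry traversable edges)
  r2 <- rowSums((cc - a)^2)
  bad <- bad | !is.finite(r2) | r2 > (1e3)^2
  if (any(bad)) cc[bad, ] <- (a + (b + c_ + d) / 4)[bad, , drop = FALSE]
  cc
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# arc-length share of each polyline point: half of each adjacent segment
point_arc_share <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(0)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  share <- numeric(n)
  share[1] <- seg[1] / 2
  share[n] <- seg[n - 1] / 2
  if (n > 2) share[2:(n - 1)] <- (seg[-1] + seg[-(n - 1)]) / 2
  share
}

`%||%` <- function(a, b) if (is.null(a)) b else a
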