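test_that("generation is deterministic: same seed, byte-identical PDB", {
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(quick_tunnel(seed = 8)$structure, f1)
  write_pdb(quick_tunnel(seed = 8)$structure, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  f3 <- tempfile(fileext = ".pdb")
  write_pdb(quick_tunnel(seed = 9)$structure, f3)
  expect_false(identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3))))
})

test_that("the carved void honours the planted radius profile", {
  spec <- tunnel_spec(direction = c(1, 0, 0), length = 24, radius = 2.6,
                      bottleneck_radius = 1.7, cavity_radius = 5)
  syn <- make_tunnel_structure(spec, seed = 19, id = "carve")
  tr <- syn$truth$tunnels[[1]]
  ts <- seq(spec$cavity_radius, tr$length - 1, by = 0.5)
  pts <- t(vapply(ts, function(t) t * c(1, 0, 0), numeric(3)))
  clr <- point_clearance(pts, syn$structure)
  rt <- chanatomy:::tunnel_radius_at(spec, ts)
  expect_true(all(clr >= rt - 1e-9))
  # cavity center is at least cavity_radius clear
  expect_gte(point_clearance(c(0, 0, 0), syn$structure), 5)
  # and the planted bottleneck is realized, not just bounded
  expect_lt(min(clr) - 1.7, 0.4) # within granularity of the planted 1.7
})

test_that("tunnel specs validate traversability and exit separation", {
  expect_error(tunnel_spec(radius = 1.0), class = "chanatomy_value_error")
  expect_error(tunnel_spec(bottleneck_radius = 0.8), class = "chanatomy_value_error")
  close_pair <- list(tunnel_spec(direction = c(1, 0, 0), length = 25),
                     tunnel_spec(direction = c(1, 0.1, 0), length = 25))
  expect_error(make_tunnel_structure(close_pair, seed = 1),
               class = "chanatomy_generation_error")
})

test_that("the pipeline recovers a planted tunnel end to end", {
  syn <- quick_tunnel(seed = 3, length = 26, radius = 2.6, bottleneck = 1.9)
  rec <- analyze_structure(syn$structure, syn$sites)
  expect_gte(length(rec$channels), 1)
  ch <- rec$channels[[1]]
  tr <- syn$truth$tunnels[[1]]
  expect_lte(abs(ch$length - tr$length), max(4.5, 0.15 * tr$length))
  expect_lte(abs(ch$bottleneck$radius - tr$bottleneck_radius), 0.75)
})

test_that("detected lining identities agree with the plant by weight", {
  aa19 <- setdiff(property_scales()$aa, "TRP")
  syn <- make_tunnel_structure(
    tunnel_spec(direction = c(0, 0, 1), length = 24, radius = 2.5,
                bottleneck_radius = 1.8, cavity_radius = 5,
                lining = list(internal = "TRP", middle = "TRP",
                              external = "TRP", bottleneck = "TRP")),
    seed = 47, id = "ident",
    filler_composition = setNames(rep(1 / 19, 19), aa19))
  rec <- analyze_structure(syn$structure, syn$sites)
  lin <- rec$channels[[1]]$lining
  agree <- sum(lin$weight[lin$resname == "TRP"]) / sum(lin$weight)
  expect_gte(agree, 0.9)
})

test_that("annotated and unannotated cavities differ between modes", {
  # two cavities with radially outward tunnels (a tunnel always reaches the
  # packing surface, so inward-pointing specs would cross the ball)
  specs <- list(
    tunnel_spec(direction = c(-1, 0, 0), length = 22, cavity_radius = 5,
                cavity_center = c(-14, 0, 0), annotate = TRUE),
    tunnel_spec(direction = c(1, 0, 1), length = 22, cavity_radius = 5,
                cavity_center = c(10, 0, 10), annotate = FALSE))
  syn <- make_tunnel_structure(specs, seed = 21, ball_radius = 34, id = "two")
  expect_length(syn$sites, 1)
  rec <- analyze_structure(syn$structure, syn$sites, generic = TRUE)
  # active-site mode only reports the annotated cavity's channels
  expect_gte(length(rec$channels), 1)
  starts <- t(sapply(rec$channels, function(ch) ch$centerline[1, ]))
  expect_true(all(sqrt(rowSums(sweep(starts, 2, c(-14, 0, 0))^2)) < 8))
  # generic mode reaches both cavities
  gstarts <- t(sapply(rec$generic, function(ch) ch$centerline[1, ]))
  d_a <- sqrt(rowSums(sweep(gstarts, 2, c(-14, 0, 0))^2))
  d_b <- sqrt(rowSums(sweep(gstarts, 2, c(10, 0, 10))^2))
  expect_true(any(d_a < 8))
  expect_true(any(d_b < 8))
})

test_that("cohort generation writes a consumable manifest with ground truth", {
  co <- make_cohort(1, seed = 6, out_dir = tempfile("co1"))
  m <- load_manifest(co$manifest)
  expect_equal(nrow(m), 1)
  expect_true(all(m$pass))
  expect_true(file.exists(m$structure_path))
  expect_true(file.exists(m$sites_path))
  expect_true(file.exists(file.path(co$dir, "truth.json")))
  tr <- jsonlite::read_json(file.path(co$dir, "truth.json"))
  expect_equal(length(tr), 1)
  expect_equal(tr[[1]]$ec_class, "EC1")
})

test_that("hydrophobic vs hydrophilic lining plans order the class hydropathy", {
  comps <- default_class_compositions()
  mk <- function(comp, seed) {
    syn <- make_tunnel_structure(
      tunnel_spec(direction = c(0, 1, 0), length = 20, radius = 2.5,
                  cavity_radius = 5,
                  lining = list(internal = comp, middle = comp, external = comp)),
      seed = seed, id = "cls")
    rec <- analyze_structure(syn$structure, syn$sites)
    rec$channels[[1]]$physchem$hydropathy
  }
  h_phob <- mk(comps$EC1, 51)
  h_phil <- mk(comps$EC6, 52)
  expect_gt(h_phob, 1)
  expect_lt(h_phil, -1)
})
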