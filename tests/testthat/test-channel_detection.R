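test_that("channel parameters validate their ranges", {
  p <- channel_params()
  expect_equal(p$probe_radius, 5)
  expect_equal(p$origin_radius, 5)
  expect_equal(p$interior_threshold, 1.1)
  expect_error(channel_params(probe_radius = -1), class = "chanatomy_value_error")
  expect_error(channel_params(cutoff_ratio = 0), class = "chanatomy_value_error")
})

test_that("Dijkstra on a path graph returns the path and its summed weight", {
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  g <- fake_void_graph(pos,
                       data.frame(from = c(1, 2), to = c(2, 3), weight = c(2, 7)),
                       status = c("interior", "interior", "boundary"))
  paths <- shortest_channels(g, 1, exits = 3L)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$vertices, 1:3)
  expect_equal(paths[[1]]$cost, 9)
})

test_that("Dijkstra cost matches exhaustive enumeration on random small graphs", {
  for (seed in 1:25) {
    gr <- withr::with_seed(seed, {
      nv <- sample(4:10, 1)
      ne <- sample(nv:(nv * (nv - 1) / 2), 1)
      all_pairs <- t(combn(nv, 2))
      pick <- sample(nrow(all_pairs), ne)
      list(nv = nv,
           edges = data.frame(from = all_pairs[pick, 1], to = all_pairs[pick, 2],
                              weight = round(stats::runif(ne, 0.1, 5), 3)),
           pos = matrix(stats::runif(nv * 3, 0, 100), ncol = 3))
    })
    status <- rep("interior", gr$nv)
    status[gr$nv] <- "boundary"
    g <- fake_void_graph(gr$pos, gr$edges, status = status)
    got <- shortest_channels(g, 1, exits = gr$nv)
    want <- brute_force_cost(gr$nv, gr$edges, 1, gr$nv)
    if (!length(got)) {
      expect_true(is.infinite(want))
    } else {
      expect_equal(got[[1]]$cost, want, tolerance = 1e-12)
    }
  }
})

test_that("exits within the surface cover radius collapse to one channel", {
  # start 1; exits 4 and 5 sit 4 A apart (< 10 A cover radius)
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(30, 0, 0), c(30, 4, 0))
  edges <- data.frame(from = c(1, 2, 3, 3), to = c(2, 3, 4, 5),
                      weight = c(1, 1, 1, 2))
  g <- fake_void_graph(pos, edges,
                       status = c(rep("interior", 3), "boundary", "boundary"))
  paths <- shortest_channels(g, 1)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$vertices, 1:4) # the cheaper exit wins
})

test_that("paths through an earlier surface contact are discarded", {
  # 1 -> 2 -> 3(boundary) -> 4(boundary, 30 A away)
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(50, 0, 0))
  edges <- data.frame(from = c(1, 2, 3), to = c(2, 3, 4), weight = c(1, 1, 1))
  g <- fake_void_graph(pos, edges,
                       status = c("interior", "interior", "boundary", "boundary"))
  paths <- shortest_channels(g, 1)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$vertices, 1:3)
})

test_that("channel filters: sub-threshold flag, overlap and narrow-run drops", {
  # straight corridor of vertices 1 A apart, generous clearance
  n <- 31
  pos <- cbind(seq(0, 30), 0, 0)
  edges <- data.frame(from = 1:(n - 1), to = 2:n, weight = rep(1, n - 1))
  g <- fake_void_graph(pos, edges, clearance = rep(3, n))
  p_long <- list(vertices = 1:n, cost = 30)
  p_short <- list(vertices = 1:13, cost = 12)
  chans <- refine_and_filter(list(p_long, p_short), g, NULL,
                             channel_params(surface_cover_radius = 0.5,
                                            cutoff_ratio = 0.99))
  expect_length(chans, 2)
  # kept channels come back in cost order: the 12 A path first
  expect_true(chans[[1]]$sub_threshold)  # 12 A < 15 A
  expect_false(chans[[2]]$sub_threshold) # 30 A

  # overlap: shares 8/10 vertices (0.8 > 0.7) with the kept cheaper path
  p_a <- list(vertices = 1:10, cost = 9)
  p_b <- list(vertices = c(1:8, 12, 13), cost = 11)
  chans <- refine_and_filter(list(p_a, p_b), g, NULL,
                             channel_params(surface_cover_radius = 0.5))
  expect_length(chans, 1)
  expect_equal(chans[[1]]$vertices, 1:10)

  # sustained narrow stretch: radius < 1.25 A over 4 A of arc
  clr <- rep(3, n); clr[10:14] <- 1.0
  g2 <- fake_void_graph(pos, edges, clearance = clr)
  chans <- refine_and_filter(list(p_long), g2, NULL, channel_params())
  expect_length(chans, 0)
})

test_that("raising the report length never increases the qualifying count", {
  syn <- quick_tunnel(seed = 23, length = 24)
  g <- mark_exterior(build_void_graph(syn$structure))
  st <- locate_start(g, syn$structure, c(syn$sites[[1]], list(copy = 0L)))
  paths <- shortest_channels(g, st)
  counts <- sapply(c(5, 10, 15, 20, 30), function(L) {
    chs <- refine_and_filter(paths, g, syn$structure,
                             channel_params(min_report_length = L))
    sum(!vapply(chs, `[[`, logical(1), "sub_threshold"))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("the start vertex prefers the roomy apex and deeper ties", {
  s <- make_test_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(40, 40, 40)))
  pos <- rbind(c(1, 1, 0), c(1.5, 1, 0), c(30, 30, 30))
  g <- fake_void_graph(pos, data.frame(from = c(1, 2), to = c(2, 3), weight = 1),
                       clearance = c(2, 2, 2), depth = c(5, 2, 0))
  site <- list(site_id = "S1",
               residues = data.frame(chain = "A", resno = 1:3,
                                     resname = "ALA"))
  st <- locate_start(g, s, site, channel_params())
  expect_equal(st$vertex, 1L) # clearance tie -> depth 5 beats depth 2
  g2 <- fake_void_graph(pos, data.frame(from = c(1, 2), to = c(2, 3), weight = 1),
                        clearance = c(2, 3.5, 2), depth = c(5, 2, 0))
  expect_equal(locate_start(g2, s, site, channel_params())$vertex, 2L)
})

test_that("unreachable sites raise the dedicated error", {
  s <- make_test_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(40, 40, 40)))
  g <- fake_void_graph(rbind(c(100, 100, 100)),
                       data.frame(from = integer(0), to = integer(0),
                                  weight = numeric(0)))
  site <- list(site_id = "S1",
               residues = data.frame(chain = "A", resno = 1, resname = "ALA"))
  expect_error(locate_start(g, s, site, channel_params()),
               class = "chanatomy_site_unreachable")
})

test_that("site selection follows count, then total length, then id", {
  ch <- function(L) {
    c0 <- fake_channel(cbind(seq(0, L, length.out = 5), 0, 0), rep(2, 5))
    c0$sub_threshold <- L < 15
    c0
  }
  expect_equal(select_site(list(a = list(ch(20), ch(20)),
                                b = list(ch(20), ch(20), ch(20), ch(18), ch(19)))),
               "b")
  expect_equal(select_site(list(a = list(ch(20), ch(20), ch(20)),
                                b = list(ch(30), ch(30), ch(20)))), "b")
  expect_equal(select_site(list(only = list(ch(16)))), "only")
  # sub-threshold channels do not count
  expect_equal(select_site(list(a = list(ch(10), ch(10), ch(10)),
                                b = list(ch(16)))), "b")
})
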