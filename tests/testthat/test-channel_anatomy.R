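test_that("channel measurement gives polyline length and per-point radii", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 10), c(0, 0, 20))
  g <- fake_void_graph(pos, data.frame(from = 1:2, to = 2:3, weight = 1),
                       clearance = c(2, 1.5, 2.5))
  ch <- measure_channel(list(vertices = 1:3, cost = 2), g)
  expect_equal(ch$length, 20)
  expect_equal(ch$radii, c(2, 1.5, 2.5))
  expect_false(ch$degenerate)

  # right-angle path: length exceeds the straight chord
  pos2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  g2 <- fake_void_graph(pos2, data.frame(from = 1:2, to = 2:3, weight = 1))
  ch2 <- measure_channel(list(vertices = 1:3, cost = 2), g2)
  expect_equal(ch2$length, 20)
  chord <- sqrt(sum((pos2[3, ] - pos2[1, ])^2))
  expect_equal(chord, 14.1421356, tolerance = 1e-6)
  expect_gte(ch2$length, chord)

  ch3 <- measure_channel(list(vertices = 1L, cost = 0), g)
  expect_true(ch3$degenerate)
})

test_that("the bottleneck is the first global radius minimum", {
  mk <- function(r) fake_channel(cbind(seq_along(r), 0, 0), r)
  bn <- find_bottleneck(mk(c(3.0, 1.4, 2.5)))
  expect_equal(bn$index, 2L)
  expect_equal(bn$radius, 1.4)
  bn2 <- find_bottleneck(mk(c(2, 2, 2)))
  expect_equal(bn2$index, 1L)
  expect_equal(bn2$radius, 2)
  # bottleneck radius bounds the whole profile
  r <- c(2.5, 1.9, 3.1, 1.7, 2.2)
  expect_true(all(find_bottleneck(mk(r))$radius <= r))
})

test_that("local minima respect the plateau and endpoint rules", {
  mk <- function(r) fake_channel(cbind(seq_along(r), 0, 0), r)
  expect_equal(find_local_minima(mk(c(3, 2, 2.5, 1.8, 2.2))), c(2L, 4L))
  expect_equal(find_local_minima(mk(c(1, 2, 3, 4))), integer(0))
  expect_equal(find_local_minima(mk(c(3, 2, 2, 3))), 2L)
  expect_equal(find_local_minima(mk(c(3, 2))), integer(0))
  expect_equal(find_local_minima(mk(c(2, 1, 2))), 2L)
})

test_that("lining inclusion follows the contact threshold arithmetic", {
  # one centerline point with radius 2.5; carbon atom (vdw 1.7), tolerance 1:
  # cutoff = 2.5 + 1.7 + 1.0 = 5.2
  ch <- fake_channel(rbind(c(0, 0, 0), c(0, 0, 4)), c(2.5, 2.5))
  s_in <- make_test_structure(rbind(c(5.0, 0, 0), c(30, 30, 30), c(31, 30, 30),
                                    c(30, 31, 30)))
  lin <- lining_residues(ch, s_in, contact_tolerance = 1.0)
  expect_equal(lin$resno, 1L)
  s_out <- make_test_structure(rbind(c(6.2, 0, 0), c(30, 30, 30), c(31, 30, 30),
                                     c(30, 31, 30)))
  expect_equal(nrow(lining_residues(ch, s_out, contact_tolerance = 1.0)), 0)
  # monotone in the tolerance
  s3 <- make_test_structure(rbind(c(5.0, 0, 0), c(5.9, 0, 2), c(30, 30, 30),
                                  c(31, 30, 30)))
  l_small <- lining_residues(ch, s3, contact_tolerance = 0.2)
  l_big <- lining_residues(ch, s3, contact_tolerance = 1.8)
  expect_true(all(l_small$resno %in% l_big$resno))
  expect_gte(nrow(l_big), nrow(l_small))
})

test_that("lining weights are arc-length fractions in (0, 1]", {
  syn <- quick_tunnel(seed = 29, length = 20)
  rec <- analyze_structure(syn$structure, syn$sites)
  lin <- rec$channels[[1]]$lining
  expect_gt(nrow(lin), 10)
  expect_true(all(lin$weight > 0 & lin$weight <= 1))
})

test_that("layers partition the lining with start precedence", {
  n <- 31
  ch <- fake_channel(cbind(seq(0, 30), 0, 0), rep(2.5, n))
  atoms <- rbind(c(2, 3, 0),    # near start -> internal
                 c(15, 3, 0),   # midpoint -> middle
                 c(29, 3, 0),   # near end -> external
                 c(-20, -20, -20))
  s <- make_test_structure(atoms)
  lin <- assign_layers(lining_residues(ch, s), ch)
  lin <- lin[order(lin$resno), ]
  expect_equal(lin$layer[lin$resno == 1], "internal")
  expect_equal(lin$layer[lin$resno == 2], "middle")
  expect_equal(lin$layer[lin$resno == 3], "external")
  expect_setequal(lin$resno, 1:3)

  # short channel: a midpoint within 5 A of both ends is internal
  ch8 <- fake_channel(cbind(seq(0, 8), 0, 0), rep(2.5, 9))
  s8 <- make_test_structure(rbind(c(4, 3, 0), c(-20, -20, -20),
                                  c(-21, -20, -20), c(-20, -21, -20)))
  lin8 <- assign_layers(lining_residues(ch8, s8), ch8)
  expect_equal(lin8$layer[lin8$resno == 1], "internal")
})

test_that("reversing a channel swaps internal and external layers only", {
  syn <- quick_tunnel(seed = 37, length = 20)
  rec <- analyze_structure(syn$structure, syn$sites)
  ch <- rec$channels[[1]]
  rev_ch <- ch
  rev_ch$centerline <- ch$centerline[nrow(ch$centerline):1, , drop = FALSE]
  rev_ch$radii <- rev(ch$radii)
  lin_f <- assign_layers(lining_residues(ch, syn$structure), ch)
  lin_r <- assign_layers(lining_residues(rev_ch, syn$structure), rev_ch)
  key <- function(d) paste(d$chain, d$resno)
  expect_setequal(key(lin_f), key(lin_r))
  m <- match(key(lin_f), key(lin_r))
  swap <- c(internal = "external", middle = "middle", external = "internal")
  expect_equal(unname(swap[lin_f$layer]), lin_r$layer[m])
  # partition property
  expect_true(all(lin_f$layer %in% c("internal", "middle", "external")))
})
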