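test_that("residue frequencies normalize to one", {
  f <- residue_frequencies(c("ALA", "ALA", "ALA", "GLY"))
  expect_equal(unname(f[c("ALA", "GLY")]), c(0.75, 0.25))
  expect_equal(sum(f), 1)
  expect_equal(unname(residue_frequencies("TRP")), 1)
  pooled <- residue_frequencies(c("ALA", "GLY")) # two one-residue structures pooled
  expect_equal(unname(pooled), c(0.5, 0.5))
  expect_error(residue_frequencies(character(0)), class = "chanatomy_value_error")
  # property check on random multisets
  withr::with_seed(3, {
    for (i in 1:10) {
      x <- sample(property_scales()$aa, sample(5:50, 1), replace = TRUE)
      expect_equal(sum(residue_frequencies(x)), 1, tolerance = 1e-9)
    }
  })
})

test_that("propensity is region over background with undefined flags", {
  p <- propensity(c(HIS = 0.05, ALA = 0.95), c(HIS = 0.025, ALA = 0.975))
  expect_equal(p$propensity[p$aa == "HIS"], 2)
  same <- residue_frequencies(c("ALA", "GLY", "HIS", "ALA"))
  p2 <- propensity(same, same)
  expect_true(all(p2$propensity == 1))
  p3 <- propensity(c(TRP = 0.01, ALA = 0.99), c(ALA = 1))
  expect_true(p3$undefined[p3$aa == "TRP"])
  expect_true(is.na(p3$propensity[p3$aa == "TRP"]))
})

test_that("cohort summaries reproduce hand-computed P, M and L", {
  recs <- list(fake_record("a", "EC1", 1000, c(20, 25)),
               fake_record("b", "EC1", 2000, c(18, 22, 30)),
               fake_record("c", "EC1", 1500, rep(20, 68)))
  su <- summarize_cohort(recs)
  allr <- su$table[su$table$ec_class == "All", ]
  expect_equal(allr$M, 3) # median of {2, 3, 68}
  expect_equal(allr$P, 100)
  expect_equal(allr$Na, 1500)

  # one channel-free record: excluded from M/L but in the P denominator
  recs10 <- c(lapply(1:9, function(i)
    fake_record(paste0("r", i), "EC2", 1000, c(16, 17))),
    list(fake_record("r10", "EC2", 1000, numeric(0))))
  su10 <- summarize_cohort(recs10)
  allr10 <- su10$table[su10$table$ec_class == "All", ]
  expect_equal(allr10$P, 90)
  expect_equal(allr10$M, 2)
  expect_equal(allr10$L, 16.5)

  # sub-threshold channels count toward the lower length thresholds only
  recs2 <- list(fake_record("x", "EC3", 500, c(7, 12)),
                fake_record("y", "EC3", 500, c(24)))
  t2 <- summarize_cohort(recs2)$table
  a2 <- t2[t2$ec_class == "All", ]
  expect_equal(unlist(a2[c("n_ge5", "n_ge10", "n_ge15", "n_ge20")],
                      use.names = FALSE), c(2, 2, 1, 1))
  expect_equal(a2$P, 50)
  # threshold counts non-increasing
  expect_true(all(diff(unlist(a2[c("n_ge5", "n_ge10", "n_ge15", "n_ge20")])) <= 0))
})

test_that("per-class rows and extremes are reported", {
  recs <- c(lapply(1:3, function(i)
    fake_record(paste0("e1_", i), "EC1", 1000, 20 + i, hydropathy = 2 + i / 10)),
    lapply(1:3, function(i)
      fake_record(paste0("e6_", i), "EC6", 1000, 20 + i, hydropathy = -3 - i / 10)))
  su <- summarize_cohort(recs)
  expect_setequal(su$table$ec_class, c("EC1", "EC6", "All"))
  h1 <- su$table$hydropathy[su$table$ec_class == "EC1"]
  h6 <- su$table$hydropathy[su$table$ec_class == "EC6"]
  expect_gt(h1, h6)
  expect_equal(su$extremes$hydrophobic$hydropathy[1], 2.3)
  expect_equal(su$extremes$hydrophilic$hydropathy[1], -3.3)
  expect_true(su$table$hydropathy_sem[su$table$ec_class == "All"] > 0)
})

test_that("compartment classification respects precedence and burial", {
  # 3-residue fully exposed peptide -> everything surface
  s <- make_test_structure(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                                 c(3.8, 3.8, 0)))
  cls <- classify_compartments(s)
  expect_true(all(cls$compartment == "surface"))

  # dense ball: central residue interior, shell residues surface
  gr <- as.matrix(expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3),
                              z = seq(-6, 6, 3)))
  sb <- make_test_structure(gr)
  clsb <- classify_compartments(sb)
  central <- which(gr[, 1] == 0 & gr[, 2] == 0 & gr[, 3] == 0)
  corner <- which(gr[, 1] == -6 & gr[, 2] == -6 & gr[, 3] == -6)
  expect_equal(clsb$compartment[clsb$resno == central], "interior")
  expect_equal(clsb$compartment[clsb$resno == corner], "surface")

  # precedence: site beats channel wall beats surface
  ch <- fake_channel(rbind(c(0, 0, 3), c(7.6, 0, 3)), c(2, 2))
  ch$lining <- data.frame(chain = "A", resno = c(1, 2), icode = "",
                          resname = "ALA", copy = 0L, weight = 1,
                          closest_index = 1L, touches_bottleneck = FALSE,
                          touches_local_minimum = FALSE, layer = "middle")
  site <- list(site_id = "S", residues = data.frame(chain = "A", resno = 1,
                                                    resname = "ALA"))
  cls2 <- classify_compartments(s, channels = list(ch), sites = list(site))
  expect_equal(cls2$compartment[cls2$resno == 1], "active_site")
  expect_equal(cls2$compartment[cls2$resno == 2], "channel_wall")
  expect_equal(cls2$compartment[cls2$resno == 3], "surface")
})

test_that("planted compositions drive bottleneck and layer propensities", {
  # all-Cys bottleneck gates, neutral layers
  syn_bn <- make_tunnel_structure(
    tunnel_spec(direction = c(1, 0, 0), length = 22, radius = 2.5,
                bottleneck_radius = 1.8, cavity_radius = 5,
                lining = list(bottleneck = "CYS")),
    seed = 41, id = "plant_bn")
  rec_bn <- analyze_structure(syn_bn$structure, syn_bn$sites)
  rec_bn$ec_class <- "EC1"
  comp_bn <- bottleneck_and_layer_composition(list(rec_bn))
  expect_equal(comp_bn$bottleneck$aa[which.max(comp_bn$bottleneck$propensity)],
               "CYS")
  expect_gt(comp_bn$bottleneck$propensity[comp_bn$bottleneck$aa == "CYS"], 1)

  # one residue type per layer (the bottleneck gates inherit the middle plan)
  syn <- make_tunnel_structure(
    tunnel_spec(direction = c(1, 0, 0), length = 22, radius = 2.5,
                bottleneck_radius = 1.8, cavity_radius = 5,
                lining = list(internal = "HIS", middle = "GLY",
                              external = "ARG")),
    seed = 41, id = "plant")
  rec <- analyze_structure(syn$structure, syn$sites)
  rec$ec_class <- "EC1"
  comp <- bottleneck_and_layer_composition(list(rec))
  expect_equal(comp$internal$aa[which.max(comp$internal$propensity)], "HIS")
  expect_equal(comp$middle$aa[which.max(comp$middle$propensity)], "GLY")
  expect_equal(comp$external$aa[which.max(comp$external$propensity)], "ARG")
})
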