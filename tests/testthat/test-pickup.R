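pro6 <- proprioception_classes()

test_that("pickup weight decays with distance and respects ring symmetry", {
  lay16 <- build_cuff_layout("cuff16")
  # fascicle directly under the 0-degree contacts vs the opposite side
  site <- nerve_site_model("distal",
                           list(fascicle_spec("f", c(0.3, 0), 0.1)),
                           matrix(1, 1, 6))
  W <- compute_pickup_weights(lay16, site)
  near <- lay16$contacts$angular_pos == 0
  far <- lay16$contacts$angular_pos == 180
  expect_true(all(W[near, 1] > W[far, 1]))
  expect_true(all(W > 0 & W <= 1))
  # centred fascicle: the four contacts of any ring see identical weights
  site0 <- nerve_site_model("proximal",
                            list(fascicle_spec("f", c(0, 0), 0.1)),
                            matrix(1, 1, 6))
  W0 <- compute_pickup_weights(lay16, site0)
  expect_equal(diff(range(W0)), 0)
})

test_that("36-point ring average matches a dense quadrature oracle", {
  lay3 <- build_cuff_layout("cuff3")
  site <- nerve_site_model("distal",
                           list(fascicle_spec("f", c(0.3, 0), 0.1)),
                           matrix(1, 1, 6))
  W36 <- compute_pickup_weights(lay3, site)
  Wdense <- compute_pickup_weights(lay3, site, n_ring_points = 3600L)
  expect_lt(max(abs(W36 - Wdense) / Wdense), 1e-3)
})

test_that("ring weights are invariant to fascicle rotation about the axis", {
  lay3 <- build_cuff_layout("cuff3")
  w_at <- function(theta) {
    ctr <- 0.3 * c(cos(theta), sin(theta))
    site <- nerve_site_model("distal", list(fascicle_spec("f", ctr, 0.1)),
                             matrix(1, 1, 6))
    compute_pickup_weights(lay3, site)[1, 1]
  }
  ws <- vapply(seq(0, 2 * pi, length.out = 13), w_at, numeric(1))
  expect_lt(diff(range(ws)) / mean(ws), 1e-3)
})

test_that("default geometry separates fascicles distally but not proximally", {
  lay16 <- build_cuff_layout("cuff16")
  ratio_spread <- function(site) {
    W <- compute_pickup_weights(lay16, site)
    ring1 <- lay16$contacts$axial_pos == lay16$contacts$axial_pos[1]
    r <- W[ring1, "tibial"] / W[ring1, "peroneal"]
    max(r) / min(r)
  }
  expect_gte(ratio_spread(default_nerve_site("distal", pro6)), 2)
  expect_lte(ratio_spread(default_nerve_site("proximal", pro6)), 1.2)
})

test_that("invalid pickup parameters and geometry are rejected", {
  fas <- list(fascicle_spec("f", c(0.2, 0), 0.1))
  expect_error(nerve_site_model("distal", fas, matrix(1, 1, 2),
                                pickup_d0 = 0), "pickup_d0")
  expect_error(nerve_site_model("distal", fas, matrix(1, 1, 2),
                                pickup_gamma = -1), "pickup_gamma")
  expect_error(nerve_site_model("distal", fas, matrix(-1, 1, 2)), "gains")
  # fascicle poking out of the nerve
  expect_error(
    nerve_site_model("distal", list(fascicle_spec("f", c(0.45, 0), 0.1)),
                     matrix(1, 1, 2)),
    "does not fit")
  # gain matrix row count must match fascicles
  expect_error(nerve_site_model("distal", fas, matrix(1, 2, 2)),
               "one row per fascicle")
})
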