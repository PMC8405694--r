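test_that("area per lipid is box area over leaflet count, averaged over frames", {
  spec <- bilayer_spec(128, 8, 8, n_frames = 1, seed = 1)
  tr <- generate_bilayer(spec)
  expect_equal(area_per_lipid(tr)$mean, 0.5)
  # explicit N overrides the leaflet count; halving N doubles APL
  expect_equal(area_per_lipid(tr, n_per_leaflet = 64)$mean, 1.0)
  # two frames with different per-frame values average
  tr2 <- tr
  tr2[[2L]] <- tr[[1L]]
  tr2[[2L]]$box[c("lx", "ly")] <- c(8 * 0.6, 8)  # 0.30 nm^2 per lipid
  est <- area_per_lipid(tr2)
  expect_equal(est$mean, mean(c(0.5, 0.3)))
  expect_equal(est$n_frames, 2L)
  expect_error(area_per_lipid(tr, n_per_leaflet = 0), class = "undefined_metric")
})

test_that("APL scales linearly with box area at fixed lipid count", {
  areas <- c(1, 2, 4)
  vals <- vapply(areas, function(s) {
    spec <- bilayer_spec(16, 4 * s, 4, n_frames = 1, seed = 1)
    area_per_lipid(generate_bilayer(spec))$mean
  }, numeric(1))
  expect_equal(vals / vals[1L], areas)
})

test_that("membrane thickness matches phosphate-plane separation and is
           translation invariant", {
  spec <- bilayer_spec(32, 5, 5, phosphate_z_upper = 2.16,
                       phosphate_z_lower = -2.16, n_frames = 3, seed = 2)
  tr <- generate_bilayer(spec)
  expect_equal(membrane_thickness(tr)$mean, 4.32)
  # rigid shift in z changes nothing (leaflets found from geometry)
  shifted <- lapply(tr, function(fr) { fr$atoms$z <- fr$atoms$z + 5; fr })
  expect_equal(membrane_thickness(shifted)$mean, 4.32)
  # flipping the frame upside-down still gives a positive thickness
  flipped <- lapply(tr, function(fr) { fr$atoms$z <- -fr$atoms$z; fr })
  expect_equal(membrane_thickness(flipped)$mean, 4.32)
})

test_that("thickness estimate converges at the CLT rate under jitter", {
  spec <- bilayer_spec(40, 6, 6, phosphate_z_upper = 2.2325,
                       phosphate_z_lower = -2.2325,
                       phosphate_z_jitter_sd = 0.05,
                       chain_carbons = 2, n_frames = 100, seed = 33)
  est <- membrane_thickness(generate_bilayer(spec))
  # sd of the estimator: jitter * sqrt(2 / (n_per_leaflet * n_frames))
  bound <- 3 * 0.05 * sqrt(2 / (40 * 100))
  expect_lt(abs(est$mean - 4.465), bound)
  expect_lt(abs(est$mean - 4.465), 0.01)
})

test_that("order parameter matches the closed form for fixed tilt angles", {
  for (ang in c(0, 45, 90, 30, 60)) {
    spec <- bilayer_spec(8, 3, 3, ch_tilt_mode = "fixed_angle",
                         tilt_angle_deg = ang, chain_carbons = 4,
                         n_frames = 2, seed = 4)
    est <- order_parameter(generate_bilayer(spec))
    expect_equal(est$mean, 0.5 * (3 * cos(ang * pi / 180)^2 - 1),
                 tolerance = 1e-12, info = paste("angle", ang))
    expect_true(est$mean >= -0.5 && est$mean <= 1)
  }
})

test_that("wobble-cone orientations give the same S_CD as the fixed angle", {
  spec <- bilayer_spec(8, 3, 3, ch_tilt_mode = "wobble_cone",
                       tilt_angle_deg = 45, chain_carbons = 4,
                       n_frames = 2, seed = 4)
  expect_equal(order_parameter(generate_bilayer(spec))$mean, 0.25,
               tolerance = 1e-12)
})

test_that("isotropic C-H orientations give S_CD near zero", {
  # 2 leaflets x 128 lipids x 20 carbons x 2 H = 10240 bonds per frame
  spec <- bilayer_spec(128, 8, 8, ch_tilt_mode = "isotropic",
                       chain_carbons = 20, n_frames = 10, seed = 9)
  est <- order_parameter(generate_bilayer(spec))
  expect_lt(abs(est$mean), 0.01)
})

test_that("per-carbon profile and chain-position selection are consistent", {
  spec <- bilayer_spec(8, 3, 3, tilt_angle_deg = 45, chain_carbons = 6,
                       n_frames = 2, seed = 4)
  tr <- generate_bilayer(spec)
  est <- order_parameter(tr)
  expect_equal(nrow(est$per_carbon_profile), 6L)
  expect_equal(est$per_carbon_profile$mean, rep(0.25, 6), tolerance = 1e-12)
  sel <- order_parameter(tr, chain_positions = 2:3)
  expect_equal(sel$mean, 0.25, tolerance = 1e-12)
  expect_error(order_parameter(tr, chain_positions = 99),
               class = "undefined_metric")
})

test_that("replicate summary uses the first k replicates only", {
  mk <- function(v) property_estimate("APL", v)
  est <- replicate_summary(list(mk(0.54), mk(0.53), mk(0.55)), k = 3)
  expect_equal(est$mean, 0.540)
  expect_equal(est$sd, 0.010)
  # identical replicates: zero spread
  expect_equal(replicate_summary(list(mk(0.5), mk(0.5), mk(0.5)))$sd, 0)
  # extra replicates are ignored beyond the first k
  est5 <- replicate_summary(list(mk(0.54), mk(0.53), mk(0.55),
                                 mk(9), mk(-9)), k = 3)
  expect_equal(est5$mean, 0.540)
  expect_error(replicate_summary(list(mk(0.5), mk(0.5))),
               class = "insufficient_replicates")
  expect_error(replicate_summary(list(mk(1), mk(1), property_estimate("MT", 1))),
               class = "invalid_argument")
})

test_that("analysis recovers generator ground truth end to end", {
  spec <- bilayer_spec(64, 5.89, 5.89, phosphate_z_upper = 2.16,
                       phosphate_z_lower = -2.16,
                       phosphate_z_jitter_sd = 0.04,
                       ch_tilt_mode = "fixed_angle", tilt_angle_deg = 20,
                       chain_carbons = 8, n_frames = 20, seed = 12)
  tr <- generate_bilayer(spec)
  truth <- bilayer_ground_truth(spec)
  expect_equal(area_per_lipid(tr)$mean, truth$apl, tolerance = 1e-12)
  expect_lt(abs(membrane_thickness(tr)$mean - truth$mt),
            3 * 0.04 * sqrt(2 / (64 * 20)))
  expect_equal(order_parameter(tr)$mean, truth$scd, tolerance = 1e-12)
})
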