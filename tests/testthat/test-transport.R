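test_that("Compton sampling respects the kinematic edge and the KN mean", {
  s <- sample_compton(2e5, 1, seed = 11)
  edge <- 1 / (1 + 2 / 0.51099895)
  expect_gte(min(s$energy), edge)          # 0.2034 MeV at 1 MeV incident
  expect_true(all(s$energy <= 1))
  expect_true(all(abs(s$cos_theta) <= 1))
  # sampled mean scattered-energy fraction vs numerical quadrature, 3 sigma
  for (E in c(0.05, 0.5, 1, 6)) {
    s <- sample_compton(4e5, E, seed = 17)
    m <- mean(s$energy) / E
    se <- sd(s$energy / E) / sqrt(nrow(s))
    expect_lt(abs(m - kn_mean_eps_quadrature(E)), 3 * se)
  }
})

test_that("the low-energy limit loses almost no energy (Thomson regime)", {
  s <- sample_compton(1e5, 0.015, seed = 5)
  expect_lt(mean(1 - s$energy / 0.015), 0.05)
  s2 <- sample_compton(1e5, 0.9, seed = 5)
  expect_gt(mean(1 - s2$energy / 0.9), mean(1 - s$energy / 0.015))
})

test_that("narrow-beam transmission through water matches exp(-mu t)", {
  cfg <- transport_config(n_histories = 2e5, batches = 20, seed = 3,
                          absorption_only = TRUE)
  th <- 10
  r <- pencil_slab("water", 1.25, th, cfg)
  mu <- coefficient_at(get_material("water"), 1.25, "mu") * 1.0
  expect_lt(abs(mean(r$transmitted) - exp(-mu * th)),
            3 * batch_se(r$transmitted))
  # energy bookkeeping is exact in absorption-only mode
  expect_equal(mean(r$deposited + r$escaped), mean(r$initial),
               tolerance = 1e-12)
})

test_that("energy is conserved per history in full physics mode", {
  cfg <- transport_config(n_histories = 5e4, batches = 10, seed = 4)
  r <- pencil_slab("water", 6, 30, cfg)
  total <- r$deposited + r$escaped
  expect_equal(total, r$initial, tolerance = 1e-9)
})

test_that("a near-vacuum slab transmits the beam with no deposit", {
  cfg <- transport_config(n_histories = 2e4, batches = 10, seed = 6,
                          absorption_only = TRUE)
  r <- pencil_slab("air", 2, 10, cfg)   # 10 cm of air
  expect_gt(mean(r$transmitted), 0.999)
  expect_lt(mean(r$deposited), 1e-3 * mean(r$initial))
})

test_that("Russian roulette and splitting leave the expectation unchanged", {
  th <- 5
  mu <- coefficient_at(get_material("water"), 1.25, "mu")
  expected <- mean(c(0.02, 3)) * exp(-mu * th)
  cfg_vr <- transport_config(n_histories = 2e5, batches = 20, seed = 9,
                             absorption_only = TRUE, split_factor = 4,
                             rr_weight_threshold = 0.05, rr_survival = 0.2)
  r_vr <- pencil_slab("water", 1.25, th, cfg_vr,
                      init_weights = c(0.02, 3), init_probs = c(0.5, 0.5),
                      vr_enabled = TRUE)
  r_plain <- pencil_slab("water", 1.25, th, cfg_vr,
                         init_weights = c(0.02, 3), init_probs = c(0.5, 0.5),
                         vr_enabled = FALSE)
  se <- sqrt(batch_se(r_vr$transmitted)^2 + batch_se(r_plain$transmitted)^2)
  expect_lt(abs(mean(r_vr$transmitted) - mean(r_plain$transmitted)), 3 * se)
  expect_lt(abs(mean(r_vr$transmitted) - expected),
            3 * batch_se(r_vr$transmitted))
  expect_lt(abs(mean(r_plain$transmitted) - expected),
            3 * batch_se(r_plain$transmitted))
})

test_that("source sampling covers the aperture with the right open fraction", {
  # 10 x 10 aperture inside the (10 + 2 x 3) margin sampling window: the
  # unattenuated fraction is the area (~ solid angle) ratio 100/256
  ap <- aperture_at(list(x1 = 5, x2 = 5, y1 = 5, y2 = 5))
  src <- source_model(5, focal_fwhm_cm = 0)
  col <- collimation_model(head_leakage = 0)
  ph <- sample_source_photon(2e5, src, col, ap, beam_frame(0), seed = 3)
  wmax <- max(ph$weight)
  p_open <- mean(ph$weight == wmax)
  p_exp <- 100 / 256
  expect_lt(abs(p_open - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / nrow(ph)))
  # monoenergetic source: every photon carries the stated energy
  expect_true(all(ph$energy == 5))
  # open weight is the sampled-area fraction of the source cone
  expect_equal(wmax, 256 / 1600)
})

test_that("a fully closed collimation yields zero-weight photons", {
  ap <- aperture_at(list(x1 = 0, x2 = 0, y1 = 0, y2 = 0))
  src <- source_model(2, focal_fwhm_cm = 0)
  col <- collimation_model(mlc_transmission = 0, jaw_transmission = 0,
                           head_leakage = 0)
  ph <- sample_source_photon(5e3, src, col, ap, beam_frame(0), seed = 1)
  expect_true(all(ph$weight == 0))
})

test_that("collimation model validates and warns appropriately", {
  expect_error(collimation_model(mlc_transmission = 1.2), "\\[0, 1\\)")
  expect_warning(collimation_model(mlc_transmission = 0.001,
                                   jaw_transmission = 0.01),
                 "more opaque")
})

test_that("primary kerma falls off as inverse square of the distance", {
  # two small water probes in an air box, 10 and 20 cm from an isotropic
  # source in perpendicular-ish directions (no mutual shadowing)
  near <- organ_spec("near", "ellipsoid", c(1.5, 1.5, 1.5), c(0, 20, 0),
                     material = "water", is_target = TRUE)
  far <- organ_spec("far", "ellipsoid", c(1.5, 1.5, 1.5), c(12, 14, 0),
                    material = "water")
  body <- organ_spec("box", "box", c(15, 16, 4), c(0, 10, 0),
                     material = "air")
  ph <- build_phantom(list(near, far), body, dims = c(61, 65, 17),
                      voxel_size = c(0.5, 0.5, 0.5))
  src <- source_model(1.0, focal_fwhm_cm = 0, sad = 30)  # S = (0, 30, 0)
  col <- collimation_model(mlc_transmission = 0, jaw_transmission = 0,
                           head_leakage = 0.999)
  field <- list(field_id = "iso", gantry = 0, collimator = 0, couch = 0,
                x1 = 0, x2 = 0, y1 = 0, y2 = 0)
  cfg <- transport_config(n_histories = 2e6, batches = 20, seed = 12)
  tal <- run_beam(ph, field, src, col, cfg)
  dn <- tal[tal$organ == "near", ]
  df <- tal[tal$organ == "far", ]
  ratio <- dn$dose_per_particle / df$dose_per_particle
  rel_se <- sqrt(dn$rel_se^2 + df$rel_se^2)
  expect_lt(abs(ratio - 4), 3 * rel_se * ratio)
})

test_that("beam runs are reproducible and scale like Monte Carlo", {
  ph <- pediatric_phantom()
  f1 <- parse_plan_table(fixture_plans()$plan_3dcrt)$fields[1, ]
  src <- source_model()
  col <- collimation_model()
  cfg <- transport_config(n_histories = 1e5, batches = 10, seed = 77)
  t1 <- run_beam(ph, f1, src, col, cfg)
  t2 <- run_beam(ph, f1, src, col, cfg)
  expect_identical(t1$dose_per_particle, t2$dose_per_particle)  # bit-stable
  t3 <- run_beam(ph, f1, src, col,
                 transport_config(n_histories = 1e5, batches = 10,
                                  seed = 78))
  expect_false(identical(t1$dose_per_particle, t3$dose_per_particle))
  # doubling histories: PTV mean stable within 3 sigma, SE shrinks ~ sqrt(2)
  t4 <- run_beam(ph, f1, src, col,
                 transport_config(n_histories = 2e5, batches = 10,
                                  seed = 79))
  i <- which(t1$organ == "ptv")
  se_comb <- sqrt((t1$rel_se[i] * t1$dose_per_particle[i])^2 +
                  (t4$rel_se[i] * t4$dose_per_particle[i])^2)
  expect_lt(abs(t1$dose_per_particle[i] - t4$dose_per_particle[i]),
            3 * se_comb)
  se_ratio <- (t1$rel_se[i] * t1$dose_per_particle[i]) /
    (t4$rel_se[i] * t4$dose_per_particle[i])
  expect_gt(se_ratio, 1.0)
  expect_lt(se_ratio, 2.1)
})

test_that("in-field dose exceeds every out-of-field organ dose", {
  ph <- pediatric_phantom()
  f1 <- parse_plan_table(fixture_plans()$plan_3dcrt)$fields[1, ]
  cfg <- transport_config(n_histories = 2e5, batches = 10, seed = 15)
  tal <- run_beam(ph, f1, source_model(), collimation_model(), cfg)
  ptv <- tal$dose_per_particle[tal$organ == "ptv"]
  oof <- tal$dose_per_particle[tal$organ %in% tld_reference_doses()$organ]
  expect_true(all(ptv > oof))
})

test_that("the reference calibration behaves like a pure normalization", {
  src <- source_model()
  col <- collimation_model()
  cfg <- transport_config(n_histories = 1.5e5, batches = 10, seed = 21)
  cal <- calibrate_cf(src, col, cfg)
  # by construction: CF x reference tally = calibration dose
  expect_equal(cal$cf * cal$ref_tally, 10, tolerance = 1e-12)
  # linear in the configured calibration dose
  cal5 <- calibrate_cf(src, col, cfg, cal_dose_mgy_per_mu = 5)
  expect_equal(cal5$cf, cal$cf / 2, tolerance = 1e-12)
  # independent of the number of histories within statistical error
  cal2 <- calibrate_cf(src, col,
                       transport_config(n_histories = 3e5, batches = 10,
                                        seed = 22))
  rel <- sqrt(cal$ref_rel_se^2 + cal2$ref_rel_se^2)
  expect_lt(abs(cal2$cf / cal$cf - 1), 3 * rel)
})

test_that("plan simulation is linear in monitor units and validates input", {
  ph <- pediatric_phantom()
  pl <- parse_plan_table(fixture_plans()$plan_3dcrt)
  src <- source_model()
  col <- collimation_model()
  cfg <- transport_config(n_histories = 2e4, batches = 10, seed = 31)
  rep1 <- simulate_plan(ph, pl, src, col, cfg, cf = 1000)
  # all MU zero: all organ doses zero
  pl0 <- pl
  pl0$fields$mu <- 0
  rep0 <- simulate_plan(ph, pl0, src, col, cfg, cf = 1000)
  expect_true(all(rep0$dose_mGy == 0))
  # scaling every field MU by k scales every organ dose by k
  plk <- pl
  plk$fields$mu <- pl$fields$mu * 2.5
  repk <- simulate_plan(ph, plk, src, col, cfg, cf = 1000)
  expect_equal(repk$dose_mGy, rep1$dose_mGy * 2.5, tolerance = 1e-9)
})
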