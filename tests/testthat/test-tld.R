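test_that("the air-kerma chain is the documented product of factors", {
  r <- tld_records("t1", "right_eye", "3DCRT", rd = 1)
  expect_equal(kerma_from_reading(r), 1)
  # hand-computed product: 250 * 1.02 * 0.98 / 0.5
  r2 <- tld_records("t2", "right_eye", "3DCRT", rd = 250, ecc = 1.02,
                    f_q = 0.98, rcf = 0.5)
  expect_equal(kerma_from_reading(r2), 499.8)
})

test_that("the chain is linear in the reading and homogeneous in each factor", {
  set.seed(1)
  for (i in 1:25) {
    base <- tld_records("x", "heart", "IMRT", rd = runif(1, 1, 500),
                        ecc = runif(1, 0.9, 1.1), f_q = runif(1, 0.9, 1.1),
                        f_fad = runif(1, 0.9, 1.1), f_e = runif(1, 0.9, 1.1),
                        f_alpha = runif(1, 0.9, 1.1), rcf = runif(1, 0.2, 2))
    k <- kerma_from_reading(base)
    dbl <- base; dbl$rd <- 2 * base$rd
    expect_equal(kerma_from_reading(dbl), 2 * k)
    fac <- sample(c("ecc", "f_q", "f_fad", "f_e", "f_alpha"), 1)
    sc <- base; sc[[fac]] <- 1.7 * base[[fac]]
    expect_equal(kerma_from_reading(sc), 1.7 * k)
    inv <- base; inv$rcf <- 2 * base$rcf
    expect_equal(kerma_from_reading(inv), k / 2)
  }
})

test_that("tissue dose applies the 6 MeV coefficient ratio", {
  air6 <- coefficient_at(get_material("air"), 6, "muen")
  # an organ whose coefficient equals air's: dose equals kerma
  same <- data.frame(organ = "airlike", muen_rho = air6)
  expect_equal(tissue_dose(50, "airlike", coefficients = same), 50)
  # thyroid uses 0.0194 cm^2/g against the packaged air value
  expect_equal(tissue_dose(100, "thyroid"), 100 * 0.0194 / air6)
  expect_equal(tissue_dose(100, "thyroid"), 117.7899, tolerance = 1e-6)
  expect_error(tissue_dose(1, "spleen"), "no conversion coefficient")
})

test_that("quadrature combination reproduces the stated budget", {
  expect_equal(combine_uncertainty(c(3, 4)), 5)
  expect_equal(combine_uncertainty(7.3), 7.3)
  expect_equal(round(combine_uncertainty(c(3.0, 3.8, 15.0, 1.4)), 1), 15.8)
  expect_equal(round(combine_uncertainty(uncertainty_budget()), 1), 15.8)
})

test_that("combination is permutation-invariant and monotone", {
  u <- c(3.0, 3.8, 15.0, 1.4)
  set.seed(2)
  for (i in 1:10) {
    expect_equal(combine_uncertainty(sample(u)), combine_uncertainty(u))
    j <- sample(4, 1)
    up <- u; up[j] <- up[j] + runif(1, 0.1, 5)
    expect_gt(combine_uncertainty(up), combine_uncertainty(u))
  }
})

test_that("organ means follow the clinical reporting convention", {
  # a single dosimeter reading engineered to reduce to exactly 593.0 mGy
  air6 <- coefficient_at(get_material("air"), 6, "muen")
  rd <- 593.0 * air6 / 0.0179
  r <- tld_records("e1", "right_eye", "3DCRT", rd = rd)
  m <- organ_mean(r)
  expect_equal(m$mean_mGy, 593.0, tolerance = 1e-12)
  expect_equal(round(m$sd_mGy, 1), 93.7)   # mean x 15.8%
  expect_equal(m$n, 1)
  # four-dosimeter thyroid layout
  cfg <- generator_config(true_doses = c(thyroid = 79.4), seed = 3)
  rec <- generate_tld_readings(cfg, "IMRT", noiseless = TRUE)
  m2 <- organ_mean(rec)
  expect_equal(m2$n, 4)
  expect_equal(m2$mean_mGy, 79.4, tolerance = 1e-9)
  expect_error(organ_mean(r[0, ]), "no records")
})

test_that("mixed organs or techniques are refused in organ_mean", {
  a <- tld_records("a", "heart", "IMRT", rd = 1)
  b <- tld_records("b", "thyroid", "IMRT", rd = 1)
  expect_error(organ_mean(rbind(a, b)), "mixed organs")
  c_ <- tld_records("c", "heart", "3DCRT", rd = 1)
  expect_error(organ_mean(rbind(a, c_)), "mixed techniques")
})

test_that("every printed reference SD equals mean x the combined uncertainty", {
  ref <- tld_reference_doses()
  u <- round(combine_uncertainty(uncertainty_budget()), 1) / 100
  expect_equal(round(ref$dose_3dcrt_mGy * u, 1), ref$sd_3dcrt_mGy)
  expect_equal(round(ref$dose_imrt_mGy * u, 1), ref$sd_imrt_mGy)
})

test_that("TLD tables round-trip through the text dialect", {
  rec <- generate_tld_readings(generator_config(seed = 8), "IMRT")
  tmp <- tempfile(fileext = ".tsv")
  write_tld_table(rec, tmp)
  rec2 <- read_tld_table(tmp)
  expect_equal(rec2$rd, rec$rd, tolerance = 1e-9)
  expect_equal(rec2$organ, rec$organ)
  expect_equal(reduce_tld(rec2)$mean_mGy, reduce_tld(rec)$mean_mGy,
               tolerance = 1e-9)
})
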