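test_that("packaged plan tables parse with the clinical field structure", {
  paths <- fixture_plans()
  p3 <- parse_plan_table(paths$plan_3dcrt)
  expect_equal(nrow(p3$fields), 6)
  expect_equal(p3$technique, "3DCRT")
  expect_equal(sum(p3$fields$mu), 269)          # 32+30+31+63+53+60
  expect_equal(p3$fields$mu[4], 63)
  expect_equal(p3$fields$collimator[6], 309)
  pi_ <- parse_plan_table(paths$plan_imrt)
  expect_equal(nrow(pi_$fields), 7)
  expect_true(all(pi_$fields$couch == 0))
  expect_true(all(pi_$fields$collimator == 0))
  expect_equal(pi_$fields$ssd[7], 91.5)
  expect_equal(sum(pi_$fields$mu), 334)
})

test_that("jaw-consistency violations name the offending row", {
  tmp <- tempfile(fileext = ".tsv")
  lines <- readLines(fixture_plans()$plan_3dcrt)
  lines[4] <- sub("3.2\t1.6\t1.6", "3.2\t1.6\t2.0", lines[4])  # row 1
  writeLines(lines, tmp)
  expect_error(parse_plan_table(tmp), "field '1'")
})

test_that("plan tables round-trip field for field", {
  p3 <- parse_plan_table(fixture_plans()$plan_3dcrt)
  tmp <- tempfile(fileext = ".tsv")
  write_plan_table(p3, tmp)
  p3b <- parse_plan_table(tmp)
  expect_equal(p3$fields, p3b$fields)
  expect_equal(p3$technique, p3b$technique)
})

test_that("MLC logs parse, validate and round-trip", {
  field <- parse_plan_table(fixture_plans()$plan_imrt)$fields[1, ]
  lf <- generate_mlc_log(field, 100, seed = 5)
  cps <- parse_mlc_log(lf)
  expect_equal(nrow(cps), 100)
  expect_equal(cps$mu_fraction[100], 1)
  expect_true(all(diff(cps$mu_fraction) > 0))
  expect_true(all(cps$bank_a <= cps$bank_b + 1e-12))
  # round trip
  tmp <- tempfile()
  write_mlc_log(cps, "1", tmp)
  cps2 <- parse_mlc_log(tmp)
  expect_equal(cps2$mu_fraction, cps$mu_fraction, tolerance = 1e-6)
  expect_equal(unname(cps2$bank_a), unname(cps$bank_a), tolerance = 1e-5)
})

test_that("only the configured leaf pairs move in generated logs", {
  field <- parse_plan_table(fixture_plans()$plan_imrt)$fields[2, ]
  cps <- parse_mlc_log(generate_mlc_log(field, 100, seed = 9))
  moving <- which(apply(cps$bank_a, 2, function(x) diff(range(x)) > 1e-9) |
                  apply(cps$bank_b, 2, function(x) diff(range(x)) > 1e-9))
  expect_true(length(moving) > 0)
  expect_true(all(moving %in% 27:34))
})

test_that("generated logs are byte-identical under a fixed seed", {
  field <- parse_plan_table(fixture_plans()$plan_imrt)$fields[1, ]
  f1 <- generate_mlc_log(field, 50, seed = 33, file = tempfile())
  f2 <- generate_mlc_log(field, 50, seed = 33, file = tempfile())
  expect_identical(readLines(f1)[-2], readLines(f2)[-2])  # header field_id same
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed MLC logs are rejected with a reason", {
  field <- parse_plan_table(fixture_plans()$plan_imrt)$fields[1, ]
  cps <- parse_mlc_log(generate_mlc_log(field, 20, seed = 2))
  # crossed pair
  bad <- cps
  bad$bank_a[5, 30] <- bad$bank_b[5, 30] + 0.5
  tmp <- tempfile()
  write_mlc_log(bad, "x", tmp)
  expect_error(parse_mlc_log(tmp), "crossed leaf pair 30")
  # non-monotone MU fraction
  bad2 <- cps
  bad2$mu_fraction[10] <- bad2$mu_fraction[12]
  bad2$mu_fraction[11] <- bad2$mu_fraction[9]
  write_mlc_log(bad2, "x", tmp)
  expect_error(parse_mlc_log(tmp), "non-monotone")
})

test_that("control-point subsampling selects every step-th point with equal MU", {
  field <- parse_plan_table(fixture_plans()$plan_imrt)$fields[1, ]
  cps <- parse_mlc_log(generate_mlc_log(field, 100, seed = 4))
  sub <- subsample_control_points(cps, 5, field_mu = field$mu)
  expect_equal(nrow(sub), 20)
  expect_equal(sub$index, seq(5, 100, by = 5))
  expect_equal(sum(sub$mu_weight), field$mu)
  # step equal to the sequence length keeps only the last point
  last <- subsample_control_points(cps, 100, field_mu = 10)
  expect_equal(nrow(last), 1)
  expect_equal(last$index, 100)
  expect_error(subsample_control_points(cps, 0), "positive")
  expect_error(subsample_control_points(cps[1:3, ], 5), "length")
})

test_that("a seven-field dynamic plan expands to 140 equally weighted jobs", {
  pl <- load_fixture_plans(seed = 11)
  jobs <- plan_jobs(pl$plan_imrt, step = 5)
  expect_equal(nrow(jobs), 140)
  expect_equal(sum(jobs$mu), sum(pl$plan_imrt$fields$mu))
  expect_equal(nrow(plan_jobs(pl$plan_3dcrt)), 6)
  # bare IMRT plan (no sequences) cannot be expanded
  bare <- parse_plan_table(fixture_plans()$plan_imrt)
  expect_error(plan_jobs(bare), "missing MLC sequence")
})

test_that("apertures compose jaws and leaves correctly", {
  # static field: jaw rectangle only
  f1 <- parse_plan_table(fixture_plans()$plan_3dcrt)$fields[1, ]
  ap <- aperture_at(f1)
  expect_equal(ap$jaw, c(-1.6, 1.6, -1.6, 1.6))
  expect_equal(aperture_area(ap), 3.2 * 3.2)
  # fully retracted leaves reproduce the jaw rectangle area
  geo <- mlc_geometry()
  cp_open <- list(bank_a = rep(-20, 60), bank_b = rep(20, 60))
  f <- list(x1 = 5, x2 = 5, y1 = 5, y2 = 5)
  expect_equal(aperture_area(aperture_at(f, cp_open)), 100)
  # one pair open 1 cm inside 10 x 10 jaws: area = 1 x leaf width
  cp_one <- list(bank_a = rep(0, 60), bank_b = rep(0, 60))
  cp_one$bank_b[30] <- 1
  expect_equal(aperture_area(aperture_at(f, cp_one)), 1 * 0.5)
})

test_that("retracting a leaf never shrinks the aperture", {
  f <- list(x1 = 5, x2 = 5, y1 = 5, y2 = 5)
  set.seed(42)
  for (rep in 1:20) {
    a <- runif(60, -3, 0)
    b <- a + runif(60, 0, 3)
    ap0 <- aperture_area(aperture_at(f, list(bank_a = a, bank_b = b)))
    i <- sample(60, 1)
    a2 <- a; a2[i] <- a[i] - runif(1, 0, 2)      # retract one bank-A leaf
    ap1 <- aperture_area(aperture_at(f, list(bank_a = a2, bank_b = b)))
    expect_gte(ap1, ap0 - 1e-12)
  }
})

test_that("field invariants are enforced", {
  fields <- parse_plan_table(fixture_plans()$plan_3dcrt)$fields
  fields$mu[1] <- -1
  expect_error(treatment_plan("3DCRT", fields), "MU")
  fields <- parse_plan_table(fixture_plans()$plan_3dcrt)$fields
  fields$gantry[1] <- 380
  expect_error(treatment_plan("3DCRT", fields), "angles")
})
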