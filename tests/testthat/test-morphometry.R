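test_that("Cobb's ratios convert to the supplemented 7-coordinate profile", {
  prof <- aa_profile()
  expect_s3_class(prof, "morphometric_profile")
  expect_equal(prof$coords$l, c(0, 0.001, 0.126, 0.21, 0.51, 0.87, 1))
  expect_equal(prof$coords$r, c(0, 0.004, 0.011, 0.0115, 0.012, 0.0095, 0))
  expect_equal(prof$length_L, 0.6e-3)
})

test_that("uniform diameters give a constant interior radius", {
  cr <- cobb_ratios(1e-3, l = c(10, 20, 40, 60, 80), d = rep(2, 5))
  prof <- cobb_to_profile(cr)
  expect_equal(prof$coords$r[2:6], rep(0.01, 5))
})

test_that("profile validation rejects malformed coordinates with informative errors", {
  expect_error(cobb_ratios(1e-3, l = c(10, 5, 40, 60, 80), d = rep(2, 5)),
               "l2.*out of order")
  expect_error(morphometric_profile(c(0, 0.5, 0.5, 1), c(0, 1, 1, 0) / 100, 1e-3),
               "duplicate axial position at index 3")
  expect_error(morphometric_profile(c(0, 0.7, 0.4, 1), c(0, 1, 1, 0) / 100, 1e-3),
               "index 3.*out of order")
  expect_error(morphometric_profile(c(0, 0.5, 1), c(0, 0, 0), 1e-3),
               "interior radii")
  expect_error(morphometric_profile(c(0, 1), c(0.01, 0.01), -1),
               "length_L")
})

test_that("cobb_to_profile is invertible on its range", {
  cr <- aplectus_antarcticus()
  back <- profile_to_cobb(cobb_to_profile(cr))
  expect_equal(back$l, cr$l)
  expect_equal(back$d, cr$d)
  expect_equal(back$length_L, cr$length_L)
})

test_that("supplementation always yields terminal coordinates (0,0) and (1,0)", {
  for (k in c(1, 3, 5)) {
    l <- seq(0.2, 0.8, length.out = k)
    prof <- morphometric_profile(l, rep(0.01, k), 1e-3, supplement = TRUE)
    n <- nrow(prof$coords)
    expect_equal(prof$coords$l[c(1, n)], c(0, 1))
    expect_equal(prof$coords$r[c(1, n)], c(0, 0))
  }
  # already-supplemented input is left unchanged
  prof <- supplement_profile(aa_profile())
  expect_equal(nrow(prof$coords), 7)
})

test_that("de Man indices map onto the known subset of Cobb's ratios", {
  # maximum diameter 2.4% of L inverts to a = 200/2.4
  idx <- deman_indices(0.6e-3, a = 200 / 2.4, b = 100 / 21, c = 100 / 13,
                       c_prime = (13 / 100) / (1.9 / 200))
  pc <- deman_to_partial_cobb(idx)
  expect_equal(pc$d[4], 2.4)
  expect_equal(pc$l[3], 21)
  expect_equal(pc$l[5], 87)
  expect_equal(pc$d[5], 1.9)
  expect_setequal(pc$missing, c("l1", "l2", "l4", "d1", "d2", "d3"))

  # direct substitutions
  expect_equal(deman_to_partial_cobb(deman_indices(1e-3, 50, 2, 10, 5))$l[3], 50)
  pc2 <- deman_to_partial_cobb(deman_indices(1e-3, 50, 2, 10, 5))
  expect_equal(pc2$l[5], 90)
  expect_equal(pc2$d[5], 4)
  expect_error(deman_indices(1e-3, a = -1, b = 2, c = 3, c_prime = 1),
               "positive")
})

test_that("index computation round-trips through the partial Cobb record", {
  cr <- aplectus_antarcticus()
  pc <- deman_to_partial_cobb(deman_from_cobb(cr))
  expect_equal(pc$l[3], cr$l[3])
  expect_equal(pc$l[5], cr$l[5])
  expect_equal(pc$d[4], max(cr$d))
  expect_equal(pc$d[5], cr$d[5])
  prof <- partial_cobb_to_profile(pc)
  expect_equal(prof$coords$l[1], 0)
  expect_equal(prof$coords$l[nrow(prof$coords)], 1)
})

test_that("absolute conversion scales by L and preserves order", {
  prof <- aa_profile()
  abs_co <- profile_to_absolute(prof)
  expect_equal(abs_co$position[5], 3.06e-4)
  expect_equal(abs_co$radius[5], 7.2e-6)
  expect_equal(abs_co$position[1], 0)
  expect_equal(abs_co$position[7], 6e-4)
  expect_equal(abs_co$radius[7], 0)
  expect_true(all(diff(abs_co$position) > 0))
})

test_that("CSV and JSON readers honour units and radius/diameter conventions", {
  prof <- aa_profile()

  # package dialect round-trip (fractions, radii)
  f1 <- tmpfile("prof.csv")
  write_profile_csv(prof, f1)
  expect_equal(read_profile(f1)$coords, prof$coords)

  # percent + diameter input reduces to the same canonical profile
  f2 <- tmpfile("cobb.csv")
  writeLines(c("#units=percent", "#value_kind=diameter", "#length_m=6e-4",
               "#supplement=true", "position,value",
               "0.1,0.8", "12.6,2.2", "21,2.3", "51,2.4", "87,1.9"), f2)
  expect_equal(read_profile(f2)$coords, prof$coords)

  # absolute metres input
  f3 <- tmpfile("abs.csv")
  ab <- profile_to_absolute(prof)[2:6, ]
  writeLines(c("#units=absolute", "#value_kind=radius", "#length_m=6e-4",
               "#supplement=true", "position,value",
               sprintf("%.17g,%.17g", ab$position, ab$radius)), f3)
  expect_equal(read_profile(f3)$coords$r, prof$coords$r)

  # JSON mirror
  f4 <- tmpfile("prof.json")
  jsonlite::write_json(list(units = "percent", value_kind = "diameter",
                            length_m = 6e-4, supplement = "true",
                            position = aplectus_antarcticus()$l,
                            value = aplectus_antarcticus()$d),
                       f4, auto_unbox = TRUE, digits = NA)
  expect_equal(read_profile(f4)$coords, prof$coords)

  # conventions are never guessed
  f5 <- tmpfile("bad.csv")
  writeLines(c("#units=percent", "#length_m=6e-4", "position,value", "50,1"), f5)
  expect_error(read_profile(f5), "value_kind")
})
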