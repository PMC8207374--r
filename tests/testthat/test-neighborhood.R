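# Neighborhood sums: worked inverse-distance examples, boundary
# conventions, brute-force agreement, and the nonspatial limit.

two_tree_census <- function(neighbor_d = 3, neighbor_ba = 1) {
  data.frame(
    tree_id = c("focal", "nb"), species = c("A", "A"),
    x = c(50, 50 + neighbor_d), y = c(50, 50),
    gbh_1 = c(1, gbh_from_basal_area(neighbor_ba)),
    status_1 = "alive", gbh_2 = c(1.2, gbh_from_basal_area(neighbor_ba) + 1),
    status_2 = "alive", stringsAsFactors = FALSE)
}

test_that("two-point crowns reproduce the inverse-distance worked examples", {
  per <- period_spec(1, 2, plot_spec(100, 100, 20))
  # neighbor crown radius 1 m centered 3 m away: edge points at 2 and 4 m
  trees <- two_tree_census(3)
  canopy <- as_canopy(list(
    crown_cloud("nb", 53, 50, trees$gbh_1[2], "A",
                px = c(52, 54), py = c(50, 50), ba = 1, cr = 1)))
  spatial <- neighbor_sum_spatial("focal", canopy, trees, per, r = 20)
  expect_identical(spatial, (1 / 2 + 1 / 4) / 2)   # 0.375
  nonspatial <- neighbor_sum_nonspatial("focal", trees, per, r = 20)
  expect_equal(nonspatial, 1 / 3, tolerance = 1e-12)  # 0.333

  # crown radius 5 m centered 7 m away: edge points at 2 and 12 m
  trees2 <- two_tree_census(7)
  canopy2 <- as_canopy(list(
    crown_cloud("nb", 57, 50, trees2$gbh_1[2], "A",
                px = c(52, 62), py = c(50, 50), ba = 1, cr = 5)))
  expect_identical(neighbor_sum_spatial("focal", canopy2, trees2, per, 20),
                   (1 / 2 + 1 / 12) / 2)            # 0.292
  expect_equal(neighbor_sum_nonspatial("focal", trees2, per, 20), 1 / 7,
               tolerance = 1e-12)                   # 0.143
})

test_that("single-neighbor sums follow ba * decay(d) with a closed boundary", {
  per <- period_spec(1, 2, plot_spec(100, 100, 20))
  trees <- two_tree_census(5, neighbor_ba = 100)
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 10), 20)
  # neighbor at exactly r is included; just beyond is not
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 5), 20)
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 4.999), 0)
  # decay variants
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 10,
                                       decay = "none"), 100)
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 10,
                                       decay = "squared"), 4)
  # empty neighborhood: sum 0, ln(0 + 1) = 0
  expect_equal(neighbor_sum_nonspatial("nb", trees, per, 20), 0)
  expect_identical(log1p(0), 0)
})

test_that("dead and smaller trees are never neighbors", {
  per <- period_spec(1, 2, plot_spec(100, 100, 20))
  trees <- two_tree_census(5, neighbor_ba = 100)
  trees$status_2[2] <- "dead"   # neighbor did not survive the period
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 20), 0)
  trees$status_2[2] <- "alive"
  # focal larger than "neighbor": excluded by the size rule
  trees$gbh_1[1] <- 60
  expect_equal(neighbor_sum_nonspatial("focal", trees, per, 20), 0)
})

test_that("spatial sums agree with a brute-force loop on a generated plot", {
  fx <- small_forest()
  clouds <- fill_plot(fx$trees, 1, fill_mode = "larsm", seed = 3)
  canopy <- as_canopy(clouds)
  focal_ids <- fx$trees$tree_id[fx$trees$x > 30 & fx$trees$x < 40][1:4]
  for (fid in focal_ids) for (cls in c("CON", "HET", "ALL")) {
    got <- neighbor_sum_spatial(fid, canopy, fx$trees, fx$period, r = 8,
                                decay = "linear", class = cls)
    want <- oracle_sum(fid, canopy, fx$trees, fx$period, 8, "linear", cls)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("predictor tables satisfy CON + HET = ALL and radius monotonicity", {
  fx <- small_forest()
  focal <- focal_subset(fx$trees, "SP01", fx$period, fx$plot)[1:15, ]
  canopy <- as_canopy(fill_plot(fx$trees, 1, seed = 3))
  tab <- predictor_table(focal, fx$trees, fx$period, canopy,
                         radii = c(2, 5, 10, 15), decay = "none")
  expect_identical(tab$sum_all, tab$sum_con + tab$sum_het)
  for (id in unique(tab$focal_id)) {
    sub <- tab[tab$focal_id == id, ]
    expect_true(all(diff(sub$sum_all) >= 0))  # set inclusion in r
  }
  expect_equal(tab$ln_con, log1p(tab$sum_con))
  # spot-check one cell against the single-sum routine
  expect_equal(tab$sum_con[tab$focal_id == focal$tree_id[1] & tab$r == 10],
               neighbor_sum_spatial(focal$tree_id[1], canopy, fx$trees,
                                    fx$period, 10, "none", "CON"))
})

test_that("the crown-centroid focal position is the unshaded point mean", {
  trees <- two_tree_census(3)
  cl <- crown_cloud("nb", 53, 50, trees$gbh_1[2], "A",
                    px = c(52, 53, 55), py = c(49, 50, 52))
  canopy <- as_canopy(list(cl))
  expect_equal(focal_position("nb", trees, canopy, "crown"),
               c(mean(c(52, 53, 55)), mean(c(49, 50, 52))))
  expect_equal(focal_position("nb", trees, canopy, "stem"), c(53, 50))
  # empty cloud falls back to the stem
  gone <- adjust_relocation(cl, rep(TRUE, 3), 1)
  expect_equal(focal_position("nb", trees, as_canopy(list(gone)), "crown"),
               c(53, 50))
  # for the largest tree the disc centroid sits at the stem (in expectation)
  big <- fill_crown("big", 20, 20, 200, "A", seed = 1)
  expect_equal(focal_position("big", data.frame(
    tree_id = "big", species = "A", x = 20, y = 20), as_canopy(list(big)),
    "crown"), c(20, 20), tolerance = 0.15)
})

test_that("with all crowns at radius zero the spatial pipeline is exactly nonspatial", {
  fx <- small_forest()
  canopy <- as_canopy(fill_plot(fx$trees, 1, fill_mode = "larsm",
                                seed = 5, cr_zero = TRUE))
  focal <- focal_subset(fx$trees, "SP01", fx$period, fx$plot)
  sp <- predictor_table(focal, fx$trees, fx$period, canopy, radii = 1:20)
  ns <- predictor_table(focal, fx$trees, fx$period, NULL, radii = 1:20)
  expect_identical(sp, ns)
  # and per-focal single sums agree bit-for-bit
  fid <- focal$tree_id[1]
  expect_identical(
    neighbor_sum_spatial(fid, canopy, fx$trees, fx$period, 1:20),
    neighbor_sum_nonspatial(fid, fx$trees, fx$period, 1:20))
})

test_that("spatial extension up-weights a single neighbor (Jensen property)", {
  per <- period_spec(1, 2, plot_spec(100, 100, 20))
  trees <- two_tree_census(8, neighbor_ba = 1e4)  # big crown, many points
  trees$gbh_1[2] <- 150
  cl <- fill_crown("nb", 58, 50, 150, "A", fill_mode = "larsm", seed = 2)
  spatial <- neighbor_sum_spatial("focal", as_canopy(list(cl)), trees, per,
                                  r = 30, decay = "linear")
  nonspatial <- neighbor_sum_nonspatial("focal", trees, per, r = 30,
                                        decay = "linear")
  # mean of inverse distances exceeds inverse distance to the center
  expect_gt(spatial, nonspatial)
  expect_equal(spatial / nonspatial, 1.06, tolerance = 0.05)
})
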