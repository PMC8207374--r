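# Shading flags and crown plasticity adjustments.

# three overlapping conspecific/heterospecific crowns plus one far tree
overlap_clouds <- function(seed = 5, gbh = c(90, 60, 30, 45),
                           density = 8) {
  trees <- data.frame(
    tree_id = c("big", "mid", "small", "far"),
    species = c("A", "A", "B", "B"),
    x = c(50, 53, 51, 90), y = c(50, 51, 49, 90),
    gbh_1 = gbh, status_1 = "alive", stringsAsFactors = FALSE)
  fill_plot(trees, 1, fill_mode = "equal", density = density, seed = seed)
}

test_that("dd = 0 flags nothing and disjoint crowns never flag", {
  clouds <- overlap_clouds()
  fl <- flag_shaded(clouds, 0, 0)
  expect_false(any(unlist(fl)))
  # far tree is beyond cr1 + cr2 + dd of everything
  fl2 <- flag_shaded(clouds, 1.2, 1.2)
  expect_false(any(fl2$far))
  expect_false(any(fl2$big))  # nothing is larger than the largest tree
})

test_that("flags equal the brute-force all-pairs distance check", {
  clouds <- overlap_clouds(density = 3)
  for (dd in list(c(0.4, 0.4), c(1.2, 0), c(0.2, 0.8))) {
    expect_identical(flag_shaded(clouds, dd[1], dd[2]),
                     oracle_flags(clouds, dd[1], dd[2]))
  }
  # hand-built six-point configuration with known answer
  a <- crown_cloud("L", 0, 0, 100, "A", px = c(0, 1, 2), py = c(0, 0, 0))
  b <- crown_cloud("S", 1, 0.3, 50, "A",
                   px = c(0.5, 1.0, 3.0), py = c(0.3, 0.1, 0.3))
  fl <- flag_shaded(list(L = a, S = b), dd_con = 0.6, dd_het = 0)
  # S's first two points are within 0.6 of a point of L; the third is not
  expect_identical(fl$S, c(TRUE, TRUE, FALSE))
  expect_identical(fl$L, c(FALSE, FALSE, FALSE))
})

test_that("flag counts are non-decreasing in dd", {
  clouds <- overlap_clouds()
  counts <- vapply(dd_grid(), function(dd)
    sum(unlist(flag_shaded(clouds, dd, dd))), 0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[length(counts)], 0)
})

test_that("removal deletes flagged points and shrinks weight arithmetically", {
  cl <- fill_crown("t", 0, 0, 60, fill_mode = "larsm", seed = 2)
  n <- length(cl$x)
  expect_identical(adjust_removal(cl, rep(FALSE, n))$x, cl$x)
  flags <- seq_len(n) <= 10
  pruned <- adjust_removal(cl, flags)
  expect_equal(length(pruned$x), n - 10)
  expect_equal(pruned$weight * length(pruned$x),
               cl$ba * (n - 10) / n)
  gone <- adjust_removal(cl, rep(TRUE, n))
  expect_equal(length(gone$x), 0)
})

test_that("relocation conserves point count and weight and targets the unshaded region", {
  cl <- fill_crown("t", 0, 0, 80, fill_mode = "equal", density = 15,
                   seed = 4)
  flags <- cl$x < 0   # shade the left half-disc
  rel <- adjust_relocation(cl, flags, seed = 4)
  expect_equal(length(rel$x), length(cl$x))
  expect_equal(rel$weight * length(rel$x), cl$ba)
  # unshaded points untouched
  expect_identical(rel$x[!flags], cl$x[!flags])
  # relocated points fall in the contour of the unshaded (right) half:
  # none can sit far left of it (one bandwidth of slack)
  h <- MASS::bandwidth.nrd(cl$x[!flags])
  expect_true(all(rel$x[flags] > min(cl$x[!flags]) - h))
  # the bulk moved to the unshaded side
  expect_gt(mean(rel$x[flags] > 0), 0.8)
  # no flags is the identity
  expect_identical(adjust_relocation(cl, rep(FALSE, length(cl$x)), 1)$x,
                   cl$x)
})

test_that("relocation falls back gracefully on degenerate unshaded sets", {
  cl <- crown_cloud("t", 0, 0, 50, "A",
                    px = c(0, 0, 1, 1.5, 2), py = c(0, 0, 0, 0, 0),
                    cr = 2)
  flags <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  rel <- adjust_relocation(cl, flags, seed = 1)
  expect_equal(length(rel$x), 5)
  # jittered copies stay near the unshaded points
  expect_true(all(abs(rel$x[3:5]) < 1))
  # fully flagged tree vanishes
  gone <- adjust_relocation(cl, rep(TRUE, 5), seed = 1)
  expect_equal(length(gone$x), 0)
})

test_that("hierarchical adjustment works largest-down and leaves no residual shading", {
  clouds <- overlap_clouds()
  can <- adjust_plot(clouds, 0.8, 0.8, "removal", seed = 5)
  # disjoint tree untouched
  expect_identical(can$clouds$far$x, clouds$far$x)
  # the largest tree is never pruned
  expect_identical(can$clouds$big$x, clouds$big$x)
  # re-flagging the adjusted canopy finds nothing left to shade
  refl <- flag_shaded(can$clouds, 0.8, 0.8)
  expect_false(any(unlist(refl)))
  # removal never increases a tree's weight
  for (id in names(clouds))
    expect_lte(can$clouds[[id]]$weight * length(can$clouds[[id]]$x),
               clouds[[id]]$ba + 1e-9)
  # relocation conserves every tree's weight (unless vanished)
  rel <- adjust_plot(clouds, 0.8, 0.8, "relocation", seed = 5)
  for (id in setdiff(names(clouds), rel$vanished))
    expect_equal(rel$clouds[[id]]$weight * length(rel$clouds[[id]]$x),
                 clouds[[id]]$ba)
  # all crowns pairwise disjoint -> identity in both modes
  iso <- overlap_clouds(gbh = c(20, 20, 20, 20))
  for (mode in c("removal", "relocation")) {
    ident <- adjust_plot(iso, 1.2, 1.2, mode, seed = 5)
    for (id in names(iso))
      expect_identical(ident$clouds[[id]]$x, iso[[id]]$x)
  }
})

test_that("adjustment is deterministic given the seed", {
  clouds <- overlap_clouds()
  a <- adjust_plot(clouds, 0.6, 0.6, "relocation", seed = 7)
  b <- adjust_plot(clouds, 0.6, 0.6, "relocation", seed = 7)
  expect_identical(a$points, b$points)
})
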