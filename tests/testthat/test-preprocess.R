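cube_cloud <- function() {
  as_point_cloud(expand.grid(x = 0:1, y = 0:1, z = 0:1))
}

test_that("rigid transforms rotate, translate and compose correctly", {
  cloud <- cube_cloud()
  expect_equal(apply_rigid_transform(cloud, rigid_transform(diag(3))), cloud)

  # 90 degrees about the vertical axis sends (1, 0, 0) to (0, 0, -1)
  th <- pi / 2
  rot_y <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  pt <- as_point_cloud(data.frame(x = 1, y = 0, z = 0))
  out <- apply_rigid_transform(pt, rigid_transform(rot_y))
  expect_equal(unlist(out[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, -1), tolerance = 1e-12)

  withr::with_seed(11, {
    t1 <- rigid_transform(random_rotation(), rnorm(3))
    t2 <- rigid_transform(random_rotation(), rnorm(3))
    cloud <- random_cloud(50)
  })
  seq_applied <- apply_rigid_transform(apply_rigid_transform(cloud, t1), t2)
  composed <- rigid_transform(t2$rotation %*% t1$rotation,
                              as.double(t2$rotation %*% t1$translation) +
                                t2$translation)
  expect_equal(apply_rigid_transform(cloud, composed), seq_applied,
               tolerance = 1e-9)
})

test_that("rigid transforms preserve pairwise distances", {
  withr::with_seed(5, {
    cloud <- random_cloud(40)
    tr <- rigid_transform(random_rotation(), rnorm(3))
  })
  d0 <- dist(as.matrix(cloud[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(apply_rigid_transform(cloud, tr)[, c("x", "y", "z")]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("invalid rotations are rejected", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(-diag(3)), "orthonormal") # det -1
})

test_that("principal-axis correction recovers a tilted plant", {
  gen <- generate_plant_cloud(plant_profile("cylinder"), rings = 15,
                              azimuth_steps = 24, seed = 3)
  upright <- gen$cloud
  # already upright: transform is a near-identity rotation (up to sign)
  tr <- principal_axis_transform(upright)
  expect_equal(abs(tr$rotation[2, 2]), 1, tolerance = 1e-6)

  # tilt 30 degrees about the horizontal x axis, then recover
  th <- pi / 6
  tilt <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tilted <- apply_rigid_transform(upright, rigid_transform(tilt))
  recovered <- orient_plant(tilted)
  expect_equal(max(recovered$y) - min(recovered$y),
               max(upright$y) - min(upright$y), tolerance = 1e-3)

  expect_error(principal_axis_transform(
    as_point_cloud(data.frame(x = 0:1, y = 0, z = 0))), "at least 3")
  expect_error(principal_axis_transform(
    as_point_cloud(data.frame(x = 0:5, y = 0, z = 0))), "collinear")
})

test_that("statistical filter matches the hand-worked Gaussian band", {
  # collinear points at x = 0..3 plus an outlier at x = 100, k = 2:
  # mean kNN distances (1.5, 1, 1, 1.5, 97.5), mu = 20.5, sigma ~ 38.50
  cloud <- as_point_cloud(data.frame(x = c(0, 1, 2, 3, 100), y = 0, z = 0))
  out <- filter_statistical_outliers(cloud, k = 2, std_mult = 1)
  expect_equal(out$x, c(0, 1, 2, 3))

  # an effectively infinite band removes nothing
  expect_equal(nrow(filter_statistical_outliers(cloud, k = 2,
                                                std_mult = 1e6)), 5)

  # perfectly regular cloud: all mean kNN distances equal, sigma = 0,
  # every point retained
  th <- (0:23) * 2 * pi / 24
  ring <- as_point_cloud(data.frame(x = 5 * cos(th), y = 0, z = 5 * sin(th)))
  expect_equal(nrow(filter_statistical_outliers(ring, k = 4)), 24)

  expect_error(filter_statistical_outliers(cloud, k = 5), "more than k")
})

test_that("statistical filter agrees with the distance-matrix oracle", {
  withr::with_seed(21, {
    cloud <- random_cloud(120)
  })
  for (k in c(3, 10)) {
    keep <- oracle_stat_filter_keep(as.matrix(cloud[, c("x", "y", "z")]),
                                    k, 1.0)
    expect_equal(filter_statistical_outliers(cloud, k = k, std_mult = 1.0),
                 cloud[keep, ])
  }
})

test_that("statistical filter is idempotent-or-shrinking", {
  withr::with_seed(8, {
    cloud <- random_cloud(100)
  })
  once <- filter_statistical_outliers(cloud, k = 5)
  twice <- filter_statistical_outliers(once, k = 5)
  expect_lte(nrow(twice), nrow(once))
  # surviving points are a subset of the input, order preserved
  expect_true(all(once$x %in% cloud$x))
})

test_that("color filter keeps exactly the channelwise band", {
  cloud <- as_point_cloud(data.frame(x = 1:2, y = 0, z = 0,
                                     r = c(10, 120), g = c(10, 200),
                                     b = c(10, 90)))
  expect_equal(filter_color(cloud, c(0, 0, 0), c(255, 255, 255)), cloud)
  expect_equal(filter_color(cloud, min_rgb = c(41, 41, 41))$x, 2)

  withr::with_seed(31, {
    big <- random_cloud(500)
  })
  lo <- c(40, 60, 10)
  hi <- c(200, 255, 180)
  keep <- big$r >= lo[1] & big$r <= hi[1] &
    big$g >= lo[2] & big$g <= hi[2] &
    big$b >= lo[3] & big$b <= hi[3]
  expect_equal(filter_color(big, lo, hi), big[keep, ])
  expect_error(filter_color(big, c(100, 0, 0), c(50, 255, 255)), "min_rgb")
})

test_that("voxel down-sampling averages occupied cells", {
  cube <- cube_cloud()
  one <- downsample_voxel(cube, leaf = 2)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, c("x", "y", "z")], use.names = FALSE),
               c(0.5, 0.5, 0.5))

  # leaf below the minimum spacing: same point set, possibly reordered
  tiny <- downsample_voxel(cube, leaf = 0.5)
  expect_equal(sort_rows(tiny[, c("x", "y", "z")]),
               sort_rows(cube[, c("x", "y", "z")]))

  expect_error(downsample_voxel(cube, leaf = -1), "leaf")
})

test_that("voxel down-sampling matches the bucket-mean oracle", {
  withr::with_seed(13, {
    cloud <- random_cloud(2000, span = 5)
  })
  leaf <- 0.8
  got <- downsample_voxel(cloud, leaf = leaf)
  expect_lte(nrow(got), nrow(cloud))
  want <- oracle_voxel(cloud, leaf)
  got_m <- as.matrix(got)
  got_m <- got_m[order(got_m[, 1], got_m[, 2], got_m[, 3]), ]
  expect_equal(unname(got_m), unname(want), tolerance = 1e-9)
})

test_that("height and width traits follow their definitions", {
  cube <- cube_cloud()
  tp <- measure_plant(cube)
  expect_equal(tp$height, 1)
  expect_equal(tp$width, sqrt(2), tolerance = 1e-12)

  # cylinder preset: vertical span 4.5, max diameter 2 * 0.80
  gen <- generate_plant_cloud(plant_profile("cylinder"), rings = 30,
                              azimuth_steps = 360, seed = 2)
  tp <- measure_plant(gen$cloud)
  expect_equal(tp$height, 4.5, tolerance = 1e-9)
  expect_equal(tp$width, 1.6, tolerance = 1e-3)

  expect_error(measure_plant(as_point_cloud(data.frame(x = 0, y = 0, z = 0))),
               "at least 2")
})
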