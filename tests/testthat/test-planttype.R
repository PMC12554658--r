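# chain |K'| values hand-evaluated from the packaged example-hull corners
EXAMPLE_HULL_LEFT_RATES <- c(0.138382, 0.254028, 0.104745, 0.045704)
EXAMPLE_HULL_RIGHT_RATES <- c(0.535425, 0.005561, 0.084291, 0.093333)

chain_xy <- function(side) {
  ch <- example_hull_chains()
  ch <- ch[ch$chain == side, ]
  tibble::tibble(x = ch$lateral, y = ch$height)
}

test_that("corner change rate follows the second-difference formula", {
  expect_equal(corner_change_rate(c(0, 0), c(1, 1), c(2, 2)), 0)
  expect_equal(corner_change_rate(c(0, 0), c(1, 1), c(2, 4)), 1.0)
  # first triple of the example left chain, (X, Y) = (height, lateral)
  expect_equal(corner_change_rate(c(5.47, 0.01), c(5.05, -0.26),
                                  c(4.22, -0.65)),
               0.138382, tolerance = 1e-4)
  # tied heights signal a degenerate triple
  expect_true(is.na(corner_change_rate(c(1, 0), c(1, 1), c(2, 2))))
})

test_that("chain rates reproduce the published example hull", {
  left <- chain_rates(chain_xy("left"))
  expect_equal(nrow(left), 4)
  expect_equal(left$rate, EXAMPLE_HULL_LEFT_RATES, tolerance = 1e-4)
  expect_equal(left$height, c(5.05, 4.22, 3.39, 2.05))

  right <- chain_rates(chain_xy("right"))
  expect_equal(right$rate, EXAMPLE_HULL_RIGHT_RATES, tolerance = 1e-4)

  expect_equal(nrow(chain_rates(tibble::tibble(x = c(0, 1), y = c(2, 0)))), 0)
})

test_that("K' is translation invariant, mirror invariant, and scales as 1/s", {
  withr::with_seed(12, {
    for (i in 1:20) {
      x <- sort(rnorm(3, sd = 2))
      y <- rnorm(3)
      k0 <- corner_change_rate(c(x[1], y[1]), c(x[2], y[2]), c(x[3], y[3]))
      dx <- rnorm(1); dy <- rnorm(1); s <- runif(1, 0.2, 5)
      k_shift <- corner_change_rate(c(x[1] + dx, y[1] + dy),
                                    c(x[2] + dx, y[2] + dy),
                                    c(x[3] + dx, y[3] + dy))
      k_mirror <- corner_change_rate(c(x[1], -y[1]), c(x[2], -y[2]),
                                     c(x[3], -y[3]))
      k_scaled <- corner_change_rate(c(x[1], y[1]) * s, c(x[2], y[2]) * s,
                                     c(x[3], y[3]) * s)
      expect_equal(k_shift, k0, tolerance = 1e-8)
      expect_equal(abs(k_mirror), abs(k0), tolerance = 1e-12)
      expect_equal(k_scaled, k0 / s, tolerance = 1e-8)
    }
  })
})

test_that("K' keeps a constant sign along a convex chain", {
  withr::with_seed(44, {
    for (trial in 1:10) {
      pts <- cbind(rnorm(80), rnorm(80))
      chains <- split_chains(quickhull(pts))
      for (side in c("left", "right")) {
        ch <- chains[chains$chain == side, c("x", "y")]
        if (nrow(ch) < 4) next
        m <- as.matrix(ch)
        ks <- sapply(seq_len(nrow(m) - 2), function(i) {
          corner_change_rate(c(m[i, 2], m[i, 1]), c(m[i + 1, 2], m[i + 1, 1]),
                             c(m[i + 2, 2], m[i + 2, 1]))
        })
        ks <- ks[!is.na(ks)]
        if (length(ks) > 1) expect_true(all(ks > 0) || all(ks < 0))
      }
    }
  })
})

test_that("rate profiles collect both chains over all views", {
  cyl <- generate_plant_cloud(plant_profile("cylinder"), rings = 15,
                              azimuth_steps = 120, seed = 1)
  prof <- plant_rate_profile(project_views(cyl$cloud, 10))
  expect_equal(nrow(prof), 144) # 2 interior corners per chain, 36 views

  tow <- generate_plant_cloud(plant_profile("tower"), rings = 15,
                              azimuth_steps = 120, seed = 1)
  prof_t <- plant_rate_profile(project_views(tow$cloud, 10))
  expect_equal(nrow(prof_t), 72) # 1 interior corner per chain

  # a square silhouette has two 2-vertex chains: no rate samples
  square <- tibble::tibble(angle_deg = 0, u = c(0, 0, 1, 1),
                           v = c(0, 1, 0, 1))
  expect_equal(nrow(plant_rate_profile(square, normalize = FALSE)), 0)

  # collinear views are skipped; all-collinear input errors
  line <- tibble::tibble(angle_deg = 0, u = c(0, 1, 2), v = 0)
  expect_error(suppressWarnings(plant_rate_profile(line)), "degenerate")
})

test_that("interval classification uses the closed-interval majority rule", {
  res <- classify_plant(c(0.05, 0.10, 0.50))
  expect_equal(res$n_cylinder, 2)
  expect_equal(res$n_tower, 1)
  expect_equal(res$label, "cylinder")

  expect_equal(classify_plant(c(0.10, 0.50))$label, "tower") # tie
  res2 <- classify_plant(c(0.25, 0.30, 1.80)) # all in the gap
  expect_equal(res2$n_cylinder + res2$n_tower, 0)
  expect_equal(res2$label, "tower")
  # closed endpoints count
  expect_equal(classify_plant(c(0.2, 0.2, 0.4))$label, "cylinder")
  expect_error(classify_plant(numeric()), "nonempty")
})

test_that("tidy and glance expose the classification result", {
  res <- classify_plant(c(0.05, 0.45))
  expect_equal(nrow(tidy(res)), 2)
  g <- glance(res)
  expect_equal(g$label, "tower")
  expect_equal(g$n_samples, 2)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("interval fitting supports minmax and central-95% methods", {
  rates <- tibble::tibble(
    label = c(rep("cylinder", 3), rep("tower", 2)),
    rate = c(0.05, 0.10, 0.15, 0.5, 0.9))
  iv <- fit_intervals(rates, "minmax")
  expect_equal(iv$cylinder, c(0.05, 0.15))
  expect_equal(iv$tower, c(0.5, 0.9))

  const <- tibble::tibble(label = rep(c("cylinder", "tower"), each = 2),
                          rate = rep(c(0.1, 0.6), each = 2))
  ivc <- fit_intervals(const, "minmax")
  expect_equal(diff(ivc$cylinder), 0)

  withr::with_seed(10, {
    u <- runif(1000)
  })
  ivp <- fit_intervals(tibble::tibble(label = c(rep("cylinder", 1000),
                                                "tower", "tower"),
                                      rate = c(u, 0.5, 0.6)),
                       "percentile95")
  expect_equal(ivp$cylinder, c(0.025, 0.975), tolerance = 0.02)

  expect_error(fit_intervals(tibble::tibble(label = "cylinder", rate = 1)),
               "at least 2")
})

test_that("the t-based confidence interval matches the closed form", {
  same <- mean_ci95(rep(2.5, 6))
  expect_equal(same$low, 2.5)
  expect_equal(same$high, 2.5)

  ci <- mean_ci95(1:5)
  expect_equal(ci$mean, 3)
  expect_equal(ci$high - ci$mean, 1.963243, tolerance = 1e-6)
  withr::with_seed(6, {
    x <- rnorm(30)
  })
  ci2 <- mean_ci95(x)
  expect_true(ci2$low <= mean(x) && mean(x) <= ci2$high)
  expect_error(mean_ci95(1), "n >= 2")
})
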