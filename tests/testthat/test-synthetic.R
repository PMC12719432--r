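test_that("region assignment follows the symmetric interface band", {
  geom <- slide_geometry(8000, 8000, tumor_center = c(4000, 4000),
                         tumor_radius_um = 2000, im_band_width_um = 1000)
  at_d <- function(d) assign_region(4000 + d, 4000, geom)
  expect_equal(at_d(0), "TC")
  expect_equal(at_d(1499.999), "TC")
  expect_equal(at_d(1500), "IM")        # inner band edge is in the band
  expect_equal(at_d(2000), "IM")        # boundary point is inside the band
  expect_equal(at_d(2500), "IM")
  expect_equal(at_d(2500.001), "N")
  expect_equal(at_d(3000), "N")
  expect_error(assign_region(8001, 10, geom), "outside slide")
  expect_error(slide_geometry(tumor_radius_um = 500, im_band_width_um = 1250),
               "exceed")
})

test_that("region assignment partitions every slide point exactly once", {
  geom <- slide_geometry()
  set.seed(5)
  x <- runif(2000, 0, geom$slide_width_um)
  y <- runif(2000, 0, geom$slide_height_um)
  reg <- assign_region(x, y, geom)
  expect_true(all(reg %in% c("TC", "IM", "N")))
  expect_equal(length(reg), 2000)
})

test_that("stamped frames lie fully inside a single compartment and never overlap", {
  geom <- slide_geometry()
  rois <- stamp_rois(geom, max_per_region = 8)
  expect_true(all(table(rois$region) >= 4))
  for (i in seq_len(nrow(rois))) {
    corners_x <- rois$x0_um[i] + c(0, rois$width_um[i], 0, rois$width_um[i])
    corners_y <- rois$y0_um[i] + c(0, 0, rois$height_um[i], rois$height_um[i])
    # corners plus the nearest interior point all share the frame's region
    expect_true(all(assign_region(corners_x, corners_y, geom) == rois$region[i]),
                label = rois$roi_id[i])
  }
  if (nrow(rois) > 1) {
    for (i in 1:(nrow(rois) - 1)) {
      for (j in (i + 1):nrow(rois)) {
        overlap <- abs(rois$x0_um[i] - rois$x0_um[j]) < rois$width_um[i] &&
          abs(rois$y0_um[i] - rois$y0_um[j]) < rois$height_um[i]
        expect_false(overlap)
      }
    }
  }
})

test_that("simulation is bit-identical under the same config and seed", {
  cfg <- sim_config(n_rois_per_region = 3, seed = 123)
  a <- simulate_slide(cfg)
  b <- simulate_slide(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$rois, b$rois)
})

test_that("zero intensities and no attractions give zero cells but stamped frames", {
  cfg <- sim_config(
    intensities = tibble::tibble(phenotype = "CD8+T", region = "TC",
                                 intensity = 0),
    attractions = default_sim_attractions("NG"),
    n_rois_per_region = 2, seed = 1)
  ds <- simulate_slide(cfg)
  expect_equal(nrow(ds$cells), 0)
  expect_gt(nrow(ds$rois), 0)
})

test_that("background counts match the Poisson mean over repeated seeds", {
  geom <- slide_geometry()
  areas_um2 <- region_areas(geom) * 1e6
  lambda <- 1e-4
  expected <- lambda * areas_um2[["TC"]]
  n_rep <- 200
  counts <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    set.seed(s)
    pts <- sim_poisson_points(lambda, geom$slide_width_um, geom$slide_height_um)
    counts[s] <- sum(assign_region(pts$x, pts$y, geom) == "TC")
  }
  # Monte-Carlo check of the Poisson mean: 3 sigma band on the mean of n_rep draws
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / n_rep))
})

test_that("attraction children always land within the placement radius of a parent", {
  set.seed(9)
  parents <- sim_poisson_points(5e-5, 3000, 3000)
  kids <- sim_cluster_children(parents, mean_children = 2, radius_um = 10,
                               width = 3000, height = 3000, boundary = "clip")
  d <- sqrt((kids$x - parents$x[kids$parent])^2 +
              (kids$y - parents$y[kids$parent])^2)
  expect_true(all(d <= 10 + 1e-9))
})

test_that("closed-form CSR effective score follows lambda * pi * r^2", {
  expect_equal(expected_effective_score_csr(0, 30), 0)
  expect_equal(expected_effective_score_csr(5e-4, 30), 5e-4 * pi * 900)
  expect_equal(expected_effective_score_csr(1e-3, 30), 1e-3 * pi * 900)
  expect_error(expected_effective_score_csr(-1, 30), "non-negative")
  expect_error(expected_effective_score_csr(1e-3, 0), "positive")
  expect_equal(expected_mean_pair_distance_csr(30), 20)
})

test_that("simulation fails loudly when a populated region cannot hold a frame", {
  geom <- slide_geometry(3000, 3000, tumor_radius_um = 700,
                         im_band_width_um = 1250)
  cfg <- sim_config(geometry = geom,
                    intensities = tibble::tibble(
                      phenotype = "CD8+T", region = "TC", intensity = 1e-4),
                    attractions = default_sim_attractions("NG"),
                    seed = 1)
  expect_error(simulate_slide(cfg), "region too small.*TC")
})
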