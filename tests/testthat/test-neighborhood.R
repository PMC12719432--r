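worked_example <- function() {
  make_cells(c(0, 100, 10, 20, 110, 200), c(0, 0, 0, 0, 0, 200),
             c(rep(list("C"), 2), rep(list("T"), 4)))
}

test_that("radius pairing matches the hand-worked example", {
  pairs <- find_pairs(worked_example(), "C", "T", 30)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$central_id, c("c1", "c1", "c2"))
  expect_equal(pairs$target_id, c("c3", "c4", "c5"))
  expect_equal(pairs$distance_um, c(10, 20, 10))
  met <- neighborhood_metrics(pairs, n_central = 2, n_target = 4)
  expect_equal(met$effective_score, 1.5)
  expect_equal(met$average_distance_um, 40 / 3)
})

test_that("a cell is never its own neighbor and the radius boundary is inclusive", {
  solo <- make_cells(5, 5, list(c("C", "T")))
  expect_equal(nrow(find_pairs(solo, "C", "T", 30)), 0)

  boundary <- make_cells(c(0, 30), c(0, 0), list("C", "T"))
  expect_equal(nrow(find_pairs(boundary, "C", "T", 30)), 1)
  beyond <- make_cells(c(0, 30.0001), c(0, 0), list("C", "T"))
  expect_equal(nrow(find_pairs(beyond, "C", "T", 30)), 0)
})

test_that("a target in range of k centrals contributes k pairs", {
  cells <- make_cells(c(0, 10, 5), c(0, 0, 0), list("C", "C", "T"))
  pairs <- find_pairs(cells, "C", "T", 30)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$central_id, c("c1", "c2"))
})

test_that("grid search equals the brute-force oracle on random fixtures", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    cells <- random_label_cells(n)
    r <- sample(c(10, 30, 80), 1)
    grid <- find_pairs(cells, "A", "B", r, method = "grid")
    brute <- find_pairs(cells, "A", "B", r, method = "brute")
    expect_identical(grid, brute)
  }
})

test_that("metrics handle empty neighborhoods and zero centrals", {
  empty <- find_pairs(make_cells(c(0, 500), c(0, 500), list("C", "T")),
                      "C", "T", 30)
  met <- neighborhood_metrics(empty, n_central = 5, n_target = 1)
  expect_equal(met$effective_score, 0)
  expect_true(is.na(met$average_distance_um))
  expect_true(met$defined)

  undef <- neighborhood_metrics(empty, n_central = 0, n_target = 1)
  expect_false(undef$defined)
  expect_true(is.na(undef$effective_score))
})

test_that("every central with one target at distance d gives score 1 and distance d", {
  d <- 17.5
  cells <- make_cells(c(0, 0, 300, 300), c(0, d, 0, d),
                      list("C", "T", "C", "T"))
  pairs <- find_pairs(cells, "C", "T", 30)
  met <- neighborhood_metrics(pairs, 2, 2)
  expect_equal(met$effective_score, 1)
  expect_equal(met$average_distance_um, d)
})

test_that("effective score is invariant to rigid translation and rotation", {
  set.seed(102)
  cells <- random_label_cells(200, width = 600, height = 400)
  base <- neighborhood_metrics(find_pairs(cells, "A", "B", 30),
                               sum(sapply(cells$phenotypes, function(p) "A" %in% p)),
                               sum(sapply(cells$phenotypes, function(p) "B" %in% p)))
  shifted <- cells
  shifted$x_um <- cells$x_um + 5
  shifted$y_um <- cells$y_um + 5
  expect_equal(find_pairs(shifted, "A", "B", 30)$distance_um,
               find_pairs(cells, "A", "B", 30)$distance_um)

  theta <- 0.7
  rotated <- cells
  rotated$x_um <- cells$x_um * cos(theta) - cells$y_um * sin(theta)
  rotated$y_um <- cells$x_um * sin(theta) + cells$y_um * cos(theta)
  met_rot <- neighborhood_metrics(find_pairs(rotated, "A", "B", 30),
                                  base$n_central, base$n_target)
  expect_equal(met_rot$effective_score, base$effective_score)
  expect_equal(met_rot$average_distance_um, base$average_distance_um,
               tolerance = 1e-10)
})

test_that("score and pair count are non-decreasing in the radius", {
  set.seed(103)
  cells <- random_label_cells(300)
  radii <- c(5, 10, 20, 30, 50, 100)
  n_c <- sum(sapply(cells$phenotypes, function(p) "A" %in% p))
  scores <- sapply(radii, function(r) {
    nrow(find_pairs(cells, "A", "B", r)) / n_c
  })
  expect_true(all(diff(scores) >= 0))
})

test_that("per-ROI table emits one row per ROI x query with flagged undefined rows", {
  cells <- dplyr::bind_rows(
    make_cells(c(10, 20), c(10, 10), list("C", "T"), roi_id = "r1"),
    make_cells(c(10, 20), c(10, 10), list("T", "T"), roi_id = "r2",
               prefix = "d"))
  rois <- make_rois(c("r1", "r2"), region = c("TC", "N"))
  ds <- tme_dataset(cells, rois, panel = character())
  queries <- neighborhood_query(c("C", "C"), c("T", "T"), c(30, 60))
  tab <- roi_neighborhood_table(ds, queries)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$defined[tab$roi_id == "r1"]))
  expect_true(all(!tab$defined[tab$roi_id == "r2"]))
})

test_that("pooling sums pairs and centrals before taking the ratio", {
  # two ROIs with (pairs, centrals) = (3, 2) and (1, 2): pooled score 4/4 = 1
  roi1 <- make_cells(c(0, 100, 10, 20, 110), c(0, 0, 0, 0, 0),
                     list("C", "C", "T", "T", "T"), roi_id = "r1")
  roi2 <- make_cells(c(0, 200, 10, 500), c(0, 0, 0, 0),
                     list("C", "C", "T", "T"), roi_id = "r2", prefix = "d")
  ds <- tme_dataset(dplyr::bind_rows(roi1, roi2),
                    make_rois(c("r1", "r2"), region = c("TC", "TC")),
                    panel = character())
  pooled <- pooled_neighborhood_metrics(ds, "C", "T", 30, scope = "all")
  expect_equal(pooled$n_pairs, 4)
  expect_equal(pooled$n_central, 4)
  expect_equal(pooled$effective_score, 1)

  # single-ROI scope reduces to the per-ROI metric
  ds1 <- tme_dataset(roi1, make_rois("r1"), panel = character())
  one <- pooled_neighborhood_metrics(ds1, "C", "T", 30, scope = "all")
  per_roi <- roi_neighborhood_table(ds1, neighborhood_query("C", "T", 30))
  expect_equal(one$effective_score, per_roi$effective_score)
  expect_equal(one$average_distance_um, per_roi$average_distance_um)
})

test_that("pooling never pairs across ROI boundaries", {
  # centrals in r1 sit within 30 um of targets in r2 in shared coordinates
  cells <- dplyr::bind_rows(
    make_cells(925, 10, list("C"), roi_id = "r1"),
    make_cells(935, 10, list("T"), roi_id = "r2", prefix = "d"))
  rois <- make_rois(c("r1", "r2"), x0 = c(0, 931))
  ds <- tme_dataset(cells, rois, panel = character())
  pooled <- pooled_neighborhood_metrics(ds, "C", "T", 30, scope = "all")
  expect_equal(pooled$n_pairs, 0)
})

test_that("permutation null is deterministic, bounded, and p = 1 when labels are exchangeable-identical", {
  set.seed(104)
  cells <- random_label_cells(80)
  a <- permutation_null(cells, "A", "B", 30, n_perm = 49, seed = 7)
  b <- permutation_null(cells, "A", "B", 30, n_perm = 49, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 50)
  expect_lte(a$p_value, 1)

  # all cells carry both labels: every permutation reproduces the observed score
  same <- make_cells(runif(20, 0, 100), runif(20, 0, 100),
                     rep(list(c("A", "B")), 20))
  res <- permutation_null(same, "A", "B", 30, n_perm = 19, seed = 1)
  expect_equal(res$p_value, 1)

  expect_error(permutation_null(make_cells(1, 1, list("A")), "A", "B",
                                n_perm = 9),
               "too few cells")
})

test_that("permutation p-values are calibrated under spatial randomness", {
  set.seed(105)
  n_sim <- 40
  rejected <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    cells <- random_label_cells(60, p_both = 0)
    res <- permutation_null(cells, "A", "B", 30, n_perm = 49, seed = s)
    rejected[s] <- res$p_value < 0.05
  }
  # nominal 5% level within Monte-Carlo slack
  expect_lt(mean(rejected), 0.12)
})
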