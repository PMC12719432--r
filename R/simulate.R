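#' Slide geometry for the synthetic tumor microenvironment
#'
#' The slide is a rectangle holding a circular tumor. Tissue compartments are
#' concentric: tumor core (TC) inside the tumor boundary minus half the
#' interface band, the invasion margin (IM) a band straddling the boundary
#' symmetrically, and normal tissue (N) outside. The default band width of
#' 1250 um is the midpoint of the 1--1.5 mm interface typically annotated on
#' resected specimens.
#'
#' @param slide_width_um,slide_height_um Slide dimensions in um.
#' @param tumor_center Numeric length-2, tumor center (x, y) in um; defaults
#'   to the slide center.
#' @param tumor_radius_um Tumor radius in um.
#' @param im_band_width_um Width of the invasion-margin band in um.
#' @return A `slide_geometry` object.
#' @export
slide_geometry <- function(slide_width_um = 8000, slide_height_um = 8000,
                           tumor_center = NULL, tumor_radius_um = 2300,
                           im_band_width_um = 1250) {
  if (is.null(tumor_center)) {
    tumor_center <- c(slide_width_um / 2, slide_height_um / 2)
  }
  if (im_band_width_um <= 0) abort("im_band_width_um must be positive")
  if (tumor_radius_um <= im_band_width_um / 2) {
    abort("tumor_radius_um must exceed half the invasion-margin band width")
  }
  structure(list(slide_width_um = slide_width_um,
                 slide_height_um = slide_height_um,
                 tumor_center = tumor_center,
                 tumor_radius_um = tumor_radius_um,
                 im_band_width_um = im_band_width_um),
            class = "slide_geometry")
}

#' Assign tissue compartments to points
#'
#' With `d` the distance to the tumor center, `R` the tumor radius and `w`
#' the band width: TC iff `d < R - w/2`; IM iff `R - w/2 <= d <= R + w/2`;
#' N otherwise. The band straddles the tumor boundary symmetrically, so every
#' point of the slide maps to exactly one compartment.
#'
#' @param x,y Point coordinates in um (vectorised).
#' @param geometry A [slide_geometry()].
#' @return Character vector of regions (`"TC"`, `"IM"`, `"N"`).
#' @export
assign_region <- function(x, y, geometry) {
  if (any(x < 0 | x > geometry$slide_width_um |
          y < 0 | y > geometry$slide_height_um)) {
    abort("point outside slide bounds")
  }
  d <- sqrt((x - geometry$tumor_center[1])^2 + (y - geometry$tumor_center[2])^2)
  r1 <- geometry$tumor_radius_um - geometry$im_band_width_um / 2
  r2 <- geometry$tumor_radius_um + geometry$im_band_width_um / 2
  dplyr::case_when(d < r1 ~ "TC", d <= r2 ~ "IM", TRUE ~ "N")
}

#' Analytic compartment areas
#'
#' Exact areas (mm^2) of TC, IM and N, valid when the outer band circle lies
#' fully inside the slide (the geometry the simulator defaults to).
#'
#' @param geometry A [slide_geometry()].
#' @return Named numeric vector (mm^2) over TC, IM, N.
#' @export
region_areas <- function(geometry) {
  r1 <- geometry$tumor_radius_um - geometry$im_band_width_um / 2
  r2 <- geometry$tumor_radius_um + geometry$im_band_width_um / 2
  cx <- geometry$tumor_center[1]; cy <- geometry$tumor_center[2]
  if (cx - r2 < 0 || cx + r2 > geometry$slide_width_um ||
      cy - r2 < 0 || cy + r2 > geometry$slide_height_um) {
    abort("outer band circle must lie fully inside the slide for analytic areas")
  }
  tc <- pi * r1^2
  im <- pi * (r2^2 - r1^2)
  n <- geometry$slide_width_um * geometry$slide_height_um - pi * r2^2
  c(TC = tc, IM = im, N = n) / 1e6
}

# distance from the tumor center to the nearest / farthest point of a rectangle
rect_dist_range <- function(x0, y0, w, h, cx, cy) {
  dx_min <- pmax(0, x0 - cx, cx - (x0 + w))
  dy_min <- pmax(0, y0 - cy, cy - (y0 + h))
  dx_max <- pmax(abs(x0 - cx), abs(x0 + w - cx))
  dy_max <- pmax(abs(y0 - cy), abs(y0 + h - cy))
  list(min = sqrt(dx_min^2 + dy_min^2), max = sqrt(dx_max^2 + dy_max^2))
}

#' Stamp fixed-size ROI frames inside each compartment
#'
#' Deterministic greedy placement: candidate lower-left corners on a regular
#' grid are scanned row-major; a candidate is accepted when its frame lies
#' fully inside one compartment and does not overlap a previously accepted
#' frame. Frames never cross compartment boundaries.
#'
#' @param geometry A [slide_geometry()].
#' @param group Treatment group label for the stamped frames (`"NG"`/`"EG"`).
#' @param slide_id Slide identifier used to build ROI ids.
#' @param width_um,height_um Frame size in um.
#' @param step_um Candidate grid pitch in um.
#' @param max_per_region Keep at most this many frames per compartment.
#' @return ROI tibble in the [read_roi_manifest()] layout (plus `area_mm2`),
#'   coordinates being slide-level lower-left corners.
#' @export
stamp_rois <- function(geometry, group = "EG", slide_id = "s1",
                       width_um = roi_default_size[["width_um"]],
                       height_um = roi_default_size[["height_um"]],
                       step_um = 100, max_per_region = Inf) {
  W <- geometry$slide_width_um; H <- geometry$slide_height_um
  r1 <- geometry$tumor_radius_um - geometry$im_band_width_um / 2
  r2 <- geometry$tumor_radius_um + geometry$im_band_width_um / 2
  cx <- geometry$tumor_center[1]; cy <- geometry$tumor_center[2]
  if (width_um > W || height_um > H) abort("ROI frame larger than the slide")

  ys <- seq(0, H - height_um, by = step_um)
  xs <- seq(0, W - width_um, by = step_um)
  cand <- expand.grid(x0 = xs, y0 = ys, KEEP.OUT.ATTRS = FALSE)
  dr <- rect_dist_range(cand$x0, cand$y0, width_um, height_um, cx, cy)
  cand$region <- dplyr::case_when(
    dr$max < r1 ~ "TC",
    dr$min >= r1 & dr$max <= r2 ~ "IM",
    dr$min > r2 ~ "N",
    TRUE ~ NA_character_
  )
  cand <- cand[!is.na(cand$region), , drop = FALSE]

  kept <- vector("list", nrow(cand))
  acc_x <- numeric(0); acc_y <- numeric(0)
  n_by_region <- c(TC = 0, IM = 0, N = 0)
  k <- 0
  for (i in seq_len(nrow(cand))) {
    reg <- cand$region[i]
    if (n_by_region[[reg]] >= max_per_region) next
    x0 <- cand$x0[i]; y0 <- cand$y0[i]
    if (k > 0) {
      overlap <- any(abs(acc_x - x0) < width_um & abs(acc_y - y0) < height_um)
      if (overlap) next
    }
    k <- k + 1
    acc_x[k] <- x0; acc_y[k] <- y0
    n_by_region[[reg]] <- n_by_region[[reg]] + 1
    kept[[k]] <- tibble(region = reg, x0_um = x0, y0_um = y0)
  }
  frames <- dplyr::bind_rows(kept[seq_len(k)])
  if (k == 0) frames <- tibble(region = character(), x0_um = numeric(), y0_um = numeric())
  frames <- frames |>
    dplyr::arrange(factor(region, levels = tme_regions), x0_um, y0_um) |>
    dplyr::group_by(region) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::ungroup()
  tibble(roi_id = sprintf("%s_%s_%02d", slide_id, frames$region, frames$idx),
         slide_id = slide_id, group = group, region = frames$region,
         x0_um = frames$x0_um, y0_um = frames$y0_um,
         width_um = width_um, height_um = height_um,
         area_mm2 = width_um * height_um / 1e6)
}

#' Spatial attraction between two phenotypes
#'
#' Parent--child (Thomas-style) clustering: each realised central cell spawns
#' `Poisson(mean_children)` extra target cells placed uniformly in the disk
#' of radius `placement_radius_um` around it. The mean number of children per
#' central maps directly onto the neighborhood effective score when the
#' placement radius does not exceed the query radius.
#'
#' @param central_phenotype,target_phenotype Phenotype labels.
#' @param mean_children Mean extra target cells per central (mu >= 0).
#' @param placement_radius_um Placement disk radius in um (> 0).
#' @return One-row tibble.
#' @export
attraction_spec <- function(central_phenotype, target_phenotype,
                            mean_children, placement_radius_um) {
  if (mean_children < 0) abort("mean_children must be non-negative")
  if (placement_radius_um <= 0) abort("placement_radius_um must be positive")
  tibble(central_phenotype = central_phenotype,
         target_phenotype = target_phenotype,
         mean_children = mean_children,
         placement_radius_um = placement_radius_um)
}

#' Default per-region generating intensities
#'
#' Per-phenotype background intensities (cells/mm^2, converted internally to
#' cells/um^2) emulating the contrast the analysis is designed to detect:
#' under checkpoint blockade (`"EG"`) CD8 tissue-resident subsets ramp up
#' from normal tissue through the invasion margin into the tumor core, while
#' the untreated profile (`"NG"`) is spatially flat.
#'
#' @param group `"NG"` or `"EG"`.
#' @return Tibble with columns `phenotype`, `region`, `intensity`
#'   (cells/um^2).
#' @export
default_sim_intensities <- function(group = c("EG", "NG")) {
  group <- match.arg(group)
  per_mm2 <- if (group == "EG") {
    tibble::tribble(
      ~phenotype,       ~N,  ~IM,  ~TC,
      "CD8+T",          200, 220,  300,
      "CD4+T",          130, 180,  130,
      "CD68+",          150, 150,  150,
      "CD8+TRM",        60,  120,  240,
      "CD8+PD-1+TRM",   20,  60,   150,
      "CD8+CD69+T",     50,  50,   50,
      "CD4+CD69+TRM",   40,  40,   40,
      "CD4+PD-1+TRM",   25,  25,   25
    )
  } else {
    tibble::tribble(
      ~phenotype,       ~N,  ~IM,  ~TC,
      "CD8+T",          150, 150,  150,
      "CD4+T",          200, 200,  200,
      "CD68+",          150, 150,  150,
      "CD8+TRM",        80,  80,   80,
      "CD8+PD-1+TRM",   60,  60,   60,
      "CD8+CD69+T",     50,  50,   50,
      "CD4+CD69+TRM",   60,  60,   60,
      "CD4+PD-1+TRM",   40,  40,   40
    )
  }
  per_mm2 |>
    tidyr::pivot_longer(cols = c("N", "IM", "TC"),
                        names_to = "region", values_to = "intensity") |>
    dplyr::mutate(intensity = intensity / 1e6)
}

#' Default attraction rules
#'
#' Under checkpoint blockade the CD8+PD-1+ tissue-resident subset clusters
#' around CD68+ myeloid cells; the untreated profile has no attraction.
#'
#' @param group `"NG"` or `"EG"`.
#' @return Attraction tibble (possibly empty).
#' @export
default_sim_attractions <- function(group = c("EG", "NG")) {
  group <- match.arg(group)
  if (group == "EG") {
    attraction_spec("CD8+PD-1+TRM", "CD68+", mean_children = 2,
                    placement_radius_um = 15)
  } else {
    tibble(central_phenotype = character(), target_phenotype = character(),
           mean_children = numeric(), placement_radius_um = numeric())
  }
}

#' Default marker-emission model
#'
#' Per-marker log-normal intensity components: positive cells at meanlog
#' log(10), negative cells at meanlog 0, both with sdlog 0.35 — a ten-fold
#' separation wide enough that threshold gating at the log-midpoint recovers
#' the generating phenotype for essentially every cell.
#'
#' @param panel Marker names.
#' @return Tibble with columns `marker`, `pos_meanlog`, `pos_sdlog`,
#'   `neg_meanlog`, `neg_sdlog`.
#' @export
default_marker_model <- function(panel = default_panel()) {
  tibble(marker = panel,
         pos_meanlog = log(10), pos_sdlog = 0.35,
         neg_meanlog = 0, neg_sdlog = 0.35)
}

#' Full simulation configuration
#'
#' @param geometry A [slide_geometry()].
#' @param intensities Tibble `phenotype`, `region`, `intensity` (cells/um^2).
#' @param attractions Attraction tibble (see [attraction_spec()]).
#' @param marker_model Tibble as from [default_marker_model()].
#' @param rules Phenotype rule set mapping each generated phenotype to the
#'   markers it must express (used by the marker-emission step).
#' @param group,slide_id Labels stamped onto the generated ROI frames.
#' @param boundary_mode `"clip"` (children falling off the slide are dropped)
#'   or `"toroidal"` (wrapped); toroidal placement makes edge-free closed
#'   forms exact in validation runs.
#' @param n_rois_per_region Frames stamped per compartment.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(geometry = slide_geometry(),
                       intensities = default_sim_intensities("EG"),
                       attractions = default_sim_attractions("EG"),
                       marker_model = default_marker_model(),
                       rules = default_phenotype_rules(),
                       group = "EG", slide_id = "s1",
                       boundary_mode = c("clip", "toroidal"),
                       n_rois_per_region = 6,
                       seed = 1L) {
  boundary_mode <- match.arg(boundary_mode)
  if (any(intensities$intensity < 0)) abort("intensities must be non-negative")
  unknown <- setdiff(unique(c(intensities$phenotype,
                              attractions$central_phenotype,
                              attractions$target_phenotype)),
                     rules$name)
  if (length(unknown) > 0) {
    abort(paste0("phenotype(s) without a rule: ", paste(unknown, collapse = ", ")))
  }
  structure(list(geometry = geometry, intensities = intensities,
                 attractions = attractions, marker_model = marker_model,
                 rules = rules, group = group, slide_id = slide_id,
                 boundary_mode = boundary_mode,
                 n_rois_per_region = n_rois_per_region,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seed from a base seed and string tags
substream_seed <- function(base, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 1987654321
  (as.numeric(base) * 7919 + h) %% 2147483647
}

#' Homogeneous Poisson points on a rectangle
#'
#' Uses the current RNG state; callers control reproducibility with
#' `set.seed()`.
#'
#' @param lambda Intensity in points/um^2.
#' @param width,height Window dimensions in um.
#' @return Tibble with columns `x`, `y`.
#' @export
sim_poisson_points <- function(lambda, width, height) {
  if (lambda < 0) abort("lambda must be non-negative")
  n <- rpois(1, lambda * width * height)
  tibble(x = runif(n, 0, width), y = runif(n, 0, height))
}

#' Scatter cluster children around parent points
#'
#' Each parent spawns `Poisson(mean_children)` children uniformly in the disk
#' of radius `radius_um`; children leaving the window are dropped (`"clip"`)
#' or wrapped (`"toroidal"`). Uses the current RNG state.
#'
#' @param parents Tibble with columns `x`, `y`.
#' @param mean_children Mean children per parent.
#' @param radius_um Placement disk radius.
#' @param width,height Window dimensions in um.
#' @param boundary `"clip"` or `"toroidal"`.
#' @return Tibble with columns `x`, `y`, `parent` (parent row index).
#' @export
sim_cluster_children <- function(parents, mean_children, radius_um,
                                 width, height,
                                 boundary = c("clip", "toroidal")) {
  boundary <- match.arg(boundary)
  n_par <- nrow(parents)
  if (n_par == 0) return(tibble(x = numeric(), y = numeric(), parent = integer()))
  counts <- rpois(n_par, mean_children)
  total <- sum(counts)
  if (total == 0) return(tibble(x = numeric(), y = numeric(), parent = integer()))
  parent <- rep(seq_len(n_par), counts)
  # uniform in a disk: radius ~ a*sqrt(U), angle uniform
  rad <- radius_um * sqrt(runif(total))
  ang <- runif(total, 0, 2 * pi)
  x <- parents$x[parent] + rad * cos(ang)
  y <- parents$y[parent] + rad * sin(ang)
  if (boundary == "toroidal") {
    x <- x %% width
    y <- y %% height
  } else {
    keep <- x >= 0 & x <= width & y >= 0 & y <= height
    x <- x[keep]; y <- y[keep]; parent <- parent[keep]
  }
  tibble(x = x, y = y, parent = parent)
}

#' Expected effective score under complete spatial randomness
#'
#' Edge-free expectation of target neighbors per central cell when targets
#' form a homogeneous Poisson process: `lambda * pi * r^2`.
#'
#' @param lambda_target Target intensity in cells/um^2.
#' @param radius Query radius in um.
#' @return Expected effective score.
#' @export
expected_effective_score_csr <- function(lambda_target, radius) {
  if (lambda_target < 0) abort("lambda_target must be non-negative")
  if (radius <= 0) abort("radius must be positive")
  lambda_target * pi * radius^2
}

#' Expected mean pair distance under complete spatial randomness
#'
#' Distances of uniform points in a disk of radius `r` have density
#' proportional to `d`, so the mean pair distance is `2r/3`.
#'
#' @param radius Query radius in um.
#' @return Expected mean pair distance.
#' @export
expected_mean_pair_distance_csr <- function(radius) {
  if (radius <= 0) abort("radius must be positive")
  2 * radius / 3
}

#' Simulate a synthetic tumor slide
#'
#' For every (phenotype, compartment) pair, background cells are a
#' homogeneous Poisson process restricted to the compartment at the
#' configured intensity. Each attraction rule then makes every realised
#' central cell spawn `Poisson(mean_children)` extra target cells uniformly
#' in its placement disk. Marker intensities are emitted per cell from the
#' positive component for markers the generating phenotype requires and the
#' negative component otherwise. ROI frames are stamped fully inside each
#' compartment; cells outside every frame are discarded and the rest are
#' re-expressed in ROI-local coordinates.
#'
#' Randomness is drawn from substreams derived deterministically from the
#' seed per phenotype/compartment, so adding a phenotype never perturbs the
#' realisation of the others; identical configs give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A [tme_dataset()] whose cells carry a `true_phenotype` column
#'   (the generating label) and an empty `phenotypes` column to be filled by
#'   [gate_cells()].
#' @export
simulate_slide <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geom <- config$geometry
  W <- geom$slide_width_um; H <- geom$slide_height_um

  rois <- stamp_rois(geom, group = config$group, slide_id = config$slide_id,
                     max_per_region = config$n_rois_per_region)
  active_regions <- unique(config$intensities$region[config$intensities$intensity > 0])
  missing_frames <- setdiff(active_regions, unique(rois$region))
  if (length(missing_frames) > 0) {
    abort(paste0("region too small to hold one ROI frame: ",
                 paste(missing_frames, collapse = ", ")))
  }

  # background: Poisson over the slide, restricted to the compartment
  combos <- config$intensities |>
    dplyr::filter(intensity > 0) |>
    dplyr::arrange(phenotype, region)
  bg <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ph <- combos$phenotype[i]; reg <- combos$region[i]
    set.seed(substream_seed(config$seed, "bg", ph, reg))
    pts <- sim_poisson_points(combos$intensity[i], W, H)
    if (nrow(pts) > 0) {
      keep <- assign_region(pts$x, pts$y, geom) == reg
      pts <- pts[keep, , drop = FALSE]
    }
    bg[[i]] <- tibble(x = pts$x, y = pts$y, true_phenotype = ph)
  }
  cells <- dplyr::bind_rows(bg)

  # attraction children
  if (nrow(config$attractions) > 0) {
    att <- dplyr::arrange(config$attractions, central_phenotype, target_phenotype)
    for (i in seq_len(nrow(att))) {
      parents <- cells[cells$true_phenotype == att$central_phenotype[i],
                       c("x", "y")]
      set.seed(substream_seed(config$seed, "att", att$central_phenotype[i],
                              att$target_phenotype[i]))
      kids <- sim_cluster_children(parents, att$mean_children[i],
                                   att$placement_radius_um[i], W, H,
                                   boundary = config$boundary_mode)
      if (nrow(kids) > 0) {
        cells <- dplyr::bind_rows(
          cells,
          tibble(x = kids$x, y = kids$y,
                 true_phenotype = att$target_phenotype[i]))
      }
    }
  }

  if (nrow(cells) == 0) {
    empty <- tibble(cell_id = character(), roi_id = character(),
                    x_um = numeric(), y_um = numeric())
    for (m in config$marker_model$marker) empty[[m]] <- numeric()
    empty$true_phenotype <- character()
    empty$phenotypes <- list()
    return(tme_dataset(empty, rois, panel = config$marker_model$marker,
                       validate = FALSE))
  }

  # marker emission, per generating phenotype so streams stay independent
  mm <- config$marker_model
  for (m in mm$marker) cells[[m]] <- NA_real_
  rules <- config$rules
  for (ph in sort(unique(cells$true_phenotype))) {
    sel <- which(cells$true_phenotype == ph)
    pos_markers <- rules$positive[[match(ph, rules$name)]]
    set.seed(substream_seed(config$seed, "markers", ph))
    for (j in seq_len(nrow(mm))) {
      m <- mm$marker[j]
      if (m %in% pos_markers) {
        cells[[m]][sel] <- rlnorm(length(sel), mm$pos_meanlog[j], mm$pos_sdlog[j])
      } else {
        cells[[m]][sel] <- rlnorm(length(sel), mm$neg_meanlog[j], mm$neg_sdlog[j])
      }
    }
  }

  # crop to stamped frames (half-open bounds); cells keep slide coordinates
  cells$roi_id <- NA_character_
  for (i in seq_len(nrow(rois))) {
    inside <- is.na(cells$roi_id) &
      cells$x >= rois$x0_um[i] & cells$x < rois$x0_um[i] + rois$width_um[i] &
      cells$y >= rois$y0_um[i] & cells$y < rois$y0_um[i] + rois$height_um[i]
    cells$roi_id[inside] <- rois$roi_id[i]
  }
  cells <- cells[!is.na(cells$roi_id), , drop = FALSE]

  out <- tibble(cell_id = sprintf("c%06d", seq_len(max(nrow(cells), 0))),
                roi_id = cells$roi_id,
                x_um = cells$x, y_um = cells$y) |>
    dplyr::bind_cols(cells[mm$marker]) |>
    dplyr::mutate(true_phenotype = cells$true_phenotype,
                  phenotypes = rep(list(character()), nrow(cells)))
  tme_dataset(out, rois, panel = mm$marker, validate = FALSE)
}
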