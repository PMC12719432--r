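#' Regions and treatment groups recognised in ROI manifests
#'
#' Tissue compartments are `TC` (tumor core), `IM` (invasion margin, the
#' tumor--normal interface band) and `N` (tumor-free normal tissue). Treatment
#' groups are `NG` (untreated) and `EG` (immune-checkpoint-blockade treated).
#'
#' @name tme-vocab
#' @keywords internal
NULL

tme_regions <- c("TC", "IM", "N")
tme_groups <- c("NG", "EG")

#' Default ROI frame size in micrometres
#'
#' Fixed-size fields stamped on a whole-slide scan at a 20x objective:
#' 931 um wide by 698 um high (0.649838 mm^2).
#'
#' @format Named numeric vector with elements `width_um` and `height_um`.
#' @export
roi_default_size <- c(width_um = 931, height_um = 698)

#' Assemble a cell-map dataset
#'
#' Bundles a cell table, an ROI manifest and a marker panel into a single
#' validated object that the rest of the pipeline consumes.
#'
#' @param cells Tibble of segmented cells: columns `cell_id`, `roi_id`,
#'   `x_um`, `y_um`, one numeric intensity column per panel marker, and a
#'   `phenotypes` list-column of character vectors (possibly empty).
#' @param rois Tibble of ROI frames as returned by [read_roi_manifest()].
#' @param panel Character vector of marker names; defaults to the intensity
#'   columns found in `cells`.
#' @param validate If `TRUE` (default) the dataset is checked with
#'   [validate_dataset()] and assembly fails on any violation.
#'
#' @return An object of class `tme_dataset`: a list with elements `cells`,
#'   `rois` and `panel`.
#' @export
tme_dataset <- function(cells, rois, panel = NULL, validate = TRUE) {
  cells <- as_tibble(cells)
  rois <- as_tibble(rois)
  if (is.null(panel)) {
    reserved <- c("cell_id", "roi_id", "x_um", "y_um", "phenotypes")
    panel <- setdiff(names(cells), reserved)
  }
  if (!"phenotypes" %in% names(cells)) {
    cells$phenotypes <- rep(list(character()), nrow(cells))
  }
  ds <- structure(list(cells = cells, rois = rois, panel = panel),
                  class = "tme_dataset")
  if (validate) {
    rep <- validate_dataset(ds)
    if (nrow(rep$violations) > 0) {
      abort(c("dataset validation failed",
              paste(utils::head(rep$violations$message, 5), collapse = "; ")))
    }
  }
  ds
}

#' @export
print.tme_dataset <- function(x, ...) {
  cat("<tme_dataset>\n")
  cat("  cells :", nrow(x$cells), "across", nrow(x$rois), "ROIs\n")
  cat("  panel :", paste(x$panel, collapse = ", "), "\n")
  tab <- dplyr::count(x$rois, region, group)
  cat("  ROIs  :", paste(sprintf("%s/%s=%d", tab$region, tab$group, tab$n),
                         collapse = " "), "\n")
  invisible(x)
}

parse_phenotypes <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE) |>
    map(~ .x[nzchar(.x)])
}

format_phenotypes <- function(x) {
  map_chr(x, paste, collapse = ";")
}

#' Read a cell table from delimited text
#'
#' The file is comma-separated with a mandatory header naming `cell_id`,
#' `roi_id`, `x_um`, `y_um`, one intensity column per panel marker and an
#' optional `phenotypes` column holding semicolon-separated labels. Row order
#' is preserved.
#'
#' @param path Path to the CSV file.
#' @param panel Character vector of marker names expected as columns.
#' @return Tibble of cells (one row per cell) with a `phenotypes` list-column.
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) abort(paste0("cell table not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  required <- c("cell_id", "roi_id", "x_um", "y_um", panel)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("cell table is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  num_cols <- c("x_um", "y_um", panel)
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                    col, bad[1], raw[[col]][bad[1]]))
    }
    raw[[col]] <- vals
  }
  dup <- raw$cell_id[duplicated(raw$cell_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate cell_id: ", paste(unique(dup), collapse = ", ")))
  }
  neg <- panel[map_lgl(panel, ~ any(raw[[.x]] < 0, na.rm = TRUE))]
  if (length(neg) > 0) {
    abort(paste0("negative intensity in marker column(s): ",
                 paste(neg, collapse = ", ")))
  }
  phen <- if ("phenotypes" %in% names(raw)) {
    parse_phenotypes(raw$phenotypes)
  } else {
    rep(list(character()), nrow(raw))
  }
  tibble(cell_id = raw$cell_id, roi_id = raw$roi_id,
         x_um = raw$x_um, y_um = raw$y_um) |>
    dplyr::bind_cols(raw[panel]) |>
    dplyr::mutate(phenotypes = phen)
}

#' Write a cell table to delimited text
#'
#' Inverse of [read_cell_table()]: the `phenotypes` list-column is serialised
#' as semicolon-separated labels. Coordinates and intensities are written with
#' full precision so a read-back reproduces the values exactly.
#'
#' @param cells Cell tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  if ("phenotypes" %in% names(out)) {
    out$phenotypes <- format_phenotypes(out$phenotypes)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an ROI manifest from delimited text
#'
#' Columns: `roi_id`, `slide_id`, `group` (NG or EG), `region` (TC, IM or N),
#' `x0_um`, `y0_um` (lower-left corner), and optional `width_um` / `height_um`
#' which default to the fixed stamp size of 931 x 698 um.
#'
#' @param path Path to the CSV file.
#' @return Tibble of ROI frames with an `area_mm2` column.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("ROI manifest not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  required <- c("roi_id", "slide_id", "group", "region", "x0_um", "y0_um")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("ROI manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("width_um", "height_um")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  raw$width_um[!nzchar(raw$width_um) | is.na(raw$width_um)] <-
    as.character(roi_default_size[["width_um"]])
  raw$height_um[!nzchar(raw$height_um) | is.na(raw$height_um)] <-
    as.character(roi_default_size[["height_um"]])
  for (col in c("x0_um", "y0_um", "width_um", "height_um")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1]))
    }
    raw[[col]] <- vals
  }
  build_roi_frames(raw)
}

build_roi_frames <- function(raw) {
  bad_region <- setdiff(unique(raw$region), tme_regions)
  if (length(bad_region) > 0) {
    abort(sprintf("unknown region '%s'; allowed: %s",
                  bad_region[1], paste(tme_regions, collapse = ", ")))
  }
  bad_group <- setdiff(unique(raw$group), tme_groups)
  if (length(bad_group) > 0) {
    abort(sprintf("unknown group '%s'; allowed: %s",
                  bad_group[1], paste(tme_groups, collapse = ", ")))
  }
  dup <- raw$roi_id[duplicated(raw$roi_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate roi_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(raw$width_um <= 0) || any(raw$height_um <= 0)) {
    abort("ROI width_um and height_um must be positive")
  }
  tibble(roi_id = raw$roi_id, slide_id = raw$slide_id,
         group = raw$group, region = raw$region,
         x0_um = raw$x0_um, y0_um = raw$y0_um,
         width_um = raw$width_um, height_um = raw$height_um,
         area_mm2 = raw$width_um * raw$height_um / 1e6)
}

#' Write an ROI manifest to delimited text
#'
#' @param rois ROI tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_manifest <- function(rois, path) {
  cols <- c("roi_id", "slide_id", "group", "region",
            "x0_um", "y0_um", "width_um", "height_um")
  readr::write_csv(rois[cols], path, progress = FALSE)
  invisible(path)
}

#' Validate a cell-map dataset
#'
#' Checks referential integrity and geometry: every cell must reference an
#' existing ROI and fall inside its frame. ROI bounds are half-open,
#' `[x0, x0 + width) x [y0, y0 + height)`, so adjacent stamped frames
#' partition space without double counting. Violations are reported, not
#' raised.
#'
#' @param dataset A `tme_dataset` (or a list with `cells` and `rois`).
#' @return A list with `per_roi` (tibble: roi_id, n_cells, n_out_of_bounds)
#'   and `violations` (tibble: cell_id, roi_id, kind, message); the dataset is
#'   acceptable iff `violations` has zero rows.
#' @export
validate_dataset <- function(dataset) {
  cells <- dataset$cells
  rois <- dataset$rois
  joined <- dplyr::left_join(
    cells[c("cell_id", "roi_id", "x_um", "y_um")],
    rois[c("roi_id", "x0_um", "y0_um", "width_um", "height_um")],
    by = "roi_id"
  )
  dangling <- is.na(joined$x0_um)
  inside <- !dangling &
    joined$x_um >= joined$x0_um & joined$x_um < joined$x0_um + joined$width_um &
    joined$y_um >= joined$y0_um & joined$y_um < joined$y0_um + joined$height_um
  out_of_bounds <- !dangling & !inside

  violations <- dplyr::bind_rows(
    tibble(cell_id = joined$cell_id[dangling],
           roi_id = joined$roi_id[dangling],
           kind = "dangling_roi",
           message = sprintf("cell %s references unknown ROI %s",
                             joined$cell_id[dangling], joined$roi_id[dangling])),
    tibble(cell_id = joined$cell_id[out_of_bounds],
           roi_id = joined$roi_id[out_of_bounds],
           kind = "out_of_bounds",
           message = sprintf("cell %s at (%g, %g) lies outside ROI %s",
                             joined$cell_id[out_of_bounds],
                             joined$x_um[out_of_bounds],
                             joined$y_um[out_of_bounds],
                             joined$roi_id[out_of_bounds]))
  )
  oob_tab <- tibble(roi_id = joined$roi_id[!dangling], oob = out_of_bounds[!dangling]) |>
    dplyr::group_by(roi_id) |>
    dplyr::summarise(n_cells = dplyr::n(), n_out_of_bounds = sum(oob), .groups = "drop")
  per_roi <- dplyr::full_join(rois["roi_id"], oob_tab, by = "roi_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(n_cells, 0L),
                  n_out_of_bounds = dplyr::coalesce(n_out_of_bounds, 0L))
  list(per_roi = per_roi, violations = violations)
}
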