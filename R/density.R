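#' Per-ROI phenotype densities and proportions
#'
#' One record per ROI x phenotype. Counts use non-exclusive labels: a cell
#' counts toward every phenotype it carries. Density is count / ROI area
#' (cells/mm^2); proportion is the fraction of all cells in the ROI carrying
#' the label.
#'
#' @param dataset Gated [tme_dataset()].
#' @param phenotypes Phenotype labels to tabulate.
#' @return Tibble of class `tme_density` with columns `roi_id`, `region`,
#'   `group`, `phenotype`, `count`, `area_mm2`, `density`, `proportion`.
#' @export
density_table <- function(dataset, phenotypes) {
  cells <- dataset$cells
  rois <- dataset$rois
  totals <- cells |> dplyr::count(roi_id, name = "n_cells_total")
  long <- tibble(roi_id = rep(cells$roi_id, lengths(cells$phenotypes)),
                 phenotype = unlist(cells$phenotypes)) |>
    dplyr::filter(phenotype %in% phenotypes) |>
    dplyr::count(roi_id, phenotype, name = "count")
  grid <- tidyr::expand_grid(roi_id = rois$roi_id, phenotype = phenotypes)
  out <- grid |>
    dplyr::left_join(long, by = c("roi_id", "phenotype")) |>
    dplyr::left_join(totals, by = "roi_id") |>
    dplyr::left_join(rois[c("roi_id", "region", "group", "area_mm2")],
                     by = "roi_id") |>
    dplyr::mutate(
      count = dplyr::coalesce(count, 0L),
      n_cells_total = dplyr::coalesce(n_cells_total, 0L),
      density = count / area_mm2,
      proportion = ifelse(n_cells_total > 0, count / n_cells_total, 0)) |>
    dplyr::select(roi_id, region, group, phenotype, count, area_mm2,
                  density, proportion)
  class(out) <- c("tme_density", class(out))
  out
}
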