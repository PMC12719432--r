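#' ROI-by-phenotype cell-count matrix
#'
#' Entry (roi, phenotype) = number of cells in that ROI carrying the label
#' (non-exclusive counts). Optional filters subset the ROI rows to one
#' region and/or one group before the matrix is built.
#'
#' @param dataset Gated [tme_dataset()].
#' @param phenotypes Phenotype labels (columns).
#' @param region,group Optional filters (`NULL` keeps everything).
#' @return Integer matrix with ROI ids as rownames; possibly zero rows after
#'   filtering.
#' @export
count_matrix <- function(dataset, phenotypes, region = NULL, group = NULL) {
  rois <- dataset$rois
  if (!is.null(region)) rois <- rois[rois$region %in% region, ]
  if (!is.null(group)) rois <- rois[rois$group %in% group, ]
  dens <- density_table(
    tme_dataset(dataset$cells[dataset$cells$roi_id %in% rois$roi_id, ],
                rois, panel = dataset$panel, validate = FALSE),
    phenotypes)
  wide <- dens |>
    dplyr::select(roi_id, phenotype, count) |>
    tidyr::pivot_wider(names_from = phenotype, values_from = count)
  m <- as.matrix(wide[phenotypes])
  storage.mode(m) <- "integer"
  rownames(m) <- wide$roi_id
  m
}

#' Pairwise Pearson correlation network over phenotype counts
#'
#' Product-moment r per phenotype pair across ROIs, with the two-sided
#' p-value from `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. Pairs involving a constant column (or fewer than 3 ROIs) are
#' emitted flagged undefined rather than dropped, so exports stay
#' rectangular.
#'
#' @param matrix Count matrix from [count_matrix()].
#' @param alpha Significance level for the `significant` annotation.
#' @return Tibble of class `tme_corr`: `phenotype_a`, `phenotype_b`, `n`,
#'   `r`, `p_value`, `significant`, `defined`.
#' @export
pearson_network <- function(matrix, alpha = 0.05) {
  phen <- colnames(matrix)
  n <- nrow(matrix)
  combs <- utils::combn(phen, 2)
  rows <- vector("list", ncol(combs))
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    xa <- matrix[, a]; xb <- matrix[, b]
    ok <- n >= 3 && sd(xa) > 0 && sd(xb) > 0
    if (ok) {
      ct <- cor.test(xa, xb, method = "pearson")
      rows[[j]] <- tibble(phenotype_a = a, phenotype_b = b, n = n,
                          r = unname(ct$estimate), p_value = ct$p.value,
                          significant = ct$p.value < alpha, defined = TRUE)
    } else {
      rows[[j]] <- tibble(phenotype_a = a, phenotype_b = b, n = n,
                          r = NA_real_, p_value = NA_real_,
                          significant = NA, defined = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tme_corr", class(out))
  out
}
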