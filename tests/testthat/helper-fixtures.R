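# Builders for in-memory fixtures; everything is generated, nothing stored.

make_cells <- function(x, y, labels, roi_id = "r1", prefix = "c") {
  tibble::tibble(
    cell_id = paste0(prefix, seq_along(x)),
    roi_id = roi_id,
    x_um = x, y_um = y,
    phenotypes = lapply(labels, function(l) if (is.null(l)) character() else l))
}

make_rois <- function(roi_id = "r1", group = "EG", region = "TC",
                      x0 = 0, y0 = 0, width = 931, height = 698) {
  tibble::tibble(roi_id = roi_id, slide_id = "s1", group = group,
                 region = region, x0_um = x0, y0_um = y0,
                 width_um = width, height_um = height,
                 area_mm2 = width * height / 1e6)
}

# random labelled point fixture on one ROI frame
random_label_cells <- function(n, labels = c("A", "B"), width = 931,
                               height = 698, p_both = 0.1) {
  pick <- sample(c(labels, "both"), n, replace = TRUE,
                 prob = c(rep((1 - p_both) / length(labels), length(labels)),
                          p_both))
  make_cells(runif(n, 0, width), runif(n, 0, height),
             lapply(pick, function(s) if (s == "both") labels else s))
}

# single big rectangular window disguised as one ROI, for validation runs
window_dataset <- function(cells, width, height, group = "EG", region = "TC") {
  tmespatial::tme_dataset(
    cells, make_rois(group = group, region = region,
                     width = width, height = height),
    panel = character(), validate = FALSE)
}

# fraction of simulated cells whose generating phenotype is among the gated labels
recovery_rate <- function(gated_cells) {
  mean(mapply(function(tp, ph) tp %in% ph,
              gated_cells$true_phenotype, gated_cells$phenotypes))
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
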