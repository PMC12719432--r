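#' Phenotype rules
#'
#' A phenotype rule is a boolean combination of marker-positivity literals:
#' the cell must be positive for every marker in `positive` and negative for
#' every marker in `negative`. Rules are non-exclusive — a cell receives every
#' label whose rule it satisfies, so composite labels nest (a
#' CD8+CD103+PD-1+ cell is both `CD8+TRM` and `CD8+PD-1+TRM`).
#'
#' @param name Phenotype label.
#' @param positive Markers required above threshold.
#' @param negative Markers required below threshold (may be empty).
#' @return One-row tibble with list-columns `positive` and `negative`.
#' @export
phenotype_rule <- function(name, positive, negative = character()) {
  tibble(name = name, positive = list(positive), negative = list(negative))
}

#' Default phenotype rule set for the six-marker panel
#'
#' Encodes the conventional gates for a CD8/CD4/CD69/CD68/PD-1/CD103 panel:
#' tissue-residence is read from CD103 for CD8 T cells and from CD69 for CD4
#' T cells. All rules are replaceable; nothing downstream assumes this set.
#'
#' @return Tibble of rules, one row per phenotype label.
#' @export
default_phenotype_rules <- function() {
  dplyr::bind_rows(
    phenotype_rule("CD8+T", "CD8"),
    phenotype_rule("CD4+T", "CD4"),
    phenotype_rule("CD68+", "CD68"),
    phenotype_rule("CD8+TRM", c("CD8", "CD103")),
    phenotype_rule("CD8+PD-1+TRM", c("CD8", "CD103", "PD1")),
    phenotype_rule("CD8+CD69+T", c("CD8", "CD69")),
    phenotype_rule("CD4+CD69+TRM", c("CD4", "CD69")),
    phenotype_rule("CD4+PD-1+TRM", c("CD4", "CD69", "PD1"))
  )
}

#' Default marker panel
#' @return Character vector of the six marker names.
#' @export
default_panel <- function() c("CD8", "CD4", "CD69", "CD68", "PD1", "CD103")

#' Gating configuration
#'
#' @param thresholds Named numeric vector: per-marker positivity threshold in
#'   intensity units. Positivity is inclusive (intensity >= threshold).
#' @param rules Rule tibble as from [default_phenotype_rules()].
#' @param lineage_conflict_policy What to do with cells positive for more than
#'   one exclusive lineage marker (`lineage_markers`): `"flag_ambiguous"`
#'   labels the cell `"ambiguous"` (and nothing else); `"drop"` removes it
#'   from the gated output.
#' @param lineage_markers Markers treated as mutually exclusive lineages.
#' @return A `gating_config` object.
#' @export
gating_config <- function(thresholds,
                          rules = default_phenotype_rules(),
                          lineage_conflict_policy = c("flag_ambiguous", "drop"),
                          lineage_markers = c("CD8", "CD4", "CD68")) {
  lineage_conflict_policy <- match.arg(lineage_conflict_policy)
  rule_markers <- unique(c(unlist(rules$positive), unlist(rules$negative)))
  missing <- setdiff(rule_markers, names(thresholds))
  if (length(missing) > 0) {
    abort(paste0("no threshold given for rule marker(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(rules$name)) abort("phenotype rule names must be unique")
  structure(list(thresholds = thresholds, rules = rules,
                 lineage_conflict_policy = lineage_conflict_policy,
                 lineage_markers = lineage_markers),
            class = "gating_config")
}

#' Default gating thresholds for the simulator's marker-emission model
#'
#' Midpoint (in log space) between the default negative and positive
#' log-normal intensity components.
#'
#' @return Named numeric vector over [default_panel()].
#' @export
default_thresholds <- function() {
  setNames(rep(exp((log(1) + log(10)) / 2), length(default_panel())),
           default_panel())
}

#' Assign phenotype labels to cells from marker intensities
#'
#' Marker positivity is `intensity >= threshold`. A cell receives every label
#' whose rule it satisfies. Cells positive for more than one exclusive
#' lineage marker are handled per the config's `lineage_conflict_policy`.
#'
#' @param cells Cell tibble with one intensity column per rule marker.
#' @param config A [gating_config()].
#' @return The cell tibble with its `phenotypes` list-column filled.
#' @export
gate_cells <- function(cells, config) {
  stopifnot(inherits(config, "gating_config"))
  rule_markers <- unique(c(unlist(config$rules$positive),
                           unlist(config$rules$negative)))
  missing <- setdiff(rule_markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("rule references marker(s) absent from the cell table: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(cells)
  pos <- matrix(FALSE, n, length(rule_markers),
                dimnames = list(NULL, rule_markers))
  for (m in rule_markers) {
    pos[, m] <- cells[[m]] >= config$thresholds[[m]]
  }

  n_rules <- nrow(config$rules)
  sat <- matrix(FALSE, n, n_rules)
  for (i in seq_len(n_rules)) {
    req_pos <- config$rules$positive[[i]]
    req_neg <- config$rules$negative[[i]]
    ok <- rep(TRUE, n)
    for (m in req_pos) ok <- ok & pos[, m]
    for (m in req_neg) ok <- ok & !pos[, m]
    sat[, i] <- ok
  }
  rule_names <- config$rules$name
  labels <- lapply(seq_len(n), function(i) rule_names[sat[i, ]])

  lin <- intersect(config$lineage_markers, rule_markers)
  conflicted <- if (length(lin) >= 2) rowSums(pos[, lin, drop = FALSE]) > 1 else rep(FALSE, n)
  out <- cells
  out$phenotypes <- labels
  if (any(conflicted)) {
    if (config$lineage_conflict_policy == "flag_ambiguous") {
      out$phenotypes[conflicted] <- list("ambiguous")
    } else {
      out <- out[!conflicted, , drop = FALSE]
    }
  }
  out
}

#' Gate every cell of a dataset in place
#'
#' @param dataset A `tme_dataset`.
#' @param config A [gating_config()].
#' @return The dataset with gated cells.
#' @export
gate_dataset <- function(dataset, config) {
  dataset$cells <- gate_cells(dataset$cells, config)
  dataset
}
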