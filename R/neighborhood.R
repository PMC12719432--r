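#' Neighborhood query table
#'
#' A query names a central phenotype, a target phenotype and a pairing
#' radius. The 30 um default matches the scale at which ligand--receptor
#' contact between neighboring cells is plausible.
#'
#' @param central,target Phenotype labels (recycled to equal length).
#' @param radius_um Pairing radius in um.
#' @return Tibble with columns `central`, `target`, `radius_um`.
#' @export
neighborhood_query <- function(central, target, radius_um = 30) {
  if (any(radius_um <= 0)) abort("radius_um must be positive")
  tibble(central = central, target = target, radius_um = radius_um)
}

has_label <- function(phenotypes, label) {
  vapply(phenotypes, function(p) label %in% p, logical(1))
}

# run code under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

pair_dist <- function(dx, dy, torus) {
  if (!is.null(torus)) {
    dx <- abs(dx); dy <- abs(dy)
    dx <- pmin(dx, torus[1] - dx)
    dy <- pmin(dy, torus[2] - dy)
  }
  sqrt(dx^2 + dy^2)
}

pairs_bruteforce <- function(cells, c_idx, t_idx, radius_um, torus = NULL) {
  if (length(c_idx) == 0 || length(t_idx) == 0) {
    return(tibble(central_id = character(), target_id = character(),
                  distance_um = numeric()))
  }
  dx <- outer(cells$x_um[c_idx], cells$x_um[t_idx], "-")
  dy <- outer(cells$y_um[c_idx], cells$y_um[t_idx], "-")
  d <- pair_dist(dx, dy, torus)
  self <- outer(c_idx, t_idx, "==")
  hit <- which(d <= radius_um & !self, arr.ind = TRUE)
  tibble(central_id = cells$cell_id[c_idx[hit[, 1]]],
         target_id = cells$cell_id[t_idx[hit[, 2]]],
         distance_um = d[hit])
}

pairs_grid <- function(cells, c_idx, t_idx, radius_um) {
  if (length(c_idx) == 0 || length(t_idx) == 0) {
    return(tibble(central_id = character(), target_id = character(),
                  distance_um = numeric()))
  }
  x <- cells$x_um; y <- cells$y_um
  x0 <- min(x[c(c_idx, t_idx)]); y0 <- min(y[c(c_idx, t_idx)])
  bx_t <- floor((x[t_idx] - x0) / radius_um)
  by_t <- floor((y[t_idx] - y0) / radius_um)
  key_t <- paste(bx_t, by_t)
  buckets <- split(seq_along(t_idx), key_t)

  bx_c <- floor((x[c_idx] - x0) / radius_um)
  by_c <- floor((y[c_idx] - y0) / radius_um)
  key_c <- paste(bx_c, by_c)
  c_groups <- split(seq_along(c_idx), key_c)

  out <- vector("list", length(c_groups))
  g <- 0
  for (key in names(c_groups)) {
    ci_local <- c_groups[[key]]
    bb <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    neigh_keys <- paste(rep(bb[1] + (-1:1), each = 3), rep(bb[2] + (-1:1), 3))
    ti_local <- unlist(buckets[intersect(neigh_keys, names(buckets))],
                       use.names = FALSE)
    if (length(ti_local) == 0) next
    ci <- c_idx[ci_local]; ti <- t_idx[ti_local]
    dx <- outer(x[ci], x[ti], "-")
    dy <- outer(y[ci], y[ti], "-")
    d <- sqrt(dx^2 + dy^2)
    self <- outer(ci, ti, "==")
    hit <- which(d <= radius_um & !self, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    g <- g + 1
    out[[g]] <- tibble(central_id = cells$cell_id[ci[hit[, 1]]],
                       target_id = cells$cell_id[ti[hit[, 2]]],
                       distance_um = d[hit])
  }
  if (g == 0) {
    return(tibble(central_id = character(), target_id = character(),
                  distance_um = numeric()))
  }
  dplyr::bind_rows(out[seq_len(g)])
}

#' Pair central with target cells within a radius
#'
#' Emits one row per ordered (central, target) pair of distinct cells whose
#' Euclidean nucleus-to-nucleus distance is at most `radius_um` (inclusive).
#' A target within range of `k` central cells contributes `k` pairs; a cell
#' carrying both phenotypes is never paired with itself. Pairing is intended
#' for the cells of a single ROI — it never crosses ROI boundaries when
#' driven through [roi_neighborhood_table()].
#'
#' @param cells Gated cell tibble (one ROI) with a `phenotypes` list-column.
#' @param central,target Phenotype labels.
#' @param radius_um Pairing radius in um.
#' @param method `"grid"` (bucketed search, default) or `"brute"`
#'   (exhaustive O(n^2) scan; the validation oracle).
#' @param torus `NULL` for plain Euclidean distance, or `c(width, height)`
#'   for periodic distance on that rectangle (used by closed-form
#'   validation runs; forces the brute method).
#' @return Tibble with columns `central_id`, `target_id`, `distance_um`,
#'   sorted by central then target id.
#' @export
find_pairs <- function(cells, central, target, radius_um = 30,
                       method = c("grid", "brute"), torus = NULL) {
  method <- match.arg(method)
  if (!"phenotypes" %in% names(cells)) {
    abort("cells must carry a 'phenotypes' column; run gate_cells() first")
  }
  c_idx <- which(has_label(cells$phenotypes, central))
  t_idx <- which(has_label(cells$phenotypes, target))
  res <- if (!is.null(torus) || method == "brute") {
    pairs_bruteforce(cells, c_idx, t_idx, radius_um, torus = torus)
  } else {
    pairs_grid(cells, c_idx, t_idx, radius_um)
  }
  dplyr::arrange(res, central_id, target_id)
}

#' Neighborhood metrics from a pair list
#'
#' Effective score = number of pairs / number of central cells (average
#' target neighbors per central cell; centrals with zero neighbors stay in
#' the denominator). Average distance = sum of pair distances / number of
#' pairs, undefined when there are no pairs. Zero central cells yields a
#' flagged undefined result rather than an error.
#'
#' @param pairs Pair tibble from [find_pairs()].
#' @param n_central,n_target Phenotype cell counts in the scope.
#' @return One-row tibble: `n_central`, `n_target`, `n_pairs`,
#'   `effective_score`, `average_distance_um`, `defined`.
#' @export
neighborhood_metrics <- function(pairs, n_central, n_target) {
  n_pairs <- nrow(pairs)
  if (n_central == 0) {
    return(tibble(n_central = 0L, n_target = as.integer(n_target),
                  n_pairs = n_pairs, effective_score = NA_real_,
                  average_distance_um = NA_real_, defined = FALSE))
  }
  tibble(n_central = as.integer(n_central), n_target = as.integer(n_target),
         n_pairs = n_pairs,
         effective_score = n_pairs / n_central,
         average_distance_um = if (n_pairs > 0) sum(pairs$distance_um) / n_pairs else NA_real_,
         defined = TRUE)
}

count_label <- function(cells, label) sum(has_label(cells$phenotypes, label))

#' Per-ROI neighborhood metrics table
#'
#' Runs every query against every ROI independently (pairing never crosses
#' ROI boundaries). ROIs with zero central cells emit flagged undefined rows
#' so they can be excluded from downstream averaging.
#'
#' @param dataset Gated [tme_dataset()].
#' @param queries Query tibble from [neighborhood_query()].
#' @param method Pair-search method, see [find_pairs()].
#' @return Tibble of class `tme_neighborhood`, one row per ROI x query, keyed
#'   by `roi_id`, `region`, `group`, `central`, `target`, `radius_um`.
#' @export
roi_neighborhood_table <- function(dataset, queries, method = "grid") {
  cells_by_roi <- split(dataset$cells, dataset$cells$roi_id)
  rows <- vector("list", nrow(dataset$rois) * nrow(queries))
  k <- 0
  for (i in seq_len(nrow(dataset$rois))) {
    roi <- dataset$rois[i, ]
    rc <- cells_by_roi[[roi$roi_id]]
    if (is.null(rc)) rc <- dataset$cells[0, ]
    for (q in seq_len(nrow(queries))) {
      qu <- queries[q, ]
      pairs <- find_pairs(rc, qu$central, qu$target, qu$radius_um,
                          method = method)
      met <- neighborhood_metrics(pairs,
                                  count_label(rc, qu$central),
                                  count_label(rc, qu$target))
      k <- k + 1
      rows[[k]] <- dplyr::bind_cols(
        tibble(roi_id = roi$roi_id, region = roi$region, group = roi$group,
               central = qu$central, target = qu$target,
               radius_um = qu$radius_um),
        met)
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(k)])
  class(out) <- c("tme_neighborhood", class(out))
  out
}

#' Pooled neighborhood metrics
#'
#' Pairs are found within each ROI independently, then pair counts and
#' phenotype counts are summed over the pooling scope before the ratios are
#' taken — the slide-level reading of the effective score, where the
#' denominator is the total number of central cells across the scope.
#'
#' @param dataset Gated [tme_dataset()].
#' @param central,target Phenotype labels.
#' @param radius_um Pairing radius in um.
#' @param scope `"slide"` (pool per slide), `"region"` (pool per region) or
#'   `"all"` (one pooled row).
#' @param method Pair-search method.
#' @return Tibble with one row per scope unit and the pooled metrics; scope
#'   units with zero central cells are flagged undefined.
#' @export
pooled_neighborhood_metrics <- function(dataset, central, target,
                                        radius_um = 30,
                                        scope = c("slide", "region", "all"),
                                        method = "grid") {
  scope <- match.arg(scope)
  per_roi <- roi_neighborhood_table(
    dataset, neighborhood_query(central, target, radius_um), method = method)
  per_roi <- dplyr::left_join(per_roi,
                              dataset$rois[c("roi_id", "slide_id")],
                              by = "roi_id")
  # recover pair distance sums: average_distance * n_pairs (0 when no pairs)
  per_roi$sum_dist <- ifelse(per_roi$n_pairs > 0,
                             per_roi$average_distance_um * per_roi$n_pairs, 0)
  key <- switch(scope,
                slide = rlang::sym("slide_id"),
                region = rlang::sym("region"),
                all = NULL)
  grouped <- if (is.null(key)) {
    dplyr::mutate(per_roi, .scope = "all") |> dplyr::group_by(.data$.scope)
  } else {
    dplyr::group_by(per_roi, !!key)
  }
  grouped |>
    dplyr::summarise(
      central = central[1], target = target[1], radius_um = radius_um[1],
      n_rois = dplyr::n(),
      n_central = sum(n_central), n_target = sum(n_target),
      n_pairs = sum(n_pairs),
      effective_score = ifelse(sum(n_central) > 0,
                               sum(n_pairs) / sum(n_central), NA_real_),
      average_distance_um = ifelse(sum(n_pairs) > 0,
                                   sum(.data$sum_dist) / sum(n_pairs), NA_real_),
      defined = sum(n_central) > 0,
      .groups = "drop")
}

#' Permutation null for the effective score
#'
#' Phenotype label sets are permuted across the fixed cell positions of one
#' ROI and the effective score is recomputed for each permutation, giving a
#' conditional null that preserves both the point pattern and the label
#' abundances. The empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param cells Gated cell tibble of one ROI.
#' @param central,target Phenotype labels.
#' @param radius_um Pairing radius in um.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List with `observed` (one-row metrics tibble), `null` (numeric
#'   vector of permuted effective scores) and `p_value`.
#' @export
permutation_null <- function(cells, central, target, radius_um = 30,
                             n_perm = 199, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (nrow(cells) < 2) abort("too few cells to permute labels across")
  n_c <- count_label(cells, central)
  n_t <- count_label(cells, target)
  obs <- neighborhood_metrics(
    find_pairs(cells, central, target, radius_um), n_c, n_t)
  if (!obs$defined) abort("no central cells: observed score undefined")
  null <- numeric(n_perm)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- cells
      perm$phenotypes <- cells$phenotypes[sample.int(nrow(cells))]
      null[b] <- neighborhood_metrics(
        find_pairs(perm, central, target, radius_um),
        count_label(perm, central), count_label(perm, target))$effective_score
    }
  })
  list(observed = obs, null = null,
       p_value = (1 + sum(null >= obs$effective_score)) / (1 + n_perm))
}
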