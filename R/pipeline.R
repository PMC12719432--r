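#' Normalise a pipeline run configuration
#'
#' A run config names the input (either a simulation block or paths to cell
#' and ROI tables), the gating setup, the neighborhood queries, the planned
#' comparisons, the optional correlation block, an output directory and a
#' seed. Accepts a YAML file path or a nested list (the YAML layout mirrors
#' the list layout).
#'
#' @param config Path to a YAML file, or a list.
#' @return A `run_config` object (validated list).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("run config needs an out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$panel)) config$panel <- default_panel()
  has_sim <- !is.null(config$simulate)
  has_paths <- !is.null(config$cells) && !is.null(config$rois)
  if (!has_sim && !has_paths) {
    abort("run config needs either a 'simulate' block or 'cells' + 'rois' paths")
  }
  if (is.null(config$gating)) config$gating <- list()
  config$queries <- normalise_queries(config$queries)
  structure(config, class = "run_config")
}

normalise_queries <- function(q) {
  if (is.null(q)) return(neighborhood_query(character(), character())[0, ])
  if (is.data.frame(q)) return(as_tibble(q))
  dplyr::bind_rows(lapply(q, function(x) {
    neighborhood_query(x$central, x$target, x$radius_um %||% 30)
  }))
}

config_hash <- function(config) {
  # hash the analytic content only: where outputs land must not change them
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

write_artifact_csv <- function(df, path, hash) {
  if ("phenotypes" %in% names(df)) df$phenotypes <- format_phenotypes(df$phenotypes)
  txt <- paste0("# config_hash=", hash, "\n", readr::format_csv(df))
  writeLines(txt, path, sep = "")
  invisible(path)
}

build_sim_config <- function(sim, seed, panel) {
  geom_args <- sim$geometry %||% list()
  geometry <- do.call(slide_geometry, geom_args)
  group <- sim$group %||% "EG"
  intensities <- if (!is.null(sim$intensities)) {
    as_tibble(dplyr::bind_rows(sim$intensities))
  } else {
    default_sim_intensities(group)
  }
  attractions <- if (!is.null(sim$attractions)) {
    dplyr::bind_rows(lapply(sim$attractions, function(a) {
      attraction_spec(a$central_phenotype, a$target_phenotype,
                      a$mean_children, a$placement_radius_um)
    }))
  } else {
    default_sim_attractions(group)
  }
  sim_config(geometry = geometry, intensities = intensities,
             attractions = attractions,
             marker_model = default_marker_model(panel),
             group = group, slide_id = sim$slide_id %||% "s1",
             boundary_mode = sim$boundary_mode %||% "clip",
             n_rois_per_region = sim$n_rois_per_region %||% 6,
             seed = sim$seed %||% seed)
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: input (simulate or read), gate, density, neighborhood,
#' correlate (when a `correlations` block is configured), compare (when a
#' `comparisons` block is configured). Every tabular artifact is written to
#' `out_dir` with a comment header recording the config hash; a failure in
#' one comparison is recorded and does not abort the remaining comparisons.
#'
#' @param config A [run_config()], list, or YAML path.
#' @return A `run_report`: list with `stages` (tibble: stage, status, n_in,
#'   n_out, elapsed_s, message), `comparisons`, `config_hash`, `version`,
#'   `ok`.
#' @export
run_pipeline <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, status, n_in, n_out, elapsed, message = "") {
    stages[[length(stages) + 1]] <<- tibble(
      stage = stage, status = status, n_in = n_in, n_out = n_out,
      elapsed_s = round(elapsed, 3), message = message)
  }
  run_stage <- function(stage, n_in, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(stage, "failed", n_in, NA_integer_, dt, conditionMessage(res))
      NULL
    } else {
      note(stage, "completed", n_in, res$n_out, dt)
      res$value
    }
  }

  # --- input -----------------------------------------------------------
  dataset <- run_stage("input", NA_integer_, function() {
    ds <- if (!is.null(config$simulate)) {
      simulate_slide(build_sim_config(config$simulate, config$seed, config$panel))
    } else {
      cells <- read_cell_table(config$cells, config$panel)
      rois <- read_roi_manifest(config$rois)
      tme_dataset(cells, rois, panel = config$panel)
    }
    write_artifact_csv(ds$cells, file.path(config$out_dir, "cells.csv"), hash)
    write_artifact_csv(ds$rois, file.path(config$out_dir, "rois.csv"), hash)
    list(value = ds, n_out = nrow(ds$cells))
  })

  gated <- if (!is.null(dataset)) {
    run_stage("gate", nrow(dataset$cells), function() {
      thresholds <- if (!is.null(config$gating$thresholds)) {
        unlist(config$gating$thresholds)
      } else {
        default_thresholds()
      }
      gc <- gating_config(
        thresholds = thresholds,
        lineage_conflict_policy = config$gating$lineage_conflict_policy %||% "flag_ambiguous")
      ds <- gate_dataset(dataset, gc)
      write_artifact_csv(ds$cells, file.path(config$out_dir, "gated.csv"), hash)
      list(value = ds, n_out = nrow(ds$cells))
    })
  } else NULL

  phenotypes <- config$phenotypes %||%
    default_phenotype_rules()$name

  dens <- if (!is.null(gated)) {
    run_stage("density", nrow(gated$cells), function() {
      d <- density_table(gated, phenotypes)
      write_artifact_csv(d, file.path(config$out_dir, "density.csv"), hash)
      list(value = d, n_out = nrow(d))
    })
  } else NULL

  if (!is.null(gated) && nrow(config$queries) > 0) {
    run_stage("neighborhood", nrow(gated$cells), function() {
      m <- roi_neighborhood_table(gated, config$queries)
      write_artifact_csv(m, file.path(config$out_dir, "metrics.csv"), hash)
      pooled <- dplyr::bind_rows(lapply(seq_len(nrow(config$queries)), function(i) {
        q <- config$queries[i, ]
        pooled_neighborhood_metrics(gated, q$central, q$target, q$radius_um,
                                    scope = "region")
      }))
      write_artifact_csv(pooled, file.path(config$out_dir, "metrics_pooled.csv"), hash)
      list(value = m, n_out = nrow(m))
    })
  }

  if (!is.null(gated) && !is.null(config$correlations)) {
    run_stage("correlate", nrow(gated$cells), function() {
      cr <- config$correlations
      cm <- count_matrix(gated, cr$phenotypes %||% phenotypes,
                         region = cr$region, group = cr$group)
      edges <- pearson_network(cm, alpha = cr$alpha %||% 0.05)
      write_artifact_csv(edges, file.path(config$out_dir, "edges.csv"), hash)
      list(value = edges, n_out = nrow(edges))
    })
  }

  comparisons <- list()
  if (!is.null(dens) && !is.null(config$comparisons)) {
    run_stage("compare", nrow(dens), function() {
      for (cmp in config$comparisons) {
        lbl <- paste(cmp$phenotype, cmp$metric %||% "density",
                     "by", cmp$by %||% "region", sep = "_")
        res <- tryCatch(
          compare_density(dens, cmp$phenotype,
                          metric = cmp$metric %||% "density",
                          by = cmp$by %||% "region",
                          within = cmp$within,
                          test = cmp$test %||% "kw"),
          error = function(e) e)
        comparisons[[lbl]] <<- if (inherits(res, "error")) {
          list(error = conditionMessage(res))
        } else res
      }
      list(value = comparisons, n_out = length(comparisons))
    })
  }

  stage_tab <- dplyr::bind_rows(stages)
  report <- structure(
    list(stages = stage_tab, comparisons = comparisons,
         config_hash = hash,
         version = as.character(utils::packageVersion("tmespatial")),
         ok = all(stage_tab$status == "completed") &&
           !any(map_lgl(comparisons, ~ !is.null(.x$error)))),
    class = "run_report")
  json <- list(
    config_hash = hash, version = report$version, ok = report$ok,
    stages = stage_tab,
    comparisons = lapply(comparisons, function(x) {
      if (!is.null(x$error)) list(error = x$error) else
        list(test = x$test, statistic = x$statistic,
             df = x$df, p_value = x$p_value)
    }))
  jsonlite::write_json(json, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", if (x$ok) "ok" else "FAILED", "\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}
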