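node_sets <- function() {
  list(
    qol6 = c("QoL", "BC", "PAS", "SMA", "PHY", "SI"),
    facets11 = c("SAB", "AUT", "PPF", "SOP", "DAD", "INT",
                 "BC", "PAS", "SMA", "PHY", "SI"),
    smas15 = c("SAB", "AUT", "PPF", "SOP", "DAD", "INT",
               "INI", "INV", "SEF", "VAR", "MUL", "PFM",
               "BC", "PAS", "PHY", "SI")
  )
}

#' Configure a full network-analysis run
#'
#' @param input A participants-by-variables matrix / data frame of scale
#'   scores, or a `generator_spec` to simulate from.
#' @param nodes Node-set choice: `"qol6"` (overall QoL plus resilience
#'   factors and stringency index), `"facets11"` (QoL facets), or
#'   `"smas15"` (QoL and self-management facets). The input must contain all
#'   columns of the chosen set.
#' @param gamma EBIC hyperparameter for model selection; default 0 (BIC).
#' @param filter_variable Variable screened by the robust outlier filter
#'   before estimation; default `"PHY"`. `NULL` disables filtering.
#' @param filter_threshold Robust-SD cutoff; default 2.5.
#' @param boot_B Edge-bootstrap replicates (0 disables); default 0.
#' @param cs_B Case-dropping subsamples per proportion (0 disables);
#'   default 0.
#' @param cs_grid Case-dropping proportions.
#' @param alpha Significance level for difference tests.
#' @param focus Node subset for restricted strength summaries; default
#'   `"QoL"` when present in the node set.
#' @param seed Integer seed governing simulation and all bootstraps.
#' @param output_dir Directory for exported artifacts; `NULL` writes
#'   nothing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, nodes = "qol6", gamma = 0,
                       filter_variable = "PHY", filter_threshold = 2.5,
                       boot_B = 0, cs_B = 0,
                       cs_grid = c(seq(0.1, 0.7, by = 0.1), 0.75),
                       alpha = 0.05, focus = NULL, seed = 1,
                       output_dir = NULL) {
  nodes <- match.arg(nodes, names(node_sets()))
  if (is.null(focus) && "QoL" %in% node_sets()[[nodes]]) focus <- "QoL"
  structure(list(input = input, nodes = nodes, gamma = gamma,
                 filter_variable = filter_variable,
                 filter_threshold = filter_threshold,
                 boot_B = boot_B, cs_B = cs_B, cs_grid = cs_grid,
                 alpha = alpha, focus = focus, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the scoring-to-stability analysis pipeline
#'
#' Executes, in order: input resolution (simulation if the input is a
#' `generator_spec`), schema validation against the chosen node set, robust
#' outlier filtering on the physical-activity score, descriptive statistics,
#' stepwise-EBIC GGM estimation, relative-importance network construction on
#' the selected structure, total and focus-restricted strength summaries,
#' and - when enabled - edge bootstrap with difference tests and
#' case-dropping correlation-stability analysis. Artifacts (edge-list CSVs,
#' GraphML, layout coordinates, JSON report and run log) are written to
#' `output_dir` when set.
#'
#' @param config A `run_config`.
#' @return A report bundle (list) with elements `data`, `filter_report`,
#'   `descriptives`, `ggm`, `relimp`, `strengths`, `edge_boot` (or NULL),
#'   `cs` (or NULL), `config`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logline <- character(0)
  say <- function(fmt, ...) {
    logline <<- c(logline, sprintf(fmt, ...))
  }
  wanted <- node_sets()[[config$nodes]]

  if (inherits(config$input, "generator_spec")) {
    x <- generate_dataset(config$input, seed = config$seed)
    say("simulated %d x %d dataset (seed %d)", nrow(x), ncol(x), config$seed)
  } else {
    x <- as.matrix(config$input)
    say("loaded %d x %d dataset", nrow(x), ncol(x))
  }
  missing_cols <- setdiff(wanted, colnames(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("input is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- x[, wanted, drop = FALSE]

  filter_report <- NULL
  if (!is.null(config$filter_variable) &&
      config$filter_variable %in% colnames(x)) {
    flt <- filter_outliers(x, config$filter_variable,
                           config$filter_threshold)
    filter_report <- flt$report
    x <- flt$data
    say("robust filter on %s: %d -> %d participants",
        config$filter_variable, filter_report$n_before,
        filter_report$n_after)
  }

  descr <- describe_variables(x)
  ggm <- ggm_model_select(x, gamma = config$gamma)
  say("selected GGM with %d edges (EBIC %.2f)", ggm$n_edges, ggm$ebic)
  rin <- relative_importance_network(x, ggm)
  strengths <- strength_summaries(rin, focus = config$focus)

  edge_boot <- NULL
  if (config$boot_B > 0) {
    labels <- ggm$labels
    pairs <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
    estimator <- function(d) {
      net <- ggm_model_select(d, gamma = config$gamma)
      w <- net$weights[upper.tri(net$weights)]
      names(w) <- paste(labels[pairs[, 1]], labels[pairs[, 2]], sep = "--")
      w
    }
    edge_boot <- nonparametric_bootstrap(x, estimator, B = config$boot_B,
                                         seed = config$seed)
    say("edge bootstrap: B = %d, %d failures", config$boot_B,
        edge_boot$n_failed)
  }

  cs <- NULL
  if (config$cs_B > 0) {
    stat_fn <- function(d) {
      net <- ggm_model_select(d, gamma = config$gamma)
      ri <- relative_importance_network(d, net)
      s <- strength_summaries(ri)
      cbind(outstrength = s$outstrength, instrength = s$instrength)
    }
    cs <- case_dropping_cs(x, stat_fn, grid = config$cs_grid,
                           B = config$cs_B, seed = config$seed)
    say("case-dropping CS: out %.2f, in %.2f", cs$cs[["outstrength"]],
        cs$cs[["instrength"]])
  }

  bundle <- list(data = x, filter_report = filter_report,
                 descriptives = descr, ggm = ggm, relimp = rin,
                 strengths = strengths, edge_boot = edge_boot, cs = cs,
                 config = config, log = logline)
  if (!is.null(config$output_dir)) {
    export_bundle(bundle, config$output_dir)
  }
  bundle
}

export_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_edge_list(bundle$ggm, file.path(dir, "ggm_edges.csv"))
  write_edge_list(bundle$relimp, file.path(dir, "relimp_edges.csv"))
  write_graphml(bundle$ggm, file.path(dir, "ggm.graphml"))
  write_graphml(bundle$relimp, file.path(dir, "relimp.graphml"))
  utils::write.csv(network_layout(bundle$ggm, seed = bundle$config$seed),
                   file.path(dir, "layout.csv"), row.names = FALSE)
  utils::write.csv(bundle$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$strengths, file.path(dir, "strengths.csv"),
                   row.names = FALSE)
  report <- list(
    seed = bundle$config$seed,
    nodes = bundle$config$nodes,
    gamma = bundle$config$gamma,
    n = nrow(bundle$data),
    filter = bundle$filter_report[c("variable", "threshold", "center",
                                    "scale", "n_before", "n_after",
                                    "dropped_ids")],
    n_edges = bundle$ggm$n_edges,
    ebic = bundle$ggm$ebic,
    cs = as.list(if (is.null(bundle$cs)) NULL else bundle$cs$cs),
    package_version = as.character(utils::packageVersion("resilnet"))
  )
  jsonlite::write_json(report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
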