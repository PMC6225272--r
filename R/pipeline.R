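#' Assemble a pipeline run configuration
#'
#' All stage tunables default to the package-wide conventions (lattice
#' spacing 2.0 A, margin 4.0 A, energy cap 30 kcal/mol, attenuation 0.3,
#' column filtration 2.0, up to 10 latent components, top decile 0.10,
#' cluster thresholds 3/0.45/0.5/0.05, 999 permutations). Unset input
#' paths disable the stages that need them.
#'
#' @param molecules Optional SDF path of aligned structures.
#' @param activity Optional activity CSV (columns `compound`, `pld50`,
#'   optional `is_test`).
#' @param block Optional precomputed field-block CSV (used instead of
#'   `molecules`).
#' @param edges Optional PPI edge-list TSV.
#' @param clusters Optional cluster-membership CSV (columns `cluster`,
#'   `protein`).
#' @param rankings Optional ranking CSV (see [read_ranking_csv()]).
#' @param stages Character vector of stages to run, from
#'   `c("qstr", "network", "ranking")`.
#' @param spacing,margin,cap,alpha,filter_threshold Field-stage tunables.
#' @param max_components Component-scan limit for the QSTR stage.
#' @param top Top-centile fraction for network screening.
#' @param min_size,min_density,min_quality,max_p Cluster filter thresholds.
#' @param n_perm Permutation draws for cluster p-values.
#' @param seed Master seed for every random draw.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(molecules = NULL, activity = NULL, block = NULL,
                       edges = NULL, clusters = NULL, rankings = NULL,
                       stages = c("qstr", "network", "ranking"),
                       spacing = 2.0, margin = 4.0, cap = 30, alpha = 0.3,
                       filter_threshold = 2.0, max_components = 10,
                       top = 0.10, min_size = 3, min_density = 0.45,
                       min_quality = 0.5, max_p = 0.05, n_perm = 999,
                       seed = 1) {
  cfg <- list(molecules = molecules, activity = activity, block = block,
              edges = edges, clusters = clusters, rankings = rankings,
              stages = stages, spacing = spacing, margin = margin,
              cap = cap, alpha = alpha,
              filter_threshold = filter_threshold,
              max_components = max_components, top = top,
              min_size = min_size, min_density = min_density,
              min_quality = min_quality, max_p = max_p, n_perm = n_perm,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected. The file round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output YAML file.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

stage_fail <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the configured pipeline stages
#'
#' Executes, as toggled: the QSTR stage (field block construction or
#' loading, column filtration, component selection, PLS fit, fit/LOO/test
#' statistics, field fractions, applicability-domain report), the network
#' stage (centralities, top-decile subnetwork, optional cluster
#' evaluation and filtering), and the ranking stage (NDCG per ordering).
#' Every random draw is seeded from the config; the report embeds the
#' config hash so identical configurations yield byte-identical reports.
#'
#' @param config A [run_config()].
#' @return A named list (the run report) with one element per executed
#'   stage plus `config_hash`; assign class `json` via
#'   [write_run_report()] to serialize.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- intersect(config$stages, c("qstr", "network", "ranking"))
  if (length(stages) == 0L)
    stop("validation: no stages toggled", call. = FALSE)
  for (f in c("molecules", "activity", "block", "edges", "clusters",
              "rankings")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("validation: input '%s' not found: %s", f, config[[f]]),
           call. = FALSE)
  }
  report <- list(config_hash = config_hash(config))

  if ("qstr" %in% stages) {
    report$qstr <- tryCatch({
      if (is.null(config$activity))
        stop("the qstr stage needs an activity table")
      act <- utils::read.csv(config$activity, stringsAsFactors = FALSE)
      block <- if (!is.null(config$block)) {
        read_field_csv(config$block)
      } else if (!is.null(config$molecules)) {
        mols <- read_sdf(config$molecules)
        mols <- lapply(mols, assign_gasteiger_charges)
        field_block(mols, type = "comfa", cap = config$cap,
                    spacing = config$spacing, margin = config$margin)
      } else stop("the qstr stage needs a field block or molecules")
      block <- column_filter(block, config$filter_threshold)
      ids <- rownames(block$matrix)
      m <- match(ids, as.character(act$compound))
      if (anyNA(m)) stop("activity table misses compounds: ",
                         paste(ids[is.na(m)], collapse = ", "))
      is_test <- if ("is_test" %in% names(act)) act$is_test[m] else NULL
      ds <- qstr_dataset(block, act$pld50[m], is_test = is_test,
                         seed = config$seed)
      onc <- select_components(ds, config$max_components)
      model <- fit_pls(ds, onc)
      stats <- model_stats(model, ds)
      q2 <- loo_q2(ds, onc)
      ad <- williams_report(model, ds)
      list(n_components = as.integer(onc), q2 = q2, r2 = stats$r2,
           see = stats$see, f_stat = stats$f_stat,
           r2_pred = if (any(ds$is_test)) predictive_r2(model, ds) else NULL,
           acceptable = model_acceptable(q2, stats$r2),
           field_fractions = as.list(field_fractions(model, ds)),
           ad = list(h_star = ad$h_star,
                     outliers = ad$table$id[ad$table$outlier],
                     high_leverage = ad$table$id[ad$table$high_leverage]))
    }, error = function(e) stage_fail("qstr", e))
  }

  if ("network" %in% stages) {
    report$network <- tryCatch({
      if (is.null(config$edges))
        stop("the network stage needs an edge list")
      g <- read_edge_list(config$edges)
      ct <- centrality_table(g, top = config$top)
      sub <- top_decile_overlap(ct)
      out <- list(n_nodes = igraph::vcount(g),
                  n_edges = igraph::ecount(g),
                  subnetwork = sub)
      if (!is.null(config$clusters)) {
        cl <- utils::read.csv(config$clusters, stringsAsFactors = FALSE)
        mem <- split(as.character(cl$protein), cl$cluster)
        metrics <- lapply(mem, function(m)
          cluster_metrics(g, m, n_perm = config$n_perm,
                          seed = config$seed))
        kept <- filter_clusters(metrics, config$min_size,
                                config$min_density, config$min_quality,
                                config$max_p)
        out$clusters <- lapply(names(mem), function(nm) {
          m <- metrics[[nm]]
          list(cluster = nm, size = m$size, density = m$density,
               quality = m$quality, p_value = m$p_value,
               accepted = attr(kept, "accepted")[match(nm, names(mem))])
        })
      }
      out
    }, error = function(e) stage_fail("network", e))
  }

  if ("ranking" %in% stages) {
    report$ranking <- tryCatch({
      if (is.null(config$rankings))
        stop("the ranking stage needs a ranking table")
      rt <- read_ranking_csv(config$rankings)
      nt <- ndcg_table(rt, digits = NA)
      list(n_items = length(rt$items),
           ndcg = stats::setNames(as.list(nt$ndcg), nt$ordering))
    }, error = function(e) stage_fail("ranking", e))
  }

  report
}

#' Serialize a run report to JSON
#'
#' @param report Output of [run_pipeline()].
#' @param path Output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
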