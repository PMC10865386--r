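workflow_defaults <- function() {
  list(
    data = list(preset = NULL, tensor = NULL, diets = NULL, clinical = NULL,
                preset_args = list()),
    preprocessing = list(subtract_baseline = TRUE, standardize = FALSE,
                         standardize_mode = "per_metabolite",
                         variance_filter = NULL, downsample = NULL),
    model = list(V = NULL, S = NULL, tie_S_to_V = FALSE),
    evaluation = list(fractions = c(0.6, 0.2, 0.2), n_iter = 100L,
                      tol = 0.30),
    metabotyping = list(k = 2L, states = NULL, diets = NULL,
                        cp_components = 3L, cp_starts = 5L,
                        cp_max_iter = 500L,
                        degeneracy_threshold = 0.85, anova = TRUE),
    seed = 1L,
    output_dir = NULL)
}

#' Validated workflow configuration
#'
#' Builds the configuration consumed by [run_prediction_workflow()] and
#' [run_metabotyping_workflow()].  Unknown keys are rejected; every field has
#' a documented default (see `workflow_defaults` in the package source).  A
#' config can also be loaded from YAML.
#'
#' @param ... named sections (`data`, `preprocessing`, `model`, `evaluation`,
#'   `metabotyping`, `seed`, `output_dir`) overriding the defaults.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(...) {
  over <- list(...)
  defs <- workflow_defaults()
  bad <- setdiff(names(over), names(defs))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  for (sec in names(over)) {
    if (is.list(defs[[sec]]) && !is.null(names(defs[[sec]]))) {
      if (!is.list(over[[sec]])) stopf("config section `%s` must be a list", sec)
      unknown <- setdiff(names(over[[sec]]), names(defs[[sec]]))
      if (length(unknown))
        stopf("unknown keys in config section `%s`: %s", sec,
              paste(unknown, collapse = ", "))
      defs[[sec]] <- utils::modifyList(defs[[sec]], over[[sec]],
                                       keep.null = TRUE)
    } else {
      defs[[sec]] <- over[[sec]]
    }
  }
  if (any(defs$evaluation$fractions < 0) ||
      abs(sum(defs$evaluation$fractions) - 1) > 1e-8)
    stopf("evaluation fractions must be non-negative and sum to 1")
  if (defs$evaluation$fractions[3] == 0)
    stopf("prediction workflow requires a non-empty test fraction")
  structure(defs, class = "workflow_config")
}

#' Load a workflow configuration from YAML
#' @param path YAML file.
#' @return A [workflow_config()].
#' @export
read_workflow_config <- function(path) {
  do.call(workflow_config, yaml::read_yaml(path))
}

resolve_workflow_data <- function(cfg) {
  d <- cfg$data
  if (!is.null(d$preset)) {
    args <- c(list(preset = d$preset, seed = cfg$seed), d$preset_args)
    pop <- do.call(synthetic_preset, args)
    clinical <- if (!is.null(d$clinical)) read_clinical_table(d$clinical)
    return(list(tensor = pop$tensor, diets = pop$diets, clinical = clinical,
                ground_truth = pop$ground_truth))
  }
  if (is.null(d$tensor) || is.null(d$diets))
    stopf("config must give either a preset or tensor + diets paths")
  list(tensor = read_tensor_long(d$tensor), diets = read_diet_inputs(d$diets),
       clinical = if (!is.null(d$clinical)) read_clinical_table(d$clinical),
       ground_truth = NULL)
}

apply_preprocessing <- function(x, p) {
  scales <- NULL
  if (!is.null(p$downsample)) x <- downsample_logarithmic(x, p$downsample)
  if (!is.null(p$variance_filter)) x <- filter_low_variance(x, p$variance_filter)
  if (isTRUE(p$subtract_baseline)) x <- subtract_baseline(x)
  if (isTRUE(p$standardize)) {
    st <- standardize_per_diet(x, mode = p$standardize_mode)
    x <- st$tensor
    scales <- st$scales
  }
  list(tensor = x, scales = scales)
}

write_manifest <- function(cfg, dir, extra = list()) {
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- c(list(package = "pdmdc",
                     version = as.character(utils::packageVersion("pdmdc")),
                     seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(cfg_path))),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' End-to-end prediction workflow
#'
#' Preprocess, then run the resampled split / rank-selection / pooled-fit /
#' test-prediction cycle and report R-squared.  When `output_dir` is set, the
#' report (JSON + per-iteration CSV) and a reproducibility manifest (config,
#' seeds, package version) are written there.
#'
#' @param cfg a [workflow_config()].
#' @return The [resampling_experiment()] report.
#' @export
run_prediction_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  dat <- resolve_workflow_data(cfg)
  prep <- apply_preprocessing(dat$tensor, cfg$preprocessing)
  grid <- if (!is.null(cfg$model$V)) seq_len(cfg$model$V)
  report <- resampling_experiment(prep$tensor, dat$diets,
                                  n_iter = cfg$evaluation$n_iter,
                                  seed = cfg$seed,
                                  fractions = cfg$evaluation$fractions,
                                  tol = cfg$evaluation$tol, V_grid = grid)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$iterations,
                     file.path(cfg$output_dir, "iterations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mean_r2 = report$mean_r2,
                              selected_ranks = report$iterations$rank,
                              seed = cfg$seed),
                         file.path(cfg$output_dir, "prediction_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(cfg, cfg$output_dir,
                   list(mean_r2 = report$mean_r2))
  }
  report
}

#' End-to-end metabotyping workflow
#'
#' Preprocess, compute the shared basis (scree-suggested S unless configured),
#' fit per-individual latent models, cluster the cosine-similarity matrix of
#' every (state, diet) combination, run the CP comparator with k-means on the
#' individual scores, report the per-state overlap between the two methods,
#' and (when a clinical table is available) the ANOVA associations.
#'
#' @param cfg a [workflow_config()].
#' @return List with `labels` (state x diet list of cluster labelings),
#'   `cp_labels`, `overlap` (percent per state/diet vs CP), `scree`,
#'   `latent_dim`, `cp_model`, `anova` (NULL when no clinical table) and,
#'   for synthetic presets, `ground_truth_ari` per state/diet.
#' @export
run_metabotyping_workflow <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  dat <- resolve_workflow_data(cfg)
  prep <- apply_preprocessing(dat$tensor, cfg$preprocessing)
  x <- prep$tensor
  spectrum <- svd(flatten_tensor(x), nu = 0, nv = 0)$d
  S <- cfg$model$S %||% as.integer(scree_inflection(spectrum))
  V <- if (isTRUE(cfg$model$tie_S_to_V)) S else cfg$model$V
  basis <- compute_shared_basis(x, S)
  models <- fit_shared_latent(x, dat$diets, basis, V = V)
  ts <- extract_state_trajectories(models, dat$diets, T_ = dim(x)[2])
  k <- cfg$metabotyping$k
  if (k >= dim(x)[3])
    warning("k equals the number of individuals: singleton clusters",
            call. = FALSE)
  states <- cfg$metabotyping$states %||% seq_len(S)
  diet_idx <- cfg$metabotyping$diets %||% seq_len(dim(x)[4])
  labels <- list()
  for (s in states) for (d in diet_idx) {
    key <- paste0("state", s, ":", x$diet_ids[d])
    labels[[key]] <- cluster_similarity(
      cosine_similarity_matrix(ts, s, d), min(k, dim(x)[3]))
  }
  # CP comparator on the per-metabolite unit-sd scaled tensor
  cp <- cp_als(x, cfg$metabotyping$cp_components,
               n_starts = cfg$metabotyping$cp_starts,
               max_iter = cfg$metabotyping$cp_max_iter, seed = cfg$seed,
               scale_metabolites = TRUE)
  cp_labels <- cluster_cp_scores(cp, min(k, dim(x)[3]), seed = cfg$seed)
  overlap <- vapply(labels, function(lb) as.numeric(cluster_overlap(lb, cp_labels)),
                    numeric(1))
  anova_tab <- NULL
  if (!is.null(dat$clinical)) {
    anova_tab <- lapply(labels, anova_association, clinical = dat$clinical)
  } else if (isTRUE(cfg$metabotyping$anova)) {
    message("no clinical table supplied: ANOVA association step skipped")
  }
  gt_ari <- NULL
  if (!is.null(dat$ground_truth)) {
    truth <- dat$ground_truth$cluster_labels
    gt_ari <- vapply(labels, function(lb) adjusted_rand_index(lb, truth),
                     numeric(1))
  }
  out <- list(labels = labels, cp_labels = cp_labels, overlap = overlap,
              scree = spectrum, latent_dim = S, cp_model = cp,
              anova = anova_tab, ground_truth_ari = gt_ari,
              trajectories = ts)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(key = names(labels), do.call(rbind, labels)),
                     file.path(cfg$output_dir, "labels.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(spectrum),
                                singular_value = spectrum),
                     file.path(cfg$output_dir, "scree.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(individual = x$individual_ids,
                                cp_cluster = cp_labels),
                     file.path(cfg$output_dir, "cp_labels.csv"),
                     row.names = FALSE)
    write_manifest(cfg, cfg$output_dir, list(latent_dim = S))
  }
  out
}
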