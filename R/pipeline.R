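#' Build a pipeline configuration
#'
#' Defaults describe a desk-scale synthetic study: correlated smooth
#' climate layers, Gaussian-niche virtual species with a planted
#' climate-morphology coupling, ecoregion-style block backgrounds, the
#' r-squared 0.75 variable filter, 100-replicate background tests at
#' alpha 0.05, 2B-PLS on the correlation matrix with 1000 permutations,
#' seven trait models with AICc selection on a depth-100 tree, and a
#' 999-permutation Mantel test of log Hellinger versus Euclidean
#' morphological distances.  With `mode = "files"` the inputs are read
#' from `rasters_dir` (ESRI ASCII layers), `occurrences`, `tree`,
#' `traits` and optional `region_raster` paths instead.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param ... overrides of any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    mode = "synthetic", seed = as.integer(seed),
    # synthetic study size
    n_species = 6L, n_occ = 30L, n_layers = 6L,
    grid_rows = 48L, grid_cols = 48L, smoothness = 3L,
    inter_layer_corr = 0.6, breadth_sd = 0.6,
    n_traits = 10L, trait_noise = 0.5, coupling = 1,
    # file-mode inputs
    rasters_dir = NULL, occurrences = NULL, tree = NULL, traits = NULL,
    region_raster = NULL,
    # analysis settings
    threshold_r2 = 0.75, priority = NULL,
    background = "regions", region_blocks = 3L, radius_km = 100,
    nreps = 100L, alpha = 0.05, link = "logistic",
    pls_nperm = 1000L, mantel_nperm = 999L, mantel_transform = "log",
    rescale_to = 100,
    models = c("white", "BM", "lambda", "OU", "EB", "delta", "kappa"),
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$threshold_r2 <= 0 || cfg$threshold_r2 >= 1)
    stop("pipeline_config: threshold_r2 must be in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("pipeline_config: alpha must be in (0, 1)")
  if (!cfg$background %in% c("regions", "buffer"))
    stop("pipeline_config: background must be 'regions' or 'buffer'")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  sprintf("%08x", as.integer(fnv1a32(jsonlite::toJSON(unclass(cfg),
                                                      auto_unbox = TRUE)) %% 2^31))
}

load_inputs <- function(cfg) {
  if (cfg$mode == "synthetic") {
    seed_r <- stage_seed(cfg$seed, "rasters")
    stack <- gen_raster_stack(seed_r, n_vars = cfg$n_layers,
                              n_rows = cfg$grid_rows, n_cols = cfg$grid_cols,
                              smoothness = cfg$smoothness,
                              inter_layer_corr = cfg$inter_layer_corr)
    region <- gen_region_raster(stack$grid, cfg$region_blocks)
    sp <- paste0("sp", seq_len(cfg$n_species))
    cells <- which(stack$mask)
    occ <- lapply(seq_len(cfg$n_species), function(i) {
      sd_i <- stage_seed(cfg$seed, paste0("species", i))
      mu_cell <- with_seed(sd_i, sample(cells, 1))
      mu <- stats::setNames(drop(stack_env(stack, mu_cell)), names(stack$layers))
      gen_virtual_species(stack, mu, cfg$breadth_sd^2, cfg$n_occ,
                          seed = sd_i + 1L, species_id = sp[i])$occurrences
    })
    names(occ) <- sp
    tree <- gen_tree(cfg$n_species, stage_seed(cfg$seed, "tree"))
    tree$tip.label <- sp
    list(stack = stack, region = region, occ = occ, tree = tree, traits = NULL)
  } else {
    files <- sort(list.files(cfg$rasters_dir, "\\.asc$", full.names = TRUE))
    if (!length(files)) stop("run_pipeline: no .asc layers in ", cfg$rasters_dir)
    stack <- raster_stack(lapply(files, read_raster))
    region <- if (!is.null(cfg$region_raster))
      read_raster(cfg$region_raster, name = "region") else NULL
    list(stack = stack, region = region,
         occ = read_occurrences(cfg$occurrences),
         tree = read_newick(cfg$tree),
         traits = read_traits(cfg$traits))
  }
}

# plant a climate-coupled trait block for the synthetic study: one latent
# axis drawn from the species' standardized climate means
synth_traits <- function(means, cfg) {
  z <- scale(means)
  sd_t <- stage_seed(cfg$seed, "traits")
  with_seed(sd_t, {
    w <- stats::rnorm(ncol(z)); w <- w / sqrt(sum(w^2))
    latent <- drop(z %*% w) * cfg$coupling
    load <- stats::rnorm(cfg$n_traits)
    traits <- outer(latent, load) +
      cfg$trait_noise * matrix(stats::rnorm(length(latent) * cfg$n_traits),
                               length(latent))
    dimnames(traits) <- list(rownames(means), paste0("trait", seq_len(cfg$n_traits)))
    traits
  })
}

#' Run the full niche-morphology pipeline
#'
#' Stages, in dependency order: input loading (or synthesis), extraction
#' of environmental values at localities, the pairwise r-squared
#' variable filter, per-species suitability models with AUC, background
#' randomization tests over all ordered species pairs with the directed
#' classification matrix, niche (log Hellinger) and morphological
#' (Euclidean) distance matrices, continuous-trait model fitting with
#' AICc selection per trait, 2B-PLS of climate means versus traits, and
#' the Mantel correlation.  Every stage draws its seed from the master
#' seed by stage-name hashing, so runs are reproducible and stages can
#' be added without shifting other streams.
#'
#' @param config a [pipeline_config()].
#' @return A run report (list) with per-stage seeds and timings and all
#'   stage outputs; written as JSON/CSV to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  stages <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- list(seed = stage_seed(cfg$seed, name),
                            elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  inp <- timed("inputs", load_inputs(cfg))
  sp <- names(inp$occ)
  n <- length(sp)

  env_tables <- timed("extract", lapply(inp$occ, extract_env, stack = inp$stack))
  sel <- timed("filter_vars",
               correlation_filter(do.call(rbind, lapply(env_tables, as.matrix)),
                                  threshold_r2 = cfg$threshold_r2,
                                  priority = cfg$priority))
  means <- timed("climate_means", species_env_means(env_tables, sel$retained))
  traits <- inp$traits %||% timed("synth_traits", synth_traits(means, cfg))

  sub_stack <- raster_stack(inp$stack$layers[sel$retained])
  masks <- timed("backgrounds", lapply(inp$occ, function(o) {
    if (cfg$background == "regions" && !is.null(inp$region))
      make_background(inp$region, o)
    else buffer_background(o, cfg$radius_km, sub_stack$grid,
                           valid = sub_stack$mask)
  }))

  enm <- timed("enm", lapply(sp, function(s) {
    et <- env_tables[[s]][, sel$retained, drop = FALSE]
    bg_cells <- which(masks[[s]]$included & sub_stack$mask)
    bg <- stack_env(sub_stack, bg_cells)
    model <- fit_suitability(as.matrix(et), bg,
                             seed = stage_seed(cfg$seed, paste0("enm_", s)))
    map <- project_suitability(model, sub_stack, masks[[s]],
                               link = cfg$link, species = s)
    pres_cells <- attr(env_tables[[s]], "cells")
    full <- project_suitability(model, sub_stack,
                                background_mask(sub_stack$grid, sub_stack$mask),
                                link = cfg$link, species = s)
    auc <- enm_auc(full$values[match(pres_cells, full$cells)],
                   map$values)
    list(model = model, map = map, full_map = full, auc = auc)
  }))
  names(enm) <- sp

  bg_tests <- timed("background_tests", {
    res <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      res[[paste(sp[i], sp[j], sep = "|")]] <- background_test(
        inp$occ[[i]], masks[[i]], inp$occ[[j]], masks[[j]], sub_stack,
        nreps = cfg$nreps, alpha = cfg$alpha,
        seed = stage_seed(cfg$seed, paste0("bg_", sp[i], "_", sp[j])),
        link = cfg$link)
    }
    res
  })
  classification <- overlap_matrix(bg_tests, species = sp)

  niche_d <- timed("niche_distances", {
    surfs <- lapply(enm, function(e) standardize_surface(e$full_map))
    hellinger_distances(surfs)
  })
  morpho_d <- timed("morpho_distances", euclidean_distances(traits, standardize = TRUE))

  # models with n <= k + 1 have undefined AICc at this species count;
  # skip them and record the restriction in the report
  k_of <- function(m) if (m %in% c("white", "BM")) 2L else 3L
  usable_models <- cfg$models[vapply(cfg$models, function(m) n > k_of(m) + 1L,
                                     logical(1))]
  if (!length(usable_models))
    stop("run_pipeline: too few species for AICc on any requested model")
  phylo <- timed("phylo_models", {
    tr <- rescale_depth(inp$tree, cfg$rescale_to)
    per_trait <- lapply(colnames(traits), function(tn) {
      fits <- lapply(usable_models, function(m)
        fit_trait_model(stats::setNames(traits[, tn], rownames(traits)), tr, m))
      model_select(fits)
    })
    names(per_trait) <- colnames(traits)
    per_trait
  })

  pls <- timed("pls", two_block_pls(means, traits, scale = "correlation",
                                    nperm = cfg$pls_nperm,
                                    seed = stage_seed(cfg$seed, "pls")))
  mant <- timed("mantel", mantel_test(niche_d, morpho_d,
                                      nperm = cfg$mantel_nperm,
                                      transform = cfg$mantel_transform,
                                      seed = stage_seed(cfg$seed, "mantel")))

  winners <- vapply(phylo, function(tab) tab$model[1], character(1))
  lambda_hat <- if ("lambda" %in% usable_models)
    vapply(phylo, function(tab) tab$theta[tab$model == "lambda"], numeric(1))
  else NULL
  report <- list(
    tool = "nichemorph",
    version = as.character(utils::packageVersion("nichemorph")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = stages,
    species = sp,
    retained_variables = sel$retained,
    auc = vapply(enm, function(e) e$auc, numeric(1)),
    classification_matrix = classification$matrix,
    classification_counts = classification$counts,
    n_comparisons = classification$n_comparisons,
    niche_distances = niche_d,
    morpho_distances = morpho_d,
    models_fitted = usable_models,
    model_winners = winners,
    lambda_estimates = lambda_hat,
    pls = list(singular_values = pls$singular_values,
               proportion = pls$proportion,
               correlation = pls$correlation,
               rv = pls$rv, p_rv = pls$p_rv,
               p_singular = pls$p_singular,
               p_correlation = pls$p_correlation),
    mantel = unclass(mant))

  if (!is.null(cfg$out_dir)) write_report(report, pls, cfg$out_dir)
  report
}

write_report <- function(report, pls, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor")
  utils::write.csv(report$classification_matrix,
                   file.path(out_dir, "classification.csv"))
  utils::write.csv(report$classification_counts,
                   file.path(out_dir, "classification_counts.csv"),
                   row.names = FALSE)
  loadings <- rbind(
    data.frame(block = "F1", variable = rownames(pls$left_loadings),
               pls$left_loadings, check.names = FALSE),
    data.frame(block = "F2", variable = rownames(pls$right_loadings),
               pls$right_loadings, check.names = FALSE))
  utils::write.csv(loadings, file.path(out_dir, "pls_loadings.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
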