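# Orchestration: a declarative run configuration and the end-to-end
# pipeline — thin, screen, tune, fit replicates, project periods/GCMs,
# ensemble, classify, range dynamics, multi-species stacking — with every
# random draw seeded from one master seed.

#' Default run configuration
#'
#' Returns the pipeline configuration as a nested list; override any entry
#' via `modifyList()` or supply a YAML file to [load_config()]. The
#' defaults encode the conventional protocol (screening at |r| >= 0.8 /
#' contribution > 10%, RM x FC tuning with block partitions for n >= 25
#' and jackknife otherwise, 10,000 background points, bootstrap
#' replicates averaged on the continuous scale, classes at 0.1/0.3/0.5,
#' binary dynamics at 0.5, stacking at 0.1) at a desk-scale synthetic
#' fixture size.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("sdm_run_"), seed = 1) {
  structure(list(
    out_dir = out_dir,
    seed = seed,
    synth = list(grid = list(west = 98, north = 30, cell_size = 2.5,
                             n_rows = 60, n_cols = 60),
                 n_layers = 4, correlation = 0.3, n_bumps = 25,
                 n_species = 2, n_presences = 40,
                 periods = list(lgm = list(Bio1 = -4, Bio2 = -2),
                                future = list(Bio1 = 2, Bio2 = 1)),
                 n_gcms = 2, noise_sd = 0.3),
    occurrences = NULL,                 # CSV path; NULL = synthetic
    screening = list(r_threshold = 0.8, contrib_threshold = 10,
                     always_keep = character()),
    tuning = list(rm_values = c(1, 1.5, 2), fc_sets = c("L", "LQ", "LQH"),
                  auc_min = 0.9, cbi_min = 0.5, delta_window = 2),
    background_size = 2000,
    replicates = 3,
    hinge_knots = 8,
    class_thresholds = c(0.1, 0.3, 0.5),
    binary_threshold = 0.5,
    stacking_threshold = 0.1,
    block_min_n = 25), class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file; entries override [default_config()].
#' @return `run_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  ct <- cfg$class_thresholds
  if (length(ct) != 3 || any(diff(ct) <= 0) || any(ct <= 0 | ct >= 1))
    stop("class_thresholds must be 3 strictly increasing values in (0,1)")
  if (cfg$binary_threshold <= 0 || cfg$binary_threshold >= 1)
    stop("binary_threshold must be in (0,1)")
  if (cfg$background_size < 1 || cfg$replicates < 1)
    stop("background_size and replicates must be positive")
  if (!is.null(cfg$occurrences) && !file.exists(cfg$occurrences))
    stop("occurrence file not found: ", cfg$occurrences)
  invisible(cfg)
}

#' Sample background cells
#'
#' Uniform seeded sample of valid study-area cells (presence cells are not
#' excluded, matching standard presence-background practice).
#'
#' @param stack An [env_stack()].
#' @param n Number of background cells.
#' @param seed RNG seed.
#' @return Integer vector of linear cell indices.
#' @export
sample_background <- function(stack, n, seed = 1) {
  cells <- valid_cells(stack)
  set.seed(seed)
  sample(cells, min(n, length(cells)), replace = n > length(cells))
}

#' Run the full modelling pipeline
#'
#' Executes thin -> screen -> tune -> replicate fits -> projection across
#' periods/GCMs -> GCM ensemble -> classification/binarization -> areas,
#' change maps, centroids -> multi-species stacking and refugium
#' inference, writing summary CSVs, .asc rasters and a JSON manifest under
#' `cfg$out_dir`. Reruns with the same config and seed reproduce
#' byte-identical summary CSVs.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @return The manifest (invisibly), listing every artifact path.
#' @export
run_pipeline <- function(cfg = default_config()) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  artifacts <- character()
  note <- function(p) artifacts[[length(artifacts) + 1L]] <<- p

  ## --- data: synthetic workspace (or user occurrences + stacks) --------
  sg <- cfg$synth$grid
  grid <- grid_spec(sg$west, sg$north, sg$cell_size, sg$n_rows, sg$n_cols)
  base_stack <- make_env_stack(grid, n_layers = cfg$synth$n_layers,
                               correlation_target = cfg$synth$correlation,
                               seed = derive_seed(seed, "stack"),
                               n_bumps = cfg$synth$n_bumps)
  scen <- make_scenario_series(base_stack, cfg$synth$periods,
                               n_gcms = cfg$synth$n_gcms,
                               noise_sd = cfg$synth$noise_sd,
                               seed = derive_seed(seed, "gcm"))
  bio_vars <- setdiff(names(base_stack$layers), "elevation")
  if (is.null(cfg$occurrences)) {
    nsp <- cfg$synth$n_species
    occ_list <- lapply(seq_len(nsp), function(i) {
      vars <- bio_vars[c(1 + (i - 1) %% length(bio_vars),
                         1 + i %% length(bio_vars))]
      truth <- make_truth(base_stack, "linear+quadratic", vars = vars)
      sample_presences(truth, cfg$synth$n_presences,
                       seed = derive_seed(seed, "presence", i),
                       species = sprintf("species_%02d", i))
    })
    occ <- occurrence_set(do.call(rbind, occ_list))
  } else {
    occ <- load_occurrences(cfg$occurrences)
  }
  occ <- thin_occurrences(occ, grid)
  note(write_occurrences(occ, file.path(cfg$out_dir, "occurrences_thinned.csv")))

  bg_cells <- sample_background(base_stack, cfg$background_size,
                                seed = derive_seed(seed, "background"))
  bg_env_all <- extract_env(base_stack, bg_cells, bio_vars)

  species <- unique(occ$species)
  all_class_areas <- list(); all_change <- list(); all_centroids <- list()
  binmaps_stacking <- list()   # period -> species -> binary map (0.1)
  per_species <- list()

  for (sp in species) {
    so <- occ[occ$species == sp, , drop = FALSE]
    idx <- cell_index(grid, so$lon, so$lat)
    pres_env <- extract_env(base_stack, idx$cell, bio_vars)
    keep_rows <- stats::complete.cases(pres_env)
    pres_env <- pres_env[keep_rows, , drop = FALSE]
    so <- so[keep_rows, , drop = FALSE]

    ## screen variables on a pilot fit's contributions
    pilot <- fit_maxent(pres_env, bg_env_all, fc = "LQH", rm = 1,
                        hinge_knots = cfg$hinge_knots)
    corr <- correlation_matrix(base_stack, bg_cells)[bio_vars, bio_vars]
    scr <- screen_variables(corr, variable_contributions(pilot),
                            r_threshold = cfg$screening$r_threshold,
                            contrib_threshold = cfg$screening$contrib_threshold,
                            always_keep = cfg$screening$always_keep)
    kept <- scr$kept
    if (length(kept) < 2) kept <- bio_vars
    utils::write.csv(scr$log,
                     file.path(cfg$out_dir, sprintf("screening_log_%s.csv", sp)),
                     row.names = FALSE)
    note(file.path(cfg$out_dir, sprintf("screening_log_%s.csv", sp)))
    p_env <- pres_env[, kept, drop = FALSE]
    b_env <- bg_env_all[, kept, drop = FALSE]

    ## tune RM x FC
    scheme <- if (nrow(so) >= cfg$block_min_n) "block" else "jackknife"
    part <- make_partition(so, scheme, seed = derive_seed(seed, "part", sp))
    tg <- tuning_grid(cfg$tuning$rm_values, cfg$tuning$fc_sets)
    tune <- run_grid(p_env, b_env, tg, part, hinge_knots = cfg$hinge_knots)
    sel <- select_best(tune, auc_min = cfg$tuning$auc_min,
                       cbi_min = cfg$tuning$cbi_min,
                       delta_window = cfg$tuning$delta_window)
    tune_out <- as.data.frame(tune)
    tune_out$selected <- tune_out$rm == sel$rm & tune_out$fc == sel$fc
    utils::write.csv(tune_out,
                     file.path(cfg$out_dir, sprintf("tuning_%s.csv", sp)),
                     row.names = FALSE)
    note(file.path(cfg$out_dir, sprintf("tuning_%s.csv", sp)))

    ## bootstrap replicate fits, averaged on the continuous scale
    boots <- make_partition(so, "bootstrap_replicate",
                            seed = derive_seed(seed, "boot", sp),
                            n_replicates = cfg$replicates)
    fits <- lapply(boots$folds, function(f)
      fit_maxent(p_env[f$train, , drop = FALSE], b_env,
                 fc = sel$fc, rm = sel$rm, hinge_knots = cfg$hinge_knots))
    contrib <- rowMeans(vapply(fits, variable_contributions,
                               numeric(length(kept))))
    utils::write.csv(data.frame(variable = kept, contribution_pct = contrib),
                     file.path(cfg$out_dir, sprintf("contributions_%s.csv", sp)),
                     row.names = FALSE)
    note(file.path(cfg$out_dir, sprintf("contributions_%s.csv", sp)))

    project_avg <- function(stk) {
      preds <- lapply(fits, function(m) predict(m, stk)$values)
      env_raster(stk$grid, Reduce(`+`, preds) / length(preds))
    }

    ## project: current + each period's GCM ensemble
    suit <- list(current = project_avg(base_stack))
    for (p in names(cfg$synth$periods)) {
      members <- scen[grep(paste0("^", p, ":"), names(scen))]
      suit[[p]] <- ensemble_mean(lapply(members, project_avg))
    }
    for (p in names(suit)) {
      pth <- file.path(cfg$out_dir, sprintf("suitability_%s_%s.asc", sp, p))
      note(write_asc(suit[[p]], pth))
    }

    ## classify / binarize / areas
    bins <- lapply(suit, to_binary, threshold = cfg$binary_threshold)
    for (p in names(suit)) {
      cls <- classify_suitability(suit[[p]], cfg$class_thresholds)
      ca <- class_areas(cls)
      ca$species <- sp; ca$period <- p
      all_class_areas[[paste(sp, p)]] <- ca
      binmaps_stacking[[p]][[sp]] <-
        to_binary(suit[[p]], threshold = cfg$stacking_threshold)
    }

    ## change maps and centroids vs current
    cur_centroid <- tryCatch(centroid(bins$current,
                                      stack_layer(base_stack, "elevation")),
                             error = function(e) NULL)
    for (p in setdiff(names(suit), "current")) {
      ch <- change_map(bins[[p]], bins$current)
      ca <- ch$areas; ca$species <- sp; ca$from <- p; ca$to <- "current"
      all_change[[paste(sp, p)]] <- ca
      pth <- file.path(cfg$out_dir, sprintf("change_%s_%s_to_current.asc", sp, p))
      note(write_asc(ch$map, pth))
      shift <- tryCatch({
        c_from <- centroid(bins[[p]])
        s <- centroid_shift(c_from, cur_centroid)
        data.frame(species = sp, from = p, to = "current",
                   lon_from = c_from$lon, lat_from = c_from$lat,
                   lon_to = cur_centroid$lon, lat_to = cur_centroid$lat,
                   elevation_to_m = cur_centroid$elevation_m,
                   distance_km = s$distance_km, bearing_deg = s$bearing_deg)
      }, error = function(e) NULL)
      if (!is.null(shift)) all_centroids[[paste(sp, p)]] <- shift
    }

    ## refugium: first configured period (glacial stand-in) vs current
    p1 <- names(cfg$synth$periods)[1]
    ref <- infer_refugium(bins[[p1]], bins$current)
    note(write_asc(ref, file.path(cfg$out_dir,
                                  sprintf("refugium_%s.asc", sp))))
    per_species[[sp]] <- list(selected = sel, suitability = suit,
                              binary = bins, contributions = contrib)
  }

  ## multi-species stacking per period
  stack_rows <- lapply(names(binmaps_stacking), function(p) {
    st <- stack_species(binmaps_stacking[[p]])
    note(write_asc(st$counts, file.path(cfg$out_dir,
                                        sprintf("overlap_%s.asc", p))))
    data.frame(period = p, n_species = length(st$species),
               max_overlap = st$max_count,
               n_max_cells = length(st$max_cells))
  })

  write_sorted <- function(lst, file) {
    df <- do.call(rbind, lst)
    rownames(df) <- NULL
    utils::write.csv(df, file.path(cfg$out_dir, file), row.names = FALSE)
    note(file.path(cfg$out_dir, file))
    df
  }
  areas_df <- write_sorted(all_class_areas, "class_areas.csv")
  change_df <- if (length(all_change)) write_sorted(all_change, "change_areas.csv")
  centroids_df <- if (length(all_centroids)) write_sorted(all_centroids, "centroids.csv")
  stack_df <- write_sorted(stack_rows, "stack_summary.csv")

  manifest <- list(package_version = as.character(utils::packageVersion("maxentsdm")),
                   seed = seed,
                   species = species,
                   selected = lapply(per_species, function(x)
                     list(rm = x$selected$rm, fc = x$selected$fc)),
                   artifacts = unlist(artifacts))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, per_species = per_species,
                 class_areas = areas_df, change_areas = change_df,
                 centroids = centroids_df, stacking = stack_df,
                 out_dir = cfg$out_dir))
}
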