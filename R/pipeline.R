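#' @title Configuration and end-to-end pipeline
#' @description Schema-validated configuration and the orchestrated run from
#'   synthetic world generation through occurrence preparation, per-species
#'   ensemble SDMs, PA-effectiveness metrics and conservation-gap maps. A
#'   single master seed derives all stage and species seeds, so adding a
#'   species never perturbs existing results and identical configs reproduce
#'   identical artifacts.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' The defaults define the package's reference study conditions: a 200 x 200
#' km synthetic world, 30 virtual species with two-variable Gaussian niches,
#' biased presence-only sampling, a PA network covering ~15% of cells placed
#' in climate-stable locations, warming of +2.5 deg C with 10% drier
#' precipitation, and climate-change damping of 0.5 inside PAs.
#'
#' @return A nested named list understood by [validate_config()].
#' @export
default_config <- function() {
  list(
    grid = list(n_rows = 200L, n_cols = 200L, cell_size_km = 1),
    climate = list(range_km = 15, bio1_mean = 15, bio1_sd = 5,
                   bio3_mean = 45, bio3_sd = 8, bio5_offset = 8,
                   bio6_offset = 12, bio12_median = 800, bio12_logsd = 0.5,
                   bio18_frac = 0.4),
    scenario = list(bio1_add = 2.5, bio5_add = 2.5, bio6_add = 2.5,
                    bio12_mul = 0.9, bio18_mul = 0.9, noise_sd = 0.1,
                    pa_damping = 0.5, label = "future"),
    species = list(n_species = 30L, n_occurrences = 400L,
                   niche_vars = c("BIO1", "BIO12"), niche_sd_frac = 0.35,
                   presence_threshold = 0.3, bias = "gradient",
                   bias_ratio = 3),
    pa = list(target_fraction = 0.15, n_patches = 25L,
              placement = "stable",
              class_mix = list(Ia = 0.1, II = 0.3, IV = 0.2, V = 0.2,
                               VI = 0.2)),
    partition = list(k_regions = 6L, k_countries = 8L),
    prep = list(min_records = 5L, buffer_km = 400, dedup = TRUE),
    sdm = list(buffer_km = 500, vif_threshold = 10, n_vif_cells = 10000L,
               n_pa = NULL, train_frac = 0.7, n_rep = 5L,
               retention_min = 0.7,
               algorithms = c("glm", "gbm", "maxent", "rf", "svm")),
    analysis = list(benchmarks = c(0.15, 0.30), top_frac = 0.2,
                    bottom_frac = 0.2, subset = "strict"),
    seed = 1L
  )
}

#' Validate and complete a raw configuration
#'
#' Unknown keys are rejected with the offending name; missing keys take the
#' documented defaults; out-of-range values raise errors naming the key and
#' its constraint.
#'
#' @param raw A nested list (e.g. parsed from YAML/JSON), or NULL for pure
#'   defaults.
#' @return The completed configuration, classed `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  def <- default_config()
  cfg <- merge_config(raw %||% list(), def, path = "")
  chk <- function(ok, key, constraint) {
    if (!ok) stop("config error: ", key, " must be ", constraint,
                  call. = FALSE)
  }
  chk(cfg$grid$n_rows >= 1 && cfg$grid$n_cols >= 1, "grid.n_rows/n_cols",
      "positive")
  chk(cfg$grid$cell_size_km > 0, "grid.cell_size_km", "> 0")
  chk(cfg$climate$range_km > 0, "climate.range_km", "> 0")
  chk(cfg$scenario$pa_damping >= 0 && cfg$scenario$pa_damping <= 1,
      "scenario.pa_damping", "in [0, 1]")
  chk(cfg$species$n_species >= 1, "species.n_species", ">= 1")
  chk(cfg$species$presence_threshold > 0 && cfg$species$presence_threshold < 1,
      "species.presence_threshold", "in (0, 1)")
  chk(cfg$pa$target_fraction > 0 && cfg$pa$target_fraction < 1,
      "pa.target_fraction", "in (0, 1)")
  chk(abs(sum(unlist(cfg$pa$class_mix)) - 1) < 1e-8, "pa.class_mix",
      "proportions summing to 1")
  chk(cfg$pa$placement %in% c("uniform", "stable"), "pa.placement",
      "'uniform' or 'stable'")
  chk(cfg$sdm$train_frac > 0 && cfg$sdm$train_frac < 1, "sdm.train_frac",
      "in (0, 1)")
  chk(cfg$sdm$retention_min >= -1 && cfg$sdm$retention_min <= 1,
      "sdm.retention_min", "in [-1, 1]")
  chk(cfg$sdm$vif_threshold > 1, "sdm.vif_threshold", "> 1")
  chk(all(cfg$sdm$algorithms %in% c("glm", "gbm", "maxent", "rf", "svm")),
      "sdm.algorithms", "a subset of glm/gbm/maxent/rf/svm")
  chk(cfg$analysis$subset %in% c("strict", "all"), "analysis.subset",
      "'strict' or 'all'")
  chk(cfg$analysis$top_frac > 0 && cfg$analysis$top_frac <= 1 &&
        cfg$analysis$bottom_frac > 0 && cfg$analysis$bottom_frac <= 1,
      "analysis.top_frac/bottom_frac", "in (0, 1]")
  chk(cfg$seed == as.integer(cfg$seed), "seed", "an integer")
  class(cfg) <- c("run_config", "list")
  cfg
}

merge_config <- function(user, def, path) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("config error: unknown key ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  }
  out <- def
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(user[[k]])) {
      out[[k]] <- merge_config(user[[k]], def[[k]], paste0(path, ".", k))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Run the pipeline end to end (or a stage subset)
#'
#' Stages: `simulate` (world generation), `prep` (occurrence cleaning and
#' the minimum-record rule), `sdm` (per-species ensembles and no-dispersal
#' projections), `assess` (PA-effectiveness metrics and Wilcoxon tests),
#' `gaps` (priority/gap maps and country accounting). Stage state is cached
#' in `out_dir/state.rds`, so later stages can be re-run alone; a missing
#' upstream artifact raises a dependency error.
#'
#' @param config A [validate_config()] result (or raw list, validated here).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate","prep","sdm","assess","gaps")` in pipeline order, or
#'   `"all"`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `config`, `results` (all in-memory stage
#'   products) and `manifest` (seeds, statuses, artifact checksums).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         stages = "all", quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  all_stages <- c("simulate", "prep", "sdm", "assess", "gaps")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state_path <- file.path(out_dir, "state.rds")
  st <- if (file.exists(state_path)) readRDS(state_path) else list()
  log_path <- file.path(out_dir, "log.jsonl")
  say <- function(stage, ...) {
    msg <- paste0(...)
    cat(jsonlite::toJSON(list(stage = stage, msg = msg), auto_unbox = TRUE),
        "\n", file = log_path, append = TRUE)
    if (!quiet) message("[", stage, "] ", msg)
  }
  need <- function(field, from) {
    if (is.null(st[[field]])) {
      stop("dependency error: stage needs '", field,
           "' from the '", from, "' stage; run it first", call. = FALSE)
    }
    st[[field]]
  }
  master <- as.integer(cfg$seed)
  manifest <- list(seed = master, stage_seeds = list(), statuses = list(),
                   warnings = character())

  if ("simulate" %in% stages) {
    say("simulate", "generating synthetic world")
    world <- simulate_world(cfg, master, say)
    st[names(world)] <- world
  }
  if ("prep" %in% stages) {
    need("occurrences", "simulate")
    grid <- need("grid", "simulate")
    say("prep", "cleaning and thinning occurrences")
    occ <- lapply(st$occurrences, function(o) {
      o <- clean_coordinates(o, blacklist = NULL, dedup = cfg$prep$dedup)
      thin_occurrences(o, grid)
    })
    sel <- select_modelable_species(occ, cfg$prep$min_records)
    st$occ_clean <- occ
    st$modelable <- sel
    utils::write.csv(cleaning_report(occ, cfg$prep$min_records),
                     file.path(out_dir, "cleaning_report.csv"),
                     row.names = FALSE)
    say("prep", sum(sel$modelable), " of ", nrow(sel), " species modelable")
  }
  if ("sdm" %in% stages) {
    occ <- need("occ_clean", "prep")
    sel <- need("modelable", "prep")
    climate <- need("climate_current", "simulate")
    future <- need("climate_future", "simulate")
    part <- need("partition", "simulate")
    current <- list(); future_r <- list(); status <- list()
    for (id in sel$species_id[sel$modelable]) {
      say("sdm", "fitting ", id)
      o <- occ[[id]]
      fit <- withCallingHandlers(
        ensemble_sdm(o, climate, partition = part,
                     buffer_km = cfg$sdm$buffer_km,
                     vif_threshold = cfg$sdm$vif_threshold,
                     n_vif_cells = cfg$sdm$n_vif_cells,
                     n_pa = cfg$sdm$n_pa, train_frac = cfg$sdm$train_frac,
                     n_rep = cfg$sdm$n_rep,
                     algorithms = cfg$sdm$algorithms,
                     retention_min = cfg$sdm$retention_min,
                     species_id = id,
                     seed = derive_seed(master, paste0("sdm:", id))),
        warning = function(w) {
          manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (fit$status != "ok") {
        status[[id]] <- "unmodelable"
        next
      }
      current[[id]] <- fit$range
      fr <- project_range(fit, future, cfg$scenario$label)
      future_r[[id]] <- fr
      status[[id]] <- if (fr$extinct) "extinct_future" else "modelled"
    }
    for (id in sel$species_id[!sel$modelable]) status[[id]] <- "dropped"
    st$ranges_current <- current
    st$ranges_future <- future_r
    st$species_status <- status
    jsonlite::write_json(status, file.path(out_dir, "species_status.json"),
                         auto_unbox = TRUE)
    say("sdm", length(current), " species modelled; ",
        sum(unlist(status) == "unmodelable"), " unmodelable; ",
        sum(unlist(status) == "extinct_future"), " extinct in future")
  }
  if ("assess" %in% stages) {
    current <- need("ranges_current", "sdm")
    future_r <- need("ranges_future", "sdm")
    pa <- need("pa", "simulate")
    say("assess", "computing PA-effectiveness metrics")
    st$metrics <- species_metrics_table(current, future_r, pa,
                                        cell_area_km2 = cfg$grid$cell_size_km^2)
    st$assessment <- assess_pa_effectiveness(st$metrics, current, future_r,
                                             pa, cfg)
    utils::write.csv(st$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(st$assessment$summaries,
                     file.path(out_dir, "summaries.csv"), row.names = FALSE)
    utils::write.csv(st$assessment$tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
  }
  if ("gaps" %in% stages) {
    current <- need("ranges_current", "sdm")
    future_r <- need("ranges_future", "sdm")
    pa <- need("pa", "simulate")
    part <- need("partition", "simulate")
    grid <- need("grid", "simulate")
    say("gaps", "mapping conservation priorities and gaps")
    rich <- richness_map(current, grid)
    loss <- species_loss_map(current, future_r, grid)
    pm <- identify_priority_and_gaps(rich, loss, pa, cfg$analysis$subset,
                                     cfg$analysis$top_frac,
                                     cfg$analysis$bottom_frac)
    cg <- country_gap_summary(pm$gap, part, cfg$grid$cell_size_km^2)
    st$richness <- rich; st$loss <- loss; st$priority <- pm
    st$country_gaps <- cg
    write_ascii_raster(rich, grid, file.path(out_dir, "richness_current.asc"))
    write_ascii_raster(loss, grid, file.path(out_dir, "species_loss_pct.asc"))
    write_ascii_raster(pm$priority * 1, grid,
                       file.path(out_dir, "priority.asc"))
    write_ascii_raster(pm$gap * 1, grid, file.path(out_dir, "gap.asc"))
    utils::write.csv(cg, file.path(out_dir, "country_gaps.csv"),
                     row.names = FALSE)
  }
  saveRDS(st, state_path)
  arts <- list.files(out_dir, pattern = "\\.(csv|asc|json)$",
                     full.names = TRUE)
  manifest$artifacts <- as.list(tools::md5sum(arts))
  manifest$config <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, results = st, manifest = manifest))
}

# world generation: climate (current, draft future), PA placement, damped
# future, partitions, virtual species and raw occurrence records
simulate_world <- function(cfg, master, say) {
  grid <- grid_spec(cfg$grid$n_rows, cfg$grid$n_cols, cfg$grid$cell_size_km)
  cp <- do.call(climate_params, cfg$climate)
  current <- simulate_climate(grid, cp, seed = derive_seed(master, "climate"))
  shift <- list(BIO1 = c(add = cfg$scenario$bio1_add),
                BIO5 = c(add = cfg$scenario$bio5_add),
                BIO6 = c(add = cfg$scenario$bio6_add),
                BIO12 = c(mul = cfg$scenario$bio12_mul),
                BIO18 = c(mul = cfg$scenario$bio18_mul))
  draft_future <- project_future_climate(
    current, shift, noise_sd = cfg$scenario$noise_sd,
    seed = derive_seed(master, "future"), scenario_label = cfg$scenario$label)
  pa <- simulate_pa_network(
    grid, cfg$pa$target_fraction, cfg$pa$n_patches,
    class_mix = unlist(cfg$pa$class_mix), placement = cfg$pa$placement,
    climate_current = current, climate_future = draft_future,
    seed = derive_seed(master, "pa"))
  future <- if (cfg$scenario$pa_damping < 1) {
    project_future_climate(
      current, shift, noise_sd = cfg$scenario$noise_sd,
      pa_stability = list(pa = pa, damping = cfg$scenario$pa_damping),
      seed = derive_seed(master, "future"),
      scenario_label = cfg$scenario$label)
  } else draft_future
  part <- simulate_partition(grid, cfg$partition$k_regions,
                             cfg$partition$k_countries,
                             seed = derive_seed(master, "partition"))
  bias <- NULL
  if (identical(cfg$species$bias, "gradient")) {
    # sampling effort declines west to east by bias_ratio
    w <- seq(cfg$species$bias_ratio, 1, length.out = grid$n_cols)
    bias <- matrix(w, grid$n_rows, grid$n_cols, byrow = TRUE)
  }
  species <- list(); occurrences <- list(); truths <- list()
  set.seed(derive_seed(master, "species"))
  layer_sd <- lapply(cfg$species$niche_vars, function(v)
    stats::sd(current$layers[[v]][current$mask]))
  names(layer_sd) <- cfg$species$niche_vars
  for (i in seq_len(cfg$species$n_species)) {
    id <- sprintf("vsp%03d", i)
    anchor <- sample(which(current$mask), 1)
    niche <- lapply(cfg$species$niche_vars, function(v)
      c(opt = current$layers[[v]][anchor],
        sd = cfg$species$niche_sd_frac * layer_sd[[v]]))
    names(niche) <- cfg$species$niche_vars
    vsp <- virtual_species(id, niche, cfg$species$presence_threshold)
    suit <- true_suitability(vsp, current)
    truth <- true_range(vsp, current)
    if (!any(truth)) {
      say("simulate", id, " has an empty true range; skipped")
      next
    }
    species[[id]] <- vsp
    truths[[id]] <- truth
    occurrences[[id]] <- sample_occurrences(
      id, suit, truth, cfg$species$n_occurrences, grid, bias = bias,
      seed = derive_seed(master, paste0("occ:", id)))
  }
  say("simulate", length(species), " virtual species generated")
  list(grid = grid, climate_current = current, climate_future = future,
       pa = pa, partition = part, species = species, truths = truths,
       occurrences = occurrences, bias = bias)
}

# the assess-stage statistics: global summaries, benchmark shares,
# protected percentages, RWR, and the Wilcoxon comparisons
assess_pa_effectiveness <- function(metrics, current, future_r, pa, cfg) {
  subset <- cfg$analysis$subset
  alive_future <- !vapply(future_r, `[[`, TRUE, "extinct")
  cov_cur <- metrics$coverage_strict
  cov_fut <- metrics$coverage_strict_future
  if (subset == "all") {
    cov_cur <- metrics$coverage_all
    cov_fut <- metrics$coverage_all_future
  }
  loss_in <- metrics$loss_inside
  loss_out <- metrics$loss_outside
  both <- !is.na(loss_in) & !is.na(loss_out)
  w_loss <- wilcoxon_signed_rank(loss_out[both], loss_in[both])
  w_cov <- wilcoxon_rank_sum(cov_fut[!is.na(cov_fut)],
                             cov_cur[!is.na(cov_cur)])
  tests <- data.frame(
    comparison = c("loss_outside_vs_inside", "coverage_future_vs_current"),
    n = c(w_loss$n_used, w_cov$n_used),
    Z = c(w_loss$Z, w_cov$Z), p = c(w_loss$p, w_cov$p),
    paired = c(TRUE, FALSE))
  bm <- cfg$analysis$benchmarks
  list(
    summaries = rbind(
      cbind(scenario = "current",
            summarize_group(metrics, "none", bm)),
      cbind(scenario = "future", summarize_group(
        within(metrics, {
          coverage_strict <- coverage_strict_future
          loss_inside <- NA_real_; loss_outside <- NA_real_
        }), "none", bm))),
    tests = tests,
    pct_protected_current = pct_species_protected(current, pa, subset),
    pct_protected_future = pct_species_protected(future_r, pa, subset),
    rwr_current = rarity_weighted_richness(current, pa, subset),
    rwr_future = rarity_weighted_richness(
      Filter(function(r) any(r$raster), future_r), pa, subset),
    benchmark_current = vapply(bm, function(b)
      benchmark_proportion(cov_cur[!is.na(cov_cur)], b), 0),
    benchmark_future = vapply(bm, function(b)
      benchmark_proportion(cov_fut[!is.na(cov_fut)], b), 0),
    median_loss_inside = stats::median(loss_in, na.rm = TRUE),
    median_loss_outside = stats::median(loss_out, na.rm = TRUE),
    n_extinct = sum(!alive_future))
}
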