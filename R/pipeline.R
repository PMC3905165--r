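# Orchestration: one entry point running the analysis stages over a
# configuration, writing one output sub-directory per stage plus a
# machine-readable summary.  The numbered scripts under analysis/ are
# thin drivers over this function and the stage functions themselves.

#' Read a pipeline configuration file
#'
#' YAML key-value configuration; see [run_pipeline()] for the
#' recognised keys.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # hash the analysis parameters, not where they came from or go to
  saveRDS(config[setdiff(names(config), c("config_path", "outdir"))], f)
  unname(tools::md5sum(f))
}

provenance_header <- function(config) {
  c(sprintf("# gatescape %s",
            as.character(utils::packageVersion("gatescape"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", config$seed %||% "NA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_prov <- function(df, path, config) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# resolve the input system: either a synthetic bundle spec or paths
resolve_input <- function(config) {
  if (!is.null(config$bundle)) {
    b <- config$bundle
    spec <- bundle_spec(gate_cyt = b$gate_cyt %||% 0,
                        gate_peri = b$gate_peri %||% 0,
                        seed = b$seed %||% config$seed %||% 1)
    s <- make_bundle(spec)
    ens <- if (!is.null(config$n_frames) && config$n_frames > 1)
      make_transition(s, s, config$n_frames, noise_sigma = 0.1,
                      seed = config$seed %||% 1)
    else ensemble3d(s, list(coords(s)))
    list(structure = s, ensemble = ens)
  } else if (!is.null(config$ensemble)) {
    e <- read_ensemble(config$ensemble)
    list(structure = e$topology, ensemble = e)
  } else if (!is.null(config$structure)) {
    s <- read_structure(config$structure)
    list(structure = s, ensemble = ensemble3d(s, list(coords(s))))
  } else stop("configuration names no input (bundle, ensemble or structure)")
}

resolve_gate_pairs <- function(config, input) {
  g <- config$gates
  if (is.null(g) || identical(g, "bundle")) {
    if (is.null(input$structure$anchors))
      stop("gates stage: no gate definition in config and the input ",
           "carries no recorded anchors")
    bundle_gate_pairs(input$structure)
  } else {
    list(cyt = gate_pair("cytoplasmic", g$cyt$chainA, g$cyt$residA,
                         g$cyt$chainB, g$cyt$residB),
         peri = gate_pair("periplasmic", g$peri$chainA, g$peri$residA,
                          g$peri$chainB, g$peri$residB))
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages over one configured input system and
#' writes per-stage outputs plus `summary.json` under `outdir`.  Every
#' output file carries a provenance header (package version, config
#' hash, seed).
#'
#' Recognised configuration keys: `bundle` (gate_cyt, gate_peri, seed)
#' or `structure`/`ensemble` (paths); `n_frames`; `gates` ("bundle" or
#' explicit anchor pairs); `thresholds` (cyt, peri); `pore` (z_min,
#' z_max, step); `water` (density, region/regionA/regionB boxes,
#' threshold, connectivity); `born` (schedule scale or levels,
#' z_points); `deer` (siteA/siteB chain+resid, n_rotamers,
#' clash_cutoff); `cluster` (cutoff_nm); `seed`; `outdir`.
#'
#' @param config named list (see [read_run_config()]).
#' @param stages subset of `c("gates", "pore", "water", "born", "deer",
#'   "cluster")`.
#' @return invisible list with the stage summaries (also serialized to
#'   `summary.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("gates", "pore", "water", "deer",
                                    "cluster")) {
  known <- c("gates", "pore", "water", "born", "deer", "cluster")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  input <- resolve_input(config)
  summary <- list(seed = config$seed %||% NA,
                  config_hash = config_hash(config),
                  input_label = input$structure$label)

  run_stage <- function(name, fn) {
    sdir <- file.path(outdir, name)
    dir.create(sdir, showWarnings = FALSE)
    tryCatch(fn(sdir), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("gates" %in% stages) {
    summary$gates <- run_stage("gates", function(sdir) {
      pairs <- resolve_gate_pairs(config, input)
      thr <- state_thresholds(config$thresholds$cyt %||% 13,
                              config$thresholds$peri %||% 8)
      tr <- order_parameter_trace(input$ensemble, pairs$cyt, pairs$peri,
                                  thr)
      write_tsv_prov(tr, file.path(sdir, "trace.tsv"), config)
      counts <- table(tr$state)
      list(state_counts = as.list(counts),
           dominant_state = names(counts)[which.max(counts)],
           d_cyt_mean = mean(tr$d_cyt), d_peri_mean = mean(tr$d_peri))
    })
  }
  if ("pore" %in% stages) {
    summary$pore <- run_stage("pore", function(sdir) {
      pz <- config$pore
      zg <- seq(pz$z_min %||% -15, pz$z_max %||% 15, by = pz$step %||% 1.5)
      prof <- pore_profile(input$ensemble, zg)
      write_tsv_prov(prof, file.path(sdir, "profile.tsv"), config)
      list(min_radius = min(prof$mean_radius, na.rm = TRUE),
           min_radius_cyt = min(prof$mean_radius[prof$z < 0], na.rm = TRUE),
           min_radius_peri = min(prof$mean_radius[prof$z > 0], na.rm = TRUE))
    })
  }
  if ("water" %in% stages) {
    summary$water <- run_stage("water", function(sdir) {
      wc <- config$water
      region <- list(min = unlist(wc$region$min),
                     max = unlist(wc$region$max))
      waters <- fill_cavity_waters(input$structure, region,
                                   wc$density %||% spc_bulk_number_density(),
                                   seed = config$seed %||% 1,
                                   n_frames = wc$n_frames %||% 20L)
      dims <- ceiling((region$max - region$min) / (wc$spacing %||% 1)) + 1L
      dens <- water_density(waters, origin = region$min,
                            spacing = wc$spacing %||% 1, dims = dims)
      write_dx(dens, file.path(sdir, "relative_density.dx"))
      verdicts <- list()
      for (face in c("cyt", "peri")) {
        rb <- wc[[paste0("region_", face)]]
        if (is.null(rb)) next
        conn <- pathway_connected(dens, wc$threshold %||% 0.5,
                                  list(min = unlist(wc$region_cavity$min),
                                       max = unlist(wc$region_cavity$max)),
                                  list(min = unlist(rb$min),
                                       max = unlist(rb$max)),
                                  connectivity = wc$connectivity %||% 26)
        verdicts[[face]] <- conn$connected
      }
      c(list(n_water_frames = length(waters),
             mean_rel_density = mean(dens$values)),
        connected = verdicts)
    })
  }
  if ("born" %in% stages) {
    summary$born <- run_stage("born", function(sdir) {
      bc <- config$born %||% list()
      schedule <- if (!is.null(bc$levels))
        focusing_schedule(lapply(bc$levels, unlist))
      else focusing_schedule(scale = bc$scale %||% "desk")
      ion <- born_ion(1, bc$radius %||% born_radius(1, -110.4, 80))
      model <- dielectric_model()
      prof <- membrane_barrier_profile(ion, model, schedule,
                                       z_points = unlist(bc$z_points %||%
                                                           c(35, 0)))
      write_tsv_prov(prof, file.path(sdir, "barrier.tsv"), config)
      list(W_bulk = prof$W[1], W_core = prof$W[nrow(prof)],
           barrier = max(prof$W) - min(prof$W))
    })
  }
  if ("deer" %in% stages) {
    summary$deer <- run_stage("deer", function(sdir) {
      dc <- config$deer %||% list()
      lib <- make_rotamer_library(dc$n_rotamers %||% 20,
                                  arm_length = dc$arm_length %||% 7,
                                  seed = config$seed %||% 1)
      siteA <- label_site(dc$siteA$chain %||% "A", dc$siteA$resid,
                          dc$clash_cutoff %||% 2.0)
      siteB <- label_site(dc$siteB$chain %||% "B", dc$siteB$resid,
                          dc$clash_cutoff %||% 2.0)
      dist <- ensemble_distribution(input$ensemble, siteA, siteB, lib)
      write_distribution(dist, file.path(sdir, "distribution.tsv"))
      list(mean_distance = distribution_mean(dist),
           empty = isTRUE(dist$empty),
           skipped_frames = attr(dist, "skipped_frames"))
    })
  }
  if ("cluster" %in% stages) {
    summary$cluster <- run_stage("cluster", function(sdir) {
      cc <- config$cluster %||% list()
      rm <- pairwise_rmsd(input$ensemble)
      cl <- daura_cluster(rm, cutoff = cc$cutoff_nm %||% 0.25)
      rep <- data.frame(
        cluster = seq_along(cl$clusters),
        center = vapply(cl$clusters, `[[`, integer(1), "center"),
        size = vapply(cl$clusters, function(x) length(x$members),
                      integer(1)),
        members = vapply(cl$clusters, function(x)
          paste(x$members, collapse = ","), character(1)))
      write_tsv_prov(rep, file.path(sdir, "clusters.tsv"), config)
      list(n_clusters = length(cl$clusters),
           dominant_size = length(cl$clusters[[1]]$members),
           last_frame_in_dominant = contains_frame(cl,
                                                   n_frames(input$ensemble)))
    })
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
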