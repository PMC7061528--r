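# End-to-end orchestration: simulate -> landscape -> basins -> barriers ->
# MFPT -> flux (-> sensitivity -> synthetic comparison), with per-stage
# caching keyed on the config hash and a provenance manifest.

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; each stage's outputs are written as
#' TSV/JSON under `cfg$out_dir` and skipped on re-run when the config hash
#' matches. Every stage derives its seeds deterministically from the master
#' seed, so a (config, seed) pair reproduces every numeric output.
#'
#' @param cfg a `run_config` (see [run_config()], [read_run_config()]).
#' @param stages subset of
#'   `c("simulate", "landscape", "kinetics", "sensitivity", "synthetic")`
#'   (earlier stages are implied).
#' @param quiet suppress progress messages.
#' @return A `run_manifest` (list): config hash, per-stage outputs, wall
#'   times, and in-memory results (`grid`, `basins`, `barriers`, `mfpts`,
#'   `flux`, ...).
#' @export
run_all <- function(cfg = run_config(), stages = c("simulate", "landscape",
                                                   "kinetics"),
                    quiet = FALSE) {
  t0_all <- proc.time()[3]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config_hash = hash, out_dir = cfg$out_dir,
                   version = as.character(utils::packageVersion("grnlandscape")),
                   stages = list(), files = list())
  network <- read_network_config(cfg$network)
  viol <- validate_network(network)
  if (length(viol)) stop(paste("invalid network:", paste(viol, collapse = "; ")))
  seeds <- derive_seeds(cfg$seed, 4)  # one per stochastic stage
  res <- list(network = network)

  cache_file <- file.path(cfg$out_dir, "manifest.json")
  cached <- if (file.exists(cache_file))
    tryCatch(jsonlite::read_json(cache_file), error = function(e) NULL) else NULL
  cache_ok <- !is.null(cached) && identical(cached$config_hash, hash)
  if (cache_ok &&
      all(stages %in% names(cached$stages)) &&
      all(vapply(cached$files, function(f) file.exists(f$path), TRUE))) {
    say("config hash %s matches cached manifest; skipping all stages", hash)
    return(invisible(structure(list(manifest = cached, cached = TRUE),
                               class = "run_result")))
  }

  sim <- cfg$simulation
  burn_in <- sim$burn_in_frac * sim$t_max

  # -- simulate + landscape (always recomputed together; occupancy histograms
  #    are not serialized, only the derived landscape is) ---------------------
  t0 <- proc.time()[3]
  say("stage simulate: %d runs x t_max %g", sim$n_runs, sim$t_max)
  inits <- if (isTRUE(sim$dispersed_inits) && all(sim$axes %in% node_names(network)))
    dispersed_inits(network, axes = unique(sim$axes)) else NULL
  ens <- ensemble_grn(network, n_runs = sim$n_runs, t_max = sim$t_max,
                      burn_in = burn_in, seed = seeds[1], inits = inits,
                      record_every = sim$record_every,
                      occupancy_axes = sim$axes, bin_width = sim$bin_width)
  manifest$stages$simulate <- list(
    wall = proc.time()[3] - t0,
    events = sum(vapply(ens, `[[`, 0, "events")))
  if (!is.null(ens[[1]]$records)) {
    f <- file.path(cfg$out_dir, "trajectory_run1.tsv")
    write.table(ens[[1]]$records, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files$trajectory <- f
  }

  t0 <- proc.time()[3]
  grid <- estimate_landscape(ens, axes = sim$axes, bin_width = sim$bin_width,
                             smooth_bw = cfg$landscape$smooth_bw)
  basins <- find_basins(grid, cfg$landscape$merge_threshold)
  if (all(c("P53", "OCT4", "ZEB") %in% sim$axes)) {
    basins <- label_basins(basins, grid, thresholds = cfg$landscape$thresholds)
  } else {
    basins$summary$label <- as.character(basins$summary$basin)
  }
  res$grid <- grid; res$basins <- basins
  f <- file.path(cfg$out_dir, "basins.tsv")
  write.table(basins$summary, f, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$files$basins <- f
  manifest$stages$landscape <- list(wall = proc.time()[3] - t0,
                                    n_basins = nrow(basins$summary),
                                    labels = basins$summary$label)
  say("stage landscape: %d basins (%s)", nrow(basins$summary),
      paste(basins$summary$label, collapse = ", "))

  if ("kinetics" %in% stages || "sensitivity" %in% stages) {
    t0 <- proc.time()[3]
    kin <- cfg$kinetics
    barriers <- barrier_matrix(grid, basins)
    res$barriers <- barriers
    f <- file.path(cfg$out_dir, "barriers.tsv")
    write.table(barriers, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files$barriers <- f

    routes <- c(kin$forward_routes, kin$reverse_routes)
    steps <- unique(do.call(rbind, c(list(data.frame(from = character(0),
                                                     to = character(0))),
                                     lapply(routes, function(r)
      data.frame(from = r[-length(r)], to = r[-1])))))
    labs <- basins$summary$label
    steps <- steps[steps$from %in% labs & steps$to %in% labs, , drop = FALSE]
    mseed <- derive_seeds(seeds[2], max(nrow(steps), 1))
    mfpts <- lapply(seq_len(nrow(steps)), function(i) {
      say("stage kinetics: MFPT %s -> %s", steps$from[i], steps$to[i])
      mfpt(network, grid, basins, steps$from[i], steps$to[i],
           n_passages = kin$n_passages, seed = mseed[i],
           delta_core = kin$delta_core, max_events = kin$max_events)
    })
    mtab <- do.call(rbind, c(list(data.frame(from = character(0), to = character(0),
                                             mean = numeric(0), se = numeric(0),
                                             n_passages = integer(0),
                                             censored = integer(0),
                                             reliable = logical(0))),
                             lapply(mfpts, function(m)
      data.frame(from = m$from, to = m$to, mean = m$mean, se = m$se,
                 n_passages = m$n_passages, censored = m$censored,
                 reliable = m$reliable))))
    res$mfpts <- mtab
    f <- file.path(cfg$out_dir, "mfpt.tsv")
    write.table(mtab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files$mfpt <- f

    probs <- setNames(basins$summary$P_mass, basins$summary$label)
    flux <- list()
    for (dir in c("forward_routes", "reverse_routes")) {
      rts <- Filter(function(r) all(r %in% labs) &&
                      all(paste0(r[-length(r)], "->", r[-1]) %in%
                            paste0(mtab$from, "->", mtab$to)), kin[[dir]])
      if (length(rts) && !anyNA(mtab$mean[match(
            unlist(lapply(rts, function(r) paste0(r[-length(r)], "->", r[-1]))),
            paste0(mtab$from, "->", mtab$to))])) {
        flux[[dir]] <- path_flux(rts, mtab, probs)
      }
    }
    res$flux <- flux
    f <- file.path(cfg$out_dir, "flux.json")
    jsonlite::write_json(flux, f, auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest$files$flux <- f
    manifest$stages$kinetics <- list(wall = proc.time()[3] - t0,
                                     n_mfpt = nrow(mtab),
                                     censored = sum(mtab$censored))
  }

  if ("sensitivity" %in% stages) {
    t0 <- proc.time()[3]
    sen <- cfg$sensitivity
    sseed <- derive_seeds(seeds[3], length(sen$regulations))
    scans <- lapply(seq_along(sen$regulations), function(i) {
      say("stage sensitivity: %s", sen$regulations[i])
      scan_regulation(network, sen$regulations[i], scales = sen$scales,
                      t_max = sen$t_max, n_runs = sen$n_runs, seed = sseed[i],
                      thresholds = cfg$landscape$thresholds)
    })
    res$scans <- scans
    tab <- do.call(rbind, lapply(scans, `[[`, "table"))
    f <- file.path(cfg$out_dir, "sensitivity.tsv")
    write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files$sensitivity <- f
    res$ranking <- rank_regulations(scans)
    f <- file.path(cfg$out_dir, "sensitivity_ranking.json")
    jsonlite::write_json(res$ranking, f, auto_unbox = TRUE, digits = NA)
    manifest$files$sensitivity_ranking <- f
    manifest$stages$sensitivity <- list(wall = proc.time()[3] - t0)
  }

  if ("synthetic" %in% stages) {
    t0 <- proc.time()[3]
    syn <- cfg$synthetic
    # state centers from the labeled basin minima, standardized per axis
    sm <- basins$summary[basins$summary$label != "unassigned", ]
    centers <- as.matrix(sm[, cfg$simulation$axes])
    rownames(centers) <- sm$label
    colnames(centers) <- cfg$simulation$axes
    expr <- generate_expression(centers / max(centers), syn$n_per_state,
                                noise = syn$noise, seed = seeds[4])
    emb <- groupwise_pca(expr)
    cmpr <- compare_to_landscape(emb, basins)
    res$expression <- expr; res$embedding <- emb; res$comparison <- cmpr
    f <- file.path(cfg$out_dir, "expression.tsv")
    write.table(t(expr$X), f, sep = "\t", quote = FALSE)
    manifest$files$expression <- f
    f <- file.path(cfg$out_dir, "cluster_matches.tsv")
    write.table(cmpr$matches, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$files$cluster_matches <- f
    manifest$stages$synthetic <- list(wall = proc.time()[3] - t0,
                                      n_clusters = cmpr$n_clusters)
  }

  manifest$files <- lapply(manifest$files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  manifest$wall_total <- proc.time()[3] - t0_all
  jsonlite::write_json(manifest, cache_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  res$manifest <- manifest
  res$cached <- cache_ok
  class(res) <- "run_result"
  invisible(res)
}

#' @export
print.run_result <- function(x, ...) {
  if (isTRUE(x$cached) && is.null(x$basins)) {
    cat(sprintf("run_result (cached): outputs in %s\n", x$manifest$out_dir))
  } else {
    cat(sprintf("run_result: %d basins (%s); outputs in %s\n",
                nrow(x$basins$summary),
                paste(x$basins$summary$label, collapse = ", "),
                x$manifest$out_dir))
  }
  invisible(x)
}
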