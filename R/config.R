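# JSON network / run configuration. Schema documented in
# inst/extdata/config_schema.md; the shipped default network file reproduces
# the published wiring and parameters.

#' Read a network from a JSON config file
#'
#' Expected fields: `omega` (global), optional `params` overrides
#' (k, g0, lambda_a, lambda_r, h_a, h_r), `nodes` (name, kind, g0, k) and
#' `regulations` (source, target, sign, and optional m, h, f, lambda,
#' strength_scale). Unset per-regulation rates are filled from the parameter
#' set by sign.
#'
#' @param path JSON file path, or the string `"default"` for the built-in
#'   network.
#' @return A `network_spec`.
#' @export
read_network_config <- function(path) {
  if (identical(path, "default")) return(default_network())
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  pargs <- as.list(cfg$params %||% list())
  if (!is.null(cfg$omega)) pargs$omega <- cfg$omega
  params <- do.call(parameter_set, pargs)
  nodes <- lapply(seq_len(nrow(cfg$nodes)), function(i) {
    nd <- cfg$nodes[i, ]
    gene_node(nd$name, nd$kind %||% "protein",
              g0 = nd$g0 %||% params$g0, k = nd$k %||% params$k)
  })
  regs <- lapply(seq_len(nrow(cfg$regulations)), function(i) {
    rg <- cfg$regulations[i, ]
    regulation(rg$source, rg$target, rg$sign,
               m = rg$m %||% 2L, h = rg$h %||% NA_real_,
               f = rg$f %||% NA_real_, lambda = rg$lambda %||% NA_real_,
               strength_scale = rg$strength_scale %||% 1)
  })
  network_spec(nodes, regs, params)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write a network to a JSON config file
#' @param network a `network_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(network, path) {
  cfg <- list(
    omega = network$params$omega,
    params = network$params[c("k", "g0", "lambda_a", "lambda_r", "h_a", "h_r", "omega")],
    nodes = do.call(rbind, lapply(network$nodes, function(n)
      data.frame(name = n$name, kind = n$kind, g0 = n$g0, k = n$k))),
    regulations = network_table(network)[, c("source", "target", "sign", "m",
                                             "h", "f", "lambda", "strength_scale")]
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' `profile = "desk"` is the reduced budget meant to finish in minutes on one
#' CPU (basin count retained, barrier values noisier); `profile = "paper"` is
#' the headline budget (hours-scale).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param seed master seed.
#' @param out_dir output directory for [run_all()].
#' @return A nested list (`run_config`).
#' @export
run_config <- function(profile = c("desk", "paper"), seed = 1,
                       out_dir = tempfile("grnlandscape-run-")) {
  profile <- match.arg(profile)
  desk <- identical(profile, "desk")
  cfg <- list(
    profile = profile,
    network = "default",
    seed = as.integer(seed),
    out_dir = out_dir,
    simulation = list(
      t_max = if (desk) 2600 else 20000,
      n_runs = if (desk) 18 else 45,
      burn_in_frac = 0.1,
      record_every = 0,
      axes = c("P53", "ZEB", "OCT4"),
      bin_width = 5,
      dispersed_inits = TRUE
    ),
    # level cuts between the calibration's designed OFF/MID/ON expression
    # levels (see methods vignette); NULL would fall back to support tertiles
    landscape = list(smooth_bw = 1, merge_threshold = 0.5,
                     thresholds = list(P53 = c(150, 305), ZEB = c(100, 215),
                                       OCT4 = c(140, 300))),
    kinetics = list(
      delta_core = 1, n_passages = if (desk) 6 else 20,
      max_events = if (desk) 2e8 else 5e9,
      forward_routes = list(
        c("normal", "SC", "CSC", "cancer"),
        c("normal", "premalignant", "cancer"),
        c("normal", "lesion", "hyperplasia", "cancer")),
      reverse_routes = list(
        c("cancer", "CSC", "SC", "normal"),
        c("cancer", "premalignant", "normal"),
        c("cancer", "hyperplasia", "lesion", "normal"))
    ),
    sensitivity = list(
      regulations = c("miR200-|ZEB", "OCT4->OCT4", "P53->P53"),
      scales = c(0.8, 1, 1.3, 1.5),
      t_max = if (desk) 2000 else 20000,
      n_runs = if (desk) 3 else 8
    ),
    synthetic = list(n_per_state = 50, noise = 0.4)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file; missing fields fall back to the desk profile.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config(profile = user$profile %||% "desk",
                     seed = user$seed %||% 1,
                     out_dir = user$out_dir %||% tempfile("grnlandscape-run-"))
  merge_cfg <- function(b, u) {
    for (nm in names(u)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(u[[nm]]) && !is.data.frame(u[[nm]]))
        merge_cfg(b[[nm]], u[[nm]]) else u[[nm]]
    }
    b
  }
  cfg <- merge_cfg(unclass(base), as.list(user))
  class(cfg) <- c("run_config", "list")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
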