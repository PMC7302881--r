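# Configuration, structured outputs and the command-line entry point.
#
# A run is described by a nested config (YAML on disk): a command plus
# blocks for the model, mortality, grids, pool and integration controls.
# Every run writes a CSV of data rows plus a JSON sidecar echoing the fully
# resolved config, so results are reproducible from their own metadata.

default_config <- function() {
  list(
    command = "classify",
    model = list(kind = "asym_competition", d = 0.5, alpha1 = 0, alpha = 0,
                 delta = 0, alpha1p = 0),
    mortality = list(kind = "hyperbolic", s = 0, ref_density = 1),
    grid = list(x = seq(0, 1, by = 0.1), s = "canonical", s_n = 60,
                s_range = c(1e-2, 1e4)),
    pool = list(scenario = "all_asymmetries", n_species = 100, n_pools = 500,
                comp_range = NULL, ri_range = NULL, delta_range = c(0, 1),
                symmetric_alpha = NULL, d = 0.5, pdd_fraction = 1),
    sim = list(s_values = c(0, 1, 100, 1e4), intro_density = 1e-2),
    controls = list(extinction_threshold = 1e-3, window_length = 1000,
                    max_time = 1e6, conv_tol = 1e-9, rtol = 1e-10,
                    atol = 1e-12),
    seed = 1L,
    out_prefix = "cpdd_run",
    verbosity = 1L
  )
}

#' Read a run configuration
#'
#' Reads a YAML config file and merges it over the documented defaults.
#' Unknown top-level fields are rejected; parameter ranges are validated
#' before any computation starts.
#'
#' @param path path to a YAML file, or a named list to validate directly.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(cfg)
}

merge_block <- function(defaults, user, block) {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop(sprintf("unknown field(s) in config block '%s': %s", block,
                 paste(extra, collapse = ", ")), call. = FALSE)
  modifyList(defaults, user)
}

validate_config <- function(cfg) {
  def <- default_config()
  extra <- setdiff(names(cfg), names(def))
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  out <- def
  for (nm in c("model", "mortality", "grid", "pool", "sim", "controls"))
    out[[nm]] <- merge_block(def[[nm]], cfg[[nm]], nm)
  for (nm in c("command", "seed", "out_prefix", "verbosity"))
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  out$command <- match.arg(out$command,
                           c("classify", "scan", "threshold", "richness",
                             "assembly"))
  for (nm in c("d", "alpha1", "alpha", "delta", "alpha1p"))
    check_unit_interval(out$model[[nm]], paste0("model$", nm))
  if (out$mortality$s < 0) stop("mortality s must be >= 0", call. = FALSE)
  if (!out$mortality$kind %in% mortality_kinds())
    stop("unknown mortality kind: ", out$mortality$kind, call. = FALSE)
  out
}

config_mortality <- function(cfg) {
  mortality_spec(cfg$mortality$kind, cfg$mortality$s,
                 cfg$mortality$ref_density)
}

config_two_species <- function(cfg) {
  m <- cfg$model
  args <- list(model = m$kind, d = m$d, mortality = config_mortality(cfg))
  args[[.asymmetry_param[[m$kind]]]] <- m[[.asymmetry_param[[m$kind]]]]
  if (m$kind != "asym_competition") args$alpha <- m$alpha
  do.call(two_species_params, args)
}

config_pool <- function(cfg) {
  p <- cfg$pool
  args <- list(scenario = p$scenario, n_species = p$n_species,
               delta_range = p$delta_range, d = p$d,
               pdd_fraction = p$pdd_fraction,
               mortality_kind = cfg$mortality$kind, seed = cfg$seed)
  if (!is.null(p$comp_range)) args$comp_range <- p$comp_range
  if (!is.null(p$ri_range)) args$ri_range <- p$ri_range
  if (!is.null(p$symmetric_alpha)) args$symmetric_alpha <- p$symmetric_alpha
  do.call(pool_config, args)
}

config_s_grid <- function(cfg) {
  g <- cfg$grid
  if (identical(g$s, "canonical")) canonical_s_grid(g$s_n, g$s_range)
  else as.numeric(g$s)
}

config_controls <- function(cfg) do.call(sim_controls, cfg$controls)

# Data rows are printed with 12 significant digits, '.' decimal, so output
# files are byte-stable across runs.
format_records <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA, sprintf("%.12g", df[[nm]]))
  }
  df
}

#' Write / read record tables
#'
#' CSV writer and reader used for all tabular outputs. Numeric columns are
#' printed with 12 significant digits so identical runs give byte-identical
#' files; [read_records()] restores the numeric types.
#'
#' @param df data frame of records.
#' @param path output path.
#' @export
write_records <- function(df, path) {
  write.csv(format_records(df), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) if (is.logical(df[[nm]])) df[[nm]] <- df[[nm]]
  df
}

write_sidecar <- function(cfg, path, extra = list()) {
  meta <- c(list(config = cfg,
                 package = "cpdd",
                 version = as.character(utils::packageVersion("cpdd"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a configured pipeline command
#'
#' Dispatches on `config$command`:
#' \describe{
#'   \item{classify}{one tristate classification; writes a JSON record with
#'     the label, equilibria, eigenvalues and residuals.}
#'   \item{scan}{a full (asymmetry, s) plane; writes CSV rows `x_name,
#'     x_value, s, class, n1_star, n2_star, inconclusive_flag`.}
#'   \item{threshold}{class-change values of s at the configured asymmetry
#'     value; writes CSV `s, from, to`.}
#'   \item{richness}{simultaneous-start multispecies experiment; CSV
#'     `pool_id, seed, scenario, s, final_richness, converged, stable`.}
#'   \item{assembly}{sequential-introduction experiment; same columns.}
#' }
#' Every command also writes a JSON sidecar with the resolved config.
#'
#' @param config a config list or path to a YAML file (see [read_config()]).
#' @param out_dir directory for output files.
#' @return the primary result object, invisibly.
#' @export
run_command <- function(config, out_dir = ".") {
  cfg <- read_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- file.path(out_dir, paste0(cfg$out_prefix, "_", cfg$command))
  log_info <- function(...) if (cfg$verbosity > 0) message(sprintf(...))

  result <- switch(cfg$command,
    classify = {
      cl <- classify_coexistence(config_two_species(cfg))
      rec <- list(
        label = cl$label, inconclusive = cl$inconclusive,
        reason = if (is.null(cl$reason)) NA else cl$reason,
        equilibria = lapply(cl$equilibria, function(r)
          list(location = r$location, residual = r$residual,
               feasible = r$feasible, eig_real_parts = r$eig_real_parts,
               locally_stable = r$locally_stable)))
      jsonlite::write_json(rec, paste0(stem, ".json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      log_info("classify: %s%s", cl$label,
               if (cl$inconclusive) " (inconclusive)" else "")
      cl
    },
    scan = {
      fixed <- list(d = cfg$model$d, alpha = cfg$model$alpha,
                    mortality_kind = cfg$mortality$kind)
      sc <- scan_plane(cfg$model$kind, as.numeric(cfg$grid$x),
                       config_s_grid(cfg), fixed_params = fixed)
      write_records(as.data.frame(sc), paste0(stem, ".csv"))
      if (any(sc$inconclusive))
        warning(sum(sc$inconclusive), " inconclusive cell(s) in scan",
                call. = FALSE)
      sc
    },
    threshold = {
      x_val <- cfg$model[[.asymmetry_param[[cfg$model$kind]]]]
      fixed <- list(d = cfg$model$d, alpha = cfg$model$alpha,
                    mortality_kind = cfg$mortality$kind)
      th <- find_s_threshold(cfg$model$kind, fixed, x_val,
                             s_grid = config_s_grid(cfg))
      write_records(th, paste0(stem, ".csv"))
      th
    },
    richness = {
      df <- richness_experiment(config_pool(cfg), cfg$pool$n_pools,
                                cfg$sim$s_values, config_controls(cfg))
      if (any(!df$converged))
        warning(sum(!df$converged), " non-converged simulation(s)",
                call. = FALSE)
      write_records(df, paste0(stem, ".csv"))
      df
    },
    assembly = {
      df <- assembly_experiment(config_pool(cfg), cfg$pool$n_pools,
                                cfg$sim$s_values,
                                intro_density = cfg$sim$intro_density,
                                controls = config_controls(cfg))
      write_records(df, paste0(stem, ".csv"))
      df
    })
  write_sidecar(cfg, paste0(stem, "_meta.json"))
  invisible(result)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/cli/cpdd` script:
#' `cpdd <command> [--config file.yaml] [flag overrides]`. Flags mirror the
#' config schema (`--model`, `--d`, `--alpha1`, `--alpha`, `--delta`,
#' `--alpha1p`, `--mortality`, `--s`, `--scenario`, `--species`, `--pools`,
#' `--seed`, `--out-dir`, `--out-prefix`).
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cpdd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: cpdd {classify|scan|threshold|richness|assembly} [options]")
    return(invisible(1L))
  }
  command <- args[[1L]]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--model", type = "character", default = NULL),
    optparse::make_option("--d", type = "double", default = NULL),
    optparse::make_option("--alpha1", type = "double", default = NULL),
    optparse::make_option("--alpha", type = "double", default = NULL),
    optparse::make_option("--delta", type = "double", default = NULL),
    optparse::make_option("--alpha1p", type = "double", default = NULL),
    optparse::make_option("--mortality", type = "character", default = NULL),
    optparse::make_option("--s", type = "double", default = NULL),
    optparse::make_option("--scenario", type = "character", default = NULL),
    optparse::make_option("--species", type = "integer", default = NULL),
    optparse::make_option("--pools", type = "integer", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "."),
    optparse::make_option("--out-prefix", dest = "out_prefix",
                          type = "character", default = NULL)))
  opt <- optparse::parse_args(parser, args = args[-1L])

  cfg <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  cfg$command <- command
  set_in <- function(cfg, block, field, value) {
    if (is.null(value)) return(cfg)
    if (is.null(cfg[[block]])) cfg[[block]] <- list()
    cfg[[block]][[field]] <- value
    cfg
  }
  cfg <- set_in(cfg, "model", "kind", opt$model)
  for (f in c("d", "alpha1", "alpha", "delta", "alpha1p"))
    cfg <- set_in(cfg, "model", f, opt[[f]])
  cfg <- set_in(cfg, "mortality", "kind",
                if (is.null(opt$mortality)) NULL else
                  c(hyperbolic = "hyperbolic", exponential = "exponential",
                    linear = "linear",
                    control = "density-independent-control")[[opt$mortality]])
  cfg <- set_in(cfg, "mortality", "s", opt$s)
  cfg <- set_in(cfg, "pool", "scenario", opt$scenario)
  cfg <- set_in(cfg, "pool", "n_species", opt$species)
  cfg <- set_in(cfg, "pool", "n_pools", opt$pools)
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$out_prefix)) cfg$out_prefix <- opt$out_prefix

  status <- tryCatch({
    run_command(cfg, out_dir = opt$out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
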