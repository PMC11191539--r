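#' Default run configuration
#'
#' Flat configuration for the end-to-end pipeline: all model parameters
#' (see [nm_params()]), the connectome source (surrogate spec or a file
#' path), run layout, bands, measures, and analysis options. Serializes to
#' strict-schema JSON via [save_config()] / [load_config()].
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  p <- nm_params()
  cfg <- list(
    # model (published initial values)
    fs = p$fs, epoch_len = p$epoch_len, transient_len = p$transient_len,
    Pt = p$Pt, noiselevel = p$noiselevel, sigma0 = p$sigma0,
    Amp1 = p$Amp1, Amp2 = p$Amp2, a1 = p$a1, b1 = p$b1, a2 = p$a2,
    b2 = p$b2, g = p$g, q = p$q, Vd1 = p$Vd1, Vd2 = p$Vd2,
    C1 = p$C1, C2 = p$C2, S = p$S,
    # degeneration calibration
    d = p$d, kappa = p$kappa, add_literal = p$add_literal,
    substeps = p$substeps, psp_normalize = p$psp_normalize,
    strength_floor = p$strength_floor,
    # connectome: a file path, or surrogate spec
    adjacency_path = "", surrogate_n = 78L, surrogate_density = 0.10,
    surrogate_model = "modular", surrogate_modules = 5L,
    # run layout
    n_epochs = 10L, n_runs = 1L, seed = 1L, add_enabled = TRUE,
    # analysis
    measures = c("AECc", "PLI", "JPE", "PLT", "rel_theta"),
    bands = c("delta", "theta", "alpha", "beta"),
    n_perm = 5000L, fdr_q = 0.05, trim = 0.01,
    plt_boundary = "truncated", jpe_n = 4L, jpe_tau = 1L,
    jpe_literal = FALSE,
    write_rates = TRUE)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save / load a run configuration (strict JSON)
#'
#' @param cfg a configuration list.
#' @param path JSON file path.
#' @return `load_config` returns the validated configuration;
#'   `save_config` returns `path` invisibly. Unknown keys are errors.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(raw)
  cfg <- default_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  cfg$measures <- as.character(cfg$measures)
  cfg$bands <- as.character(cfg$bands)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num_pos <- c("fs", "epoch_len", "transient_len", "n_epochs", "n_runs")
  for (k in intersect(num_pos, names(cfg)))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config field '", k, "' must be a positive number")
  if (!is.null(cfg$surrogate_density) &&
      (cfg$surrogate_density <= 0 || cfg$surrogate_density > 1))
    stop("config field 'surrogate_density' must be in (0, 1]")
  bad <- setdiff(cfg$bands, names(c(default_bands(), spectral_bands())))
  if (length(bad) > 0L)
    stop("config field 'bands' has unknown band(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# materialize nm_params and network from a config
config_params <- function(cfg) {
  nm_params(fs = cfg$fs, epoch_len = cfg$epoch_len,
            transient_len = cfg$transient_len, Pt = cfg$Pt,
            noiselevel = cfg$noiselevel, sigma0 = cfg$sigma0,
            Amp1 = cfg$Amp1, Amp2 = cfg$Amp2, a1 = cfg$a1, b1 = cfg$b1,
            a2 = cfg$a2, b2 = cfg$b2, g = cfg$g, q = cfg$q, Vd1 = cfg$Vd1,
            Vd2 = cfg$Vd2, C1 = cfg$C1, C2 = cfg$C2, S = cfg$S, d = cfg$d,
            kappa = cfg$kappa, add_literal = cfg$add_literal,
            substeps = cfg$substeps, psp_normalize = cfg$psp_normalize,
            strength_floor = cfg$strength_floor)
}

config_network <- function(cfg) {
  if (nzchar(cfg$adjacency_path)) load_adjacency(cfg$adjacency_path)
  else generate_surrogate(cfg$surrogate_n, cfg$surrogate_density,
                          cfg$surrogate_model, seed = cfg$seed,
                          n_modules = cfg$surrogate_modules)
}

config_bands <- function(cfg) {
  all <- c(default_bands(), spectral_bands())
  all[!duplicated(names(all))][cfg$bands]
}
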