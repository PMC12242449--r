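# End-to-end orchestration: configuration, tracked-series file I/O, and the
# quantify -> shape space -> model fit pipeline with reproducible outputs.

tracked_columns <- c("axoneme_id", "condition", "frame", "point_index",
                     "x_um", "y_um")

#' Pipeline configuration
#'
#' Builds a validated configuration with documented defaults. Unknown keys
#' are rejected. Can also be populated from a YAML file whose top-level keys
#' match the argument names.
#'
#' @param input_dir directory with `tracked.csv` (+ optional
#'   `manifest.csv`); `NULL` generates a synthetic dataset instead.
#' @param out_dir output directory for tables and the run log.
#' @param kappa,xi_n material constants (pN um^2, pN s um^-2).
#' @param ficoll_factors named friction multipliers for viscous media.
#' @param acquisition an [acquisition_spec()] used when synthesizing.
#' @param conditions list of [condition_spec()]s used when synthesizing;
#'   defaults to [default_conditions()].
#' @param fit whether to run the model-fitting stage.
#' @param optimizer list with `tol` and `maxeval` for [fit_axoneme()].
#' @param seed integer seed for dataset generation.
#' @param file YAML file to read values from (arguments override it).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "ciliabeat_run",
                            kappa = 580, xi_n = 0.0049,
                            ficoll_factors = c("1%" = 1.1, "5%" = 1.6,
                                               "10%" = 3.2),
                            acquisition = acquisition_spec(n_frames = 512),
                            conditions = default_conditions(),
                            fit = TRUE,
                            optimizer = list(tol = 1e-6, maxeval = 2000L),
                            seed = 1L, file = NULL) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, kappa = kappa,
              xi_n = xi_n, ficoll_factors = ficoll_factors,
              acquisition = acquisition, conditions = conditions, fit = fit,
              optimizer = optimizer, seed = as.integer(seed))
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    bad <- setdiff(names(y), names(cfg))
    if (length(bad) > 0)
      stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    supplied <- names(as.list(match.call()))[-1]
    for (nm in setdiff(names(y), supplied)) {
      if (nm == "acquisition") cfg[[nm]] <- do.call(acquisition_spec, y[[nm]])
      else cfg[[nm]] <- y[[nm]]
    }
  }
  stopifnot_scalar(kappa = cfg$kappa, xi_n = cfg$xi_n, positive = TRUE)
  stopifnot(inherits(cfg$acquisition, "acquisition_spec"))
  structure(cfg, class = "pipeline_config")
}

#' Read a tracked-series file
#'
#' Reads the comma-separated tracked format (columns `axoneme_id`,
#' `condition`, `frame`, `point_index`, `x_um`, `y_um`; frames and points
#' 0-based, points ordered base to tip), validates per-axoneme structure
#' (constant point count, contiguous frames) and returns one
#' `tracked_series` per axoneme. `write_tracked()` is its inverse;
#' write-then-read restores identical coordinate values.
#'
#' @param file path of the tracked CSV.
#' @param fps frame rate (Hz) of the recordings; per-axoneme values can be
#'   supplied through `manifest`.
#' @param viscosity_factor friction multiplier; per-axoneme values can be
#'   supplied through `manifest`.
#' @param manifest optional manifest data.frame (or CSV path) with columns
#'   `axoneme_id` and optionally `fps`, `viscosity_factor`.
#' @return named list of `tracked_series`.
#' @export
read_tracked <- function(file, fps = 1000, viscosity_factor = 1,
                         manifest = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(tracked_columns, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)

  out <- list()
  for (id in unique(df$axoneme_id)) {
    sub <- df[df$axoneme_id == id, ]
    frames <- sort(unique(sub$frame))
    if (!identical(as.integer(frames),
                   seq.int(0L, length(frames) - 1L)))
      stop(sprintf("axoneme '%s': non-contiguous frames (missing frame %d)",
                   id, setdiff(seq.int(0L, max(frames)), frames)[1]))
    counts <- table(sub$frame)
    if (length(unique(counts)) != 1L)
      stop(sprintf("axoneme '%s': point count varies between frames", id))
    n_pts <- as.integer(counts[1])
    sub <- sub[order(sub$frame, sub$point_index), ]
    xy <- array(NA_real_, dim = c(length(frames), n_pts, 2L))
    xy[, , 1L] <- matrix(sub$x_um, ncol = n_pts, byrow = TRUE)
    xy[, , 2L] <- matrix(sub$y_um, ncol = n_pts, byrow = TRUE)
    fps_i <- fps; visc_i <- viscosity_factor
    if (!is.null(manifest)) {
      row <- manifest[manifest$axoneme_id == id, , drop = FALSE]
      if (nrow(row) == 1L) {
        if (!is.null(row$fps)) fps_i <- row$fps
        if (!is.null(row$viscosity_factor)) visc_i <- row$viscosity_factor
      }
    }
    out[[id]] <- structure(
      list(axoneme_id = id, condition = sub$condition[1L], fps = fps_i,
           viscosity_factor = visc_i, xy = xy),
      class = "tracked_series")
  }
  out
}

#' @rdname read_tracked
#' @param series list of `tracked_series` (or a single one).
#' @export
write_tracked <- function(series, file) {
  if (inherits(series, "tracked_series")) series <- list(series)
  rows <- lapply(series, function(sr) {
    d <- dim(sr$xy)
    data.frame(axoneme_id = sr$axoneme_id, condition = sr$condition,
               frame = rep(seq_len(d[1]) - 1L, each = d[2]),
               point_index = rep(seq_len(d[2]) - 1L, times = d[1]),
               x_um = as.vector(t(sr$xy[, , 1L])),
               y_um = as.vector(t(sr$xy[, , 2L])))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: load (or synthesize) tracked series, quantify each
#' into its fundamental mode, build the behavioural-space table, optionally
#' fit the mechanochemical model, and write all tables plus a run log with
#' seed and configuration echo to `config$out_dir`. Per-axoneme failures are
#' logged and flagged; the pipeline aborts only when no axoneme is usable.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `modes`, `features` (behavioural table),
#'   `fits` (or `NULL`), and `summary` (variance components of frequency and
#'   amplitude, variance explained, PCA correlations, lambda/L statistics,
#'   fraction of fits with R^2 > 0.9).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("ciliabeat %s",
                         as.character(utils::packageVersion("ciliabeat"))),
                 sprintf("started: %s", format(Sys.time())),
                 sprintf("seed: %d", config$seed),
                 sprintf("config hash: %s", config_hash(config)))

  if (is.null(config$input_dir)) {
    acq <- config$acquisition
    acq$seed <- config$seed
    ds <- generate_dataset(config$conditions, acq)
    series <- ds$series
    log_lines <- c(log_lines, sprintf("synthesized %d axonemes (%d conditions)",
                                      length(series),
                                      length(config$conditions)))
  } else {
    tracked_file <- file.path(config$input_dir, "tracked.csv")
    manifest_file <- file.path(config$input_dir, "manifest.csv")
    series <- read_tracked(tracked_file,
                           manifest = if (file.exists(manifest_file))
                             manifest_file else NULL)
    log_lines <- c(log_lines, sprintf("read %d axonemes from %s",
                                      length(series), tracked_file))
  }
  if (length(series) == 0) stop("no usable axonemes: empty input")

  modes <- list()
  for (id in names(series)) {
    m <- tryCatch(fundamental_mode(tangent_field(series[[id]])),
                  error = function(e) e)
    if (inherits(m, "error")) {
      log_lines <- c(log_lines, sprintf("FAILED quantify %s: %s", id,
                                        conditionMessage(m)))
    } else modes[[id]] <- m
  }
  if (length(modes) == 0) stop("no usable axonemes: all quantifications failed")

  features <- shape_table(modes)
  profiles <- do.call(rbind, lapply(modes, function(m) m$a / mean(m$a)))

  try_stat <- function(expr) tryCatch(expr, error = function(e) {
    log_lines <<- c(log_lines, sprintf("summary statistic skipped: %s",
                                       conditionMessage(e)))
    NULL
  })
  smry <- list(
    n_axonemes = length(modes),
    freq_variance = try_stat(
      variance_components(features$f_Hz, features$condition)),
    amp_variance = try_stat(
      variance_components(features$a0_rad, features$condition)),
    variance_explained_amplitude = try_stat(variance_explained(profiles)),
    lam_over_L = c(mean = mean(features$lam_over_L),
                   sd = stats::sd(features$lam_over_L)),
    envelope = energetics_envelope(features)[c("A_elastic", "A_viscous")])
  if (nrow(features) >= 3L)
    smry$pca_correlations <- try_stat(pca_correlations(features, profiles))

  fits <- NULL
  if (isTRUE(config$fit)) {
    fits <- fit_dataset(modes, kappa = config$kappa, xi_n = config$xi_n,
                        tol = config$optimizer$tol,
                        maxeval = config$optimizer$maxeval)
    smry$fraction_r2_above_0.9 <- fits$summary$fraction_r2_above_0.9
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(fits))
    utils::write.csv(fits$results, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
  yaml::write_yaml(summary_for_yaml(smry),
                   file.path(config$out_dir, "summary.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(modes = modes, features = features, fits = fits,
                 summary = smry))
}

# cheap deterministic hash of the configuration for the run log
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * seq_along(v)) %% 4294967291)
}

summary_for_yaml <- function(s) {
  rapply(s, function(x) {
    if (is.function(x)) NULL
    else if (is.matrix(x)) as.list(as.data.frame(x))
    else x
  }, how = "replace")
}
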