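#' Run configuration defaults
#'
#' Structured key-value configuration (YAML) shared by the
#' command-line subcommands: calibration defaults, segmentation
#' defaults, PDE defaults, RNG seed, output directory and verbosity.
#' Unknown keys anywhere in the file are rejected rather than ignored,
#' so a typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML config file, or `NULL` for the built-in
#'   defaults.
#' @return An object of class `"run_config"`: nested list with
#'   sections `calibration` (pixel_size, frame_interval, z_step),
#'   `segmentation` (method, min_object_px), `pde` (D, v_umin,
#'   fraction, dx), plus `seed`, `out_dir`, `verbose`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("read_run_config: no such file '%s'", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user, "")
  }
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    calibration = list(pixel_size = 1, frame_interval = 1, z_step = 3),
    segmentation = list(method = "otsu", min_object_px = 9L),
    pde = list(D = 0.228, v_umin = 6.36, fraction = 0.01, dx = 1),
    seed = 1L,
    out_dir = ".",
    verbose = FALSE
  )
}

.merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base))
      stop(sprintf("read_run_config: unknown key '%s'", full), call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("read_run_config: '%s' must be a mapping", full),
             call. = FALSE)
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  cc <- cfg$calibration
  if (any(unlist(cc[c("pixel_size", "frame_interval", "z_step")]) <= 0))
    stop("read_run_config: calibration values must be positive", call. = FALSE)
  if (!cfg$segmentation$method %in% c("otsu", "fixed"))
    stop("read_run_config: segmentation.method must be 'otsu' or 'fixed'",
         call. = FALSE)
  if (cfg$pde$D < 0 || cfg$pde$dx <= 0 ||
      cfg$pde$fraction <= 0 || cfg$pde$fraction >= 1)
    stop("read_run_config: invalid pde defaults", call. = FALSE)
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
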