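# Pipeline configuration: one nested list with per-module sections.

.default_config <- function() {
  list(
    denoise = list(levels = 4L, beta_threshold = 0, max_iter = 30L,
                   tol = 1e-6),
    segmentation = list(r = 0.05, window_ms = 30, min_segment_ms = 100),
    integration = list(highpass_hz = 0.1, detrend_levels = 8L,
                       detrend_basis = "sym8",
                       soft_threshold_mode = "ca_only"),
    events = list(slope_window_ms = 50, drop_slope_thresh = 0.05,
                  rise_slope_thresh = 0.05, search_margin_ms = 120),
    generator = unclass(gait_params()),
    seed = 1L)
}

.check_config <- function(config) {
  def <- .default_config()
  extra <- setdiff(names(config), names(def))
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad)) {
        stop("unknown config key(s) in section '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  with(config$segmentation, {
    if (r <= 0 || r >= 1) stop("segmentation$r must be in (0, 1)",
                               call. = FALSE)
    if (window_ms <= 0) stop("segmentation$window_ms must be > 0",
                             call. = FALSE)
    if (min_segment_ms < 0) stop("segmentation$min_segment_ms must be >= 0",
                                 call. = FALSE)
  })
  if (config$integration$highpass_hz < 0) {
    stop("integration$highpass_hz must be >= 0", call. = FALSE)
  }
  if (!config$integration$detrend_basis %in% names(.wt_dec_lo)) {
    stop("integration$detrend_basis must be one of: ",
         paste(names(.wt_dec_lo), collapse = ", "), call. = FALSE)
  }
  if (!config$integration$soft_threshold_mode %in%
        c("ca_only", "ca_and_details")) {
    stop("integration$soft_threshold_mode must be 'ca_only' or 'ca_and_details'",
         call. = FALSE)
  }
  if (config$denoise$levels < 2) stop("denoise$levels must be >= 2",
                                      call. = FALSE)
  invisible(config)
}

# Recursive merge of user values over defaults.
.merge_config <- function(def, user) {
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && is.list(user[[nm]])) {
      def[[nm]] <- .merge_config(def[[nm]], user[[nm]])
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

#' Pipeline configuration
#'
#' Builds the full configuration list with per-module sections (`denoise`,
#' `segmentation`, `integration`, `events`, `generator`, `seed`). Arguments
#' override defaults; unknown keys are rejected.
#'
#' @param ... named sections (or `seed = `) overriding the defaults, e.g.
#'   `gait_config(segmentation = list(r = 0.1))`.
#' @return a validated configuration list of class `gait_config`.
#' @export
gait_config <- function(...) {
  user <- list(...)
  cfg <- .merge_config(.default_config(), user)
  # surface unknown top-level keys before deep checks
  .check_config(cfg[intersect(names(cfg), names(.default_config()))])
  extra <- setdiff(names(user), names(.default_config()))
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = c("gait_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any subset of the sections of [gait_config()];
#' missing values take their defaults and unknown keys raise an error naming
#' the key.
#'
#' @param path YAML file path.
#' @return a validated configuration list.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(gait_config, user)
}
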