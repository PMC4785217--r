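#' Write a run configuration to YAML
#'
#' Serializes every sub-configuration (schedule, betting policy, amplitude
#' model, luck model, preprocessing) plus cohort size, master seed and
#' mode, so a study is fully specified by one file.
#'
#' @param rc A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config_yaml <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config serialization",
         call. = FALSE)
  strip <- function(x) lapply(unclass(x), function(v) v)
  yaml::write_yaml(list(
    schedule = strip(rc$schedule),
    policy = strip(rc$policy),
    amplitude = strip(rc$amplitude),
    luck = strip(rc$luck),
    preprocess = strip(rc$preprocess),
    n_participants = rc$n_participants,
    master_seed = rc$master_seed,
    mode = rc$mode
  ), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Inverse of [write_run_config_yaml()]; every field is re-validated by
#' the corresponding constructor.
#'
#' @param path Path to a YAML file written by [write_run_config_yaml()].
#' @return A [run_config()].
#' @export
read_run_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config serialization",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  build <- function(ctor, x) do.call(ctor, x[names(x) %in% names(formals(ctor))])
  run_config(
    schedule = build(schedule_config, y$schedule),
    policy = build(bet_policy, y$policy),
    amplitude = build(amplitude_model, y$amplitude),
    luck = build(luck_params, y$luck),
    preprocess = build(preprocess_config, y$preprocess),
    n_participants = y$n_participants,
    master_seed = y$master_seed,
    mode = y$mode
  )
}
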