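#' Default configuration tree
#'
#' The full set of tunable parameters as a nested list, mirroring the YAML
#' layout accepted by [read_config()]: blocks `fixtures`, `augment`,
#' `morphology`, `schedule` (with `lambda1`, `lambda2`, `lambda3`, each
#' holding `s`, `e`, `t1`, `t2`), `network` and `train`.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  sch <- default_schedules()
  list(
    fixtures = unclass(synthetic_spec()),
    augment = unclass(augment_params()),
    morphology = unclass(morph_params()),
    schedule = lapply(sch, unclass),
    network = unclass(network_config()),
    train = list(epochs = 110L, batch_size = 16L, learning_rate = 1e-4,
                 optimizer_name = "adam", rng_seed = 1L,
                 checkpoint_every = 0L)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Reads a YAML file whose blocks override entries of [default_config()];
#' missing entries keep their defaults. Returns the resolved tree together
#' with constructed parameter objects ready to pass to the training and
#' inference functions.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return List with the raw resolved `config` plus `augment_params`,
#'   `morph_params`, `network_config`, `schedules`, `train_config`,
#'   `synthetic_spec`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  sch <- lapply(cfg$schedule, function(s) {
    schedule_config(s$s, s$e, s$t1, s$t2)
  })
  list(
    config = cfg,
    synthetic_spec = do.call(synthetic_spec, cfg$fixtures),
    augment_params = do.call(augment_params, cfg$augment),
    morph_params = do.call(morph_params, cfg$morphology),
    network_config = do.call(network_config, cfg$network),
    schedules = sch,
    train_config = train_config(
      epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
      learning_rate = cfg$train$learning_rate,
      optimizer_name = cfg$train$optimizer_name,
      rng_seed = cfg$train$rng_seed, schedules = sch,
      checkpoint_every = cfg$train$checkpoint_every)
  )
}
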