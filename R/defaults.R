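#' Shipped default parameter sets
#'
#' The default configuration reproduces the published aggregate tables at
#' desk scale. Population conditionals are synthetic stand-ins for the
#' registry-derived joint distributions; hazard parameters and the
#' other-cause life table were calibrated in-repo to the printed outcome
#' tables (see each file's `generated_by`/provenance block and the methods
#' vignette) and must not be mistaken for externally estimated inputs.
#'
#' @return the corresponding parameter object.
#' @name defaults
NULL

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "bcmicrosim")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("missing shipped config: ", file, call. = FALSE)
  p
}

#' @rdname defaults
#' @export
default_population_params <- function() {
  load_population_params(extdata_path("population_params.json"))
}

#' @rdname defaults
#' @export
default_hazard_model <- function() {
  load_hazard_model(extdata_path("hazard_model.json"))
}

#' @rdname defaults
#' @export
default_life_table <- function() {
  load_life_table(extdata_path("life_table_synthetic.csv"))
}

#' @rdname defaults
#' @export
default_utility_schedule <- function() {
  load_utility_schedule(extdata_path("utilities.json"))
}

#' @rdname defaults
#' @export
default_calibration_targets <- function() {
  load_calibration_targets(extdata_path("calibration_targets.json"))
}

#' @rdname defaults
#' @export
default_trial_settings <- function() {
  x <- jsonlite::read_json(extdata_path("trial_settings.json"),
                           simplifyVector = TRUE)
  x$chemo_effect <- lapply(x$chemo_effect, as.numeric)
  x
}
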