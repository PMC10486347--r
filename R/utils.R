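# Internal helpers shared across modules.

#' Run code with a temporarily fixed RNG state
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' seeded model fits never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a per-stage seed from one global seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

#' The eight texture profile analysis indicators
#'
#' Indicator vocabulary used throughout: gumminess, springiness, cohesiveness,
#' resilience, hardness, brittleness, adhesiveness, chewiness.
#' @return Character vector of length 8.
#' @export
texture_indicators <- function() {
  c("gumminess", "springiness", "cohesiveness", "resilience",
    "hardness", "brittleness", "adhesiveness", "chewiness")
}

#' The four skin/muscle regions
#'
#' @return Character vector: dorsal, pectoral, abdominal, gluteal.
#' @export
muscle_regions <- function() {
  c("dorsal", "pectoral", "abdominal", "gluteal")
}

assert_region <- function(region) {
  if (!is.character(region) || length(region) != 1 ||
      !(region %in% muscle_regions())) {
    stop("unknown region '", paste(region, collapse = ","),
         "'; must be one of: ", paste(muscle_regions(), collapse = ", "),
         call. = FALSE)
  }
  region
}

#' Default band grid
#'
#' Evenly spaced band centres on the half-open interval \[400, 1000) nm.
#' With the default 600 bands this is 400, 401, ..., 999 nm.
#'
#' @param n_bands Number of bands (default 600).
#' @param range Wavelength range in nm.
#' @return Numeric vector of band-centre wavelengths.
#' @export
default_band_grid <- function(n_bands = 600, range = c(400, 1000)) {
  stopifnot(n_bands >= 1, length(range) == 2, range[2] > range[1])
  range[1] + (seq_len(n_bands) - 1) * (range[2] - range[1]) / n_bands
}
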