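# Psychometric scale registry: admissible score range and the affine map
# from latent stress to expected score. The STAI-S slope is anchored so that
# latent 1 sits at the lower acute-stress cutpoint (34) and latent ~1.71 at
# the upper one (44), keeping the latent scale interpretable against the
# published 34/44 critical points. Other scales use their conventional index
# ranges with slopes of comparable relative steepness.
SCALE_REGISTRY <- list(
  STAIS = list(min = 20, max = 80, slope = 14),
  SCL90 = list(min = 90, max = 450, slope = 84),
  SDS = list(min = 25, max = 100, slope = 18),
  SAS = list(min = 25, max = 100, slope = 18)
)

#' Generate a psychometric scale score from latent stress
#'
#' Maps a non-negative latent stress level through a scale-specific affine
#' function (`score = min + slope * latent`), adds Gaussian noise, and clips
#' to the scale's admissible range. Supported scales: STAI-S (state
#' anxiety), SCL-90, SDS and SAS.
#'
#' @param latent_stress Non-negative latent stress level(s), dimensionless.
#' @param kind One of `"STAIS"`, `"SCL90"`, `"SDS"`, `"SAS"`.
#' @param noise_sd Noise sd in score units.
#' @param seed Integer seed (or `NULL`).
#' @return Numeric score vector, same length as `latent_stress`.
#' @export
#' @examples
#' generate_scale_scores(c(0, 1, 2), "STAIS", noise_sd = 0)
generate_scale_scores <- function(latent_stress, kind = c("STAIS", "SCL90", "SDS", "SAS"),
                                  noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  check_numeric_vector(latent_stress, "latent_stress", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  sc <- SCALE_REGISTRY[[kind]]
  score <- sc$min + sc$slope * latent_stress
  if (noise_sd > 0) {
    score <- score + with_seed_or_current(seed, rnorm(length(score), sd = noise_sd))
  }
  pmin(pmax(score, sc$min), sc$max)
}

#' Admissible range of a psychometric scale
#'
#' @param kind Scale name as in [generate_scale_scores()].
#' @return Length-2 numeric vector `c(min, max)`.
#' @export
scale_range <- function(kind = c("STAIS", "SCL90", "SDS", "SAS")) {
  kind <- match.arg(kind)
  sc <- SCALE_REGISTRY[[kind]]
  c(sc$min, sc$max)
}
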