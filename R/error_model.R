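ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B")

#' Argos location-class error model
#'
#' Bundles the per-class probability and isotropic error standard
#' deviation (metres) used both when simulating observations and as the
#' measurement-noise model for track estimation. Classes 3/2/1 carry an
#' error radius of at most 1500 m, class 0 a larger radius, and classes
#' A/B no radius at all; the defaults reproduce the observed class
#' composition of the study system (22.1% classes 1-3, 18.5% class 0,
#' 59.4% classes A/B) with the 22.1% split evenly over classes 3, 2, 1.
#' Nominal radii are treated as 1-sigma values of a zero-mean isotropic
#' Gaussian; classes A/B default to 5 and 10 km following Argos
#' conventions.
#'
#' @param class_probs named probability vector over classes 3,2,1,0,A,B;
#'   must sum to 1.
#' @param class_sd_m named positive vector of per-class error sd (metres).
#' @param outlier_prob probability that a fix is a gross outlier.
#' @param outlier_sd_m isotropic sd of gross outliers (metres).
#' @return an object of class `argos_error_model`.
#' @export
argos_error_model <- function(class_probs = c("3" = 0.221 / 3,
                                              "2" = 0.221 / 3,
                                              "1" = 0.221 / 3,
                                              "0" = 0.185,
                                              "A" = 0.594 / 2,
                                              "B" = 0.594 / 2),
                              class_sd_m = c("3" = 250, "2" = 500,
                                             "1" = 1500, "0" = 3000,
                                             "A" = 5000, "B" = 10000),
                              outlier_prob = 0,
                              outlier_sd_m = 2e5) {
  class_probs <- class_probs[ARGOS_CLASSES]
  class_sd_m <- class_sd_m[ARGOS_CLASSES]
  if (anyNA(class_probs) || anyNA(class_sd_m))
    stop("class_probs and class_sd_m must cover classes 3,2,1,0,A,B")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must sum to 1")
  if (any(class_sd_m < 0)) stop("class sd values must be non-negative")
  if (outlier_prob < 0 || outlier_prob > 1) stop("invalid outlier_prob")
  if (outlier_sd_m <= 0) stop("outlier_sd_m must be positive")
  structure(list(class_probs = class_probs, class_sd_m = class_sd_m,
                 outlier_prob = outlier_prob, outlier_sd_m = outlier_sd_m),
            class = "argos_error_model")
}

#' Default Argos error model
#'
#' The class composition and nominal error radii described in
#' [argos_error_model()], with no gross outliers.
#' @return an `argos_error_model`.
#' @export
default_error_model <- function() argos_error_model()

#' Measurement sd (metres) for each fix
#'
#' Per-fix error radius, where reported, overrides the class default.
#' @param lc character vector of Argos classes.
#' @param error_radius_m numeric vector (NA where absent).
#' @param error_model an `argos_error_model`.
#' @return numeric vector of standard deviations, metres.
#' @export
measurement_sd <- function(lc, error_radius_m, error_model) {
  sd <- unname(error_model$class_sd_m[as.character(lc)])
  if (anyNA(sd)) stop("unknown Argos class")
  use <- !is.na(error_radius_m) & error_radius_m > 0
  sd[use] <- error_radius_m[use]
  sd
}
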