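SYNAPSE_LAYERS  <- c("SO", "dSP", "sSP", "SR", "SLM")
SYNAPSE_TARGETS <- c("spine_head", "spine_neck", "shaft_spiny",
                     "shaft_aspiny", "unknown")
SYNAPSE_SHAPES  <- c("macular", "horseshoe", "perforated", "fragmented")

check_prob_vector <- function(p, categories, name) {
  if (is.null(names(p)) || !setequal(names(p), categories))
    stop(sprintf("'%s' must be named over {%s}", name,
                 paste(categories, collapse = ", ")), call. = FALSE)
  p <- p[categories]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(sprintf("'%s' must be nonnegative and sum to 1 (got %.12f)",
                 name, sum(p)), call. = FALSE)
  p
}

#' Layer population profile for the synthetic generator
#'
#' Bundles everything needed to simulate the synapse population of one
#' cortical layer: the synaptic density (intensity of the spatial Poisson
#' process), the asymmetric:symmetric mix, the categorical distributions of
#' postsynaptic target and junction shape conditional on polarity, and the
#' size model for the synaptic apposition surface (SAS).
#'
#' The SAS-area model is log-normal by default (parameterized by the mean and
#' SD of log area) with log-logistic available as an alternative; these are
#' the two families that describe right-skewed synaptic size distributions.
#'
#' @param layer layer label, one of SO, dSP, sSP, SR, SLM.
#' @param intensity synapses per um^3; >= 0.
#' @param as_fraction fraction of synapses that are asymmetric (AS), in [0,1].
#' @param target_probs named list with elements \code{AS} and \code{SS}, each
#'   a probability vector over the five target categories.
#' @param shape_probs named list with elements \code{AS} and \code{SS}, each
#'   a probability vector over the four shape classes.
#' @param size_model named list with elements \code{AS} and \code{SS}, each a
#'   list with \code{family} ("lognormal" or "loglogistic") and its
#'   parameters (\code{meanlog}/\code{sdlog}, or \code{scale}/\code{shape}).
#' @param perimeter_model per-polarity list with \code{shape_factor} (ratio
#'   of SAS perimeter to the perimeter of the equal-area circle) and
#'   \code{sdlog} (log-scale noise).
#' @param curvature_model per-polarity list with Beta parameters
#'   \code{alpha}, \code{beta} for SAS curvature in [0,1).
#' @param intensity_sd optional between-stack SD of the density, carried as
#'   metadata (not used by the homogeneous generator).
#' @return an object of class \code{layer_profile}.
#' @seealso \code{\link{ca1_layer_profiles}} for the packaged human CA1
#'   calibration, \code{\link{generate_population}}.
#' @export
layer_profile <- function(layer, intensity, as_fraction,
                          target_probs, shape_probs, size_model,
                          perimeter_model = NULL, curvature_model = NULL,
                          intensity_sd = NA_real_) {
  layer <- match.arg(layer, SYNAPSE_LAYERS)
  stop_if_not_scalar_num(intensity, "intensity")
  if (intensity < 0) stop("'intensity' must be >= 0", call. = FALSE)
  stop_if_not_scalar_num(as_fraction, "as_fraction")
  if (as_fraction < 0 || as_fraction > 1)
    stop("'as_fraction' must be in [0, 1]", call. = FALSE)
  for (pol in c("AS", "SS")) {
    target_probs[[pol]] <- check_prob_vector(unlist(target_probs[[pol]]),
                                             SYNAPSE_TARGETS,
                                             paste0("target_probs$", pol))
    shape_probs[[pol]] <- check_prob_vector(unlist(shape_probs[[pol]]),
                                            SYNAPSE_SHAPES,
                                            paste0("shape_probs$", pol))
    sm <- size_model[[pol]]
    if (is.null(sm$family) ||
        !sm$family %in% c("lognormal", "loglogistic"))
      stop("size_model family must be 'lognormal' or 'loglogistic'",
           call. = FALSE)
  }
  structure(list(layer = layer, intensity = intensity,
                 intensity_sd = intensity_sd, as_fraction = as_fraction,
                 target_probs = target_probs, shape_probs = shape_probs,
                 size_model = size_model,
                 perimeter_model = perimeter_model,
                 curvature_model = curvature_model),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("layer profile %s: %.2f synapses/um^3, %.2f%% AS\n",
              x$layer, x$intensity, 100 * x$as_fraction))
  invisible(x)
}

# method-of-moments log-normal parameters from arithmetic mean and SD
lognormal_from_moments <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(family = "lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Packaged human CA1 layer profiles
#'
#' Returns the five layer profiles (SO, dSP, sSP, SR, SLM) calibrated to the
#' published human CA1 per-layer synapse table: densities of 0.45-0.99
#' synapses/um^3, an AS:SS mix near 95:5 (90:10 in SLM), pooled postsynaptic
#' target and shape-class frequencies, and log-normal SAS-area models derived
#' by method of moments from the per-layer mean and SEM (SD recovered as
#' SEM * sqrt(n)). The per-layer log-scale parameters were not published, so
#' the moment calibration is an approximation to the real size distributions.
#'
#' @return named list of \code{layer_profile} objects.
#' @examples
#' profs <- ca1_layer_profiles()
#' profs$SO
#' @export
ca1_layer_profiles <- function() {
  path <- system.file("extdata", "ca1_layer_profiles.json",
                      package = "synaptostats3d", mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(names(cfg$layers), function(ly) {
    lp <- cfg$layers[[ly]]
    size <- lapply(c(AS = "AS", SS = "SS"), function(pol) {
      s <- lp$size[[pol]]
      lognormal_from_moments(s$mean, s$sem * sqrt(s$n))
    })
    layer_profile(
      layer = ly, intensity = lp$intensity, as_fraction = lp$as_fraction,
      target_probs = lapply(cfg$target_probs, unlist),
      shape_probs = lapply(cfg$shape_probs, unlist),
      size_model = size,
      perimeter_model = cfg$perimeter_model,
      curvature_model = cfg$curvature_model,
      intensity_sd = lp$intensity_sd
    )
  })
  names(out) <- names(cfg$layers)
  out
}
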