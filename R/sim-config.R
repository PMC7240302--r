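#' Simulation configuration for synthetic T4/T5 populations
#'
#' Bundles every parameter of the synthetic-data generators: population
#' layout, dendrite geometry, axon layer positions, the negative-binomial
#' count model, and the cell-body fluorescence model. The defaults encode
#' the study conditions the downstream analyses assume: four dendrite
#' orientations 90 degrees apart with opposite-direction subtype pairs
#' (a,b) and (c,d), four axon-position clusters on the normalized
#' anteroposterior axis, arbor growth between 36 and 72 h APF followed by
#' pruning, and eight transcriptomic clusters (T4/T5 x a-d) per stage
#' carrying the marker-gene program.
#'
#' @param n_neurons_per_subtype Neurons generated per subtype, per cell
#'   type (T4/T5), per stage. Must be a positive integer.
#' @param stages Ordered developmental stage labels (hours APF, plus
#'   `"adult"`).
#' @param kappa von Mises concentration of dendritic branch directions
#'   (dimensionless, >= 0; `Inf` gives perfectly aligned branches).
#' @param subtype_angles Named vector (a,b,c,d) of generating branch
#'   angles in degrees, counterclockwise from +x. The (a,b) and (c,d)
#'   pairs must differ by 180 degrees.
#' @param layer_centers Named vector (a,b,c,d) of mean relative axon
#'   positions in (0,1), strictly increasing.
#' @param layer_sd Standard deviation of axon positions (normalized
#'   units, > 0).
#' @param nb_mean Negative-binomial mean of housekeeping gene counts.
#' @param nb_dispersion Negative-binomial size (dispersion) parameter;
#'   larger values approach Poisson.
#' @param marker_high,marker_low Mean counts of a marker gene in the
#'   clusters where it is on, respectively off. Their ratio is the
#'   configured marker fold.
#' @param n_branches Dendritic branches per neuron.
#' @param branch_length Base branch length (micrometers) at the largest
#'   arbor stage.
#' @param stage_size Named vector of arbor-size factors per stage
#'   (fraction of maximum cable length); the default rises from 36 to
#'   72 h APF and falls from 72 h to adult.
#' @param n_cells_per_cluster Cells simulated per transcriptomic cluster
#'   per stage.
#' @param qc_fail_frac Fraction of cells per cluster generated so that
#'   they fail quality control (low depth or high mitochondrial /
#'   heat-shock load).
#' @param cb_enrichment Fold enrichment of Grain cell-body fluorescence
#'   in subtypes b,c over the Lim1-negative background.
#' @param cb_noise_sd Standard deviation of cell-body intensity noise
#'   (arbitrary fluorescence units).
#' @param ap_extent,pd_extent Anteroposterior and proximodistal extent
#'   (same length units as neuron coordinates) of the rectangular
#'   lobula-plate frame the generator embeds axons in.
#' @param conversion_penetrance Probability that a perturbed neuron
#'   actually converts identity (1 = complete conversion).
#' @param seed Single global integer seed; every sub-generator derives a
#'   child seed from it deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_neurons_per_subtype = 2, stages = "72")
#' cfg$layer_centers
#' @export
sim_config <- function(n_neurons_per_subtype = 16,
                       stages = c("24", "36", "48", "60", "72", "adult"),
                       kappa = 3,
                       subtype_angles = c(a = 0, b = 180, c = 90, d = 270),
                       layer_centers = c(a = 0.2, b = 0.4, c = 0.6, d = 0.8),
                       layer_sd = 0.02,
                       nb_mean = 40,
                       nb_dispersion = 2,
                       marker_high = 25,
                       marker_low = 0.2,
                       n_branches = 200,
                       branch_length = 5,
                       stage_size = NULL,
                       n_cells_per_cluster = 30,
                       qc_fail_frac = 0.05,
                       cb_enrichment = 3,
                       cb_noise_sd = 10,
                       ap_extent = 100,
                       pd_extent = 50,
                       conversion_penetrance = 1,
                       seed = 1L) {
  stages <- as.character(stages)
  if (is.null(stage_size)) {
    stage_size <- c("24" = 0.15, "36" = 0.30, "48" = 0.55,
                    "60" = 0.80, "72" = 1.00, "adult" = 0.75)
  }
  cfg <- list(
    n_neurons_per_subtype = n_neurons_per_subtype,
    stages = stages,
    kappa = kappa,
    subtype_angles = subtype_angles,
    layer_centers = layer_centers,
    layer_sd = layer_sd,
    nb_mean = nb_mean,
    nb_dispersion = nb_dispersion,
    marker_high = marker_high,
    marker_low = marker_low,
    n_branches = n_branches,
    branch_length = branch_length,
    stage_size = stage_size,
    n_cells_per_cluster = n_cells_per_cluster,
    qc_fail_frac = qc_fail_frac,
    cb_enrichment = cb_enrichment,
    cb_noise_sd = cb_noise_sd,
    ap_extent = ap_extent,
    pd_extent = pd_extent,
    conversion_penetrance = conversion_penetrance,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_neurons_per_subtype
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("n_neurons_per_subtype must be a positive integer", call. = FALSE)
  }
  if (length(cfg$stages) < 1L) stop("at least one stage is required", call. = FALSE)
  missing_size <- setdiff(cfg$stages, names(cfg$stage_size))
  if (length(missing_size)) {
    stop("no arbor-size factor for stage(s): ",
         paste(missing_size, collapse = ", "), call. = FALSE)
  }
  if (is.na(cfg$kappa) || cfg$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  ang <- cfg$subtype_angles
  if (!all(c("a", "b", "c", "d") %in% names(ang))) {
    stop("subtype_angles must name a, b, c, d", call. = FALSE)
  }
  if (anyDuplicated(ang %% 360)) stop("subtype_angles must be pairwise distinct", call. = FALSE)
  opp <- function(x, y) isTRUE(all.equal((x - y) %% 360, 180))
  if (!opp(ang[["a"]], ang[["b"]]) || !opp(ang[["c"]], ang[["d"]])) {
    stop("subtype pairs (a,b) and (c,d) must be 180 degrees apart", call. = FALSE)
  }
  lc <- cfg$layer_centers
  if (!all(c("a", "b", "c", "d") %in% names(lc))) {
    stop("layer_centers must name a, b, c, d", call. = FALSE)
  }
  if (any(lc <= 0) || any(lc >= 1)) stop("layer_centers must lie in (0,1)", call. = FALSE)
  if (any(diff(unname(lc[c("a", "b", "c", "d")])) <= 0)) {
    stop("layer_centers must be strictly increasing", call. = FALSE)
  }
  if (cfg$layer_sd <= 0) stop("layer_sd must be > 0", call. = FALSE)
  if (cfg$nb_mean <= 0 || cfg$nb_dispersion <= 0) {
    stop("nb_mean and nb_dispersion must be > 0", call. = FALSE)
  }
  if (cfg$qc_fail_frac < 0 || cfg$qc_fail_frac >= 1) {
    stop("qc_fail_frac must be in [0,1)", call. = FALSE)
  }
  if (cfg$conversion_penetrance < 0 || cfg$conversion_penetrance > 1) {
    stop("conversion_penetrance must be in [0,1]", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("T4/T5 simulation configuration\n")
  cat("  neurons/subtype/type/stage:", x$n_neurons_per_subtype, "\n")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  cat("  kappa:", x$kappa, " branches:", x$n_branches, "\n")
  cat("  subtype angles:",
      paste(sprintf("%s=%g", names(x$subtype_angles), x$subtype_angles),
            collapse = " "), "\n")
  cat("  layer centers:",
      paste(sprintf("%s=%g", names(x$layer_centers), x$layer_centers),
            collapse = " "), " sd:", x$layer_sd, "\n")
  cat("  counts: NB(mean=", x$nb_mean, ", size=", x$nb_dispersion,
      "), marker ", x$marker_high, "/", x$marker_low, "\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Config as a YAML-safe list (named vectors become maps, not sequences).
config_as_yaml_list <- function(cfg, ...) {
  lst <- unclass(cfg)
  for (nm in c("subtype_angles", "layer_centers", "stage_size")) {
    lst[[nm]] <- as.list(lst[[nm]])
  }
  c(lst, list(...))
}

# Deterministic child seed for sub-generator k; stays below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483629)
}

#' Draw angles from a von Mises distribution
#'
#' Circular analog of the Gaussian, used to simulate oriented dendritic
#' branch growth. Uses the Best-Fisher wrapped-Cauchy rejection sampler;
#' `kappa = 0` reduces to the uniform distribution on the circle and
#' `kappa = Inf` to a point mass at `mu_deg`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration parameter (>= 0, possibly `Inf`).
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu_deg %% 360, n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out * 180 / pi) %% 360
}
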