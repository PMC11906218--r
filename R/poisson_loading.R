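#' Chip geometry for a digital-microfluidics droplet array
#'
#' Describes the electrode array on which the droplet array is formed by
#' repeated one-to-two splitting. Each droplet sits on a single electrode,
#' so its volume is the electrode footprint times the gap height between
#' the two chip plates.
#'
#' @param electrode_pitch Electrode width in micrometres.
#' @param gap_height Plate gap (droplet depth) in micrometres.
#' @param array_rows,array_cols Dimensions of the droplet array
#'   (default 8 x 8, i.e. 64 droplets).
#'
#' @return An object of class `chip_geometry`.
#' @examples
#' geom <- chip_geometry()           # 250 um pitch, 50 um gap, 8 x 8 array
#' droplet_volume(geom)              # 3.125 nL per droplet
#' @export
chip_geometry <- function(electrode_pitch = 250, gap_height = 50,
                          array_rows = 8, array_cols = 8) {
  if (electrode_pitch <= 0 || gap_height <= 0)
    stop("invalid geometry: electrode_pitch and gap_height must be positive")
  if (array_rows < 1 || array_cols < 1)
    stop("invalid geometry: array dimensions must be >= 1")
  structure(
    list(electrode_pitch = electrode_pitch, gap_height = gap_height,
         array_rows = as.integer(array_rows), array_cols = as.integer(array_cols)),
    class = "chip_geometry")
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf("chip_geometry: %g um pitch, %g um gap, %d x %d array (%g nL/droplet)\n",
              x$electrode_pitch, x$gap_height, x$array_rows, x$array_cols,
              droplet_volume(x)))
  invisible(x)
}

#' Per-droplet volume of an array droplet
#'
#' Volume of one droplet in nanolitres: `pitch^2 * gap_height`. For the
#' default geometry (250 um pitch, 50 um gap) this is 3.125 nL, so the
#' 64-droplet array holds 0.2 uL in total.
#'
#' @param geometry A [chip_geometry()].
#' @return Droplet volume in nL.
#' @export
droplet_volume <- function(geometry = chip_geometry()) {
  # um^3 -> nL: 1 nL = 1e6 um^3
  geometry$electrode_pitch^2 * geometry$gap_height / 1e6
}

#' Convert a loading concentration to the Poisson occupancy mean
#'
#' Droplet loading is Poisson: lambda, the mean number of objects per
#' droplet, equals concentration times droplet volume. At the reference
#' loading of 3.2e5 cells/mL into 3.125 nL droplets, lambda = 1 (one cell
#' per droplet on average, 64 cells over the 8 x 8 array).
#'
#' @param concentration Cells (or particles) per mL; must be >= 0.
#' @param volume_nl Droplet volume in nL; must be > 0.
#' @return Dimensionless occupancy mean lambda.
#' @seealso [concentration_from_lambda()] for the inverse.
#' @export
lambda_from_concentration <- function(concentration, volume_nl = droplet_volume()) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (any(volume_nl <= 0)) stop("droplet volume must be positive")
  concentration * volume_nl / 1e6   # nL -> mL
}

#' @rdname lambda_from_concentration
#' @param lambda Occupancy mean; must be >= 0.
#' @export
concentration_from_lambda <- function(lambda, volume_nl = droplet_volume()) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (any(volume_nl <= 0)) stop("droplet volume must be positive")
  lambda * 1e6 / volume_nl
}

#' Occupancy means of a two-species mixture from the target:background ratio
#'
#' For a target:background number ratio `ratio`, with the target species
#' loaded at mean `lambda_target` per droplet, the background species has
#' mean `lambda_target / ratio`. A ratio of 1 (equal mixture) gives equal
#' means; a ratio of 5 gives a background mean one fifth of the target's.
#'
#' @param lambda_target Occupancy mean of the target species (> 0).
#' @param ratio Target:background ratio (> 0).
#' @return Named numeric vector `c(lambda_target =, lambda_background =)`.
#' @export
lambdas_from_ratio <- function(lambda_target = 1, ratio = 1) {
  if (lambda_target <= 0) stop("lambda_target must be positive")
  if (ratio <= 0) stop("ratio must be positive")
  c(lambda_target = lambda_target, lambda_background = lambda_target / ratio)
}

#' Loading specification for a two-species droplet array
#'
#' Bundles the occupancy means of the two species. Either give both
#' lambdas, or a target lambda plus a target:background ratio, or a
#' concentration (converted through the droplet volume) plus a ratio.
#'
#' @param lambda_target,lambda_background Occupancy means (>= 0).
#' @param ratio Target:background ratio; used to derive
#'   `lambda_background` when that is not given.
#' @param concentration Target-species concentration in cells/mL; used to
#'   derive `lambda_target` when that is not given.
#' @param geometry Chip geometry used for the concentration conversion.
#' @return An object of class `loading_spec` with fields `lambda_target`
#'   and `lambda_background`.
#' @export
loading_spec <- function(lambda_target = NULL, lambda_background = NULL,
                         ratio = NULL, concentration = NULL,
                         geometry = chip_geometry()) {
  if (is.null(lambda_target)) {
    if (is.null(concentration))
      stop("give either lambda_target or concentration")
    lambda_target <- lambda_from_concentration(concentration,
                                               droplet_volume(geometry))
  }
  if (is.null(lambda_background)) {
    if (is.null(ratio))
      stop("give either lambda_background or ratio")
    lambda_background <- unname(lambdas_from_ratio(lambda_target, ratio)[2])
  }
  if (lambda_target < 0 || lambda_background < 0)
    stop("occupancy means must be non-negative")
  structure(list(lambda_target = lambda_target,
                 lambda_background = lambda_background),
            class = "loading_spec")
}

#' Sample a droplet array
#'
#' Draws per-droplet target and background counts as independent Poisson
#' variates (i.i.d. across droplets), the standard model for passive
#' single-cell encapsulation. Reproducible under `set.seed()`.
#'
#' @param spec A [loading_spec()].
#' @param n_droplets Number of droplets (>= 1); default 64 (8 x 8 array).
#' @return Integer matrix with `n_droplets` rows and columns
#'   `n_target`, `n_background`.
#' @export
sample_array <- function(spec, n_droplets = 64) {
  if (n_droplets < 1) stop("n_droplets must be >= 1")
  m <- cbind(n_target = stats::rpois(n_droplets, spec$lambda_target),
             n_background = stats::rpois(n_droplets, spec$lambda_background))
  storage.mode(m) <- "integer"
  m
}

#' Droplet type labels
#'
#' The four droplet types arising in a two-species mixture.
#' @format Character vector of the four labels.
#' @export
DROPLET_LABELS <- c("EMPTY", "TARGET_ONLY", "BACKGROUND_ONLY", "MIXED")

#' Classify droplets by their true contents
#'
#' A droplet is `EMPTY` with no objects, `TARGET_ONLY` / `BACKGROUND_ONLY`
#' with objects of just one species, and `MIXED` with both.
#'
#' @param n_target,n_background Non-negative integer count vectors
#'   (recycled to a common length).
#' @return Character vector of labels from [DROPLET_LABELS].
#' @export
true_label <- function(n_target, n_background) {
  if (is.matrix(n_target) && missing(n_background)) {
    n_background <- n_target[, 2]
    n_target <- n_target[, 1]
  }
  if (any(n_target < 0) || any(n_background < 0))
    stop("counts must be non-negative")
  ifelse(n_target == 0 & n_background == 0, "EMPTY",
    ifelse(n_target > 0 & n_background == 0, "TARGET_ONLY",
      ifelse(n_target == 0, "BACKGROUND_ONLY", "MIXED")))
}

#' Closed-form proportions of the four droplet types
#'
#' Under independent Poisson loading with means `lambda_target` and
#' `lambda_background`, the type probabilities factorise:
#' \deqn{p_{empty} = e^{-(\lambda_T+\lambda_B)}, \quad
#'       p_{target\ only} = (1-e^{-\lambda_T}) e^{-\lambda_B},}
#' \deqn{p_{background\ only} = e^{-\lambda_T} (1-e^{-\lambda_B}), \quad
#'       p_{mixed} = (1-e^{-\lambda_T})(1-e^{-\lambda_B}).}
#' The mixed-droplet proportion grows with either mean, which is why
#' dilute loading favours single-pass sorting.
#'
#' @param lambda_target,lambda_background Occupancy means (>= 0).
#' @return Named numeric vector (`EMPTY`, `TARGET_ONLY`,
#'   `BACKGROUND_ONLY`, `MIXED`) summing to 1.
#' @export
expected_type_proportions <- function(lambda_target, lambda_background) {
  if (lambda_target < 0 || lambda_background < 0)
    stop("occupancy means must be non-negative")
  et <- exp(-lambda_target)
  eb <- exp(-lambda_background)
  c(EMPTY = et * eb,
    TARGET_ONLY = (1 - et) * eb,
    BACKGROUND_ONLY = et * (1 - eb),
    MIXED = (1 - et) * (1 - eb))
}

#' Chi-square goodness of fit of occupancy counts to a Poisson law
#'
#' Tests whether per-droplet object counts are consistent with Poisson
#' loading. The mean is the maximum-likelihood estimate of lambda;
#' occupancy bins 0, 1, 2, ... are pooled from the right tail until every
#' bin's expected count is at least `min_expected`; one degree of freedom
#' is subtracted for the estimated mean (dof = bins - 2).
#'
#' @param counts Integer vector of per-droplet object counts (>= 2 values).
#' @param min_expected Minimum expected count per bin before tail pooling
#'   stops (default 5, the usual rule of thumb).
#' @return An object of class `poisson_gof` with fields `lambda_hat`,
#'   `chi2_stat`, `dof`, `p_value`, and the binned observed/expected table.
#' @export
poisson_gof <- function(counts, min_expected = 5) {
  counts <- as.integer(counts)
  if (length(counts) < 2) stop("need at least 2 droplets")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  lambda_hat <- mean(counts)
  if (lambda_hat == 0)
    stop("degenerate data: all counts are zero, no Poisson fit possible")

  # bins 0, 1, ..., K-1 and a pooled ">= K" upper tail with expected >= min_expected
  K <- max(counts)
  while (K > 1L &&
         n * stats::ppois(K - 1L, lambda_hat, lower.tail = FALSE) < min_expected) {
    K <- K - 1L
  }
  nbins <- K + 1L
  if (nbins < 3L) {
    # cannot estimate lambda and still have dof >= 1
    stop("degenerate data: too few occupancy bins for a chi-square test")
  }
  expected <- c(n * stats::dpois(0:(K - 1L), lambda_hat),
                n * stats::ppois(K - 1L, lambda_hat, lower.tail = FALSE))
  observed <- tabulate(factor(pmin(counts, K), levels = 0:K))
  chi2 <- sum((observed - expected)^2 / expected)
  dof <- nbins - 2L
  structure(list(lambda_hat = lambda_hat, chi2_stat = chi2, dof = dof,
                 p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
                 bins = data.frame(occupancy = c(as.character(0:(K - 1L)),
                                                 paste0(">=", K)),
                                   observed = observed, expected = expected)),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("Poisson goodness of fit: lambda_hat = %.4f, X2 = %.3f, df = %d, p = %.4g\n",
              x$lambda_hat, x$chi2_stat, x$dof, x$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov-type check of occupancy counts against Poisson
#'
#' Secondary companion to [poisson_gof()]: the largest absolute gap
#' between the empirical CDF of the counts and the fitted Poisson CDF.
#' Because the distribution is discrete and lambda is estimated, the
#' classical K-S null distribution does not apply; the p-value is obtained
#' by a parametric bootstrap under the fitted Poisson.
#'
#' @param counts Integer vector of per-droplet counts.
#' @param n_boot Bootstrap replicates for the p-value (default 500).
#' @return List with `lambda_hat`, `ks_stat`, `p_value`.
#' @export
poisson_ks <- function(counts, n_boot = 500) {
  counts <- as.integer(counts)
  if (length(counts) < 2) stop("need at least 2 droplets")
  lambda_hat <- mean(counts)
  stat <- function(x, lam) {
    ks <- 0:max(x)
    max(abs(stats::ecdf(x)(ks) - stats::ppois(ks, lam)))
  }
  d0 <- stat(counts, lambda_hat)
  n <- length(counts)
  db <- replicate(n_boot, {
    x <- stats::rpois(n, lambda_hat)
    stat(x, mean(x))
  })
  list(lambda_hat = lambda_hat, ks_stat = d0,
       p_value = mean(db >= d0))
}

#' Read per-droplet occupancy counts from CSV
#'
#' Accepts either a single-species table (`droplet_id, n_objects`) for
#' goodness-of-fit analysis, or a typed two-species table
#' (`droplet_id, n_target, n_background`).
#'
#' @param path CSV file path.
#' @return For the single-species layout, an integer vector of counts; for
#'   the typed layout, an integer matrix with columns `n_target`,
#'   `n_background`.
#' @export
read_occupancy_csv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("n_target", "n_background") %in% names(df))) {
    m <- cbind(n_target = as.integer(df$n_target),
               n_background = as.integer(df$n_background))
    return(m)
  }
  if ("n_objects" %in% names(df)) return(as.integer(df$n_objects))
  stop("occupancy CSV must have columns (droplet_id, n_objects) or (droplet_id, n_target, n_background)")
}
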