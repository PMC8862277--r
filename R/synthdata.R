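#' Gene-pair relationship generators
#'
#' Draws a seeded sample (x, y) from one of the bivariate relationship
#' families used throughout the evaluation harness:
#'
#' * `independent`: x and y i.i.d. standard normal.
#' * `linear`: y = x + noise.
#' * `power`: y = sign(x) |x|^3 + noise (nonlinear, monotone).
#' * `threshold`: y = 1(x > 0) + noise (step function).
#' * `quadripartite`: four point clusters centered on (-1,0), (1,0),
#'   (0,-1), (0,1); the cluster-level variables are uncorrelated but
#'   dependent, so linear metrics see nothing while dependence metrics do.
#' * `parabolic`: y = x^2 + noise on symmetric x (zero linear
#'   correlation, strong dependence).
#'
#' Default noise levels per family are calibrated so that at n = 30 the
#' best-performing metric has intermediate power, keeping comparative
#' power studies informative.
#'
#' @param kind relationship family, see above.
#' @param n sample size (>= 4).
#' @param noise_sd standard deviation of the additive Gaussian noise;
#'   `NULL` selects the per-family default.
#' @param seed optional integer seed.
#' @return list with numeric vectors `x` and `y` and the `kind`.
#' @export
#' @examples
#' p <- gen_relationship("parabolic", n = 50, seed = 1)
#' cor_pearson(p$x, p$y)  # near zero
#' dcor(p$x, p$y)         # clearly positive
gen_relationship <- function(kind = c("independent", "linear", "power",
                                      "threshold", "quadripartite",
                                      "parabolic"),
                             n, noise_sd = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 4)
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(kind)
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    out <- switch(kind,
      independent = list(x = rnorm(n), y = rnorm(n)),
      linear = {
        x <- rnorm(n)
        list(x = x, y = x + rnorm(n, sd = noise_sd))
      },
      power = {
        x <- rnorm(n)
        list(x = x, y = sign(x) * abs(x)^3 + rnorm(n, sd = noise_sd))
      },
      threshold = {
        x <- rnorm(n)
        list(x = x, y = as.numeric(x > 0) + rnorm(n, sd = noise_sd))
      },
      quadripartite = {
        centers <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2,
                          byrow = TRUE)
        j <- sample.int(4, n, replace = TRUE)
        list(x = centers[j, 1] + rnorm(n, sd = noise_sd),
             y = centers[j, 2] + rnorm(n, sd = noise_sd))
      },
      parabolic = {
        x <- rnorm(n)
        list(x = x, y = x^2 + rnorm(n, sd = noise_sd))
      }
    )
    out$kind <- kind
    out
  })
}

default_noise_sd <- function(kind) {
  switch(kind,
    independent = 0,
    linear = 1.5,
    power = 4,
    threshold = 0.8,
    quadripartite = 0.1,
    parabolic = 1)
}

#' Inject outliers relative to the fitted regression line
#'
#' Fits a least-squares line to the base (x, y) sample, then appends
#' `n_outliers` points displaced from the line's center either along its
#' direction (`"along_regression"`, which inflates linear correlation) or
#' perpendicular to it (`"normal_to_regression"`, which deflates it).
#' Displacement distances are `magnitude` scaled by the x standard
#' deviation, jittered slightly so the planted points are not coincident.
#'
#' @param x,y base sample (non-degenerate in x).
#' @param n_outliers number of points to append (0 returns the input
#'   unchanged).
#' @param direction `"along_regression"` or `"normal_to_regression"`.
#' @param magnitude displacement distance in x-standard-deviation units
#'   (default 8).
#' @param seed optional integer seed.
#' @return list with extended `x` and `y` and logical `is_outlier` flags.
#' @export
inject_outliers <- function(x, y, n_outliers,
                            direction = c("along_regression",
                                          "normal_to_regression"),
                            magnitude = 8, seed = NULL) {
  direction <- match.arg(direction)
  check_pair(x, y)
  stopifnot(n_outliers >= 0, n_outliers < length(x), magnitude > 0)
  if (n_outliers == 0) {
    return(list(x = x, y = y, is_outlier = rep(FALSE, length(x))))
  }
  if (is_constant(x)) stop("degenerate (vertical) regression fit")
  fit <- stats::lm(y ~ x)
  slope <- coef(fit)[[2]]
  u <- c(1, slope) / sqrt(1 + slope^2)        # unit along-line direction
  v <- c(-slope, 1) / sqrt(1 + slope^2)       # unit normal direction
  dir_vec <- if (direction == "along_regression") u else v
  scale <- sd(x) * magnitude
  cx <- mean(x)
  cy <- mean(y)
  with_seed(seed, {
    side <- sample(c(-1, 1), n_outliers, replace = TRUE)
    jitter <- 1 + runif(n_outliers, -0.1, 0.1)
    ox <- cx + side * jitter * scale * dir_vec[1]
    oy <- cy + side * jitter * scale * dir_vec[2]
    list(x = c(x, ox), y = c(y, oy),
         is_outlier = c(rep(FALSE, length(x)), rep(TRUE, n_outliers)))
  })
}

#' Expression matrix with planted co-expression modules
#'
#' Each module's genes load on a shared latent factor:
#' gene = sqrt(rho) * factor + sqrt(1 - rho) * noise, so the expected
#' pairwise Pearson correlation inside a module is `within_corr` = rho.
#' Background genes are independent standard normal. Gene order is
#' shuffled so module membership is not encoded in row order.
#'
#' @param module_sizes integer vector of module sizes (each >= 2).
#' @param n_background number of unassigned background genes.
#' @param n_samples number of samples.
#' @param within_corr target within-module correlation, in (0, 1).
#' @param seed optional integer seed.
#' @return list with `expr` (genes x samples matrix, rownames g1..gN,
#'   colnames s1..sn) and `labels` (named integer vector; 0 = background).
#' @export
gen_module_expression <- function(module_sizes, n_background = 0,
                                  n_samples, within_corr = 0.7,
                                  seed = NULL) {
  stopifnot(length(module_sizes) >= 1, all(module_sizes >= 2),
            n_background >= 0, n_samples >= 2,
            within_corr > 0, within_corr < 1)
  g <- sum(module_sizes) + n_background
  with_seed(seed, {
    labels <- c(rep(seq_along(module_sizes), module_sizes),
                rep(0L, n_background))
    expr <- matrix(rnorm(g * n_samples), nrow = g)
    load <- sqrt(within_corr)
    row <- 1L
    for (m in seq_along(module_sizes)) {
      f <- rnorm(n_samples)
      idx <- row:(row + module_sizes[m] - 1L)
      expr[idx, ] <- load * matrix(f, nrow = module_sizes[m],
                                   ncol = n_samples, byrow = TRUE) +
        sqrt(1 - within_corr) * expr[idx, , drop = FALSE]
      row <- row + module_sizes[m]
    }
    ord <- sample.int(g)
    expr <- expr[ord, , drop = FALSE]
    labels <- labels[ord]
    rownames(expr) <- paste0("g", seq_len(g))
    colnames(expr) <- paste0("s", seq_len(n_samples))
    names(labels) <- rownames(expr)
    list(expr = expr, labels = labels)
  })
}

#' Sample node degrees from a discrete power law
#'
#' Degrees k in 1..k_max with P(k) proportional to k^(-gamma); used to
#' exercise the scale-free-topology fit index on a known power law.
#'
#' @param gamma power-law exponent (> 1).
#' @param k_max largest degree.
#' @param n_nodes number of degrees to draw.
#' @param seed optional integer seed.
#' @param exact if `TRUE`, return the deterministic degree sequence whose
#'   counts are the rounded expected counts `n_nodes * P(k)` instead of a
#'   random sample.
#' @return integer vector of degrees.
#' @export
gen_powerlaw_degrees <- function(gamma, k_max, n_nodes, seed = NULL,
                                 exact = FALSE) {
  stopifnot(gamma > 1, k_max >= 1, n_nodes >= 1)
  k <- seq_len(k_max)
  p <- k^(-gamma)
  p <- p / sum(p)
  if (exact) {
    counts <- round(n_nodes * p)
    return(rep(k, times = counts))
  }
  with_seed(seed, sample(k, n_nodes, replace = TRUE, prob = p))
}

#' Build a seeded generator closure for power studies
#'
#' Returns a `function(seed)` producing one (x, y) draw, suitable for
#' [power_curve()]. With `outlier_rate > 0` each draw is contaminated by
#' `Binomial(n, outlier_rate)` planted outliers (via [inject_outliers()]),
#' emulating subsampling from a population that contains a small fraction
#' of aberrant samples: the chance that a draw contains an outlier grows
#' with n.
#'
#' @inheritParams gen_relationship
#' @param outlier_rate per-point probability of appending an outlier.
#' @param outlier_direction passed to [inject_outliers()].
#' @param outlier_magnitude passed to [inject_outliers()].
#' @return a function taking a seed and returning `list(x, y)`.
#' @export
relationship_generator <- function(kind, n, noise_sd = NULL,
                                   outlier_rate = 0,
                                   outlier_direction = "normal_to_regression",
                                   outlier_magnitude = 8) {
  force(kind); force(n); force(noise_sd)
  stopifnot(outlier_rate >= 0, outlier_rate < 1)
  function(seed = NULL) {
    with_seed(seed, {
      n_out <- if (outlier_rate > 0) rbinom(1, n, outlier_rate) else 0L
      n_out <- min(n_out, n - 4L, floor((n - 1L) / 2))
      base <- gen_relationship(kind, n = n - n_out, noise_sd = noise_sd)
      if (n_out > 0) {
        o <- inject_outliers(base$x, base$y, n_out,
                             direction = outlier_direction,
                             magnitude = outlier_magnitude)
        list(x = o$x, y = o$y)
      } else {
        list(x = base$x, y = base$y)
      }
    })
  }
}
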