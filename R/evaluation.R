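#' Reliability of genomic prediction
#'
#' The squared Pearson correlation between GEBV and the validation
#' phenotype (DRP, or DRP + TBV_Q for simulated data), divided by the mean
#' DRP reliability of the validation individuals. Returned on the 0-1
#' scale; multiply by 100 for the percent scale used in result tables. The
#' value can exceed 1 when the GEBV-DRP correlation is higher than the mean
#' DRP reliability.
#'
#' @param gebv,drp numeric vectors over the validation individuals.
#' @param mean_r2_drp mean DRP reliability in (0, 1].
#' @return reliability on the 0-1 scale.
#' @export
reliability <- function(gebv, drp, mean_r2_drp) {
  if (length(gebv) < 3 || length(gebv) != length(drp))
    stop("need >= 3 paired validation records")
  if (!(mean_r2_drp > 0 && mean_r2_drp <= 1)) stop("mean_r2_drp must be in (0, 1]")
  if (!(stats::var(gebv) > 0) || !(stats::var(drp) > 0))
    stop("zero variance in GEBV or DRP")
  stats::cor(gebv, drp)^2 / mean_r2_drp
}

#' Approximate standard error of the prediction accuracy
#'
#' `SE = ((1 - r2) / sqrt(N - 2)) / r_drp`, where `r2` is the reliability
#' (0-1 scale), `N` the training-set size and `r_drp` the square root of
#' the mean DRP reliability.
#'
#' @param reliability reliability of prediction on the 0-1 scale.
#' @param N training-set size (> 2).
#' @param mean_r_drp square root of the mean DRP reliability.
#' @return the approximate accuracy standard error.
#' @export
accuracy_se <- function(reliability, N, mean_r_drp) {
  if (N <= 2) stop("N must exceed 2")
  ((1 - reliability) / sqrt(N - 2)) / mean_r_drp
}

#' Scale bias of GEBV: regression slope of DRP on GEBV
#'
#' `b = cov(DRP, GEBV) / var(GEBV)`. A slope below 1 indicates
#' over-dispersed (inflated) GEBV, above 1 under-dispersed.
#'
#' @param gebv,drp numeric vectors over the validation individuals.
#' @return the regression slope.
#' @export
bias_slope <- function(gebv, drp) {
  if (length(gebv) != length(drp) || length(gebv) < 2) stop("need paired vectors")
  v <- stats::var(gebv)
  if (!(v > 0)) stop("zero-variance GEBV")
  stats::cov(drp, gebv) / v
}

#' Mean and standard error across replicates
#'
#' @param values numeric vector with one entry per replicate (>= 2).
#' @return named vector `c(mean, se)` with `se = sd / sqrt(k)` (sample
#'   standard deviation, `k - 1` denominator).
#' @export
replicate_summary <- function(values) {
  k <- length(values)
  if (k < 2) stop("need at least two replicates")
  c(mean = mean(values), se = stats::sd(values) / sqrt(k))
}

#' Heritability from variance components
#'
#' Sum of the genetic variance components divided by the total variance.
#'
#' @param genetic_variances numeric vector of non-negative genetic
#'   components.
#' @param total_variance total (phenotypic) variance, > 0.
#' @return heritability on the 0-1 scale.
#' @export
heritability <- function(genetic_variances, total_variance) {
  if (!(total_variance > 0)) stop("total variance must be positive")
  if (any(genetic_variances < 0)) stop("genetic variances must be >= 0")
  sum(genetic_variances) / total_variance
}
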