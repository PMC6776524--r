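#' Functional assay analysis: delta F/F0, Boltzmann activation fits and
#' Mann-Whitney U comparisons
#'
#' @name functional_assays
NULL

#' Maximal relative fluorescence change after a stimulus
#'
#' \eqn{\Delta F/F_0 = (F_{max} - F_{t=0}) / F_{t=0}}, with the maximum
#' searched only at or after the stimulus time (the agonist is added
#' mid-recording; default protocol adds it at t = 10 s).
#'
#' @param trace data.frame with columns \code{time} (s) and \code{F}
#'   (fluorescence, > 0); optionally \code{roi}.
#' @param stim_time stimulus time (s), default 10.
#' @return numeric delta F / F0 (dimensionless); vector if multiple ROIs.
#' @export
delta_f_over_f0 <- function(trace, stim_time = 10) {
  stopifnot(all(c("time", "F") %in% names(trace)))
  one <- function(tr) {
    if (max(tr$time) < stim_time || min(tr$time) > stim_time)
      stop("trace does not contain the stimulus time ", stim_time, " s")
    f0 <- tr$F[which.min(abs(tr$time - min(tr$time)))]
    if (!is.finite(f0) || f0 <= 0) stop("baseline F0 must be positive")
    fmax <- max(tr$F[tr$time >= stim_time])
    (fmax - f0) / f0
  }
  if ("roi" %in% names(trace) && length(unique(trace$roi)) > 1)
    vapply(split(trace, trace$roi), one, numeric(1))
  else one(trace)
}

#' Boltzmann fit of pressure-activated currents
#'
#' Least-squares fit of \eqn{I/I_{max} = scale / (1 + exp((P_{50} - P)/k))}
#' by Levenberg-Marquardt. The slope k is signed, so negative-pressure
#' (suction) activation fits naturally. Initialization: P50 from the 50
#' percent crossing of linearly interpolated data, k from the 25-75 percent
#' pressure span (with the sign of the response direction), scale = 1.
#'
#' @param pressures numeric vector (mmHg), >= 4 distinct values.
#' @param currents normalized currents I/Imax.
#' @param fit_scale also fit the saturation scale (default TRUE).
#' @return object of class \code{"boltzmann_fit"}: list(P50, k, scale,
#'   residual, fitted(p) function).
#' @export
fit_boltzmann <- function(pressures, currents, fit_scale = TRUE) {
  stopifnot(length(pressures) == length(currents))
  if (length(unique(pressures)) < 4)
    stop("need at least 4 distinct pressures")
  df <- data.frame(p = as.numeric(pressures), i = as.numeric(currents))
  df <- df[order(df$p), ]
  lo <- min(df$i); hi <- max(df$i)
  rising <- stats::cor(df$p, df$i) >= 0
  half <- lo + 0.5 * (hi - lo)
  p50_0 <- tryCatch(stats::approx(df$i, df$p, xout = half, ties = mean)$y,
                    error = function(e) NA_real_)
  if (!is.finite(p50_0)) p50_0 <- stats::median(df$p)
  q25 <- tryCatch(stats::approx(df$i, df$p, xout = lo + 0.25 * (hi - lo),
                                ties = mean)$y, error = function(e) NA_real_)
  q75 <- tryCatch(stats::approx(df$i, df$p, xout = lo + 0.75 * (hi - lo),
                                ties = mean)$y, error = function(e) NA_real_)
  k_0 <- if (is.finite(q25) && is.finite(q75) && abs(q75 - q25) > 0)
    (q75 - q25) / (2 * log(3)) else diff(range(df$p)) / 4
  if (!rising) k_0 <- -abs(k_0) else k_0 <- abs(k_0)
  if (k_0 == 0) k_0 <- 1
  form <- if (fit_scale)
    i ~ scale / (1 + exp((P50 - p) / k)) else i ~ 1 / (1 + exp((P50 - p) / k))
  start <- if (fit_scale) list(P50 = p50_0, k = k_0, scale = max(hi, 1e-6))
           else list(P50 = p50_0, k = k_0)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Boltzmann fit did not converge: ", conditionMessage(e),
           " (start P50=", signif(p50_0, 4), ", k=", signif(k_0, 4), ")"))
  cf <- stats::coef(fit)
  sc <- if (fit_scale) cf[["scale"]] else 1
  structure(list(P50 = cf[["P50"]], k = cf[["k"]], scale = sc,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 fitted = function(p) sc / (1 + exp((cf[["P50"]] - p) / cf[["k"]]))),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: P50 = %.2f mmHg, k = %.2f mmHg, scale = %.3f (RMS resid %.3g)\n",
              x$P50, x$k, x$scale, x$residual))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed with the midrank convention for ties. For combined sample
#' size n1 + n2 <= 12 the two-tailed p-value is exact, by enumeration of
#' all C(n1+n2, n1) group assignments (p = share of assignments whose U
#' deviates from n1*n2/2 by at least as much as observed). Larger samples
#' use the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @param exact_max combined size up to which enumeration is used
#'   (default 12).
#' @return list(U, p, method).
#' @export
rank_sum_test <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tiecor)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p = p, method = method)
}
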