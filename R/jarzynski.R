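#' Work trace of a single steered trajectory
#'
#' Cumulative external work versus the driven-coordinate value, sampled
#' on a uniform grid shared by every trajectory of a run.
#'
#' @param time Times (ps) of the samples.
#' @param lambda Driven-coordinate values (monotone along the trace).
#' @param work Cumulative work (kcal/mol); must start at 0.
#' @param id Trajectory identifier.
#' @return A data frame of class `work_trace` with columns `time_ps`,
#'   `lambda`, `work_kcal_mol`.
#' @export
work_trace <- function(time, lambda, work, id = 1L) {
  stopifnot(length(time) == length(lambda), length(lambda) == length(work))
  if (length(work) && abs(work[1]) > 1e-9)
    stop("invalid work trace: cumulative work must start at 0")
  dl <- diff(lambda)
  if (length(dl) && any(dl > 0) && any(dl < 0))
    stop("invalid work trace: lambda must be monotone along the trace")
  structure(data.frame(time_ps = time, lambda = lambda,
                       work_kcal_mol = work),
            id = id, class = c("work_trace", "data.frame"))
}

# numerically safe log-mean-exp with max-shift
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski free-energy estimate from an ensemble of work values
#'
#' Computes the exponential work average
#' `-kBT * log( mean( exp(-W / kBT) ) )` with a max-shifted
#' log-mean-exp, so that large `|W|/kBT` cannot overflow. The estimate is
#' never larger than the arithmetic mean of the works (Jensen), matching
#' the second law.
#'
#' @param works Numeric vector of work values (kcal/mol).
#' @param temperature Temperature (K), > 0.
#' @return Free-energy difference estimate (kcal/mol).
#' @examples
#' jarzynski_estimate(c(0, 100), 298)
#' @export
jarzynski_estimate <- function(works, temperature = 298) {
  works <- works[is.finite(works)]
  if (length(works) < 1L)
    stop("estimation error: need at least one finite work value")
  if (temperature <= 0)
    stop("estimation error: temperature must be > 0")
  b <- 1 / kBT(temperature)
  -(1 / b) * .log_mean_exp(-b * works)
}

#' Bootstrap standard error of the Jarzynski estimate
#'
#' Standard deviation of [jarzynski_estimate()] over `n_boot` resamples
#' of the work ensemble with replacement. Deterministic for a fixed
#' seed. With fewer than two work values the error is undefined and
#' `Inf` is returned with a warning.
#'
#' @inheritParams jarzynski_estimate
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Seed for the resampling stream.
#' @return Standard error (kcal/mol).
#' @export
bootstrap_error <- function(works, temperature = 298, n_boot = 1000,
                            seed = 1) {
  if (n_boot < 100) stop("estimation error: n_boot must be >= 100")
  works <- works[is.finite(works)]
  n <- length(works)
  if (n < 2L) {
    warning("bootstrap error undefined for fewer than 2 works; returning Inf")
    return(Inf)
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  est <- apply(idx, 1, function(i) jarzynski_estimate(works[i], temperature))
  stats::sd(est)
}

#' Free-energy profile from an ensemble of work traces
#'
#' Applies the Jarzynski estimator per grid point of the driven
#' coordinate and attaches pointwise bootstrap errors (trajectories are
#' resampled whole, the same resample across the grid).
#'
#' @param traces List of [work_trace()] objects sharing one lambda grid.
#' @param temperature Temperature (K).
#' @param n_boot Bootstrap resamples for the pointwise errors.
#' @param seed Bootstrap seed.
#' @return A data frame of class `fe_profile` with columns `lambda`,
#'   `dF` (kcal/mol relative to the first grid point) and `err`.
#' @export
build_profile <- function(traces, temperature = 298, n_boot = 1000,
                          seed = 1) {
  stopifnot(length(traces) >= 1L)
  lam <- traces[[1]]$lambda
  for (tr in traces)
    if (length(tr$lambda) != length(lam) ||
        max(abs(tr$lambda - lam)) > 1e-9)
      stop("alignment error: work traces do not share a lambda grid")
  W <- vapply(traces, function(tr) tr$work_kcal_mol, numeric(length(lam)))
  W <- matrix(W, nrow = length(lam))
  dF <- apply(W, 1, jarzynski_estimate, temperature = temperature)
  m <- ncol(W)
  if (m >= 2L) {
    set.seed(seed)
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), n_boot, m)
    boot <- apply(idx, 1, function(i)
      apply(W[, i, drop = FALSE], 1, jarzynski_estimate,
            temperature = temperature))
    err <- apply(matrix(boot, nrow = length(lam)), 1, stats::sd)
  } else {
    err <- rep(0, length(lam))
  }
  err[1] <- 0  # dF(lambda0) is identically 0
  structure(data.frame(lambda = lam, dF = dF, err = err),
            n_traj = m, temperature = temperature,
            class = c("fe_profile", "data.frame"))
}

#' Location and value of the profile minimum
#'
#' Ties are broken toward the grid point closest to the schedule's end
#' (the last grid point of the trace).
#'
#' @param profile An `fe_profile` from [build_profile()].
#' @return List with `lambda`, `dF` and `err` at the minimum.
#' @export
profile_minimum <- function(profile) {
  if (!nrow(profile)) stop("estimation error: empty profile")
  mn <- min(profile$dF)
  cand <- which(profile$dF <= mn + 1e-12)
  i <- cand[length(cand)]   # grid runs lambda0 -> schedule end
  list(lambda = profile$lambda[i], dF = profile$dF[i], err = profile$err[i])
}

#' @export
plot.fe_profile <- function(x, ...) {
  graphics::plot(x$lambda, x$dF, type = "l", col = "blue",
                 xlab = "driven coordinate", ylab = "dF (kcal/mol)", ...)
  graphics::arrows(x$lambda, x$dF - x$err, x$lambda, x$dF + x$err,
                   length = 0.02, angle = 90, code = 3, col = "red")
  invisible(x)
}
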