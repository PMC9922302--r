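# Sampling-efficiency protocol: divergence-vs-compute traces for the
# generator and the simulator, plateau detection for the generator, and
# the simulator crossing time. Timing values are recorded but never
# asserted; the plateau/crossing logic is deterministic and testable on
# scripted traces.

#' Build a divergence-convergence trace
#'
#' For each sample size in the schedule, the radius-of-gyration divergence
#' ([kld_r()]) of the first-n sample against the fixed reference ensemble,
#' with wall-time accounting. Generator samples are drawn fresh through
#' [sample_ensemble()]; simulator traces take prefixes of an existing
#' trajectory's frames (prefix order = simulation time order).
#'
#' @param source `"generator"` or `"simulator"`.
#' @param reference_ens The long reference [conformational_ensemble()].
#' @param sample_schedule Increasing integer sample sizes.
#' @param model Trained GAN model (generator source).
#' @param sim_ens Simulator trajectory ensemble in frame order (simulator
#'   source); the schedule must not exceed its frame count.
#' @param time_per_frame Optional seconds of compute per simulator frame
#'   (used for the time axis instead of measuring, since stored
#'   trajectories were produced earlier).
#' @param seed Integer seed for generator sampling.
#' @return Object of class `efficiency_trace`: data.frame with columns
#'   `n`, `time_s`, `kld_r`, plus attribute `source`.
#' @export
kld_r_convergence_trace <- function(source = c("generator", "simulator"),
                                    reference_ens, sample_schedule,
                                    model = NULL, sim_ens = NULL,
                                    time_per_frame = NULL, seed = 1L) {
  source <- match.arg(source)
  sched <- as.integer(sample_schedule)
  if (any(diff(sched) <= 0L)) stop("sample schedule must be increasing")
  ref_rg <- rg_values(reference_ens)
  rows <- vector("list", length(sched))
  if (source == "generator") {
    stopifnot(!is.null(model))
    t0 <- proc.time()[["elapsed"]]
    gen <- sample_ensemble(model, reference_ens$sequence, max(sched),
                           seed = seed)
    # per-sample cost assumed uniform across the batch draw
    total_t <- proc.time()[["elapsed"]] - t0
    rg <- rg_values(gen)
    for (i in seq_along(sched)) {
      n <- sched[i]
      rows[[i]] <- data.frame(
        n = n, time_s = total_t * n / max(sched),
        kld_r = as.numeric(histogram_kld(ref_rg, rg[seq_len(n)])))
    }
  } else {
    stopifnot(!is.null(sim_ens))
    if (max(sched) > n_frames(sim_ens))
      stop("schedule exceeds the available simulator frames")
    rg <- rg_values(sim_ens)
    if (is.null(time_per_frame)) time_per_frame <- 1
    for (i in seq_along(sched)) {
      n <- sched[i]
      rows[[i]] <- data.frame(
        n = n, time_s = time_per_frame * n,
        kld_r = as.numeric(histogram_kld(ref_rg, rg[seq_len(n)])))
    }
  }
  structure(do.call(rbind, rows), source = source,
            class = c("efficiency_trace", "data.frame"))
}

#' Assemble a trace from precomputed values
#'
#' @param n,time_s,kld_r Equal-length vectors (sample sizes strictly
#'   increasing, times non-decreasing).
#' @param source `"generator"` or `"simulator"`.
#' @return An `efficiency_trace`.
#' @export
efficiency_trace <- function(n, time_s, kld_r,
                             source = c("generator", "simulator")) {
  source <- match.arg(source)
  stopifnot(length(n) == length(time_s), length(n) == length(kld_r))
  if (any(diff(n) <= 0)) stop("sample sizes must be strictly increasing")
  if (any(diff(time_s) < 0)) stop("times must be non-decreasing")
  structure(data.frame(n = n, time_s = time_s, kld_r = kld_r),
            source = source, class = c("efficiency_trace", "data.frame"))
}

#' Detect the generator's divergence plateau
#'
#' Walks the trace and stops at the first point after which the running
#' minimum divergence does not improve (beyond an absolute tolerance) over
#' the subsequent `window` additional samples. Returns the minimum
#' divergence reached so far and its elapsed time.
#'
#' @param trace A generator [efficiency_trace()].
#' @param window Additional samples over which no improvement must occur
#'   (default 1000).
#' @param tol Absolute tolerance on "does not decrease".
#' @return List with `kld_r_top`, `t_gen`, `n_at_plateau` and `converged`
#'   (FALSE when the trace never plateaus; the final point is then
#'   returned).
#' @export
detect_plateau <- function(trace, window = 1000L, tol = 1e-3) {
  if (!identical(attr(trace, "source"), "generator"))
    stop("plateau detection expects a generator trace")
  k <- trace$kld_r
  n <- trace$n
  run_min <- cummin(k)
  run_min_t <- trace$time_s[match(run_min, k)]  # time of first occurrence
  for (i in seq_along(n)) {
    later <- which(n > n[i] & n <= n[i] + window)
    if (length(later) == 0L) next  # no evidence inside the window yet
    if (all(k[later] >= run_min[i] - tol))
      return(list(kld_r_top = run_min[i], t_gen = run_min_t[i],
                  n_at_plateau = n[i], converged = TRUE))
  }
  last <- length(n)
  list(kld_r_top = run_min[last], t_gen = run_min_t[last],
       n_at_plateau = n[last], converged = FALSE)
}

#' Simulator crossing time
#'
#' Elapsed simulator time at the first trace prefix whose divergence
#' strictly improves over the generator's plateau value.
#'
#' @param trace A simulator [efficiency_trace()] (prefix-ordered frames).
#' @param kld_r_top Plateau divergence from [detect_plateau()].
#' @return List with `t_MD`, `n_at_crossing` and `crossed` (FALSE with
#'   `t_MD = NA` when the trace never improves on the plateau).
#' @export
simulator_crossing_time <- function(trace, kld_r_top) {
  if (!identical(attr(trace, "source"), "simulator"))
    stop("crossing time expects a simulator trace")
  hit <- which(trace$kld_r < kld_r_top)
  if (length(hit) == 0L)
    return(list(t_MD = NA_real_, n_at_crossing = NA_integer_,
                crossed = FALSE))
  i <- hit[1L]
  list(t_MD = trace$time_s[i], n_at_crossing = trace$n[i], crossed = TRUE)
}

#' Sampling-efficiency report
#'
#' @param traces List with the generator and simulator traces.
#' @param plateau Result of [detect_plateau()].
#' @param crossing Result of [simulator_crossing_time()].
#' @param repeats Optional numeric vector of `t_MD / t_gen` ratios from
#'   repeated runs (min/max are reported).
#' @return List with the `t_MD / t_gen` ratio (NA when either time is
#'   undefined), flags, and min/max over repeats.
#' @export
efficiency_report <- function(traces, plateau, crossing, repeats = NULL) {
  ratio <- if (isTRUE(plateau$converged) && isTRUE(crossing$crossed) &&
               plateau$t_gen > 0)
    crossing$t_MD / plateau$t_gen
  else NA_real_
  out <- list(kld_r_top = plateau$kld_r_top, t_gen = plateau$t_gen,
              t_MD = crossing$t_MD, ratio = ratio,
              converged = isTRUE(plateau$converged),
              crossed = isTRUE(crossing$crossed),
              ratio_min = if (!is.null(repeats)) min(repeats) else NA_real_,
              ratio_max = if (!is.null(repeats)) max(repeats) else NA_real_,
              n_traces = length(traces))
  class(out) <- "efficiency_report"
  out
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("KLD_r_top %.4f at t_gen %.3g s; t_MD %.3g s; ratio %.3g\n",
              x$kld_r_top, x$t_gen, x$t_MD, x$ratio))
  invisible(x)
}
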