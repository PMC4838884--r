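#' Draw a random per-edge parameter set
#'
#' Samples independent Hill coefficients and thresholds for every edge,
#' uniformly over the given intervals. In `coupled` mode one pair `(n, a)`
#' is drawn per edge (the two values share an edge but are still
#' independent across edges); in `independent` mode `n` and `a` are drawn
#' independently per edge as well — the distinction matters only for
#' reproducibility of the draw stream.
#'
#' @param net an `endo_network`
#' @param n_range interval for the Hill coefficient, within `[1, Inf)`
#'   (default `c(2, 5)`)
#' @param a_range interval for the threshold, within (0,1)
#'   (default `c(0.3, 0.7)`)
#' @param mode `"independent"` or `"coupled"`
#' @param seed RNG seed; the draw is deterministic given the seed
#' @return an `endo_params` in per-edge mode
#' @export
resample_parameters <- function(net, n_range = c(2, 5), a_range = c(0.3, 0.7),
                                mode = c("independent", "coupled"), seed = 1) {
  mode <- match.arg(mode)
  if (length(n_range) != 2 || n_range[1] > n_range[2] || n_range[1] < 1)
    stop("invalid n_range")
  if (length(a_range) != 2 || a_range[1] > a_range[2] ||
      a_range[1] <= 0 || a_range[2] >= 1)
    stop("invalid a_range")
  ne <- nrow(net$edges)
  set.seed(seed)
  if (mode == "independent") {
    n <- stats::runif(ne, n_range[1], n_range[2])
    a <- stats::runif(ne, a_range[1], a_range[2])
  } else {
    draws <- matrix(stats::runif(2 * ne), ncol = 2, byrow = TRUE)
    n <- n_range[1] + draws[, 1] * diff(n_range)
    a <- a_range[1] + draws[, 2] * diff(a_range)
  }
  hill_params(n = n, a = a, mode = "per_edge")
}

#' Attractor recurrence under random parameter resampling
#'
#' Repeatedly redraws per-edge Hill parameters, re-runs the attractor
#' search, and asks for each reference attractor whether a matching
#' attractor is still found. Matching is primarily by identity of the
#' >0.5-discretized activity profile — parameter changes move attractor
#' coordinates continuously but a robust phenotype keeps its on/off
#' pattern — with a max-norm distance fallback.
#'
#' @inheritParams resample_parameters
#' @param reference an `endo_attractors` computed at the reference
#'   parameters
#' @param n_resamples number of parameter draws (must be >= 1)
#' @param starts_per_resample random starts per re-search; may be smaller
#'   than a discovery run since only recurrence is measured (default 200)
#' @param match_tol max-norm radius for the distance fallback (default 0.2)
#' @param threshold discretization cut for profile matching (default 0.5)
#' @return an `endo_robustness`: list with `recurrence` (named fraction per
#'   reference attractor), `recurrence_matrix` (resample x attractor
#'   logical), `n_resamples`, `seed`, `parameter_ranges`
#' @export
recurrence_statistics <- function(net, reference, n_range = c(2, 5),
                                  a_range = c(0.3, 0.7), n_resamples = 50,
                                  seed = 1, starts_per_resample = 200,
                                  match_tol = 0.2, threshold = 0.5,
                                  mode = "independent") {
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (length(reference$points) == 0) stop("reference attractor set is empty")
  ref_states <- attractor_states(reference)
  ref_prof <- ref_states > threshold
  hits <- matrix(FALSE, n_resamples, nrow(ref_states),
                 dimnames = list(NULL, rownames(ref_states)))
  for (r in seq_len(n_resamples)) {
    base <- (seed %% 100000L) * 20000L
    pars <- resample_parameters(net, n_range, a_range, mode = mode,
                                seed = base + 2L * r)
    found <- sample_attractors(net, pars, n_starts = starts_per_resample,
                               seed = base + 2L * r + 1L)
    if (length(found$points) == 0) next
    fs <- attractor_states(found)
    fp <- fs > threshold
    for (i in seq_len(nrow(ref_states))) {
      prof_hit <- any(apply(fp, 1, function(p) all(p == ref_prof[i, ])))
      dist_hit <- any(apply(abs(sweep(fs, 2, ref_states[i, ])), 1, max) < match_tol)
      hits[r, i] <- prof_hit || dist_hit
    }
  }
  structure(list(recurrence = colMeans(hits), recurrence_matrix = hits,
                 n_resamples = n_resamples, seed = seed,
                 parameter_ranges = list(n = n_range, a = a_range),
                 match_tol = match_tol, threshold = threshold,
                 starts_per_resample = starts_per_resample),
            class = "endo_robustness")
}

#' @export
print.endo_robustness <- function(x, ...) {
  cat("Robustness report:", x$n_resamples, "parameter resamples, n in [",
      x$parameter_ranges$n[1], ",", x$parameter_ranges$n[2], "], a in [",
      x$parameter_ranges$a[1], ",", x$parameter_ranges$a[2], "]\n")
  cat("Recurrence per reference attractor:\n")
  for (id in names(x$recurrence))
    cat(sprintf("  %s  %.1f%%\n", id, 100 * x$recurrence[[id]]))
  invisible(x)
}
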