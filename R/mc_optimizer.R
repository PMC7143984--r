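#' Target function of the Monte Carlo search
#'
#' In \code{"r_train"} mode (the default) the target is the Pearson
#' correlation between the descriptor and the endpoint over the training
#' molecules; a zero-variance descriptor scores the sentinel value -1.
#' In \code{"balance"} mode, with a calibration subset supplied, the
#' target is \code{r_sub + r_cal - 0.1 * |r_sub - r_cal|}, rewarding
#' agreement between the sub-training and calibration correlations.
#'
#' @param dcw_values numeric descriptor values over the training set.
#' @param endpoints numeric endpoint values, same length.
#' @param mode \code{"r_train"} or \code{"balance"}.
#' @param calib logical vector marking the calibration subset (balance
#'   mode only).
#' @return the target value (numeric scalar).
#' @export
target_function <- function(dcw_values, endpoints, mode = "r_train",
                            calib = NULL) {
  x <- as.numeric(dcw_values); y <- as.numeric(endpoints)
  if (length(x) == 0L) stop("empty training set")
  if (length(x) != length(y)) stop("length mismatch")
  safe_r <- function(a, b) {
    if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
    stats::cor(a, b)
  }
  if (identical(mode, "r_train") || is.null(calib)) {
    return(safe_r(x, y))
  }
  if (!identical(mode, "balance")) stop("unknown target mode: ", mode)
  r_sub <- safe_r(x[!calib], y[!calib])
  r_cal <- safe_r(x[calib], y[calib])
  r_sub + r_cal - 0.1 * abs(r_sub - r_cal)
}

#' Seeded coordinate-wise Monte Carlo optimization of correlation weights
#'
#' Runs \code{epochs_N} passes over the active attributes.  In each pass
#' the attributes are visited in a freshly shuffled order; for each one a
#' move \code{CW' = CW +/- u} with \code{u ~ Uniform(0, step_max]} is
#' proposed and accepted only if the target function strictly increases
#' (greedy acceptance, so the per-epoch trace never decreases).  All
#' randomness comes from a private stream seeded from \code{seed}; the
#' global RNG state is untouched and identical inputs give bit-identical
#' results.
#'
#' @param attr_list list of per-molecule attribute multisets (training
#'   set), as from [extract_attributes()].
#' @param endpoints numeric endpoint vector aligned with \code{attr_list}.
#' @param config a [descriptor_config()]; supplies the rarity threshold
#'   and the default epoch count.
#' @param seed integer seed of the run.
#' @param epochs_N number of epochs; defaults to \code{config$epochs_N}.
#' @param step_max largest proposal step (default 0.1).
#' @param init_mode \code{"ones"} (all weights start at 1) or
#'   \code{"uniform"} (weights start Uniform(-1, 1)).
#' @param target \code{"r_train"} or \code{"balance"}.
#' @param calib optional logical vector marking a calibration subset.
#' @param early_stop_tol stop after an epoch whose improvement is at most
#'   this value; 0 (default) disables early stopping.
#' @return list of class \code{"mc_run"}: \code{weights} (named numeric),
#'   \code{blocked} (character), \code{trace} (per-epoch target values,
#'   value at initialization first), \code{accepted_moves},
#'   \code{calibration} (\code{C0}, \code{C1}), \code{seed},
#'   \code{target_value}.
#' @export
mc_optimize <- function(attr_list, endpoints, config = descriptor_config(),
                        seed = 1L, epochs_N = config$epochs_N,
                        step_max = 0.1, init_mode = c("ones", "uniform"),
                        target = c("r_train", "balance"), calib = NULL,
                        early_stop_tol = 0) {
  init_mode <- match.arg(init_mode)
  target <- match.arg(target)
  if (step_max <= 0) stop("`step_max` must be positive")
  if (length(attr_list) < 3L) stop("need at least 3 training molecules")
  active <- active_attributes(attr_list, config$threshold_T)
  if (length(active) == 0L) {
    stop("all attributes blocked at threshold T = ", config$threshold_T)
  }
  observed <- unique(unlist(lapply(attr_list, names)))
  blocked <- sort(setdiff(observed, active), method = "radix")
  m <- attribute_matrix(attr_list, active)
  y <- as.numeric(endpoints)

  res <- with_seed(seed, {
    w <- switch(init_mode,
                ones = rep(1, length(active)),
                uniform = stats::runif(length(active), -1, 1))
    names(w) <- active
    d <- as.numeric(m %*% w)
    best <- target_function(d, y, target, calib)
    trace <- best
    accepted <- 0L
    for (epoch in seq_len(max(epochs_N, 0L))) {
      order_j <- sample.int(length(active))
      for (j in order_j) {
        u <- stats::runif(1L, 0, step_max)
        s <- if (stats::runif(1L) < 0.5) -1 else 1
        # try CW + s*u first, then the mirror move if it did not improve;
        # once a direction is accepted keep sliding along it while the
        # target keeps strictly increasing
        for (delta in c(s * u, -s * u)) {
          d_new <- d + delta * m[, j]
          val <- target_function(d_new, y, target, calib)
          if (val > best) {
            repeat {
              w[j] <- w[j] + delta
              d <- d_new
              best <- val
              accepted <- accepted + 1L
              delta <- delta * 2          # geometric line search
              d_new <- d + delta * m[, j]
              val <- target_function(d_new, y, target, calib)
              if (val <= best) break
            }
            break
          }
        }
      }
      trace <- c(trace, best)
      if (early_stop_tol > 0 &&
          trace[length(trace)] - trace[length(trace) - 1L] <= early_stop_tol) {
        break
      }
    }
    list(w = w, trace = trace, accepted = accepted, best = best, d = d)
  })

  cal <- calibrate_linear(res$d, y)
  structure(list(weights = res$w, blocked = blocked, trace = res$trace,
                 accepted_moves = res$accepted, calibration = cal,
                 seed = as.integer(seed), target_value = res$best),
            class = "mc_run")
}

#' Run an ensemble of independent optimizations
#'
#' Repeats [mc_optimize()] with one seed per run, the scheme used to probe
#' promoter stability (typically three runs per endpoint).
#'
#' @inheritParams mc_optimize
#' @param seeds integer vector of run seeds (length >= 1); duplicates
#'   trigger a warning, not an error.
#' @param ... further arguments passed to [mc_optimize()].
#' @return list of \code{"mc_run"} objects, in seed order.
#' @export
run_ensemble <- function(attr_list, endpoints, config = descriptor_config(),
                         seeds, ...) {
  if (missing(seeds) || length(seeds) == 0L) stop("at least one seed required")
  if (anyDuplicated(seeds)) warning("duplicate seeds in ensemble")
  lapply(seeds, function(s) {
    mc_optimize(attr_list, endpoints, config = config, seed = s, ...)
  })
}
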