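#' Fit a one-variable correlation-weight QSAR model
#'
#' The workhorse of the package.  Attributes are extracted from every
#' molecule's SMILES, rare attributes are blocked at the rarity threshold
#' \code{T}, the correlation weights of the remaining attributes are tuned
#' by a seeded coordinate-wise Monte Carlo search maximizing the training
#' correlation between the descriptor \code{DCW(T, N)} and the endpoint,
#' and the final descriptor is mapped to the endpoint scale by ordinary
#' least squares: \code{endpoint = C0 + C1 * DCW}.
#'
#' @param data data frame with columns \code{id}, \code{smiles},
#'   \code{endpoint} (see [read_dataset()]).
#' @param split optional split assignment: a data frame with columns
#'   \code{id} and \code{set} (values \code{"training"},
#'   \code{"validation"} and optionally \code{"calibration"}), as from
#'   [read_split()] or [make_splits()].  When omitted every molecule
#'   trains the model.
#' @param config a [descriptor_config()].
#' @param seed integer seed; the fit is bit-reproducible from
#'   \code{(data, split, config, seed)}.
#' @param split_id free-text label recorded in the model for provenance.
#' @param ... further optimizer settings passed to [mc_optimize()]
#'   (\code{step_max}, \code{init_mode}, \code{target},
#'   \code{early_stop_tol}, \code{epochs_N}).
#' @return an object of class \code{"cw_qsar"} with components
#'   \code{config}, \code{weights}, \code{blocked}, \code{calibration}
#'   (\code{C0}, \code{C1}), \code{seed}, \code{split_id}, \code{trace},
#'   \code{data} (per-molecule table with set, DCW, prediction, residual),
#'   and \code{target_value}.
#' @examples
#' set.seed(1)
#' ds <- synth_dataset(n = 40, seed = 3, noise_sd = 0)
#' fit <- cw_qsar(ds$data, ds$split, descriptor_config(epochs_N = 5), seed = 2)
#' fit
#' @export
cw_qsar <- function(data, split = NULL, config = descriptor_config(),
                    seed = 1L, split_id = NULL, ...) {
  stopifnot(is.data.frame(data),
            all(c("id", "smiles", "endpoint") %in% names(data)))
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) stop("duplicate molecule ids")
  sets <- assign_sets(data$id, split)
  if (is.null(split_id)) {
    split_id <- if (is.null(split)) "all-training" else "user-split"
  }
  attrs <- lapply(data$smiles, extract_attributes, config = config)
  tr <- sets == "training" | sets == "calibration"
  if (sum(tr) < 3L) stop("need at least 3 training molecules")
  calib <- if (any(sets == "calibration")) {
    (sets == "calibration")[tr]
  } else NULL
  run <- mc_optimize(attrs[tr], data$endpoint[tr], config = config,
                     seed = seed, calib = calib, ...)
  d_all <- vapply(attrs, function(a) as.numeric(dcw(a, run$weights)),
                  numeric(1L))
  oov <- vapply(attrs, function(a) attr(dcw(a, run$weights), "oov"),
                numeric(1L))
  pred <- run$calibration$C0 + run$calibration$C1 * d_all
  tab <- data.frame(id = data$id, smiles = data$smiles,
                    endpoint = data$endpoint, set = sets, dcw = d_all,
                    predicted = pred, residual = data$endpoint - pred,
                    oov = oov, stringsAsFactors = FALSE)
  structure(list(config = config, weights = run$weights,
                 blocked = run$blocked, calibration = run$calibration,
                 seed = as.integer(seed), split_id = split_id,
                 trace = run$trace, target_value = run$target_value,
                 accepted_moves = run$accepted_moves, data = tab,
                 call = match.call()),
            class = "cw_qsar")
}

# resolve a split argument into a set label per id
assign_sets <- function(ids, split) {
  if (is.null(split)) {
    return(rep("training", length(ids)))
  }
  if (is.data.frame(split)) {
    stopifnot(all(c("id", "set") %in% names(split)))
    map <- stats::setNames(as.character(split$set), as.character(split$id))
  } else if (!is.null(names(split))) {
    map <- stats::setNames(as.character(split), names(split))
  } else {
    stop("`split` must be a data frame (id, set) or a named vector")
  }
  bad <- setdiff(names(map), ids)
  if (length(bad)) stop("split names unknown ids: ", paste(bad, collapse = ", "))
  missing <- setdiff(ids, names(map))
  if (length(missing)) {
    stop("ids missing from split: ", paste(missing, collapse = ", "))
  }
  sets <- unname(map[ids])
  ok <- c("training", "calibration", "validation")
  if (!all(sets %in% ok)) {
    stop("split sets must be among: ", paste(ok, collapse = ", "))
  }
  sets
}

#' @export
print.cw_qsar <- function(x, digits = 4L, ...) {
  cat("One-variable correlation-weight QSAR model\n")
  print(x$config)
  cat("Seed:", x$seed, "  Split:", x$split_id, "\n")
  cat(sprintf("Calibration: endpoint = %.*g + %.*g * DCW\n",
              digits, x$calibration$C0, digits, x$calibration$C1))
  cat("Active attributes:", length(x$weights),
      "  Blocked:", length(x$blocked), "\n")
  n_set <- table(x$data$set)
  cat("Molecules:", paste(sprintf("%s = %d", names(n_set), n_set),
                          collapse = ", "), "\n")
  tr <- x$data$set %in% c("training", "calibration")
  r2 <- stats::cor(x$data$endpoint[tr], x$data$predicted[tr])^2
  cat(sprintf("Training r^2: %.*g\n", digits, r2))
  if (any(x$data$set == "validation")) {
    v <- x$data$set == "validation"
    r2v <- stats::cor(x$data$endpoint[v], x$data$predicted[v])^2
    cat(sprintf("Validation r^2: %.*g\n", digits, r2v))
  }
  invisible(x)
}

#' @export
coef.cw_qsar <- function(object, ...) {
  c(C0 = object$calibration$C0, C1 = object$calibration$C1)
}

#' Correlation weights of a fitted model
#'
#' @param object a fitted [cw_qsar()] model.
#' @param include_blocked also list blocked attributes (weight 0).
#' @return named numeric vector of correlation weights.
#' @export
correlation_weights <- function(object, include_blocked = FALSE) {
  stopifnot(inherits(object, "cw_qsar"))
  w <- object$weights
  if (include_blocked && length(object$blocked)) {
    w <- c(w, stats::setNames(rep(0, length(object$blocked)), object$blocked))
    w <- w[order(names(w), method = "radix")]
  }
  w
}

#' @export
predict.cw_qsar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(stats::setNames(object$data$predicted, object$data$id))
  }
  smiles <- if (is.data.frame(newdata)) {
    stopifnot("smiles" %in% names(newdata))
    newdata$smiles
  } else {
    as.character(newdata)
  }
  attrs <- lapply(smiles, extract_attributes, config = object$config)
  d <- vapply(attrs, function(a) as.numeric(dcw(a, object$weights)),
              numeric(1L))
  object$calibration$C0 + object$calibration$C1 * d
}

#' @export
residuals.cw_qsar <- function(object, ...) {
  stats::setNames(object$data$residual, object$data$id)
}

#' @export
fitted.cw_qsar <- function(object, ...) {
  tr <- object$data$set %in% c("training", "calibration")
  stats::setNames(object$data$predicted[tr], object$data$id[tr])
}

#' Summarize a fitted model with the full criteria suite
#'
#' Computes the predictive-potential criteria report (Pearson r, CCC,
#' through-origin statistics, the Q2 family, rm2 metrics, IIC and the
#' Golbraikh-Tropsha checks) for the training set and, when present, the
#' validation set.
#'
#' @param object a fitted [cw_qsar()] model.
#' @param ... unused.
#' @return object of class \code{"summary.cw_qsar"}: a list of
#'   [criteria_report()] objects, one per set.
#' @export
summary.cw_qsar <- function(object, ...) {
  tab <- object$data
  tr <- tab$set %in% c("training", "calibration")
  ctx <- training_context(tab$endpoint[tr])
  out <- list(training = criteria_report(tab$endpoint[tr], tab$predicted[tr],
                                         context = ctx))
  for (s in intersect(c("calibration", "validation"), unique(tab$set))) {
    i <- tab$set == s
    if (sum(i) >= 3L) {
      out[[s]] <- criteria_report(tab$endpoint[i], tab$predicted[i],
                                  context = ctx)
    }
  }
  structure(list(reports = out, model = object), class = "summary.cw_qsar")
}

#' @export
print.summary.cw_qsar <- function(x, ...) {
  print(x$model)
  for (nm in names(x$reports)) {
    cat("\n--", nm, "set --\n")
    print(x$reports[[nm]])
  }
  invisible(x)
}

#' Diagnostic plots for a fitted model
#'
#' \code{which = 1} draws observed vs predicted endpoints, one symbol per
#' set; \code{which = 2} draws the Monte Carlo target-function trace.
#'
#' @param x a fitted [cw_qsar()] model.
#' @param which plots to draw (subset of \code{1:2}).
#' @param ... passed to the underlying plotting calls.
#' @export
plot.cw_qsar <- function(x, which = 1L, ...) {
  tab <- x$data
  if (1L %in% which) {
    pch <- ifelse(tab$set == "validation", 17L,
                  ifelse(tab$set == "calibration", 15L, 1L))
    graphics::plot(tab$predicted, tab$endpoint, pch = pch,
                   xlab = "Predicted endpoint", ylab = "Observed endpoint",
                   main = "Correlation-weight QSAR", ...)
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", pch = c(1L, 15L, 17L),
                     legend = c("training", "calibration", "validation"),
                     bty = "n")
  }
  if (2L %in% which) {
    graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "s",
                   xlab = "Epoch", ylab = "Target function",
                   main = "Monte Carlo trace", ...)
  }
  invisible(x)
}
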