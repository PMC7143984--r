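#' Descriptor configuration
#'
#' Describes one DCW(T, N) descriptor: the rarity threshold \code{T}
#' (minimum number of distinct training molecules an attribute must occur
#' in to stay active), the number of Monte Carlo epochs \code{N}, and the
#' enabled attribute families.
#'
#' Three family presets mirror the common model variants:
#' \describe{
#'   \item{\code{"smiles"}}{local Sk/SSk plus global BOND/NOSP/HALO/PAIR
#'     attributes — the SMILES-only descriptor.}
#'   \item{\code{"hybrid_ec"}}{Sk/SSk plus the graph invariants EC0 and
#'     EC1 (vertex degree and first-order Morgan connectivity).}
#'   \item{\code{"hybrid_rings"}}{Sk/SSk plus the C5/C6 ring codes.}
#' }
#'
#' @param threshold_T positive integer rarity threshold (default 1).
#' @param epochs_N non-negative integer count of optimization epochs
#'   (default 10).
#' @param families either a preset name above or a character vector drawn
#'   from \code{c("sk", "ssk", "bond", "nosp", "halo", "pair", "ec0",
#'   "ec1", "rings", "nnc")}.
#' @return an object of class \code{"descriptor_config"}.
#' @examples
#' descriptor_config()                        # DCW(1, 10), SMILES families
#' descriptor_config(families = "hybrid_ec")
#' @export
descriptor_config <- function(threshold_T = 1L, epochs_N = 10L,
                              families = "smiles") {
  threshold_T <- as.integer(threshold_T)
  epochs_N <- as.integer(epochs_N)
  if (is.na(threshold_T) || threshold_T < 1L) {
    stop("`threshold_T` must be a positive integer")
  }
  if (is.na(epochs_N) || epochs_N < 0L) {
    stop("`epochs_N` must be a non-negative integer")
  }
  presets <- list(
    smiles = c("sk", "ssk", "bond", "nosp", "halo", "pair"),
    hybrid_ec = c("sk", "ssk", "ec0", "ec1"),
    hybrid_rings = c("sk", "ssk", "rings")
  )
  if (length(families) == 1L && families %in% names(presets)) {
    families <- presets[[families]]
  }
  known <- c("sk", "ssk", "bond", "nosp", "halo", "pair",
             "ec0", "ec1", "rings", "nnc")
  bad <- setdiff(families, known)
  if (length(bad)) stop("unknown attribute families: ", paste(bad, collapse = ", "))
  structure(list(threshold_T = threshold_T, epochs_N = epochs_N,
                 families = families),
            class = "descriptor_config")
}

#' @export
print.descriptor_config <- function(x, ...) {
  cat("DCW(", x$threshold_T, ", ", x$epochs_N, ") descriptor; families: ",
      paste(x$families, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Active attributes of a training set
#'
#' An attribute is active when it occurs in at least \code{T} distinct
#' training molecules; all other observed attributes are blocked (their
#' correlation weight is fixed at zero).
#'
#' @param attr_list list of per-molecule attribute multisets, as produced
#'   by [extract_attributes()].
#' @param threshold_T positive integer rarity threshold.
#' @return character vector of active attribute keys (sorted).
#' @export
active_attributes <- function(attr_list, threshold_T = 1L) {
  threshold_T <- as.integer(threshold_T)
  if (is.na(threshold_T) || threshold_T < 1L) {
    stop("`threshold_T` must be a positive integer")
  }
  if (length(attr_list) == 0L) stop("empty training set")
  presence <- unlist(lapply(attr_list, function(a) unique(names(a))))
  tab <- table(presence)
  sort(names(tab)[tab >= threshold_T], method = "radix")
}

#' Descriptor of correlation weights for one molecule
#'
#' Sums the correlation weights of a molecule's attributes, respecting
#' multiplicity.  Attributes absent from the weight table contribute zero;
#' their count is returned as the \code{"oov"} attribute, a crude
#' applicability-domain signal.
#'
#' @param attrs attribute multiset from [extract_attributes()].
#' @param weights named numeric vector of correlation weights.
#' @return the DCW value (numeric scalar) with attribute \code{"oov"}
#'   giving the number of out-of-vocabulary attribute instances.
#' @examples
#' a <- extract_attributes("CCO")
#' dcw(a, setNames(rep(1, length(a)), names(a)))  # = instance count
#' @export
dcw <- function(attrs, weights) {
  if (length(attrs) == 0L) {
    return(structure(0, oov = 0L))
  }
  idx <- match(names(attrs), names(weights))
  known <- !is.na(idx)
  val <- sum(weights[idx[known]] * attrs[known])
  structure(val, oov = sum(attrs[!known]))
}

#' Ordinary least-squares calibration of the one-variable model
#'
#' Fits \code{endpoint = C0 + C1 * DCW} by least squares.
#'
#' @param dcw_values numeric vector of descriptor values.
#' @param endpoints numeric vector of endpoint values, same length.
#' @return list with \code{C0} (intercept) and \code{C1} (slope).
#' @export
calibrate_linear <- function(dcw_values, endpoints) {
  x <- as.numeric(dcw_values); y <- as.numeric(endpoints)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("calibration needs at least 3 points")
  if (stats::var(x) <= 0) {
    stop("degenerate model: descriptor has zero variance")
  }
  c1 <- stats::cov(x, y) / stats::var(x)
  c0 <- mean(y) - c1 * mean(x)
  list(C0 = c0, C1 = c1)
}

# attribute-count design matrix: molecules x active keys; used by the
# optimizer so a single-weight update is a rank-one descriptor update
attribute_matrix <- function(attr_list, keys) {
  m <- matrix(0, nrow = length(attr_list), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(attr_list)) {
    a <- attr_list[[i]]
    idx <- match(names(a), keys)
    keep <- !is.na(idx)
    m[i, idx[keep]] <- a[keep]
  }
  m
}
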