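# Promoter-stability analysis: attributes whose correlation weight keeps
# the same sign across independent optimization runs are "promoters" of an
# endpoint increase (+1) or decrease (-1); sign-unstable or blocked
# attributes are 0.  Counting agreeing/opposing stable signs between two
# endpoints' models quantifies endpoint similarity/dissimilarity.

#' Classify attributes as stable promoters across optimization runs
#'
#' @param runs a list (length >= 2) of correlation-weight tables for one
#'   endpoint: named numeric vectors, [mc_optimize()] results, or fitted
#'   [cw_qsar()] models (blocked attributes count as weight 0).
#' @param endpoint_id label for the endpoint.
#' @return object of class \code{"stability_profile"}: list with
#'   \code{endpoint_id}, \code{labels} (named integer vector in
#'   \{-1, 0, +1\}) and \code{runs}.
#' @examples
#' runs <- list(c(A = 0.3, B = -0.2), c(A = 0.1, B = 0.4))
#' classify_promoters(runs, "toy")$labels
#' @export
classify_promoters <- function(runs, endpoint_id = "endpoint") {
  if (!is.list(runs) || length(runs) < 2L) {
    stop("need at least 2 runs to assess stability")
  }
  tables <- lapply(runs, extract_weight_table)
  universes <- lapply(tables, names)
  shared <- Reduce(intersect, universes)
  if (length(shared) == 0L) stop("runs have disjoint attribute universes")
  keys <- sort(unique(unlist(universes)), method = "radix")
  signs <- vapply(tables, function(w) {
    v <- rep(0, length(keys))
    v[match(names(w), keys)] <- w
    sign(v)
  }, numeric(length(keys)))
  signs <- matrix(signs, nrow = length(keys))
  labels <- ifelse(apply(signs > 0, 1L, all), 1L,
                   ifelse(apply(signs < 0, 1L, all), -1L, 0L))
  new_stability_profile(endpoint_id, stats::setNames(as.integer(labels), keys),
                        length(runs))
}

extract_weight_table <- function(x) {
  if (inherits(x, "cw_qsar")) return(correlation_weights(x, include_blocked = TRUE))
  if (inherits(x, "mc_run")) {
    w <- x$weights
    if (length(x$blocked)) {
      w <- c(w, stats::setNames(rep(0, length(x$blocked)), x$blocked))
    }
    return(w)
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("cannot interpret run as a correlation-weight table")
}

new_stability_profile <- function(endpoint_id, labels, runs) {
  stopifnot(is.integer(labels), !is.null(names(labels)), runs >= 2L)
  structure(list(endpoint_id = as.character(endpoint_id), labels = labels,
                 runs = as.integer(runs)),
            class = "stability_profile")
}

#' Build a stability profile from per-run promoter signs
#'
#' Used for sign tables recorded as \code{"+"} / \code{"-"} marks (one
#' column per run) rather than numeric weights.
#'
#' @param endpoint_id label for the endpoint.
#' @param signs character matrix: rows named by attribute key, one column
#'   per run, entries \code{"+"}, \code{"-"} or anything else (unstable).
#' @return a \code{"stability_profile"}.
#' @export
profile_from_signs <- function(endpoint_id, signs) {
  stopifnot(is.matrix(signs), !is.null(rownames(signs)), ncol(signs) >= 2L)
  keys <- normalize_key(rownames(signs))
  labels <- apply(signs, 1L, function(row) {
    if (all(row == "+")) 1L else if (all(row == "-")) -1L else 0L
  })
  new_stability_profile(endpoint_id, stats::setNames(as.integer(labels), keys),
                        ncol(signs))
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("Stability profile for '", x$endpoint_id, "' (", x$runs, " runs): ",
      sum(x$labels == 1L), " stable increase, ", sum(x$labels == -1L),
      " stable decrease, ", sum(x$labels == 0L), " unstable\n", sep = "")
  invisible(x)
}

#' Similarity and dissimilarity of two endpoints
#'
#' Counts attributes whose stable promoter sign agrees (similarity) or is
#' opposite (dissimilarity) between two profiles; unstable attributes
#' never count.  Profiles are compared over the union of their attribute
#' universes, missing attributes being unstable.
#'
#' @param a,b \code{"stability_profile"} objects.
#' @return named integer vector \code{c(similarity, dissimilarity)}.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "stability_profile"), inherits(b, "stability_profile"))
  keys <- union(names(a$labels), names(b$labels))
  la <- lb <- stats::setNames(rep(0L, length(keys)), keys)
  la[names(a$labels)] <- a$labels
  lb[names(b$labels)] <- b$labels
  c(similarity = sum(la == lb & la != 0L),
    dissimilarity = sum(la == -lb & la != 0L))
}

#' Pairwise endpoint similarity/dissimilarity matrices
#'
#' @param profiles list (length >= 2) of \code{"stability_profile"}
#'   objects.
#' @return object of class \code{"similarity_matrix"}: list with
#'   \code{endpoints}, symmetric integer matrices \code{similarity}
#'   (diagonal = number of stable attributes per endpoint) and
#'   \code{dissimilarity} (diagonal 0).
#' @export
similarity_matrix <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("need at least 2 profiles")
  }
  stopifnot(all(vapply(profiles, inherits, TRUE, "stability_profile")))
  k <- length(profiles)
  ids <- vapply(profiles, `[[`, "", "endpoint_id")
  sim <- dis <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    sim[i, i] <- sum(profiles[[i]]$labels != 0L)
    for (j in seq_len(k)) {
      if (j <= i) next
      cmp <- compare_profiles(profiles[[i]], profiles[[j]])
      sim[i, j] <- sim[j, i] <- cmp[["similarity"]]
      dis[i, j] <- dis[j, i] <- cmp[["dissimilarity"]]
    }
  }
  structure(list(endpoints = ids, similarity = sim, dissimilarity = dis),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Similarity\n"); print(x$similarity)
  cat("Dissimilarity\n"); print(x$dissimilarity)
  invisible(x)
}

#' Split-by-run promoter consistency table
#'
#' For each cohort (e.g. male and female rats) and each attribute, marks
#' with 1 every (split, run) cell whose correlation weight is positive,
#' then totals the marks per attribute row and per cohort.
#'
#' @param cohorts named list, one entry per cohort.  Each entry is either
#'   a list of correlation-weight tables named by \code{(split, run)}
#'   cell, or a ready-made 0/1 indicator matrix (rows = attribute keys,
#'   columns = cells).  All cohorts must have the same cells and every
#'   cell must be present.
#' @return object of class \code{"consistency_table"}: list with
#'   \code{cells} (named list of indicator matrices over the common
#'   attribute rows), \code{row_totals} (matrix attributes x cohorts) and
#'   \code{grand_totals}.
#' @export
consistency_table <- function(cohorts) {
  if (!is.list(cohorts) || is.null(names(cohorts)) || length(cohorts) < 1L) {
    stop("`cohorts` must be a named list")
  }
  as_indicator <- function(x) {
    if (is.matrix(x)) {
      if (is.null(rownames(x))) stop("indicator matrix needs attribute rownames")
      if (anyNA(x)) stop("missing cells in consistency design")
      m <- (x > 0) * 1L
      rownames(m) <- normalize_key(rownames(m))
      return(m)
    }
    if (!is.list(x) || is.null(names(x))) {
      stop("cohort must be an indicator matrix or a named list of weight tables")
    }
    tables <- lapply(x, extract_weight_table)
    keys <- sort(unique(unlist(lapply(tables, names))), method = "radix")
    m <- vapply(tables, function(w) {
      v <- rep(0, length(keys))
      v[match(names(w), keys)] <- w
      (v > 0) * 1L
    }, integer(length(keys)))
    m <- matrix(m, nrow = length(keys), dimnames = list(keys, names(tables)))
    m
  }
  cells <- lapply(cohorts, as_indicator)
  design <- lapply(cells, colnames)
  if (length(unique(vapply(design, length, 1L))) != 1L) {
    stop("cohorts disagree on the (split, run) design: ",
         paste(vapply(design, length, 1L), collapse = " vs "))
  }
  keys <- sort(unique(unlist(lapply(cells, rownames))), method = "radix")
  cells <- lapply(cells, function(m) {
    full <- matrix(0L, length(keys), ncol(m), dimnames = list(keys, colnames(m)))
    full[rownames(m), ] <- m
    full
  })
  row_totals <- vapply(cells, rowSums, numeric(length(keys)))
  row_totals <- matrix(row_totals, nrow = length(keys),
                       dimnames = list(keys, names(cells)))
  structure(list(cells = cells, row_totals = row_totals,
                 grand_totals = colSums(row_totals)),
            class = "consistency_table")
}

#' @export
print.consistency_table <- function(x, ...) {
  cat("Promoter consistency over", ncol(x$cells[[1L]]), "(split, run) cells\n")
  print(x$row_totals)
  cat("Grand totals:\n"); print(x$grand_totals)
  invisible(x)
}

#' Render a side-by-side promoter report for two endpoints
#'
#' Produces the classic text block: attributes with agreeing stable signs
#' first, then the disagreeing ones, with one \code{+}/\code{-} column per
#' run of each endpoint and the 12-character keys verbatim.
#'
#' @param a,b \code{"stability_profile"} objects.
#' @return character vector of report lines (invisibly printable).
#' @export
render_profile_report <- function(a, b) {
  stopifnot(inherits(a, "stability_profile"), inherits(b, "stability_profile"))
  keys <- union(names(a$labels), names(b$labels))
  la <- lb <- stats::setNames(rep(0L, length(keys)), keys)
  la[names(a$labels)] <- a$labels
  lb[names(b$labels)] <- b$labels
  mark <- function(l, runs) {
    paste(rep(c("+", "-", "?")[match(l, c(1L, -1L, 0L))], runs), collapse = " ")
  }
  agree <- keys[la == lb & la != 0L]
  oppose <- keys[la == -lb & la != 0L]
  line <- function(k) {
    sprintf("%-12s  %s  %s", k, mark(la[[k]], a$runs), mark(lb[[k]], b$runs))
  }
  c(sprintf("%s (#1) vs. %s (#2)", a$endpoint_id, b$endpoint_id),
    if (length(agree)) {
      c("# agreeing promoters", vapply(agree, line, "", USE.NAMES = FALSE))
    },
    if (length(oppose)) {
      c("# opposing promoters", vapply(oppose, line, "", USE.NAMES = FALSE))
    })
}

# normalize attribute keys as printed in reports into the canonical
# dialect: pad to 12 chars with '.', re-render PAIR keys (accepting the
# '.'-filled dialect and upper-case halogens)
normalize_key <- function(keys) {
  vapply(keys, function(k) {
    if (nchar(k) < KEY_WIDTH) k <- pad_field(k, KEY_WIDTH)
    if (nchar(k) != KEY_WIDTH) stop("attribute key not 12 characters: ", k)
    if (substr(k, 1L, 4L) == "++++") {
      strip <- function(x) gsub("[-=.]+$", "", x)
      fix_case <- function(f) {
        i <- match(toupper(f), toupper(PAIR_FEATURES))
        if (is.na(i)) stop("unknown PAIR feature in key: ", k)
        PAIR_FEATURES[i]
      }
      f1 <- fix_case(strip(substr(k, 5L, 8L)))
      f2 <- fix_case(strip(substr(k, 9L, 12L)))
      return(pair_key(f1, f2))
    }
    k
  }, character(1L), USE.NAMES = FALSE)
}
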