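# Readers and writers for the plain-text interchange formats: datasets
# (id / smiles / endpoint), split assignments (id / set), model documents
# (JSON), promoter-sign tables and criteria reports (TSV).

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a molecule dataset
#'
#' Expects a delimited text file with a mandatory header naming at least
#' \code{id}, \code{smiles} and \code{endpoint}; the delimiter (tab or
#' comma) is sniffed from the header line.  SMILES whitespace is
#' stripped; malformed rows are reported with their line number.
#'
#' @param path file path.
#' @return data frame with columns \code{id}, \code{smiles},
#'   \code{endpoint} (and \code{set} when present).
#' @export
read_dataset <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", colClasses = "character")
  need <- c("id", "smiles", "endpoint")
  if (!all(need %in% names(df))) {
    stop("dataset header must name columns: ", paste(need, collapse = ", "))
  }
  lines <- seq_len(nrow(df)) + 1L
  df$smiles <- gsub("[[:space:]]", "", df$smiles)
  if (any(df$smiles == "")) {
    stop("empty SMILES at line ", lines[which(df$smiles == "")[1L]])
  }
  dup <- duplicated(df$id) | duplicated(df$id, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate id '", df$id[which(duplicated(df$id))[1L]],
         "' at lines ", paste(lines[dup & df$id == df$id[which(duplicated(df$id))[1L]]],
                              collapse = " and "))
  }
  endpoint <- suppressWarnings(as.numeric(df$endpoint))
  bad <- is.na(endpoint) | !is.finite(endpoint)
  if (any(bad)) stop("unparseable endpoint at line ", lines[which(bad)[1L]])
  out <- data.frame(id = df$id, smiles = df$smiles, endpoint = endpoint,
                    stringsAsFactors = FALSE)
  if ("set" %in% names(df)) out$set <- df$set
  out
}

#' @rdname read_dataset
#' @param dataset data frame to write.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a split assignment
#'
#' A two-column delimited file \code{id} / \code{set}, where every set is
#' one of training, calibration or validation.  When a dataset is
#' supplied the assignment must cover its ids exactly once each.
#'
#' @param path file path.
#' @param dataset optional data frame with an \code{id} column to
#'   validate coverage against.
#' @return data frame with columns \code{id}, \code{set}; attribute
#'   \code{"counts"} holds the per-set sizes.
#' @export
read_split <- function(path, dataset = NULL) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "set") %in% names(df))) {
    stop("split header must name columns: id, set")
  }
  if (anyDuplicated(df$id)) {
    stop("id '", df$id[which(duplicated(df$id))[1L]],
         "' appears more than once in the split")
  }
  ok <- c("training", "calibration", "validation")
  if (!all(df$set %in% ok)) {
    stop("split sets must be among: ", paste(ok, collapse = ", "))
  }
  if (!is.null(dataset)) {
    unknown <- setdiff(df$id, as.character(dataset$id))
    if (length(unknown)) {
      stop("split names unknown ids: ", paste(unknown, collapse = ", "))
    }
    missing <- setdiff(as.character(dataset$id), df$id)
    if (length(missing)) {
      stop("ids missing from split: ", paste(missing, collapse = ", "))
    }
  }
  out <- data.frame(id = df$id, set = df$set, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$set)
  out
}

#' Read a wide table of several split assignments
#'
#' A TSV with an \code{id} column and one column per split, each entry a
#' set label; returns one (id, set) split per column, each validated as
#' in [read_split()].
#'
#' @param path file path.
#' @return named list of split data frames.
#' @export
read_split_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!("id" %in% names(df))) stop("missing 'id' column")
  cols <- setdiff(names(df), "id")
  if (length(cols) == 0L) stop("no split columns")
  out <- lapply(cols, function(cl) {
    s <- data.frame(id = df$id, set = df[[cl]], stringsAsFactors = FALSE)
    ok <- c("training", "calibration", "validation")
    if (!all(s$set %in% ok)) {
      stop("split '", cl, "' has sets outside: ", paste(ok, collapse = ", "))
    }
    attr(s, "counts") <- table(s$set)
    s
  })
  stats::setNames(out, cols)
}

#' @rdname read_split
#' @param split data frame to write.
#' @export
write_split <- function(split, path) {
  utils::write.table(split[c("id", "set")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fitted model to a self-contained JSON document
#'
#' The document carries the descriptor configuration, seed, split label,
#' blocked attributes, the weight map (17 significant digits, so a
#' read-back is bit-stable) and the linear calibration.
#'
#' @param model a fitted [cw_qsar()] model.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cw_qsar"))
  doc <- list(
    format = "cwqsar-model",
    version = 1L,
    config = list(threshold_T = model$config$threshold_T,
                  epochs_N = model$config$epochs_N,
                  families = model$config$families),
    seed = model$seed,
    split_id = model$split_id,
    calibration = list(C0 = model$calibration$C0, C1 = model$calibration$C1),
    blocked = as.list(model$blocked),
    weights = as.list(model$weights)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @return \code{read_model} returns a \code{"cw_qsar"} object (without
#'   the fitted-data table, which is not part of the document).
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "cwqsar-model")) {
    stop("not a cwqsar model document: ", path)
  }
  config <- descriptor_config(doc$config$threshold_T, doc$config$epochs_N,
                              doc$config$families)
  weights <- unlist(doc$weights)
  if (is.null(weights)) weights <- stats::setNames(numeric(0L), character(0L))
  structure(list(config = config, weights = weights,
                 blocked = as.character(unlist(doc$blocked)),
                 calibration = list(C0 = doc$calibration$C0,
                                    C1 = doc$calibration$C1),
                 seed = as.integer(doc$seed), split_id = doc$split_id,
                 trace = NULL, target_value = NA_real_,
                 accepted_moves = NA_integer_, data = NULL),
            class = "cw_qsar")
}

#' Read paired promoter-sign tables
#'
#' Parses a TSV with columns \code{pair}, \code{attribute}, then one
#' column of \code{+}/\code{-} marks per run of each endpoint
#' (\code{a1..aK}, \code{b1..bK}), into one pair of stability profiles
#' per \code{pair} value.  Attribute keys are normalized to the canonical
#' dialect on ingestion.
#'
#' @param path file path.
#' @param endpoints optional named list mapping each pair label to its
#'   two endpoint ids.
#' @return named list; each element is a list of two
#'   \code{"stability_profile"} objects (\code{a}, \code{b}).
#' @export
read_promoter_pairs <- function(path, endpoints = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  if (!all(c("pair", "attribute") %in% names(df))) {
    stop("promoter table must name columns: pair, attribute")
  }
  a_cols <- grep("^a[0-9]+$", names(df), value = TRUE)
  b_cols <- grep("^b[0-9]+$", names(df), value = TRUE)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("need at least two run columns per endpoint (a1.., b1..)")
  }
  lapply(split(df, factor(df$pair, levels = unique(df$pair))), function(blk) {
    ids <- endpoints[[blk$pair[1L]]] %||%
      paste0(blk$pair[1L], c("#1", "#2"))
    ma <- as.matrix(blk[a_cols]); rownames(ma) <- blk$attribute
    mb <- as.matrix(blk[b_cols]); rownames(mb) <- blk$attribute
    list(a = profile_from_signs(ids[[1L]], ma),
         b = profile_from_signs(ids[[2L]], mb))
  })
}

#' Read split-by-run promoter indicator cells
#'
#' Parses a TSV with columns \code{attribute} and one 0/1 column per
#' cohort cell (e.g. \code{mr_1_1 .. fr_3_3}) into per-cohort indicator
#' matrices suitable for [consistency_table()].
#'
#' @param path file path.
#' @param cohorts character vector of cohort prefixes (default derived
#'   from the column names).
#' @return named list of 0/1 integer matrices.
#' @export
read_consistency_cells <- function(path, cohorts = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!("attribute" %in% names(df))) stop("missing 'attribute' column")
  cell_cols <- setdiff(names(df), c("attribute", "class"))
  if (is.null(cohorts)) {
    cohorts <- unique(sub("_.*$", "", cell_cols))
  }
  out <- lapply(cohorts, function(p) {
    cols <- grep(paste0("^", p, "_"), cell_cols, value = TRUE)
    if (length(cols) == 0L) stop("no cells for cohort '", p, "'")
    m <- as.matrix(df[cols])
    if (anyNA(m) || !all(m %in% c(0, 1))) {
      stop("cells for cohort '", p, "' must be 0/1")
    }
    rownames(m) <- df$attribute
    storage.mode(m) <- "integer"
    m
  })
  stats::setNames(out, cohorts)
}

#' Write / read a profile interchange table
#'
#' A TSV with one row per attribute key and one column of correlation
#' weights per run.
#'
#' @param runs list of named numeric weight tables (or objects accepted
#'   by [classify_promoters()]).
#' @param path file path.
#' @export
write_profile_runs <- function(runs, path) {
  tables <- lapply(runs, extract_weight_table)
  keys <- sort(unique(unlist(lapply(tables, names))), method = "radix")
  m <- vapply(tables, function(w) {
    v <- rep(0, length(keys)); v[match(names(w), keys)] <- w; v
  }, numeric(length(keys)))
  m <- matrix(m, nrow = length(keys))
  df <- data.frame(attribute = keys, m, stringsAsFactors = FALSE)
  names(df) <- c("attribute", paste0("run", seq_along(tables)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_runs
#' @return \code{read_profile_runs} returns a list of named numeric
#'   weight tables.
#' @export
read_profile_runs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!("attribute" %in% names(df))) stop("missing 'attribute' column")
  run_cols <- setdiff(names(df), "attribute")
  lapply(df[run_cols], function(v) stats::setNames(as.numeric(v), df$attribute))
}

#' Write a criteria report as a two-column TSV
#'
#' Absent (undefined) statistics are rendered \code{NA}.
#'
#' @param report a [criteria_report()].
#' @param path file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "criteria_report"))
  df <- as.data.frame(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
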