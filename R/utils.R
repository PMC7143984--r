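# internal helpers shared across the package

# fixed-width field fill (no truncation); errors if x is too wide
pad_field <- function(x, width, fill = ".") {
  n <- nchar(x)
  if (any(n > width)) {
    stop("field wider than ", width, " characters: ", x[which(n > width)[1L]])
  }
  paste0(x, vapply(width - n, strrep, character(1L), x = fill))
}

# run `expr` under a private RNG stream seeded with `seed`; the global
# .Random.seed is restored afterwards so callers' streams are untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a 32-bit sub-seed from a user seed and a stream index
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 69069 + as.double(index) * 1234567) %% 2147483647
  as.integer(s)
}

# tabulate a character vector of keys into a named integer multiset
count_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(structure(integer(0L), names = character(0L)))
  }
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

# merge named integer multisets, summing multiplicities
merge_counts <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, length, 1L) > 0L]
  if (length(parts) == 0L) {
    return(structure(integer(0L), names = character(0L)))
  }
  all <- unlist(parts)
  tapply_sum <- tapply(all, names(all), sum)
  structure(as.integer(tapply_sum), names = names(tapply_sum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
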