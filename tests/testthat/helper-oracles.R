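# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (explicit loops, no shared code with R/).

# character-walk tokenizer: scans one character at a time, gluing the
# multi-character tokens by explicit lookahead
oracle_tokenize <- function(smiles) {
  chars <- strsplit(smiles, "")[[1L]]
  out <- character(0L)
  i <- 1L
  while (i <= length(chars)) {
    c1 <- chars[i]
    c2 <- if (i < length(chars)) chars[i + 1L] else ""
    c3 <- if (i + 1L < length(chars)) chars[i + 2L] else ""
    if ((c1 == "C" && c2 == "l") || (c1 == "B" && c2 == "r") ||
        (c1 == "@" && c2 == "@")) {
      out <- c(out, paste0(c1, c2)); i <- i + 2L
    } else if (c1 == "%" && grepl("[0-9]", c2) && grepl("[0-9]", c3)) {
      out <- c(out, paste0(c1, c2, c3)); i <- i + 3L
    } else if (c1 == ")") {
      out <- c(out, "("); i <- i + 1L
    } else {
      out <- c(out, c1); i <- i + 1L
    }
  }
  out
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_ccc <- function(x, y) {
  num <- 0
  for (i in seq_along(x)) num <- num + (x[i] - mean(x)) * (y[i] - mean(y))
  den <- sum((x - mean(x))^2) + sum((y - mean(y))^2) +
    length(x) * (mean(x) - mean(y))^2
  2 * num / den
}

oracle_through_origin <- function(y, yt) {
  k <- sum(y * yt) / sum(yt * yt)
  kp <- sum(y * yt) / sum(y * y)
  r0 <- 1 - sum((yt - k * yt)^2) / sum((yt - mean(yt))^2)
  r0p <- 1 - sum((y - kp * y)^2) / sum((y - mean(y))^2)
  list(k = k, k_primed = kp, r0_sq = r0, r0_sq_primed = r0p)
}

oracle_q2 <- function(obs, pred, y_train) {
  press <- 0
  for (i in seq_along(obs)) press <- press + (pred[i] - obs[i])^2
  n_ext <- length(obs)
  list(
    q2 = 1 - press / sum((obs - mean(obs))^2),
    q2_f1 = 1 - (press / n_ext) / (sum((obs - mean(y_train))^2) / n_ext),
    q2_f2 = 1 - (press / n_ext) / (sum((obs - mean(obs))^2) / n_ext),
    q2_f3 = 1 - (press / n_ext) /
      (sum((y_train - mean(y_train))^2) / length(y_train))
  )
}

oracle_rm2 <- function(obs, pred, sqrt_form = TRUE) {
  r2 <- oracle_pearson(obs, pred)^2
  to <- oracle_through_origin(obs, pred)
  g <- function(d) if (sqrt_form) sqrt(abs(d)) else abs(d)
  a <- r2 * (1 - g(r2 - to$r0_sq))
  b <- r2 * (1 - g(r2 - to$r0_sq_primed))
  list(rm2 = a, rm2_reverse = b, rm2_avg = (a + b) / 2, rm2_delta = abs(a - b))
}

oracle_iic <- function(obs, calc, r) {
  delta <- obs - calc
  neg <- delta[delta < 0]
  pos <- delta[delta >= 0]
  if (length(neg) == 0L || length(pos) == 0L) return(0)
  mae_n <- sum(abs(neg)) / length(neg)
  mae_p <- sum(abs(pos)) / length(pos)
  r * min(mae_n, mae_p) / max(mae_n, mae_p)
}

# small set of random paired observations with both variances positive
random_pairing <- function(n = 10L) {
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, sd = 0.7)
  list(obs = x, pred = y)
}
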