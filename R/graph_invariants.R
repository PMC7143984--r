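#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Supports the organic-subset atoms (B, C, N, O, P, S, F, Cl, Br, I and
#' their aromatic lowercase forms), bracket atoms with isotope, charge,
#' chirality and explicit hydrogen counts, the bond symbols \code{-},
#' \code{=}, \code{#}, \code{:}, branches, and ring closures (digits and
#' \code{\%NN}).  Explicit hydrogens inside brackets are suppressed: the
#' graph covers heavy atoms only.  Bond orders are not recorded — an edge
#' is an edge, aromatic bonds included.
#'
#' @param smiles a single SMILES string.
#' @return an object of class \code{"heavy_skeleton"}: a list with
#'   \code{element} (character vector per heavy atom), \code{aromatic}
#'   (logical vector), and \code{adj} (symmetric logical adjacency matrix).
#' @examples
#' parse_skeleton("c1ccccc1")
#' @export
parse_skeleton <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single character string")
  }
  smiles <- trimws(smiles)
  if (nchar(smiles) == 0L) stop("empty SMILES string")
  chars <- strsplit(smiles, "")[[1L]]
  n <- length(chars)

  element <- character(0L)
  aromatic <- logical(0L)
  edges <- matrix(integer(0L), ncol = 2L)
  prev <- NA_integer_          # atom awaiting a bond to the next atom
  branch_stack <- integer(0L)
  ring_open <- list()          # ring label -> atom index awaiting closure

  add_atom <- function(sym, arom) {
    element <<- c(element, sym)
    aromatic <<- c(aromatic, arom)
    idx <- length(element)
    if (!is.na(prev)) edges <<- rbind(edges, c(prev, idx))
    prev <<- idx
    idx
  }
  close_ring <- function(label) {
    if (!is.null(ring_open[[label]])) {
      if (is.na(prev)) stop("ring closure '", label, "' with no open atom")
      edges <<- rbind(edges, c(ring_open[[label]], prev))
      ring_open[[label]] <<- NULL
    } else {
      if (is.na(prev)) stop("ring closure '", label, "' with no open atom")
      ring_open[[label]] <<- prev
    }
  }

  two_letter <- c(Cl = "Cl", Br = "Br")
  organic_upper <- c("B", "C", "N", "O", "P", "S", "F", "I")
  organic_lower <- c("b", "c", "n", "o", "p", "s")

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "C" && nxt == "l") { add_atom("Cl", FALSE); i <- i + 2L }
    else if (ch == "B" && nxt == "r") { add_atom("Br", FALSE); i <- i + 2L }
    else if (ch %in% organic_upper) { add_atom(ch, FALSE); i <- i + 1L }
    else if (ch %in% organic_lower) { add_atom(toupper(ch), TRUE); i <- i + 1L }
    else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom starting at position ", i)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      # strip isotope digits, then read element symbol
      body2 <- sub("^[0-9]+", "", body)
      m <- regmatches(body2, regexpr("^([A-Z][a-z]?|[a-z])", body2))
      if (length(m) == 0L) {
        stop("unsupported SMILES feature: bracket atom '[", body, "]'")
      }
      sym <- m
      arom <- sym %in% organic_lower
      if (arom) sym <- toupper(sym)
      if (sym == "H") {
        # an explicit lone hydrogen: suppressed graphs carry no H vertex
        stop("unsupported SMILES feature: standalone hydrogen atom '[",
             body, "]'")
      }
      add_atom(sym, arom)
      i <- j + 1L
    }
    else if (ch %in% c("-", "=", "#", ":", "/", "\\")) i <- i + 1L
    else if (ch == "(") { branch_stack <- c(branch_stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (length(branch_stack) == 0L) stop("unmatched ')' at position ", i)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    }
    else if (grepl("^[0-9]$", ch)) { close_ring(ch); i <- i + 1L }
    else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop("'%' at position ", i, " not followed by two digits")
      }
      close_ring(paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    }
    else if (ch == "@") i <- i + 1L
    else if (ch == "H" || ch == "+") i <- i + 1L
    else stop("unsupported SMILES feature: '", ch, "' at position ", i)
  }
  if (length(branch_stack)) stop("unbalanced parentheses: unclosed branch")
  if (length(ring_open)) {
    stop("unmatched ring closure(s): ",
         paste(names(ring_open), collapse = ", "))
  }
  if (length(element) == 0L) stop("SMILES contains no heavy atom")

  nv <- length(element)
  adj <- matrix(FALSE, nv, nv)
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(adj) <- FALSE
  structure(list(element = element, aromatic = aromatic, adj = adj),
            class = "heavy_skeleton")
}

#' @export
print.heavy_skeleton <- function(x, ...) {
  cat("Hydrogen-suppressed graph:", length(x$element), "heavy atoms,",
      sum(x$adj) / 2L, "edges\n")
  cat("Elements:", paste(x$element, collapse = " "), "\n")
  invisible(x)
}

# render an invariant key: 3/2-char family tag, optional element field
invariant_key <- function(tag, element, value) {
  head <- if (nchar(tag) == 3L) paste0(tag, "-", pad_field(element, 4L))
          else paste0(tag, "......")          # C5/C6 carry no element
  pad_field(paste0(head, value), KEY_WIDTH)
}

#' Vertex-degree (EC0) attributes of a heavy skeleton
#'
#' One key per heavy atom, combining the element symbol with its vertex
#' degree in the hydrogen-suppressed graph, e.g. \code{"EC0-C...2..."}.
#'
#' @param graph a [parse_skeleton()] result.
#' @return named integer vector of attribute multiplicities.
#' @export
ec0_attributes <- function(graph) {
  deg <- rowSums(graph$adj)
  count_keys(mapply(invariant_key, "EC0", graph$element, deg))
}

#' First-order Morgan extended-connectivity (EC1) attributes
#'
#' For each heavy atom the EC1 value is the sum of the vertex degrees of
#' its neighbours.  Values above 9 keep all their digits inside the
#' 12-character key.
#'
#' @inheritParams ec0_attributes
#' @return named integer vector of attribute multiplicities.
#' @export
ec1_attributes <- function(graph) {
  deg <- rowSums(graph$adj)
  ec1 <- as.integer(graph$adj %*% deg)
  count_keys(mapply(invariant_key, "EC1", graph$element, ec1))
}

#' Ring-code (C5/C6) attributes
#'
#' Counts five- and six-membered rings in a minimum cycle basis of the
#' hydrogen-suppressed graph and renders them as the keys
#' \code{"C5......n..."} and \code{"C6......m..."} (counts clipped at 9).
#'
#' @inheritParams ec0_attributes
#' @return named integer vector with exactly two keys.
#' @export
ring_attributes <- function(graph) {
  basis <- min_cycle_basis(graph$adj)
  sizes <- vapply(basis, length, 1L)
  n5 <- min(sum(sizes == 5L), 9L)
  n6 <- min(sum(sizes == 6L), 9L)
  count_keys(c(invariant_key("C5", NULL, n5), invariant_key("C6", NULL, n6)))
}

#' Nearest-neighbour-code (NNC) attributes
#'
#' A per-vertex code under this package's documented convention: for each
#' heavy atom, the three digits count its neighbours of degree 1, of
#' degree 2, and of degree 3 or more (each clipped at 9), rendered as
#' e.g. \code{"NNC-C...120."}.  Several conventions for this invariant
#' circulate; this one is fixed here so reports can be rendered, and the
#' family is disabled by default.
#'
#' @inheritParams ec0_attributes
#' @return named integer vector of attribute multiplicities.
#' @export
nnc_attributes <- function(graph) {
  deg <- rowSums(graph$adj)
  keys <- vapply(seq_along(graph$element), function(v) {
    nb <- which(graph$adj[v, ])
    d <- deg[nb]
    code <- paste0(min(sum(d == 1L), 9L), min(sum(d == 2L), 9L),
                   min(sum(d >= 3L), 9L))
    invariant_key("NNC", graph$element[v], code)
  }, character(1L))
  count_keys(keys)
}

# ---- minimum cycle basis (Horton's algorithm) -------------------------------
# Candidate cycles are built from shortest paths: for every vertex v and
# edge (x, y), the cycle SP(v,x) + (x,y) + SP(y,v).  Candidates are sorted
# by length and greedily accepted if independent over GF(2) in edge space.
# Molecular graphs are small, so the cubic cost is irrelevant.
min_cycle_basis <- function(adj) {
  nv <- nrow(adj)
  el <- which(adj & upper.tri(adj), arr.ind = TRUE)
  ne <- nrow(el)
  n_comp <- n_components(adj)
  dim_basis <- ne - nv + n_comp
  if (dim_basis <= 0L) return(list())
  edge_id <- matrix(0L, nv, nv)
  for (e in seq_len(ne)) {
    edge_id[el[e, 1L], el[e, 2L]] <- e
    edge_id[el[e, 2L], el[e, 1L]] <- e
  }
  # all-pairs BFS shortest paths with predecessors
  paths <- lapply(seq_len(nv), function(s) bfs_tree(adj, s))
  candidates <- list()
  for (v in seq_len(nv)) {
    for (e in seq_len(ne)) {
      x <- el[e, 1L]; y <- el[e, 2L]
      pv <- paths[[v]]
      if (is.na(pv$dist[x]) || is.na(pv$dist[y])) next
      px <- path_to(pv, x); py <- path_to(pv, y)
      # paths must be vertex-disjoint except at v for a simple cycle
      if (length(intersect(px[-1L], py[-1L])) > 0L) next
      verts <- c(px, rev(py))
      ring <- unique(verts[-length(verts)])
      if (length(ring) < 3L) next
      eset <- integer(0L)
      seq_pairs <- cbind(verts[-length(verts)], verts[-1L])
      ok <- TRUE
      for (r in seq_len(nrow(seq_pairs))) {
        id <- edge_id[seq_pairs[r, 1L], seq_pairs[r, 2L]]
        if (id == 0L) { ok <- FALSE; break }
        eset <- c(eset, id)
      }
      if (!ok) next
      eset <- sort(unique(c(eset, e)))
      if (length(eset) != length(ring)) next
      candidates[[length(candidates) + 1L]] <- eset
    }
  }
  if (length(candidates) == 0L) return(list())
  candidates <- unique(candidates)
  candidates <- candidates[order(vapply(candidates, length, 1L))]
  # greedy GF(2) independence via incremental Gaussian elimination
  basis_rows <- list()
  pivots <- integer(0L)
  accepted <- list()
  for (cand in candidates) {
    vec <- logical(ne)
    vec[cand] <- TRUE
    for (b in seq_along(basis_rows)) {
      if (vec[pivots[b]]) vec <- xor(vec, basis_rows[[b]])
    }
    if (any(vec)) {
      basis_rows[[length(basis_rows) + 1L]] <- vec
      pivots <- c(pivots, which(vec)[1L])
      accepted[[length(accepted) + 1L]] <- cand
      if (length(accepted) == dim_basis) break
    }
  }
  accepted
}

bfs_tree <- function(adj, s) {
  nv <- nrow(adj)
  dist <- rep(NA_integer_, nv)
  pred <- rep(NA_integer_, nv)
  dist[s] <- 0L
  queue <- s
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (w in which(adj[u, ])) {
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        pred[w] <- u
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, pred = pred, root = s)
}

# vertex sequence from the BFS root to t (root first)
path_to <- function(tree, t) {
  path <- t
  while (!is.na(tree$pred[path[1L]])) path <- c(tree$pred[path[1L]], path)
  path
}

n_components <- function(adj) {
  nv <- nrow(adj)
  seen <- logical(nv)
  k <- 0L
  for (s in seq_len(nv)) {
    if (seen[s]) next
    k <- k + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nbr <- which(adj[u, ] & !seen)
      seen[nbr] <- TRUE
      queue <- c(queue, nbr)
    }
  }
  k
}
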