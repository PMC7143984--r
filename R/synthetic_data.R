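# Synthetic small-molecule datasets with planted correlation weights.
# The generator writes only grammar constructs the tokenizer and graph
# parser support (chains, branches, 5/6-membered rings, double/triple
# bonds over the C,N,O,S,F,Cl,Br alphabet), so generated fixtures can
# never drift out of the parsers' grammar.

#' SMILES grammar specification for the generator
#'
#' @param atoms chain-atom alphabet (halogens only terminate branches).
#' @param max_chain maximum heavy-atom chain length (>= 2).
#' @param branch_prob probability of opening a one-atom branch after a
#'   chain atom.
#' @param ring_prob probability that a molecule carries one ring.
#' @param ring_sizes candidate ring sizes, sampled uniformly.
#' @param double_prob,triple_prob probability that a chain bond is written
#'   \code{=} or \code{#}.
#' @return list of class \code{"smiles_grammar"}.
#' @export
smiles_grammar <- function(atoms = c("C", "N", "O", "S", "F", "Cl", "Br"),
                           max_chain = 12L, branch_prob = 0.3,
                           ring_prob = 0.3, ring_sizes = c(5L, 6L),
                           double_prob = 0.15, triple_prob = 0.03) {
  probs <- c(branch_prob, ring_prob, double_prob, triple_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (max_chain < 2L) stop("`max_chain` must be at least 2")
  structure(list(atoms = atoms, max_chain = as.integer(max_chain),
                 branch_prob = branch_prob, ring_prob = ring_prob,
                 ring_sizes = as.integer(ring_sizes),
                 double_prob = double_prob, triple_prob = triple_prob),
            class = "smiles_grammar")
}

#' Generate syntactically valid SMILES strings
#'
#' Every generated string round-trips through [tokenize_smiles()] and is
#' accepted by [parse_skeleton()]; generation is deterministic for a
#' fixed seed.
#'
#' @param n number of molecules (>= 1).
#' @param grammar a [smiles_grammar()].
#' @param seed integer seed.
#' @return character vector of n SMILES strings.
#' @examples
#' generate_molecules(3, seed = 42)
#' @export
generate_molecules <- function(n, grammar = smiles_grammar(), seed = 1L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    vapply(seq_len(n), function(i) one_molecule(grammar), character(1L))
  })
}

one_molecule <- function(g) {
  # chain atoms: halogens are monovalent, keep them out of the backbone
  backbone <- setdiff(g$atoms, c("F", "Cl", "Br", "I"))
  terminal <- g$atoms
  len <- sample(2L:g$max_chain, 1L)
  out <- character(0L)
  ring_left <- if (stats::runif(1L) < g$ring_prob && len >= 6L) {
    sample(g$ring_sizes, 1L)
  } else 0L
  ring_open_at <- if (ring_left > 0L) sample(seq_len(len - ring_left + 1L), 1L)
                  else 0L
  in_ring <- 0L
  for (i in seq_len(len)) {
    if (i > 1L) {
      # no bond decorations on ring bonds, keeps the ring aromatic-free
      if (in_ring == 0L) {
        u <- stats::runif(1L)
        if (u < g$triple_prob) out <- c(out, "#")
        else if (u < g$triple_prob + g$double_prob) out <- c(out, "=")
      }
    }
    atom <- sample(backbone, 1L)
    out <- c(out, atom)
    if (i == ring_open_at) {
      out <- c(out, "1")
      in_ring <- ring_left
    } else if (in_ring > 0L) {
      in_ring <- in_ring - 1L
      if (in_ring == 1L) {       # this atom closes the ring
        out <- c(out, "1")
        in_ring <- 0L
      }
    }
    if (stats::runif(1L) < g$branch_prob && i < len) {
      out <- c(out, "(", sample(terminal, 1L), ")")
    }
  }
  paste0(out, collapse = "")
}

#' Plant random correlation weights over an attribute universe
#'
#' Draws one weight Uniform(-1, 1) for every attribute observed in the
#' supplied molecules; together with an intercept and slope this defines
#' a ground-truth linear model for endpoint simulation.
#'
#' @param molecules character vector of SMILES.
#' @param config a [descriptor_config()].
#' @param seed integer seed.
#' @param intercept,slope ground-truth calibration (defaults 0 and 1).
#' @param noise_sd endpoint noise standard deviation (>= 0).  The special
#'   value \code{NULL} defers the choice to [simulate_endpoint()]'s
#'   relative noise argument.
#' @return list of class \code{"planted_model"} with \code{weights},
#'   \code{intercept}, \code{slope}, \code{noise_sd}, \code{config}.
#' @export
plant_weights <- function(molecules, config = descriptor_config(), seed = 1L,
                          intercept = 0, slope = 1, noise_sd = NULL) {
  stopifnot(length(molecules) >= 1L)
  if (slope == 0) stop("`slope` must be non-zero")
  attrs <- lapply(molecules, extract_attributes, config = config)
  keys <- sort(unique(unlist(lapply(attrs, names))), method = "radix")
  w <- with_seed(seed, stats::runif(length(keys), -1, 1))
  structure(list(weights = stats::setNames(w, keys), intercept = intercept,
                 slope = slope, noise_sd = noise_sd, config = config),
            class = "planted_model")
}

#' Simulate endpoints from a planted model
#'
#' \code{endpoint_i = intercept + slope * DCW_i + eps_i} with Gaussian
#' noise.  When the planted model carries no absolute \code{noise_sd},
#' the noise is \code{rel_noise * sd(signal)}.
#'
#' @param molecules character vector of SMILES.
#' @param planted a [plant_weights()] model.
#' @param seed integer seed for the noise draws.
#' @param rel_noise noise sd as a fraction of the signal sd, used only
#'   when the planted model has \code{noise_sd = NULL} (default 0.05).
#' @return data frame with columns \code{id}, \code{smiles},
#'   \code{endpoint}, plus attribute \code{"signal"} (the noiseless
#'   endpoints).
#' @export
simulate_endpoint <- function(molecules, planted, seed = 1L,
                              rel_noise = 0.05) {
  stopifnot(inherits(planted, "planted_model"))
  attrs <- lapply(molecules, extract_attributes, config = planted$config)
  d <- vapply(attrs, function(a) as.numeric(dcw(a, planted$weights)),
              numeric(1L))
  signal <- planted$intercept + planted$slope * d
  sdn <- planted$noise_sd %||% (rel_noise * stats::sd(signal))
  eps <- if (sdn > 0) with_seed(seed, stats::rnorm(length(signal), 0, sdn))
         else rep(0, length(signal))
  out <- data.frame(id = sprintf("M%04d", seq_along(molecules)),
                    smiles = molecules, endpoint = signal + eps,
                    stringsAsFactors = FALSE)
  attr(out, "signal") <- signal
  out
}

#' Split a dataset into training/(calibration/)validation sets
#'
#' \code{scheme = "random"} deals a seeded shuffle into the requested
#' fractions; \code{scheme = "striped"} sorts by endpoint and deals
#' round-robin, an emulation of "rational" splitting that balances the
#' endpoint distribution across sets.
#'
#' @param dataset data frame with \code{id} and \code{endpoint} columns.
#' @param scheme \code{"random"} or \code{"striped"}.
#' @param fractions named or unnamed numeric vector summing to 1; 2
#'   entries mean training/validation, 3 mean
#'   training/calibration/validation.
#' @param seed integer seed.
#' @return data frame with columns \code{id}, \code{set}.
#' @export
make_splits <- function(dataset, scheme = c("random", "striped"),
                        fractions = c(0.8, 0.2), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(dataset), all(c("id", "endpoint") %in% names(dataset)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  set_names <- switch(as.character(length(fractions)),
                      "2" = c("training", "validation"),
                      "3" = c("training", "calibration", "validation"),
                      stop("`fractions` must have length 2 or 3"))
  n <- nrow(dataset)
  sizes <- diff(round(cumsum(c(0, fractions)) * n))
  if (any(sizes == 0L)) stop("a fraction yields an empty set")
  sets <- character(n)
  if (scheme == "random") {
    order_idx <- with_seed(seed, sample.int(n))
    sets[order_idx] <- rep(set_names, sizes)
  } else {
    # deal endpoint-sorted molecules round-robin: the i-th molecule goes
    # to the set furthest below its target share, interleaving the sets
    # across the endpoint range (a "rational" split emulation)
    order_idx <- order(dataset$endpoint)
    taken <- numeric(length(fractions))
    for (i in seq_len(n)) {
      k <- which.max(i * fractions - taken)
      sets[order_idx[i]] <- set_names[k]
      taken[k] <- taken[k] + 1
    }
  }
  data.frame(id = as.character(dataset$id), set = sets,
             stringsAsFactors = FALSE)
}

#' One-call synthetic study: molecules, planted weights, endpoints, split
#'
#' Convenience wrapper used throughout the package's tests and examples.
#'
#' @param n number of molecules (default 250, the package's standard
#'   harness size).
#' @param seed master seed; molecule, weight and noise streams are
#'   derived from it.
#' @param config a [descriptor_config()].
#' @param grammar a [smiles_grammar()].
#' @param noise_sd absolute noise sd, or NULL (default) for
#'   \code{rel_noise * sd(signal)}.
#' @param rel_noise relative noise level (default 0.05).
#' @param fractions split fractions (default 0.8/0.2).
#' @param scheme split scheme (default random).
#' @return list with \code{data}, \code{split}, \code{planted},
#'   \code{molecules}.
#' @export
synth_dataset <- function(n = 250L, seed = 7L, config = descriptor_config(),
                          grammar = smiles_grammar(), noise_sd = NULL,
                          rel_noise = 0.05, fractions = c(0.8, 0.2),
                          scheme = "random") {
  mols <- generate_molecules(n, grammar, seed = derive_seed(seed, 1L))
  planted <- plant_weights(mols, config, seed = derive_seed(seed, 2L),
                           noise_sd = noise_sd)
  data <- simulate_endpoint(mols, planted, seed = derive_seed(seed, 3L),
                            rel_noise = rel_noise)
  split <- make_splits(data, scheme = scheme, fractions = fractions,
                       seed = derive_seed(seed, 4L))
  list(data = data, split = split, planted = planted, molecules = mols)
}
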