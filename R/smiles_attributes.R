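#' Tokenize a SMILES string into its attribute alphabet
#'
#' Splits a SMILES line into the tokens used as local attributes: most
#' characters stand alone, while the two-letter halogens \code{Cl} and
#' \code{Br}, the stereo marker \code{@@@@}, and two-digit ring closures
#' \code{\%NN} are kept together (greedy longest match).  Closing
#' parentheses are canonicalized to \code{"("} so that branch opening and
#' closing contribute the same attribute; the original string is always
#' recoverable by flipping canonicalized positions back (see
#' \code{attr(, "close_pos")}).
#'
#' @param smiles a single non-empty SMILES string; surrounding whitespace
#'   is stripped, internal whitespace is an error.
#' @return a character vector of tokens, with attribute \code{close_pos}
#'   giving the indices of tokens that were \code{")"} in the input.
#' @examples
#' tokenize_smiles("Clc1cc(Cl)ccc1C(O)=O")
#' tokenize_smiles("C%12CCC%12")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("`smiles` must be a single character string")
  }
  smiles <- trimws(smiles)
  if (nchar(smiles) == 0L) stop("empty SMILES string")
  if (grepl("[[:space:]]", smiles)) stop("SMILES contains internal whitespace")
  chars <- strsplit(smiles, "", fixed = FALSE)[[1L]]
  n <- length(chars)
  n_open <- sum(chars == "(")
  n_close <- sum(chars == ")")
  if (n_open != n_close) {
    stop("unbalanced parentheses in SMILES (", n_open, " '(' vs ",
         n_close, " ')')")
  }
  tokens <- character(0L)
  close_pos <- integer(0L)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "C" && nxt == "l") {
      tokens <- c(tokens, "Cl"); i <- i + 2L
    } else if (ch == "B" && nxt == "r") {
      tokens <- c(tokens, "Br"); i <- i + 2L
    } else if (ch == "@" && nxt == "@") {
      tokens <- c(tokens, "@@"); i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop("'%' at position ", i, " not followed by two digits")
      }
      tokens <- c(tokens, paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ")") {
      tokens <- c(tokens, "(")
      close_pos <- c(close_pos, length(tokens))
      i <- i + 1L
    } else {
      tokens <- c(tokens, ch); i <- i + 1L
    }
  }
  attr(tokens, "close_pos") <- close_pos
  attr(tokens, "smiles") <- smiles
  tokens
}

#' Reassemble the original SMILES from a token stream
#'
#' Inverse of [tokenize_smiles()]: concatenates the tokens, restoring
#' \code{")"} at the canonicalized positions.
#'
#' @param tokens output of [tokenize_smiles()].
#' @return the original SMILES string.
#' @export
detokenize_smiles <- function(tokens) {
  out <- as.character(tokens)
  cp <- attr(tokens, "close_pos")
  if (length(cp)) out[cp] <- ")"
  paste0(out, collapse = "")
}

# width of every attribute key in the system
KEY_WIDTH <- 12L

#' Render a local attribute key
#'
#' A single token (Sk attribute) is left-justified in a 12-character field
#' padded with dots.  A connected token pair (SSk attribute) occupies two
#' 4-character dot-padded fields followed by four dots; the token that
#' sorts higher in ASCII order comes first, so the key is independent of
#' the order in which the pair is supplied.
#'
#' @param a a canonical token (never \code{")"}).
#' @param b optional second token of a connected pair.
#' @return a 12-character attribute key.
#' @examples
#' sk_key("Cl")          # "Cl.........."
#' ssk_key("(", "Cl")    # "Cl..(......."
#' @export
sk_key <- function(a) {
  stopifnot(is.character(a), length(a) == 1L)
  if (a == ")") stop("token ')' must be canonicalized to '(' first")
  pad_field(a, KEY_WIDTH)
}

#' @rdname sk_key
#' @export
ssk_key <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (a == ")" || b == ")") stop("token ')' must be canonicalized to '(' first")
  # descending ASCII order of the token strings: the higher token first
  hi <- if (ascii_gt(a, b)) a else b
  lo <- if (identical(hi, a)) b else a
  paste0(pad_field(hi, 4L), pad_field(lo, 4L), "....")
}

# strict byte-wise (C-locale) string comparison a > b
ascii_gt <- function(a, b) {
  ab <- utf8ToInt(a); bb <- utf8ToInt(b)
  k <- min(length(ab), length(bb))
  for (i in seq_len(k)) {
    if (ab[i] != bb[i]) return(ab[i] > bb[i])
  }
  length(ab) > length(bb)
}

#' Local SMILES attributes of a token stream
#'
#' Emits one Sk instance per token and one SSk instance per adjacent token
#' pair, accumulating multiplicities.
#'
#' @param tokens output of [tokenize_smiles()].
#' @return named integer vector of attribute multiplicities.
#' @export
local_attributes <- function(tokens) {
  toks <- as.character(tokens)
  sk <- vapply(toks, sk_key, character(1L), USE.NAMES = FALSE)
  ssk <- character(0L)
  if (length(toks) > 1L) {
    ssk <- mapply(ssk_key, toks[-length(toks)], toks[-1L], USE.NAMES = FALSE)
  }
  count_keys(c(sk, ssk))
}

# canonical feature list for the PAIR descriptor: halogens, NOSP elements,
# double/triple bond, stereo marker — in this fixed order
PAIR_FEATURES <- c("F", "Cl", "Br", "I", "N", "O", "S", "P", "B2", "B3", "ST")

# which PAIR/NOSP/HALO/BOND features are present in a token stream;
# aromatic lowercase atoms count as their element
present_features <- function(tokens) {
  toks <- as.character(tokens)
  has <- function(...) any(toks %in% c(...))
  c(F  = has("F"),
    Cl = has("Cl"),
    Br = has("Br"),
    I  = has("I"),
    N  = has("N", "n"),
    O  = has("O", "o"),
    S  = has("S", "s"),
    P  = has("P", "p"),
    B2 = has("="),
    B3 = has("#"),
    ST = has("@", "@@"))
}

#' Global SMILES attributes (BOND, NOSP, HALO, PAIR)
#'
#' Encodes the presence of bond symbols, of N/O/S/P, of halogens, and of
#' every co-occurring pair of those features as fixed-width keys.  The
#' BOND flags are, in order, \code{=}, \code{#}, \code{@@} (or \code{@@@@});
#' NOSP flags are N, O, S, P; HALO flags are F, Cl, Br, I; unused flag
#' positions are \code{0}.  A PAIR key is \code{"++++"} followed by the
#' two features, the first dash-padded and the second equals-padded to
#' four characters, ordered by the canonical feature list
#' F, Cl, Br, I, N, O, S, P, B2, B3, ST.
#'
#' @param tokens output of [tokenize_smiles()].
#' @return character vector of keys: one BOND, one NOSP, one HALO, and
#'   \code{choose(f, 2)} PAIR keys for \code{f} present features.
#' @examples
#' global_attributes(tokenize_smiles("Clc1cc(Cl)ccc1C(O)=O"))
#' @export
global_attributes <- function(tokens) {
  pf <- present_features(tokens)
  flag <- function(x) as.integer(x)
  bond <- paste0("BOND", paste0(c(flag(pf[["B2"]]), flag(pf[["B3"]]),
                                  flag(pf[["ST"]]), rep(0L, 5L)), collapse = ""))
  nosp <- paste0("NOSP", paste0(c(flag(pf[["N"]]), flag(pf[["O"]]),
                                  flag(pf[["S"]]), flag(pf[["P"]]),
                                  rep(0L, 4L)), collapse = ""))
  halo <- paste0("HALO", paste0(c(flag(pf[["F"]]), flag(pf[["Cl"]]),
                                  flag(pf[["Br"]]), flag(pf[["I"]]),
                                  rep(0L, 4L)), collapse = ""))
  present <- PAIR_FEATURES[pf[PAIR_FEATURES]]
  pairs <- character(0L)
  if (length(present) >= 2L) {
    idx <- utils::combn(length(present), 2L)
    pairs <- vapply(seq_len(ncol(idx)), function(j) {
      pair_key(present[idx[1L, j]], present[idx[2L, j]])
    }, character(1L))
  }
  c(bond, nosp, halo, pairs)
}

# render one PAIR key; features must be distinct members of PAIR_FEATURES
pair_key <- function(f1, f2) {
  i1 <- match(f1, PAIR_FEATURES); i2 <- match(f2, PAIR_FEATURES)
  if (is.na(i1) || is.na(i2) || i1 == i2) {
    stop("invalid PAIR features: ", f1, ", ", f2)
  }
  if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
  paste0("++++",
         pad_field(PAIR_FEATURES[i1], 4L, "-"),
         pad_field(PAIR_FEATURES[i2], 4L, "="))
}

#' Extract the full attribute multiset of one molecule
#'
#' Combines local (Sk, SSk), global (BOND, NOSP, HALO, PAIR) and — when the
#' configuration enables them — hydrogen-suppressed-graph invariant
#' attributes (EC0, EC1, C5/C6 ring codes, optionally NNC) into one
#' multiset of 12-character keys.
#'
#' @param smiles a single SMILES string.
#' @param config a [descriptor_config()] naming the enabled families.
#' @return named integer vector mapping attribute keys to multiplicities.
#' @examples
#' extract_attributes("CCO", descriptor_config())
#' @export
extract_attributes <- function(smiles, config = descriptor_config()) {
  stopifnot(inherits(config, "descriptor_config"))
  tokens <- tokenize_smiles(smiles)
  fam <- config$families
  parts <- list()
  if ("sk" %in% fam || "ssk" %in% fam) {
    loc <- local_attributes(tokens)
    if (!("sk" %in% fam))  loc <- loc[!is_sk_key(names(loc))]
    if (!("ssk" %in% fam)) loc <- loc[is_sk_key(names(loc))]
    parts <- c(parts, list(loc))
  }
  if (any(c("bond", "nosp", "halo", "pair") %in% fam)) {
    glob <- global_attributes(tokens)
    keep <- c(bond = "^BOND", nosp = "^NOSP", halo = "^HALO", pair = "^\\+\\+\\+\\+")
    pat <- paste(keep[intersect(names(keep), fam)], collapse = "|")
    glob <- glob[grepl(pat, glob)]
    parts <- c(parts, list(count_keys(glob)))
  }
  if (any(c("ec0", "ec1", "rings", "nnc") %in% fam)) {
    g <- parse_skeleton(smiles)
    if ("ec0" %in% fam)   parts <- c(parts, list(ec0_attributes(g)))
    if ("ec1" %in% fam)   parts <- c(parts, list(ec1_attributes(g)))
    if ("rings" %in% fam) parts <- c(parts, list(ring_attributes(g)))
    if ("nnc" %in% fam)   parts <- c(parts, list(nnc_attributes(g)))
  }
  out <- do.call(merge_counts, parts)
  out[order(names(out), method = "radix")]
}

# an Sk key has its last four characters all '.', an SSk key too -- so
# distinguish by the 5th-8th field: Sk keys are '.' from the first pad
# position onward; safest test: chars 9..12 are dots for both, chars 5..8
# are dots exactly when the key is a one-token (Sk) key of width <= 4
is_sk_key <- function(keys) {
  substr(keys, 5L, 12L) == "........"
}
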