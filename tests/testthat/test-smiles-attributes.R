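test_that("the dichlorobenzoic acid worked example tokenizes as printed", {
  s <- "Clc1cc(Cl)ccc1C(O)=O"
  toks <- tokenize_smiles(s)
  expect_length(as.character(toks), 18L)
  expect_equal(as.character(toks)[1:7], c("Cl", "c", "1", "c", "c", "(", "Cl"))
  # the closing parenthesis after the second Cl is canonicalized to '('
  expect_identical(as.character(toks)[8], "(")
  expect_identical(detokenize_smiles(toks), s)
})

test_that("multi-character tokens use greedy longest match", {
  expect_equal(as.character(tokenize_smiles("CCO")), c("C", "C", "O"))
  expect_equal(as.character(tokenize_smiles("C%12CCC%12")),
               c("C", "%12", "C", "C", "C", "%12"))
  expect_equal(as.character(tokenize_smiles("C[C@@H](N)Br")),
               c("C", "[", "C", "@@", "H", "]", "(", "N", "(", "Br"))
})

test_that("malformed SMILES are rejected with informative errors", {
  expect_error(tokenize_smiles("CC(O"), "unbalanced parentheses")
  expect_error(tokenize_smiles("C%1C"), "two digits")
  expect_error(tokenize_smiles("C%"), "two digits")
  expect_error(tokenize_smiles(""), "empty")
  expect_error(tokenize_smiles("C C"), "whitespace")
})

test_that("tokenizer agrees with a naive character-walk oracle", {
  mols <- generate_molecules(1000L, seed = 915L)
  for (s in mols) {
    expect_identical(as.character(tokenize_smiles(s)), oracle_tokenize(s))
  }
  # round trip holds for every generated molecule
  for (s in mols[1:100]) {
    expect_identical(detokenize_smiles(tokenize_smiles(s)), s)
  }
})

test_that("local keys render at fixed width with ASCII-ordered pairs", {
  expect_identical(sk_key("1"), "1...........")
  expect_identical(sk_key("Cl"), "Cl..........")
  expect_identical(ssk_key("(", "Cl"), "Cl..(.......")
  expect_identical(ssk_key("c", "2"), "c...2.......")
  expect_identical(ssk_key("2", "c"), "c...2.......")
  expect_error(sk_key(")"), "canonicalized")
  # pair-order invariance over random token pairs
  pool <- c("C", "c", "N", "n", "O", "(", "1", "9", "=", "#", "@@", "Cl",
            "Br", "%12", "[", "]", "+", "-")
  set.seed(42)
  for (i in 1:200) {
    a <- sample(pool, 1L); b <- sample(pool, 1L)
    expect_identical(ssk_key(a, b), ssk_key(b, a))
  }
})

test_that("local attribute extraction counts tokens and adjacent pairs", {
  a <- local_attributes(tokenize_smiles("CCO"))
  expect_equal(a[["C..........."]], 2L)
  expect_equal(a[["O..........."]], 1L)
  expect_equal(a[["C...C......."]], 1L)
  expect_equal(a[["O...C......."]], 1L)
  expect_equal(sum(a), 3L + 2L)  # Sk per token, SSk per adjacent pair
  one <- local_attributes(tokenize_smiles("C"))
  expect_equal(sum(one), 1L)
  # the worked example contains the Cl-branch pair twice
  wrk <- local_attributes(tokenize_smiles("Clc1cc(Cl)ccc1C(O)=O"))
  expect_equal(wrk[["Cl..(......."]], 2L)
})

test_that("global attributes encode presence flags and feature pairs", {
  g <- global_attributes(tokenize_smiles("Clc1cc(Cl)ccc1C(O)=O"))
  expect_setequal(g, c("BOND10000000", "NOSP01000000", "HALO01000000",
                       "++++Cl--O===", "++++Cl--B2==", "++++O---B2=="))
  g2 <- global_attributes(tokenize_smiles("CCO"))
  expect_setequal(g2, c("BOND00000000", "NOSP01000000", "HALO00000000"))
  expect_true("++++F---B2==" %in% global_attributes(tokenize_smiles("FC=C")))
})

test_that("one BOND/NOSP/HALO each and choose(f,2) PAIR keys per molecule", {
  mols <- generate_molecules(150L, seed = 77L)
  for (s in mols) {
    toks <- tokenize_smiles(s)
    g <- global_attributes(toks)
    expect_equal(sum(startsWith(g, "BOND")), 1L)
    expect_equal(sum(startsWith(g, "NOSP")), 1L)
    expect_equal(sum(startsWith(g, "HALO")), 1L)
    f <- sum(cwqsar:::present_features(toks))
    expect_equal(sum(startsWith(g, "++++")), choose(f, 2L))
  }
})

test_that("extract_attributes gates families and emits 12-char keys", {
  a_smiles <- extract_attributes("CCO", descriptor_config())
  expect_false(any(grepl("^EC0|^EC1|^C5|^C6|^NNC", names(a_smiles))))
  a_ec <- extract_attributes("CCO", descriptor_config(families = "hybrid_ec"))
  expect_true(any(startsWith(names(a_ec), "EC0-")))
  expect_true(any(startsWith(names(a_ec), "EC1-")))
  expect_false(any(startsWith(names(a_ec), "BOND")))
  a_rings <- extract_attributes("CCO", descriptor_config(families = "hybrid_rings"))
  expect_true("C5......0..." %in% names(a_rings))
  expect_true("C6......0..." %in% names(a_rings))
  # determinism and key width on generated molecules
  mols <- generate_molecules(50L, seed = 5L)
  for (s in mols[1:10]) {
    expect_identical(extract_attributes(s), extract_attributes(s))
  }
  widths <- nchar(unlist(lapply(mols, function(s) {
    names(extract_attributes(s, descriptor_config(families = c(
      "sk", "ssk", "bond", "nosp", "halo", "pair", "ec0", "ec1", "rings",
      "nnc"))))
  })))
  expect_true(all(widths == 12L))
})
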