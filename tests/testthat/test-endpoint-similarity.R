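fixture_pairs <- function() {
  read_promoter_pairs(
    system.file("extdata", "endpoint_promoter_signs.tsv", package = "cwqsar"),
    endpoints = list(
      mutagenicity_vs_anticancer = c("mutagenicity", "anticancer"),
      mutagenicity_vs_bbb = c("mutagenicity", "bbb"),
      bbb_vs_anticancer = c("bbb", "anticancer")))
}

test_that("promoter labels require a constant sign across runs", {
  runs <- list(c(A = 0.3, B = 0.3, C = -0.5, D = 0.2),
               c(A = 0.1, B = -0.1, C = -0.8, D = 0.4),
               c(A = 0.8, B = 0.2, C = -0.1, D = 0))
  p <- classify_promoters(runs, "toy")
  expect_equal(p$labels[["A"]], 1L)    # positive in every run
  expect_equal(p$labels[["B"]], 0L)    # sign flip
  expect_equal(p$labels[["C"]], -1L)   # negative in every run
  expect_equal(p$labels[["D"]], 0L)    # a zero weight is unstable
  expect_error(classify_promoters(list(c(A = 1), c(B = 1)), "x"), "disjoint")
  expect_error(classify_promoters(list(c(A = 1)), "x"), "at least 2")
})

test_that("profile comparison is symmetric and conserves stable counts", {
  prs <- fixture_pairs()
  for (pr in prs) {
    ab <- compare_profiles(pr$a, pr$b)
    ba <- compare_profiles(pr$b, pr$a)
    expect_identical(ab, ba)
    stable_a <- sum(pr$a$labels != 0L)
    stable_b <- sum(pr$b$labels != 0L)
    expect_lte(ab[["similarity"]] + ab[["dissimilarity"]],
               min(stable_a, stable_b))
  }
  # all-zero profile never matches anything
  z <- profile_from_signs("zero", matrix("0", 2, 2,
                                         dimnames = list(c("A", "B"), NULL)))
  expect_equal(unname(compare_profiles(z, prs[[1]]$a)), c(0L, 0L))
})

test_that("the transcribed promoter blocks reproduce the published counts", {
  prs <- fixture_pairs()
  counts <- t(vapply(prs, function(pr) compare_profiles(pr$a, pr$b),
                     integer(2)))
  expect_equal(unname(counts[, 1]), c(10L, 14L, 26L))
  expect_equal(unname(counts[, 2]), c(8L, 7L, 8L))
})

test_that("similarity matrices are symmetric with stable-count diagonals", {
  runs1 <- list(c(A = 1, B = 1, C = -1), c(A = 2, B = -1, C = -2))
  runs2 <- list(c(A = 1, B = -1, C = 1), c(A = 3, B = -2, C = 2))
  p1 <- classify_promoters(runs1, "e1")
  p2 <- classify_promoters(runs2, "e2")
  sm <- similarity_matrix(list(p1, p2))
  expect_equal(diag(sm$similarity), c(e1 = 2L, e2 = 3L))
  expect_equal(diag(sm$dissimilarity), c(e1 = 0L, e2 = 0L))
  expect_identical(sm$similarity, t(sm$similarity))
  expect_identical(sm$dissimilarity, t(sm$dissimilarity))
  # A stable + in both (similar); C stable - vs + (dissimilar)
  expect_equal(sm$similarity["e1", "e2"], 1L)
  expect_equal(sm$dissimilarity["e1", "e2"], 1L)
  expect_error(similarity_matrix(list(p1)), "at least 2")
})

test_that("consistency tables mark positive weights per (split, run) cell", {
  cells <- expand.grid(split = 1:3, run = 1:3)
  names9 <- sprintf("s%d_r%d", cells$split, cells$run)
  tbl <- c("X..........." = 0.5, "Y..........." = -0.2)
  always <- setNames(lapply(1:9, function(i) tbl), names9)
  ct <- consistency_table(list(mr = always, fr = always))
  expect_equal(ct$row_totals["X...........", "mr"], 9)
  expect_equal(ct$row_totals["Y...........", "mr"], 0)
  expect_equal(unname(ct$grand_totals), unname(colSums(ct$row_totals)))
  # a rectangular design is required
  broken <- always[1:8]
  expect_error(consistency_table(list(mr = always, fr = broken)), "design")
})

test_that("the published carcinogenicity indicators reproduce row totals", {
  cells <- read_consistency_cells(
    system.file("extdata", "carcinogenicity_promoters.tsv", package = "cwqsar"))
  expect_named(cells, c("mr", "fr"))
  ct <- consistency_table(cells)
  expect_equal(ct$row_totals["HALO00000000", "mr"], 9)
  expect_equal(ct$row_totals["HALO00000000", "fr"], 0)
  expect_equal(ct$row_totals["BOND00000000", "fr"], 9)
  expect_equal(ct$row_totals["BOND10100000", "mr"], 9)
  expect_equal(ct$row_totals["NNC-C...211.", "mr"], 9)
  expect_equal(ct$row_totals["NNC-C...211.", "fr"], 9)
  # grand totals equal the sum of row totals by construction
  expect_equal(unname(ct$grand_totals), unname(colSums(ct$row_totals)))
})

test_that("rendered reports list agreeing attributes before disagreeing", {
  prs <- fixture_pairs()
  rep <- render_profile_report(prs[[1]]$a, prs[[1]]$b)
  agree_at <- which(rep == "# agreeing promoters")
  oppose_at <- which(rep == "# opposing promoters")
  expect_length(agree_at, 1L)
  expect_length(oppose_at, 1L)
  expect_equal(oppose_at - agree_at - 1L, 10L)   # agreement rows
  expect_equal(length(rep) - oppose_at, 8L)      # disagreement rows
  keys <- substr(rep[-c(1L, agree_at, oppose_at)], 1L, 12L)
  expect_true(all(nchar(keys) == 12L))
})

test_that("profiles from shared planted weights are similar, flipped ones dissimilar", {
  ds <- synth_dataset(n = 60, seed = 17)
  attrs <- lapply(ds$data$smiles, extract_attributes)
  flipped <- ds$planted
  flipped$weights <- -flipped$weights
  y_same <- simulate_endpoint(ds$molecules, ds$planted, seed = 100)$endpoint
  y_flip <- simulate_endpoint(ds$molecules, flipped, seed = 101)$endpoint
  cfg <- descriptor_config(epochs_N = 12)
  fit_runs <- function(y, seeds) {
    run_ensemble(attrs, y, cfg, seeds = seeds, init_mode = "uniform")
  }
  p_a <- classify_promoters(fit_runs(ds$data$endpoint, c(1, 2, 3)), "a")
  p_same <- classify_promoters(fit_runs(y_same, c(4, 5, 6)), "same")
  p_flip <- classify_promoters(fit_runs(y_flip, c(7, 8, 9)), "flip")
  same_cmp <- compare_profiles(p_a, p_same)
  flip_cmp <- compare_profiles(p_a, p_flip)
  expect_gte(same_cmp[["similarity"]], 5 * same_cmp[["dissimilarity"]])
  expect_gte(flip_cmp[["dissimilarity"]], 5 * flip_cmp[["similarity"]])
})
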