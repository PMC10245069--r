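freq_pair_2x1 <- function() {
  # one position, one variant cell; cpm values chosen for hand computation
  cpm_sel <- matrix(0, 1, 21, dimnames = list(1, aa_alphabet()))
  cpm_unsel <- cpm_sel
  cpm_sel[1, "G"] <- 100
  cpm_unsel[1, "G"] <- 200
  wt_aa <- c(`1` = "M")
  list(sel = make_freq(cpm_sel, 1000, wt_aa),
       unsel = make_freq(cpm_unsel, 500, wt_aa))
}

test_that("mutational cost matches direct substitution into the log-ratio", {
  fp <- freq_pair_2x1()
  fl <- compute_fitness(fp$sel, fp$unsel)
  # log(100/200) - log(1000/500) = log(0.5) - log(2)
  expect_equal(fl$delta_E[1, "G"], log(0.5) - log(2), tolerance = 1e-12)
  expect_equal(fl$delta_E[1, "G"], -1.3863, tolerance = 1e-4)
  # WT cell is exactly zero
  expect_identical(fl$delta_E[1, "M"], 0)
})

test_that("a variant enriched like the wild type scores zero", {
  cpm_sel <- matrix(0, 1, 21, dimnames = list(1, aa_alphabet()))
  cpm_unsel <- cpm_sel
  cpm_sel[1, "G"] <- 300; cpm_unsel[1, "G"] <- 100
  fl <- compute_fitness(make_freq(cpm_sel, 600, c(`1` = "M")),
                        make_freq(cpm_unsel, 200, c(`1` = "M")))
  expect_equal(fl$delta_E[1, "G"], 0, tolerance = 1e-12)
})

test_that("scores are invariant to uniform rescaling of one condition", {
  lib <- generate_nns_library(small_cds(5, seed = 3))
  truth <- simulate_true_effects(lib, seed = 2)
  pre <- library_frequencies(lib)
  post <- simulate_selection(pre, truth)
  fl <- compute_fitness(post, pre)
  scaled <- post
  scaled$cpm <- post$cpm * 7.3
  scaled$wt_cpm <- post$wt_cpm * 7.3
  fl2 <- compute_fitness(scaled, pre)
  expect_equal(fl$delta_E, fl2$delta_E, tolerance = 1e-12)
})

test_that("zero wild-type frequency is an error; zero variant cells go NA", {
  fp <- freq_pair_2x1()
  bad <- fp$sel; bad$wt_cpm <- 0
  expect_error(compute_fitness(bad, fp$unsel), "positive")
  z <- fp$unsel; z$cpm[1, "G"] <- 0
  fl <- compute_fitness(fp$sel, z)
  expect_true(is.na(fl$delta_E[1, "G"]))
})

test_that("log base is configurable", {
  fp <- freq_pair_2x1()
  nat <- compute_fitness(fp$sel, fp$unsel)
  two <- compute_fitness(fp$sel, fp$unsel, log_base = 2)
  expect_equal(two$delta_E[1, "G"], nat$delta_E[1, "G"] / log(2),
               tolerance = 1e-12)
})

test_that("replicate averaging is cell-wise with NA-tolerant partial flags", {
  d1 <- matrix(-1, 2, 21, dimnames = list(1:2, aa_alphabet()))
  d2 <- matrix(-3, 2, 21, dimnames = list(1:2, aa_alphabet()))
  wt_aa <- c(`1` = "M", `2` = "A")
  l1 <- mlascan:::new_landscape(d1, wt_aa)
  l2 <- mlascan:::new_landscape(d2, wt_aa)
  avg <- average_replicates(list(l1, l2))
  expect_equal(avg$delta_E[1, "G"], -2)
  # single replicate: identity
  expect_equal(average_replicates(list(l1))$delta_E, l1$delta_E)
  # partial observation
  l2$delta_E[1, "G"] <- NA
  avg2 <- average_replicates(list(l1, l2))
  expect_equal(avg2$delta_E[1, "G"], -1)
  expect_true(avg2$partial[1, "G"])
  expect_false(avg2$partial[1, "C"])
  # both NA stays NA
  l1$delta_E[1, "G"] <- NA
  expect_true(is.na(average_replicates(list(l1, l2))$delta_E[1, "G"]))
  # shape mismatch
  l3 <- mlascan:::new_landscape(matrix(0, 1, 21,
                                       dimnames = list(1, aa_alphabet())),
                                c(`1` = "M"))
  expect_error(average_replicates(list(l1, l3)), "mismatch")
})

test_that("position summary equals the brute-force mean over mutations", {
  set.seed(9)
  d <- matrix(rnorm(3 * 21), 3, 21, dimnames = list(1:3, aa_alphabet()))
  wt_aa <- c(`1` = "M", `2` = "A", `3` = "G")
  d[cbind(1:3, match(wt_aa, aa_alphabet()))] <- 0
  l <- mlascan:::new_landscape(d, wt_aa)
  ps <- position_summary(l)
  for (i in 1:3) {
    manual <- mean(d[i, setdiff(aa_alphabet(), wt_aa[i])])
    expect_equal(unname(ps[i]), manual, tolerance = 1e-12)
  }
  # constant rows
  d2 <- d; d2[] <- -2; d2[cbind(1:3, match(wt_aa, aa_alphabet()))] <- 0
  expect_equal(unname(position_summary(mlascan:::new_landscape(d2, wt_aa))),
               rep(-2, 3))
})

test_that("the toy landscape selects exactly position 2 under k=5, m=1", {
  l <- toy_selection_landscape()
  sel <- select_functional_residues(l, k = 5, m = 1)
  expect_equal(sel$selected_positions, 2L)
  expect_equal(sel$mu, -0.3, tolerance = 1e-12)
  expect_equal(sel$sigma, 0.9, tolerance = 0.01)  # sample vs population SD
  expect_equal(unname(sel$qualifying[c("1", "2", "3")]), c(0, 6, 0))
})

test_that("on a pure-noise landscape the rule fires at its calibrated false-positive rate", {
  # the 1-SD rule is scale-free, so on an all-neutral landscape with iid
  # gaussian noise each position is selected with probability
  # P(Binom(20, pnorm(-1)) >= 5), regardless of the noise amplitude
  set.seed(5)
  n_pos <- 400
  d <- matrix(rnorm(n_pos * 21, 0, 0.01), n_pos, 21,
              dimnames = list(seq_len(n_pos), aa_alphabet()))
  wt_aa <- stats::setNames(rep("M", n_pos), seq_len(n_pos))
  d[, "M"] <- 0
  sel <- select_functional_residues(mlascan:::new_landscape(d, wt_aa),
                                    k = 5, m = 1)
  expected_fp <- stats::pbinom(4, 20, stats::pnorm(-1), lower.tail = FALSE)
  observed_fp <- length(sel$selected_positions) / n_pos
  expect_equal(observed_fp, expected_fp, tolerance = 0.35)
  # raising the multiplier suppresses the false positives
  sel3 <- select_functional_residues(mlascan:::new_landscape(d, wt_aa),
                                     k = 5, m = 3)
  expect_lt(length(sel3$selected_positions) / n_pos, 0.01)
})

test_that("selection grows monotonically as k or m decrease", {
  lib <- generate_nns_library(small_cds(40, seed = 19),
                              sublibraries = list(c(1L, 40L)))
  truth <- simulate_true_effects(lib, seed = 7)
  pre <- library_frequencies(lib)
  fl <- compute_fitness(simulate_selection(pre, truth), pre)
  sel_ref <- select_functional_residues(fl, k = 5, m = 1)$selected_positions
  for (k in c(4, 3, 1)) {
    s <- select_functional_residues(fl, k = k, m = 1)$selected_positions
    expect_true(all(sel_ref %in% s))
  }
  for (m in c(0.8, 0.5, 0.2)) {
    s <- select_functional_residues(fl, k = 5, m = m)$selected_positions
    expect_true(all(sel_ref %in% s))
  }
  # two-sided selection contains the one-sided set at the same parameters
  s2 <- select_functional_residues(fl, k = 5, m = 1,
                                   sided = "two_sided")$selected_positions
  expect_true(all(sel_ref %in% s2))
})

test_that("degenerate landscapes cannot be thresholded", {
  d <- matrix(0, 2, 21, dimnames = list(1:2, aa_alphabet()))
  l <- mlascan:::new_landscape(d, c(`1` = "M", `2` = "A"))
  expect_error(select_functional_residues(l), "degenerate")
})

test_that("group classification follows the stated precedence", {
  l <- toy_selection_landscape()
  sel <- select_functional_residues(l, k = 5, m = 1)
  annot <- list(signal_peptide = c(1, 21), pocket_positions = 2,
                buried_positions = integer(0), surface_positions = integer(0))
  # position 2 is inside the signal-peptide range: precedence wins
  g <- classify_groups(sel, annot)
  expect_equal(g$signal_peptide, 2L)
  expect_equal(unname(g$counts[c("signal_peptide", "pocket")]), c(1L, 0L))
  # outside the signal peptide it falls to the pocket
  annot2 <- list(signal_peptide = c(10, 21), pocket_positions = 2,
                 buried_positions = integer(0), surface_positions = integer(0))
  g2 <- classify_groups(sel, annot2)
  expect_equal(g2$pocket, 2L)
  # unannotated positions warn and go unclassified
  annot3 <- list(signal_peptide = c(10, 21))
  expect_warning(g3 <- classify_groups(sel, annot3), "not covered")
  expect_equal(g3$unclassified, 2L)
  # empty selection -> empty report
  sel0 <- sel; sel0$selected_positions <- integer(0)
  g0 <- classify_groups(sel0, annot)
  expect_true(all(g0$counts == 0))
})

test_that("landscape TSV and MaveDB score exports round trip", {
  lib <- generate_nns_library(small_cds(4, seed = 23))
  truth <- simulate_true_effects(lib, seed = 3)
  pre <- library_frequencies(lib)
  fl <- compute_fitness(simulate_selection(pre, truth), pre)
  f1 <- tempfile(fileext = ".tsv")
  write_landscape_tsv(fl, f1)
  df <- read.delim(f1)
  expect_equal(nrow(df), 4 * 21)
  f2 <- tempfile(fileext = ".csv")
  write_mavedb_scores(fl, f2)
  back <- read_mavedb_scores(f2, L = 4)
  idx <- !is.na(back$delta_E)
  expect_equal(back$delta_E[idx], fl$delta_E[idx], tolerance = 1e-6)
  expect_equal(back$wt_aa, fl$wt_aa)
  unlink(c(f1, f2))
})
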