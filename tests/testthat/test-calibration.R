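nt_obs <- abundance_vector(fixture_column("nt"), basis = "classified",
                           sample_id = "mock_nt")

test_that("confusion counts on the benchmark column match an
           enumeration oracle", {
  # oracle: count fixture values directly, independent of
  # confusion_counts()
  vals <- fixture_column("nt")
  decl <- attr(vals, "declared")
  for (th in c(0.1, 0.5)) {
    tp_oracle <- sum(!is.na(decl) & vals >= th)
    fp_oracle <- sum(is.na(decl) & vals >= th)
    cc <- confusion_counts(nt_obs, mock_spec(), th)
    expect_equal(cc$tp, tp_oracle)
    expect_equal(cc$fp, fp_oracle)
    expect_equal(cc$fn, 20 - tp_oracle)
  }
  cc1 <- confusion_counts(nt_obs, mock_spec(), 0.1)
  expect_equal(unlist(cc1[c("tp", "fp", "fn")]),
               c(tp = 14, fp = 1, fn = 6))
  cc5 <- confusion_counts(nt_obs, mock_spec(), 0.5)
  expect_equal(unlist(cc5[c("tp", "fp", "fn")]),
               c(tp = 10, fp = 0, fn = 10))
})

test_that("a perfect observation scores perfectly", {
  ref <- mock_spec()
  obs <- declared_abundances(ref)
  cc <- confusion_counts(obs, ref, threshold = 0.01)
  expect_equal(unlist(cc[c("tp", "fp", "fn")]),
               c(tp = 20, fp = 0, fn = 0))
  expect_equal(f1_score(cc), 1)
})

test_that("F1 is 2TP/(2TP+FP+FN) and the precision/recall harmonic
           mean", {
  expect_equal(f1_score(confusion(14, 1, 6)), 0.8)
  expect_equal(round(f1_score(confusion(19, 188, 1)), 2), 0.17)
  for (n in c(1, 7, 100))
    expect_equal(f1_score(confusion(n, 0, 0)), 1)
  expect_error(f1_score(confusion(0, 0, 0)), "undefined")
  set.seed(9)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(f1_score(confusion(tp, fp, fn)),
                 2 * prec * rec / (prec + rec))
  }
})

test_that("threshold sweeps are monotone and conserve the reference
           size", {
  sw <- threshold_sweep(nt_obs, mock_spec())
  expect_s3_class(sw, "threshold_sweep")
  expect_true(all(diff(sw$tp) <= 0))
  expect_true(all(diff(sw$fp) <= 0))
  expect_true(all(diff(sw$fn) >= 0))
  expect_true(all(sw$tp + sw$fn == 20))
  set.seed(11)
  for (i in 1:10) {
    p <- random_profile(n_species = 10, depth = 1e4)
    obs <- relative_abundances(p)
    ref <- community_spec(c(setNames(c(40, 30, 20, 10),
                                     names(p$counts)[1:4])))
    sw <- threshold_sweep(obs, ref, thresholds = c(0.01, 0.1, 1, 5, 20))
    expect_true(all(diff(sw$tp) <= 0))
    expect_true(all(diff(sw$fn) >= 0))
    expect_true(all(sw$tp + sw$fn == 4))
  }
})

test_that("sweep of the benchmark column reproduces the recomputable
           published rows", {
  sw <- threshold_sweep(nt_obs, mock_spec(), thresholds = c(0.1, 0.5))
  expect_equal(round(sw$f1, 2), c(0.8, 0.67))
  expect_error(threshold_sweep(nt_obs, mock_spec(), c(0.1, 0.1)),
               "duplicate")
  expect_error(threshold_sweep(nt_obs, mock_spec(), numeric()),
               "no thresholds")
  # one-threshold sweep equals the composition of its parts
  one <- threshold_sweep(nt_obs, mock_spec(), 0.25)
  cc <- confusion_counts(nt_obs, mock_spec(), 0.25)
  expect_equal(one$f1, f1_score(cc))
  expect_equal(one$tp, cc$tp)
})

test_that("best threshold maximises F1 with ties toward the smallest", {
  t1 <- load_fixture("table1")
  sw <- sweep_from_confusion(t1$threshold, t1$tp, t1$fp, t1$fn)
  expect_equal(best_threshold(sw), 0.1)
  expect_equal(round(sw$f1, 2), t1$f1, tolerance = 5e-3)
  flat <- threshold_sweep(declared_abundances(mock_spec()),
                          mock_spec(), c(0.001, 0.005, 0.01))
  expect_true(all(flat$f1 == 1))
  expect_equal(best_threshold(flat), 0.001)
  single <- threshold_sweep(nt_obs, mock_spec(), 0.5)
  expect_equal(best_threshold(single), 0.5)
})

test_that("community specs validate their declared composition", {
  expect_error(community_spec(c(A = 50, A = 50)), "unique")
  expect_error(community_spec(c(A = 50, B = 49)), "sum to 100")
  expect_error(community_spec(c(A = 100, B = 0)), "> 0")
  expect_silent(community_spec(c(A = 50, B = 50)))
})

test_that("sweeps export in the published table layout", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(threshold_sweep(nt_obs, mock_spec(), c(0.1, 0.5)), f)
  tab <- read.delim(f)
  expect_named(tab, c("Threshold", "TP", "FP", "FN", "F1"))
  expect_equal(tab$TP, c(14, 10))
})
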