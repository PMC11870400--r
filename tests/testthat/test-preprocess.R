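make_blank_fixture <- function(values) {
  # first row is the blank
  ids <- c("blank1", paste0("s", seq_len(nrow(values) - 1)))
  dimnames(values) <- list(ids, paste0("f", seq_len(ncol(values))))
  md <- data.frame(type = c("blank", rep("sample", nrow(values) - 1)),
                   row.names = ids)
  list(table = feature_table(values), metadata = md)
}

test_that("blank filter applies the strict fold rule with the >= fraction rule", {
  # blank 10; non-blank [5, 25, 25, 25]; k = 2 -> threshold 20, 3/4 exceed
  fx <- make_blank_fixture(matrix(c(10, 5, 25, 25, 25), ncol = 1))
  kept <- blank_filter(fx$table, fx$metadata, "type", "blank",
                       fold_threshold = 2, min_nonblank_fraction = 0.5)
  expect_identical(colnames(kept$table), "f1")
  removed <- blank_filter(fx$table, fx$metadata, "type", "blank",
                          fold_threshold = 2, min_nonblank_fraction = 0.9)
  expect_identical(removed$report$removed_feature_ids, "f1")
  expect_equal(removed$report$n_features_after, 0L)

  # all-zero blanks: any positive intensity exceeds k * 0 strictly
  fx0 <- make_blank_fixture(matrix(c(0, 1e-6, 2, 0, 5), ncol = 1))
  for (k in c(0.1, 3, 100)) {
    res <- blank_filter(fx0$table, fx0$metadata, "type", "blank",
                        fold_threshold = k, min_nonblank_fraction = 0.5)
    expect_identical(colnames(res$table), "f1")
  }
  # ...but not with p too high (only 3/4 positive)
  res <- blank_filter(fx0$table, fx0$metadata, "type", "blank",
                      fold_threshold = 1, min_nonblank_fraction = 0.9)
  expect_equal(res$report$n_removed, 1L)
})

test_that("blank filter keeps samples, fills the report, and validates inputs", {
  fx <- make_blank_fixture(matrix(c(10, 50, 50, 1, 1, 1), 3, 2))
  res <- blank_filter(fx$table, fx$metadata, "type", "blank", 2, 0.5)
  expect_identical(rownames(res$table), rownames(fx$table)) # blanks retained
  rep <- res$report
  expect_equal(rep$n_features_after + rep$n_removed, rep$n_features_before)
  expect_equal(rep$retained_fraction, rep$n_features_after / rep$n_features_before)
  expect_output(print(rep), "removed 1 of 2")

  md_noblank <- data.frame(type = rep("sample", 3), row.names = rownames(fx$table))
  expect_error(blank_filter(fx$table, md_noblank, "type", "blank"),
               "no blank samples.*skip")
  md_allblank <- data.frame(type = rep("blank", 3), row.names = rownames(fx$table))
  expect_error(blank_filter(fx$table, md_allblank, "type", "blank"),
               "no non-blank")
  expect_error(blank_filter(fx$table, fx$metadata, "type", "blank", -1, 0.5),
               "fold_threshold")
  expect_error(blank_filter(fx$table, fx$metadata, "type", "blank", 2, 1.5),
               "min_nonblank_fraction")
})

test_that("blank filter matches the brute-force oracle and is monotone", {
  set.seed(42)
  for (draw in seq_len(30)) {
    n <- sample(4:20, 1); p <- sample(3:40, 1)
    n_blank <- sample(1:3, 1)
    vals <- matrix(rlnorm(n * p, 2, 1.5), n, p)
    vals[matrix(runif(n * p) < 0.3, n, p)] <- 0
    dimnames(vals) <- list(paste0("s", 1:n), paste0("f", 1:p))
    md <- data.frame(type = c(rep("blank", n_blank), rep("bio", n - n_blank)),
                     row.names = rownames(vals))
    k <- runif(1, 0.1, 5); pr <- runif(1, 0.05, 1)
    res <- blank_filter(feature_table(vals), md, "type", "blank", k, pr)
    expect_identical(retained_ids(res),
                     oracle_blank_filter(vals, md$type == "blank", k, pr))
    # monotone in both parameters
    tighter_k <- blank_filter(feature_table(vals), md, "type", "blank", k * 2, pr)
    expect_true(all(colnames(tighter_k$table) %in% colnames(res$table)))
    tighter_p <- blank_filter(feature_table(vals), md, "type", "blank", k,
                              min(1, pr + 0.3))
    expect_true(all(colnames(tighter_p$table) %in% colnames(res$table)))
  }
})

test_that("TIC normalization yields row-stochastic output and is idempotent", {
  m <- matrix(c(2, 2, 1, 3, 6, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  tic <- normalize_tic(feature_table(m))
  expect_equal(unname(tic["s1", ]), c(2, 2, 1) / 5, tolerance = 1e-12)
  expect_equal(unname(tic["s2", ]), c(3, 6, 0) / 9, tolerance = 1e-12)
  expect_equal(unname(rowSums(tic)), c(1, 1), tolerance = 1e-12)
  expect_table_equal(normalize_tic(tic), tic)

  zero <- matrix(c(1, 0, 2, 0), 2, 2,
                 dimnames = list(c("ok", "empty"), c("f1", "f2")))
  expect_error(normalize_tic(feature_table(zero)), "empty")
})

test_that("hand-computed TIC example [1,3,6] -> [0.1,0.3,0.6]", {
  m <- matrix(c(1, 3, 6, 2, 2, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  tic <- normalize_tic(feature_table(m))
  expect_equal(unname(tic["a", ]), c(0.1, 0.3, 0.6), tolerance = 1e-12)
})

test_that("PQN is dilution-invariant and identity on identical samples", {
  # identical samples: every dilution factor is 1 -> equals TIC output
  m <- matrix(rep(c(1, 3, 6), 3), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
  expect_table_equal(normalize_pqn(feature_table(m)),
                     normalize_tic(feature_table(m)))

  # hand computation: B = 2 x A elementwise collapses to A after TIC already;
  # dilution invariance must hold for arbitrary per-sample factors
  set.seed(7)
  base <- matrix(rlnorm(8 * 12, 3, 1), 8, 12,
                 dimnames = list(paste0("s", 1:8), paste0("f", 1:12)))
  ref <- normalize_pqn(feature_table(base))
  scaled <- base
  scaled[5, ] <- scaled[5, ] * 13.7
  out <- normalize_pqn(feature_table(scaled))
  expect_lt(max(abs(out - ref) / pmax(abs(ref), 1e-300)), 1e-9)

  single <- matrix(1:3, 1, 3, dimnames = list("s1", paste0("f", 1:3)))
  expect_error(normalize_pqn(feature_table(single)), "at least 2 samples")
})

test_that("auto-scaling gives unit-variance centered columns (n-1 convention)", {
  m <- matrix(c(1, 3, 4, 8), 2, 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  sc <- scale_auto(feature_table(m))
  expect_equal(unname(sc[, "f1"]), c(-0.70710678118654752, 0.70710678118654752),
               tolerance = 1e-12)
  ft <- toy_table(31, n = 12, p = 20, sparsity = 0.1)
  sc2 <- scale_auto(ft)
  expect_lt(max(abs(colMeans(sc2))), 1e-12)
  expect_equal(unname(apply(as.matrix(sc2), 2, sd)), rep(1, 20),
               tolerance = 1e-12)
  # constant columns become zeros with a warning, not an error
  mc <- cbind(as.matrix(ft), const = 5)
  expect_warning(scz <- scale_auto(feature_table(mc)), "constant")
  expect_equal(unname(scz[, "const"]), rep(0, 12))
  expect_error(scale_auto(feature_table(matrix(1, 1, 1,
    dimnames = list("s", "f")))), "at least 2")
})

test_that("Pareto scaling divides by sqrt(sd) and damps rather than equalizes", {
  m <- matrix(c(1, 3, 0, 1), 2, 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  sc <- scale_pareto(feature_table(m))
  expect_equal(unname(sc[, "f1"]), c(-1, 1) / 2^(1/4), tolerance = 1e-10)
  expect_equal(unname(sc["s2", "f1"]), 0.84089641525, tolerance = 1e-9)
  # pareto variance equals auto variance * sd, per column
  ft <- toy_table(77, n = 10, p = 15, sparsity = 0)
  va <- apply(as.matrix(scale_auto(ft)), 2, var)
  vp <- apply(as.matrix(scale_pareto(ft)), 2, var)
  s <- apply(as.matrix(ft), 2, sd)
  expect_equal(vp, va * s, tolerance = 1e-10)
  # location invariance of both scalers
  shifted <- as.matrix(ft); shifted[, 3] <- shifted[, 3] + 1000
  expect_equal(unname(as.matrix(scale_auto(feature_table(shifted)))),
               unname(as.matrix(scale_auto(ft))), tolerance = 1e-9)
  expect_equal(unname(as.matrix(scale_pareto(feature_table(shifted)))),
               unname(as.matrix(scale_pareto(ft))), tolerance = 1e-9)
})

test_that("preprocess composes the stages in fixed order", {
  sim <- simulate_feature_table(fixture_spec(
    n_blank = 3, n_groups = 2, n_samples_per_group = 5,
    n_contaminant_features = 20, n_biological_features = 60, seed = 5))
  # all-none is the identity
  idn <- preprocess(sim$table, sim$metadata)
  expect_table_equal(idn$table, sim$table)
  expect_null(idn$report)
  # filter + tic + auto equals manual composition
  res <- preprocess(sim$table, sim$metadata,
                    filter = list(blank_column = "sample_type",
                                  blank_value = "blank",
                                  fold_threshold = 2,
                                  min_nonblank_fraction = 0.05),
                    normalization = "tic", scaling = "auto")
  manual <- blank_filter(sim$table, sim$metadata, "sample_type", "blank",
                         2, 0.05)
  expect_identical(res$report$n_removed, manual$report$n_removed)
  expect_table_equal(res$table, scale_auto(normalize_tic(manual$table)))
  # unknown method names are rejected before running anything
  expect_error(preprocess(sim$table, sim$metadata, normalization = "quantile"),
               "arg")
  expect_error(preprocess(sim$table, filter = list(blank_column = "x",
                                                   blank_value = "y")),
               "metadata")
})
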