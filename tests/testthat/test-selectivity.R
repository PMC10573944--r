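# Cross-receptor evaluation tests run on deliberately small synthetic
# pairs and narrow networks so the protocol logic (not model quality)
# is what is exercised here.

small_sets <- function(overlap = 0, seed = 13, n_bits = 256) {
  pair <- generate_subtype_pair(generator_spec(
    n_scaffolds = 6, substituents_per_scaffold = 12, overlap = overlap,
    seed = seed))
  prepare_receptor_sets(list(A = clean_dataset(pair$A),
                             B = clean_dataset(pair$B)),
                        seed = seed, n_bits = n_bits)
}

test_that("cross-evaluation produces one cell per train/validation pair", {
  sets <- small_sets()
  sp <- tiny_spec(epochs = 8, seed = 2)
  cem <- cross_evaluate(sets, sp, n_runs = 1, base_seed = 2)
  expect_s3_class(cem, "cross_eval_matrix")
  expect_equal(nrow(cem), 4)                         # 2 x 2 receptors
  expect_setequal(paste(cem$train_receptor, cem$val_receptor),
                  c("A A", "A B", "B A", "B B"))
  # matched cells have accuracy_change exactly 0
  diag <- cem[cem$train_receptor == cem$val_receptor, ]
  expect_true(all(diag$accuracy_change == 0))
  # off-diagonal change is other minus matched
  offd <- cem[cem$train_receptor == "A" & cem$val_receptor == "B", ]
  expect_equal(offd$accuracy_change,
               offd$accuracy - diag$accuracy[diag$train_receptor == "A"])
  # Tanimoto diagnostics present and bounded
  expect_true(all(cem$avg_tanimoto >= 0 & cem$avg_tanimoto <= 1))
  expect_error(cross_evaluate(sets["A"], sp), "at least 2")
})

test_that("three receptors give nine cells", {
  pair <- generate_subtype_pair(generator_spec(
    n_scaffolds = 5, substituents_per_scaffold = 8, seed = 4))
  third <- generate_receptor_library(generator_spec(
    n_scaffolds = 5, substituents_per_scaffold = 8, seed = 40), "C")
  sets <- prepare_receptor_sets(list(A = clean_dataset(pair$A),
                                     B = clean_dataset(pair$B),
                                     C = clean_dataset(third)),
                                seed = 4, n_bits = 256)
  cem <- cross_evaluate(sets, tiny_spec(epochs = 5), n_runs = 1)
  expect_equal(nrow(cem), 9)
})

test_that("repeated-run summaries average deterministic single runs", {
  sets <- small_sets(seed = 17)
  sp <- tiny_spec(epochs = 6, seed = 1)
  one <- repeated_training_summary(sets$A$train, sets$A$validation, sp,
                                   n_runs = 1, epochs = 6, base_seed = 5)
  expect_equal(one$accuracy_sd, 0)
  expect_equal(one$loss_sd, 0)
  # n_runs = 2 mean equals the arithmetic mean of the two seeded runs
  two <- repeated_training_summary(sets$A$train, sets$A$validation, sp,
                                   n_runs = 2, epochs = 6, base_seed = 5)
  runb <- repeated_training_summary(sets$A$train, sets$A$validation, sp,
                                    n_runs = 1, epochs = 6, base_seed = 6)
  expect_equal(two$accuracy_mean,
               mean(c(one$accuracy_mean, runb$accuracy_mean)),
               tolerance = 1e-12)
  expect_equal(two$loss_mean, mean(c(one$loss_mean, runb$loss_mean)),
               tolerance = 1e-12)
  expect_error(repeated_training_summary(sets$A$train, sets$A$validation,
                                         sp, n_runs = 0), "n_runs")
})

test_that("rank correlation recovers concordant and discordant patterns", {
  conc <- data.frame(accuracy = c(.1, .2, .3, .4),
                     avg_tanimoto = c(.05, .1, .2, .3))
  expect_equal(accuracy_similarity_correlation(conc)$rho, 1)
  disc <- conc; disc$avg_tanimoto <- rev(disc$avg_tanimoto)
  expect_equal(accuracy_similarity_correlation(disc)$rho, -1)
  # hand-set cells against the rank-and-sum formula
  cells <- data.frame(accuracy = c(.19, .23, .13, .32, .12),
                      avg_tanimoto = c(.139, .141, .125, .198, .124))
  got <- accuracy_similarity_correlation(cells)
  d <- rank(cells$accuracy) - rank(cells$avg_tanimoto)
  expect_equal(got$rho, 1 - 6 * sum(d^2) / (5 * (25 - 1)), tolerance = 1e-12)
  expect_equal(nrow(got$pairs), 5)
  expect_error(accuracy_similarity_correlation(conc[1:2, ]), "at least 3")
})
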