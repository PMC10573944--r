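write_pdbqt_fixture <- function(path, affinities) {
  lines <- unlist(lapply(seq_along(affinities), function(i) {
    c(sprintf("MODEL %d", i),
      sprintf("REMARK VINA RESULT:   %7.1f      0.000      0.000",
              affinities[i]),
      "ATOM      1  C   LIG     1       0.000   0.000   0.000  0.00  0.00    +0.000 C",
      "ENDMDL")
  }))
  writeLines(lines, path)
  path
}

test_that("Vina PDBQT poses parse with affinities and pose order intact", {
  f <- file.path(tempdir(), "Z123.pdbqt")
  aff <- c(-10.5, -9.8, -9.1, -8.7, -8.2, -8.0, -7.7, -7.4, -7.2, -7.0)
  write_pdbqt_fixture(f, aff)
  sc <- read_vina_scores(f)
  expect_equal(nrow(sc), 10)                 # ten binding modes per ligand
  expect_equal(sc$affinity, aff)
  expect_equal(sc$pose_index, 1:10)
  expect_equal(unique(sc$compound_id), "Z123")
  expect_equal(sc$affinity[1], -10.5)

  # directory of files
  d <- file.path(tempdir(), "dockdir")
  dir.create(d, showWarnings = FALSE)
  write_pdbqt_fixture(file.path(d, "A1.pdbqt"), c(-11, -9))
  write_pdbqt_fixture(file.path(d, "A2.pdbqt"), c(-8, -7))
  sc2 <- read_vina_scores(d)
  expect_setequal(unique(sc2$compound_id), c("A1", "A2"))
  expect_equal(nrow(sc2), 4)

  empty <- tempfile(fileext = ".pdbqt")
  writeLines("ATOM", empty)
  expect_error(read_vina_scores(empty), basename(empty))
})

test_that("delimited docking tables parse too", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(compound_id = c("a", "a", "b"),
                       affinity = c(-11, -10, -9)), f, row.names = FALSE)
  sc <- read_vina_scores(f)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$pose_index, c(1, 2, 1))
})

test_that("the energy cutoff is inclusive, idempotent and order-preserving", {
  sc <- data.frame(compound_id = c("a", "b", "c"),
                   pose_index = 1L,
                   affinity = c(-11.2, -10.5, -9.8), source = "t")
  kept <- apply_energy_cutoff(sc)
  expect_equal(kept$compound_id, c("a", "b"))   # -10.5 itself passes
  expect_identical(apply_energy_cutoff(kept), kept)
  expect_equal(nrow(apply_energy_cutoff(sc, Inf)), 3)
  expect_equal(nrow(apply_energy_cutoff(sc[0, ])), 0)
})

test_that("best pose per compound is the minimum affinity", {
  sc <- generate_dock_scores(c("x", "y"), seed = 3, mean = -8, sd = 1)
  best <- best_pose_scores(sc)
  expect_equal(best$best_affinity[best$compound_id == "x"],
               min(sc$affinity[sc$compound_id == "x"]))
})

test_that("consensus selection is the intersection of both arms", {
  # toy: 3 NN-selected, 2 dock-passing, 1 common id
  P <- one_hot(c(7L, 7L, 7L, 2L))
  r <- score_screen(P, c("n1", "n2", "n3", "low"))
  dock <- data.frame(compound_id = c("n2", "d9", "low"),
                     pose_index = 1L,
                     affinity = c(-11, -12, -13), source = "t")
  hits <- consensus_select(r, dock)
  expect_equal(hits$compound_id, "n2")
  expect_true(all(hits$passed_nn & hits$passed_dock))
  # empty docking arm -> warning, no hits
  expect_warning(h0 <- consensus_select(r, dock[0, ]), "overlap")
  expect_equal(nrow(h0), 0)
  # identical id sets all passing -> all hits, ordered by score then affinity
  dock2 <- data.frame(compound_id = c("n1", "n2", "n3"), pose_index = 1L,
                      affinity = c(-11, -12, -10.6), source = "t")
  h2 <- consensus_select(r, dock2)
  expect_setequal(h2$compound_id, c("n1", "n2", "n3"))
  expect_equal(h2$best_affinity, sort(h2$best_affinity))  # equal scores: affinity asc
})

test_that("top-n docking arm substitutes for the cutoff", {
  P <- one_hot(rep(7L, 4))
  r <- score_screen(P, sprintf("m%d", 1:4))
  dock <- data.frame(compound_id = sprintf("m%d", 1:4), pose_index = 1L,
                     affinity = c(-9, -10, -8, -7), source = "t")
  hits <- consensus_select(r, dock, cutoff = -10.5, top_n = 2)
  expect_setequal(hits$compound_id, c("m1", "m2"))
})

test_that("consensus equals a brute-force set intersection on random instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    ids <- sprintf("c%02d", 1:n)
    cls <- sample(1:7, n, replace = TRUE)
    r <- score_screen(one_hot(cls), ids)
    dk <- data.frame(compound_id = rep(ids, each = 3), pose_index = 1:3,
                     affinity = round(rnorm(3 * n, -10, 1.2), 2), source = "t")
    hits <- suppressWarnings(consensus_select(r, dk))
    best <- tapply(dk$affinity, dk$compound_id, min)
    brute <- intersect(ids[cls == 7], names(best)[best <= -10.5])
    expect_setequal(hits$compound_id, brute)
    expect_lte(nrow(hits), min(sum(cls == 7), sum(best <= -10.5)))
  }
})
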