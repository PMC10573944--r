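test_that("model construction echoes the spec and normalizes outputs", {
  sp <- tiny_spec()
  m <- build_model(sp)
  dims <- lapply(m$params$W, dim)
  expect_equal(dims, list(c(256L, 32L), c(32L, 16L), c(16L, 7L)))
  set.seed(1)
  X <- matrix(random_bits(10 * 256), nrow = 10)
  P <- predict_proba(m, X)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-9)
  expect_true(all(P >= 0))
  # same seed -> identical untrained predictions; different seed -> not
  expect_identical(P, predict_proba(build_model(sp), X))
  sp2 <- tiny_spec(seed = 4)
  expect_false(identical(P, predict_proba(build_model(sp2), X)))
})

argmax_class_for_test <- function(model, X) {
  apply(predict_proba(model, X), 1, which.max)
}

test_that("training contracts: degenerate fits, epoch bounds, label checks", {
  sp <- tiny_spec(epochs = 40)
  set.seed(2)
  X <- matrix(random_bits(30 * 256, 0.2), nrow = 30)
  # single-class set is memorized
  m <- train_model(build_model(sp), X, rep(5L, 30))
  expect_equal(unname(argmax_class_for_test(m, X)), rep(5L, 30))
  expect_equal(evaluate_model(m, X, rep(5L, 30))$accuracy, 1)
  # epochs = 1 appends exactly one history row; epochs = 0 is an error
  m1 <- train_model(build_model(sp), X, rep(5L, 30), epochs = 1)
  expect_equal(nrow(m1$history), 1)
  expect_error(train_model(build_model(sp), X, rep(5L, 30), epochs = 0),
               "epochs")
  expect_error(train_model(build_model(sp), X, rep(8L, 30)), "1..7")
  expect_error(train_model(build_model(sp), X[0, , drop = FALSE], integer(0)),
               "Empty")
})

test_that("prediction is a pure function with shape guarantees", {
  m <- build_model(tiny_spec())
  X <- matrix(random_bits(256, 0.2), nrow = 1)
  expect_equal(nrow(predict_proba(m, X[0, , drop = FALSE])), 0)
  P2 <- predict_proba(m, rbind(X, X))
  expect_equal(P2[1, ], P2[2, ])
  expect_error(predict_proba(m, matrix(0, 2, 100)), "width")
})

test_that("evaluation matches closed forms and hand arithmetic", {
  cls <- c(1L, 3L, 7L, 2L, 5L)
  perfect <- eval_predictions(one_hot(cls), cls)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$loss, 0, tolerance = 1e-9)
  expect_equal(sum(diag(perfect$confusion)), 5)

  uniform <- eval_predictions(matrix(1 / 7, 5, 7), cls)
  expect_equal(uniform$loss, log(7), tolerance = 1e-12)

  # hand-set distributions: loss = mean(-log p_true)
  P <- rbind(c(.7, .1, .05, .05, .05, .025, .025),
             c(.1, .6, .1, .05, .05, .05, .05),
             c(.2, .2, .2, .1, .1, .1, .1))
  got <- eval_predictions(P, c(1L, 2L, 3L))
  expect_equal(got$loss, mean(-log(c(.7, .6, .2))), tolerance = 1e-12)
  expect_equal(got$accuracy, 2 / 3)  # row 3 argmax ties to class 1
  # accuracy always equals the confusion-trace ratio
  expect_equal(got$accuracy, sum(diag(got$confusion)) / sum(got$confusion))

  expect_error(evaluate_model(build_model(tiny_spec()),
                              matrix(0, 0, 256), integer(0)), "Empty")
})

test_that("argmax ties break toward the lower class", {
  P <- matrix(1 / 7, 1, 7)
  r <- score_screen(P, "t")
  expect_equal(r$predicted_class, 1L)
})

test_that("training is deterministic per seed and reduces loss", {
  d <- tiny_feature_set(seed = 5)
  sp <- tiny_spec(epochs = 30, seed = 7)
  m1 <- train_model(build_model(sp), d$X, d$classes)
  m2 <- train_model(build_model(sp), d$X, d$classes)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_lt(m1$history$loss[30], m1$history$loss[1])
})

test_that("an untrained model sits at chance on balanced random labels", {
  set.seed(31)
  n <- 700
  X <- matrix(random_bits(n * 256, 0.1), nrow = n)
  cls <- sample(rep(1:7, each = 100))
  ev <- evaluate_model(build_model(tiny_spec(seed = 8)), X, cls)
  # binomial CI around 1/7 at n = 700 (3 sigma ~ 0.04)
  expect_gt(ev$accuracy, 1 / 7 - 0.045)
  expect_lt(ev$accuracy, 1 / 7 + 0.045)
})

test_that("the classifier recovers latent classes far above chance", {
  d <- tiny_feature_set(seed = 6, n_scaffolds = 8, subs = 25)
  sp <- nn_spec(input_width = 256, hidden = c(128L, 32L), epochs = 60,
                seed = 6)
  s <- split_dataset(nrow(d$X), seed = 6)
  m <- train_model(build_model(sp), d$X[s$train_indices, ],
                   d$classes[s$train_indices])
  ev <- evaluate_model(m, d$X[s$validation_indices, ],
                       d$classes[s$validation_indices])
  expect_gt(ev$accuracy, 2 / 7)   # scaled-down recovery check, >> 1/7
})

test_that("models round-trip through the text serialization", {
  d <- tiny_feature_set(seed = 5)
  m <- train_model(build_model(tiny_spec(epochs = 5)), d$X, d$classes)
  dir <- tempfile()
  save_model(m, dir)
  back <- load_model(dir)
  expect_equal(back$spec, m$spec)
  expect_equal(predict_proba(back, d$X), predict_proba(m, d$X),
               tolerance = 1e-12)
  expect_equal(back$history, m$history, tolerance = 1e-12)
})
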