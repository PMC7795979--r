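# Small synthetic feature tables for classifier tests.
make_table <- function(X, labels, speed = 15) {
  colnames(X) <- c("asm", "entropy", "contrast", "correlation", "idm")
  seedtex:::new_feature_table(
    data.frame(X, label = labels, speed = rep(speed, length(labels))))
}

# Two (optionally three) well-separated Gaussian blobs in 5-D.
gaussian_table <- function(n_per_class, classes = c("select", "screenings"),
                           sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, 5), c(sep, rep(0, 4)), c(0, sep, rep(0, 3)))
  rows <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(rnorm(n_per_class * 5, 0, sd), n_per_class, 5) +
      matrix(centers[i, ], n_per_class, 5, byrow = TRUE)
  }))
  make_table(rows, rep(classes, each = n_per_class))
}

test_that("initialisation is deterministic and shapes follow the layer sizes", {
  m1 <- mlp_init(23, rng_seed = 9)
  m2 <- mlp_init(23, rng_seed = 9)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
  expect_equal(dim(m1$W1), c(5L, 23L))
  expect_equal(dim(m1$W2), c(23L, 3L))
  expect_length(m1$b1, 23L)
  expect_error(mlp_init(0), "hidden")
})

test_that("RMS error matches hand-computed and closed-form values", {
  m <- mlp_init(4, 1)
  tab <- gaussian_table(8)
  expect_gte(rms_error(m, tab), 0)
  # single case: output (0.5, 0.5, 0) vs target (1,0,0) -> sqrt(1/6)
  fake <- list(P = matrix(c(0.5, 0.5, 0), 1))
  Y <- matrix(c(1, 0, 0), 1)
  expect_equal(sqrt(mean((fake$P - Y)^2)), sqrt(1 / 6))
  # uniform outputs on any one-hot table -> sqrt(2/9); realised by an MLP
  # with zero output weights
  m0 <- m
  m0$W2[] <- 0
  m0$b2[] <- 0
  expect_equal(rms_error(m0, tab), sqrt(2 / 9))
  expect_error(rms_error(m, make_table(matrix(numeric(), 0, 5), character())),
               "empty")
})

test_that("classification quality counts argmax agreement with ties to lowest index", {
  tab <- gaussian_table(4, seed = 3)
  m <- mlp_init(4, 2)
  q <- classification_quality(m, tab)
  expect_true(q >= 0 && q <= 1)
  m0 <- mlp_init(4, 2)
  m0$W1[] <- 0; m0$b1[] <- 0; m0$W2[] <- 0; m0$b2[] <- 0
  # all posteriors exactly uniform -> every case predicted "select"
  expect_equal(classification_quality(m0, tab), mean(tab$label == "select"))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  for (H in c(3, 6)) {
    m <- mlp_init(H, rng_seed = H)
    X <- matrix(rnorm(10 * 5), 10, 5)
    Y <- seedtex:::one_hot(m, sample(seed_classes(), 10, replace = TRUE))
    par <- seedtex:::flatten_params(m)
    lg <- seedtex:::mlp_loss_grad(par, m, X, Y)
    h <- 1e-5
    num <- vapply(seq_along(par), function(i) {
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      (seedtex:::mlp_loss_grad(pp, m, X, Y)$loss -
         seedtex:::mlp_loss_grad(pm, m, X, Y)$loss) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(num), 1e-8)
    expect_lt(max(abs(lg$grad - num) / denom), 1e-6)
  }
})

test_that("a no-op schedule returns the initial weights", {
  tab <- gaussian_table(8, seed = 5)
  sp <- split_2_1_1(tab, 7)
  m <- mlp_init(5, 11)
  out <- mlp_train(m, sp, bp_epochs = 0, cg_max_iter = 0)
  expect_identical(out$model$W1, m$W1)
  expect_identical(out$model$W2, m$W2)
  expect_equal(out$report$rms_validation, rms_error(out$model, sp$validation))
})

test_that("well-separated Gaussian classes are learned perfectly", {
  tab <- gaussian_table(40, sep = 6, sd = 0.5, seed = 8)
  sp <- split_2_1_1(tab, 9)
  out <- mlp_train(mlp_init(6, 10), sp, bp_epochs = 30, cg_max_iter = 100)
  expect_equal(out$report$quality_test, 1.0)
  expect_lt(out$report$rms_test, 0.25)
})

test_that("training is deterministic for fixed seeds", {
  tab <- gaussian_table(12, seed = 13)
  sp <- split_2_1_1(tab, 14)
  r1 <- mlp_train(mlp_init(4, 15), sp, bp_epochs = 10, cg_max_iter = 20)
  r2 <- mlp_train(mlp_init(4, 15), sp, bp_epochs = 10, cg_max_iter = 20)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$model$W1, r2$model$W1)
})

test_that("conjugate-gradient refinement never increases the training loss", {
  tab <- gaussian_table(20, sep = 3, sd = 1, seed = 16)
  sp <- split_2_1_1(tab, 17)
  m <- mlp_init(5, 18)
  out0 <- mlp_train(m, sp, bp_epochs = 0, cg_max_iter = 0)
  out1 <- mlp_train(m, sp, bp_epochs = 0, cg_max_iter = 40)
  loss_of <- function(model, split) {
    Xs <- seedtex:::standardize(model, split$train)
    Y <- seedtex:::one_hot(model, split$train$label)
    seedtex:::mlp_loss_grad(seedtex:::flatten_params(model), model, Xs, Y)$loss
  }
  expect_lte(loss_of(out1$model, sp), loss_of(out0$model, sp) + 1e-12)
})

test_that("select_best prefers low validation RMS, then fewer hidden units", {
  mk <- function(h, v) list(model = list(hidden = h),
                            report = list(rms_validation = v))
  cands <- list(mk(8, 0.09), mk(12, 0.04), mk(4, 0.07))
  expect_equal(select_best(cands)$report$rms_validation, 0.04)
  tied <- list(mk(10, 0.05), mk(5, 0.05))
  expect_equal(select_best(tied)$model$hidden, 5)
  expect_equal(select_best(list(mk(3, 0.2)))$model$hidden, 3)
  expect_error(select_best(list()), "candidates")
})

test_that("prediction returns a normalised posterior and breaks ties low", {
  m <- mlp_init(4, 20)
  for (i in 1:5) {
    set.seed(i)
    p <- mlp_predict(m, rnorm(5))
    expect_equal(sum(p$posterior), 1, tolerance = 1e-12)
    expect_true(p$class %in% seed_classes())
  }
  m0 <- m
  m0$W1[] <- 0; m0$b1[] <- 0; m0$W2[] <- 0; m0$b2[] <- 0
  expect_equal(mlp_predict(m0, rep(0, 5))$class, "select")
  expect_error(mlp_predict(m, 1:3), "features")
})

test_that("models survive a JSON round trip", {
  tab <- gaussian_table(8, seed = 21)
  sp <- split_2_1_1(tab, 22)
  out <- mlp_train(mlp_init(4, 23), sp, bp_epochs = 5, cg_max_iter = 10)
  f <- tempfile(fileext = ".json")
  mlp_to_json(out$model, f)
  back <- mlp_from_json(f)
  expect_equal(back$W1, out$model$W1)
  expect_equal(back$center, unname(out$model$center))
  expect_equal(rms_error(back, sp$test), rms_error(out$model, sp$test))
})
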