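#' Initialise a multilayer perceptron
#'
#' One hidden layer of logistic-sigmoid units and a softmax output layer —
#' the standard architecture for one-of-N seed-class coding with five
#' texture-descriptor inputs (e.g. "MLP 5-23-3"). Weights are drawn
#' uniformly from a small symmetric range; initialisation is deterministic
#' for a fixed seed.
#'
#' @param hidden number of hidden units H (>= 1).
#' @param rng_seed integer seed for the weight draw.
#' @param n_in,n_out input and output layer sizes (defaults 5 and 3).
#' @return An `mlp_model`: weight matrices `W1` (n_in x H), `W2` (H x
#'   n_out), bias vectors `b1`, `b2`, activation identifiers, and (after
#'   training) the feature standardisation constants.
#' @export
mlp_init <- function(hidden, rng_seed = 1L, n_in = 5L, n_out = 3L) {
  if (length(hidden) != 1L || hidden < 1) {
    stop("hidden layer size must be >= 1", call. = FALSE)
  }
  hidden <- as.integer(hidden)
  with_rng(rng_seed, {
    lim <- 1 / sqrt(n_in)
    structure(list(
      n_in = as.integer(n_in), hidden = hidden, n_out = as.integer(n_out),
      W1 = matrix(runif(n_in * hidden, -lim, lim), n_in, hidden),
      b1 = runif(hidden, -lim, lim),
      W2 = matrix(runif(hidden * n_out, -lim, lim), hidden, n_out),
      b2 = runif(n_out, -lim, lim),
      hidden_activation = "logistic", output_activation = "softmax",
      rng_seed = as.integer(rng_seed),
      center = NULL, scale = NULL, classes = seed_classes()),
      class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model %d-%d-%d, logistic hidden, softmax output>\n",
              x$n_in, x$hidden, x$n_out))
  invisible(x)
}

flatten_params <- function(model) {
  c(model$W1, model$b1, model$W2, model$b2)
}

unflatten_params <- function(model, par) {
  n1 <- model$n_in * model$hidden
  n2 <- model$hidden
  n3 <- model$hidden * model$n_out
  model$W1 <- matrix(par[seq_len(n1)], model$n_in, model$hidden)
  model$b1 <- par[n1 + seq_len(n2)]
  model$W2 <- matrix(par[n1 + n2 + seq_len(n3)], model$hidden, model$n_out)
  model$b2 <- par[n1 + n2 + n3 + seq_len(model$n_out)]
  model
}

softmax_rows <- function(A) {
  Z <- exp(A - apply(A, 1, max))
  Z / rowSums(Z)
}

mlp_forward <- function(model, X) {
  A1 <- sweep(X %*% model$W1, 2, model$b1, "+")
  H <- 1 / (1 + exp(-A1))
  A2 <- sweep(H %*% model$W2, 2, model$b2, "+")
  list(H = H, P = softmax_rows(A2))
}

# Mean cross-entropy and its analytic gradient in flattened-parameter form.
mlp_loss_grad <- function(par, model, X, Y) {
  m <- unflatten_params(model, par)
  fw <- mlp_forward(m, X)
  n <- nrow(X)
  eps <- 1e-12
  loss <- -sum(Y * log(fw$P + eps)) / n
  dA2 <- (fw$P - Y) / n
  gW2 <- crossprod(fw$H, dA2)
  gb2 <- colSums(dA2)
  dH <- dA2 %*% t(m$W2)
  dA1 <- dH * fw$H * (1 - fw$H)
  gW1 <- crossprod(X, dA1)
  gb1 <- colSums(dA1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

standardize <- function(model, tab) {
  X <- as.matrix(as.data.frame(tab)[, feature_names()])
  storage.mode(X) <- "double"
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  }
  X
}

one_hot <- function(model, labels) {
  idx <- match(labels, model$classes)
  if (anyNA(idx)) stop("unknown class label", call. = FALSE)
  Y <- matrix(0, length(labels), model$n_out)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Root-mean-square error of a model on a feature table
#'
#' RMS deviation between the softmax outputs and the one-of-N class
#' targets: `sqrt(mean((output - target)^2))` over all cases and output
#' units. Zero iff the outputs match the targets exactly.
#'
#' @param model an `mlp_model`.
#' @param table a `feature_table`.
#' @return Non-negative scalar.
#' @export
rms_error <- function(model, table) {
  assert_feature_table(table)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  P <- mlp_forward(model, standardize(model, table))$P
  Y <- one_hot(model, table$label)
  sqrt(mean((P - Y)^2))
}

#' Classification quality (fraction correct)
#'
#' Fraction of cases whose argmax output equals the label; exact posterior
#' ties are broken toward the lowest class index.
#'
#' @inheritParams rms_error
#' @return Fraction in \[0, 1\].
#' @export
classification_quality <- function(model, table) {
  assert_feature_table(table)
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  P <- mlp_forward(model, standardize(model, table))$P
  pred <- max.col(P, ties.method = "first")
  mean(model$classes[pred] == table$label)
}

#' Predict the seed class of one feature vector
#'
#' @param model a trained `mlp_model`.
#' @param features numeric vector of the five texture descriptors, in the
#'   order asm, entropy, contrast, correlation, idm.
#' @return list with `class` (label) and `posterior` (softmax triple,
#'   summing to 1). Ties go to the lowest class index.
#' @export
mlp_predict <- function(model, features) {
  if (!is.numeric(features) || length(features) != model$n_in) {
    stop("expected ", model$n_in, " features", call. = FALSE)
  }
  X <- matrix(features, 1L)
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
  }
  P <- mlp_forward(model, X)$P
  list(class = model$classes[max.col(P, ties.method = "first")],
       posterior = as.numeric(P))
}

#' Train an MLP by backpropagation then conjugate-gradient refinement
#'
#' Two phases on the full training batch, minimising the mean cross-entropy
#' of the softmax outputs: first `bp_epochs` of plain gradient descent, then
#' up to `cg_max_iter` Polak–Ribiere conjugate-gradient iterations with a
#' backtracking (Armijo) line search, which never accepts a step that
#' increases the training loss. Features are standardised with z-scores
#' computed on the training subset only. Throughout both phases the
#' validation RMS error is monitored and the returned model is the snapshot
#' with the lowest validation RMS seen (early ties kept) — the "best
#' network" selection rule.
#'
#' @param model an `mlp_model` from [mlp_init()].
#' @param split a `split_table` from [split_2_1_1()]; all three subsets must
#'   be non-empty.
#' @param bp_epochs backpropagation epochs (default 50).
#' @param bp_learning_rate gradient-descent step size (default 0.2).
#' @param cg_max_iter conjugate-gradient iteration cap (default 257).
#' @return list with `model` (best-validation snapshot, carrying the
#'   standardisation constants) and `report`: RMS errors and classification
#'   qualities on the training, validation and test subsets, the realised
#'   schedule, and an `overfit` flag raised when the test quality exceeds
#'   the training quality by more than 0.05.
#' @export
mlp_train <- function(model, split, bp_epochs = 50L, bp_learning_rate = 0.2,
                      cg_max_iter = 257L) {
  if (!inherits(split, "split_table")) {
    stop("split must be a split_table", call. = FALSE)
  }
  for (s in c("train", "validation", "test")) {
    if (nrow(split[[s]]) == 0L) stop("empty ", s, " subset", call. = FALSE)
  }
  Xr <- as.matrix(as.data.frame(split$train)[, feature_names()])
  model$center <- colMeans(Xr)
  model$scale <- apply(Xr, 2, sd)
  model$scale[model$scale == 0] <- 1

  X <- standardize(model, split$train)
  Y <- one_hot(model, split$train$label)

  par <- flatten_params(model)
  best_par <- par
  best_val <- rms_error(unflatten_params(model, par), split$validation)
  note_val <- function(par) {
    v <- rms_error(unflatten_params(model, par), split$validation)
    if (v < best_val) {
      best_val <<- v
      best_par <<- par
    }
  }

  # Phase 1: full-batch gradient descent.
  for (e in seq_len(bp_epochs)) {
    lg <- mlp_loss_grad(par, model, X, Y)
    if (!is.finite(lg$loss)) {
      stop("non-finite training loss at BP epoch ", e, call. = FALSE)
    }
    par <- par - bp_learning_rate * lg$grad
    note_val(par)
  }

  # Phase 2: Polak-Ribiere conjugate gradient with Armijo backtracking.
  cg_done <- 0L
  if (cg_max_iter > 0L) {
    lg <- mlp_loss_grad(par, model, X, Y)
    f <- lg$loss
    g <- lg$grad
    d <- -g
    for (it in seq_len(cg_max_iter)) {
      gd <- sum(g * d)
      if (gd >= 0) {  # not a descent direction: restart on the gradient
        d <- -g
        gd <- sum(g * d)
      }
      if (sqrt(sum(g^2)) < 1e-10) break
      alpha <- 1
      accepted <- FALSE
      for (bt in seq_len(40L)) {
        cand <- par + alpha * d
        fc <- mlp_loss_grad(cand, model, X, Y)$loss
        if (is.finite(fc) && fc <= f + 1e-4 * alpha * gd) {
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!accepted) break
      par <- par + alpha * d
      lg2 <- mlp_loss_grad(par, model, X, Y)
      if (!is.finite(lg2$loss)) {
        stop("non-finite training loss at CG iteration ", it, call. = FALSE)
      }
      beta <- max(0, sum(lg2$grad * (lg2$grad - g)) / sum(g * g))
      d <- -lg2$grad + beta * d
      f <- lg2$loss
      g <- lg2$grad
      cg_done <- it
      note_val(par)
    }
  }

  best <- unflatten_params(model, best_par)
  report <- list(
    rms_train = rms_error(best, split$train),
    rms_validation = best_val,
    rms_test = rms_error(best, split$test),
    quality_train = classification_quality(best, split$train),
    quality_validation = classification_quality(best, split$validation),
    quality_test = classification_quality(best, split$test),
    schedule = c(bp_epochs = as.integer(bp_epochs),
                 cg_iterations = cg_done))
  report$overfit <- report$quality_test > report$quality_train + 0.05
  list(model = best, report = report)
}

#' Select the candidate with the lowest validation RMS
#'
#' Ties are broken toward fewer hidden units, then toward the earlier
#' candidate in the list.
#'
#' @param candidates list of `list(model, report)` pairs as returned by
#'   [mlp_train()].
#' @return The winning `list(model, report)` pair.
#' @export
select_best <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidates", call. = FALSE)
  val <- vapply(candidates, function(c) c$report$rms_validation, numeric(1))
  hid <- vapply(candidates, function(c) c$model$hidden, numeric(1))
  candidates[[order(val, hid, seq_along(candidates))[1L]]]
}

#' Serialise / restore an MLP model as JSON
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `mlp_from_json` returns the model.
#' @export
mlp_to_json <- function(model, path) {
  doc <- list(layer_sizes = c(model$n_in, model$hidden, model$n_out),
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              hidden_activation = model$hidden_activation,
              output_activation = model$output_activation,
              rng_seed = model$rng_seed,
              center = model$center, scale = model$scale,
              classes = model$classes)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mlp_to_json
#' @export
mlp_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- as.integer(doc$layer_sizes)
  structure(list(
    n_in = ls[1], hidden = ls[2], n_out = ls[3],
    W1 = matrix(doc$W1, ls[1], ls[2]), b1 = as.numeric(doc$b1),
    W2 = matrix(doc$W2, ls[2], ls[3]), b2 = as.numeric(doc$b2),
    hidden_activation = doc$hidden_activation,
    output_activation = doc$output_activation,
    rng_seed = as.integer(doc$rng_seed),
    center = if (is.null(doc$center)) NULL else as.numeric(doc$center),
    scale = if (is.null(doc$scale)) NULL else as.numeric(doc$scale),
    classes = as.character(doc$classes)),
    class = "mlp_model")
}
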