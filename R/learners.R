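# The three binding-residue classifiers behind one train/score contract.

#' Hyperparameter bundle for one learning algorithm
#'
#' Defaults are the grid-search operating points reported for this class of
#' predictor: window 9; SVM cost 1.0, sigma 0.1; NN 25 hidden nodes, learning
#' rate 0.1; RF 1501 trees with 20 feature tries per split.
#'
#' @param algorithm One of `"svm"`, `"nn"`, `"rf"`.
#' @param C,sigma SVM soft-margin cost (> 0) and Gaussian kernel width (> 0).
#' @param hidden_nodes,learning_rate NN hidden-layer size (>= 1) and
#'   gradient-descent step (> 0).
#' @param n_trees,mtry RF ensemble size (>= 1) and features tried per split
#'   (>= 1).
#' @param w Odd sliding-window size shared by all algorithms.
#' @param kernel_variant `"half"` for exp(-d^2 / (2 sigma^2)) (default) or
#'   `"plain"` for exp(-d^2 / sigma^2).
#' @return Object of class `pl_params`.
#' @export
hyperparams <- function(algorithm = c("svm", "nn", "rf"),
                        C = 1.0, sigma = 0.1,
                        hidden_nodes = 25, learning_rate = 0.1,
                        n_trees = 1501, mtry = 20,
                        w = 9, kernel_variant = c("half", "plain")) {
  algorithm <- match.arg(algorithm)
  kernel_variant <- match.arg(kernel_variant)
  stopifnot(C > 0, sigma > 0, hidden_nodes >= 1, learning_rate > 0,
            n_trees >= 1, mtry >= 1, w >= 1, w %% 2 == 1)
  p <- switch(algorithm,
    svm = list(C = C, sigma = sigma, kernel_variant = kernel_variant),
    nn = list(hidden_nodes = as.integer(hidden_nodes),
              learning_rate = learning_rate),
    rf = list(n_trees = as.integer(n_trees), mtry = as.integer(mtry))
  )
  structure(c(list(algorithm = algorithm, w = as.integer(w)), p),
            class = "pl_params")
}

#' Gaussian radial basis kernel between two feature vectors
#'
#' `K(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2))`; the `"plain"` variant
#' drops the factor 2 in the denominator (the two forms differ only by a
#' sigma rescaling).
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @param variant `"half"` (default) or `"plain"`.
#' @return Similarity in (0, 1].
#' @export
rbf_kernel <- function(x1, x2, sigma, variant = c("half", "plain")) {
  variant <- match.arg(variant)
  if (length(x1) != length(x2))
    stop("rbf_kernel: dimension mismatch", call. = FALSE)
  stopifnot(sigma > 0)
  denom <- if (variant == "half") 2 * sigma^2 else sigma^2
  exp(-sum((x1 - x2)^2) / denom)
}

.as_xy <- function(data) {
  if (inherits(data, "pl_dataset")) list(X = data$X, y = data$y)
  else if (is.list(data) && !is.null(data$X)) list(X = as.matrix(data$X),
                                                   y = as.integer(data$y))
  else stop("expected a pl_dataset or list(X, y)", call. = FALSE)
}

#' Train a binding-residue classifier
#'
#' Dispatches on `params$algorithm`: a soft-margin RBF-kernel SVM fitted by
#' SMO; a single-hidden-layer sigmoidal network trained by full-batch
#' gradient descent on squared error (at most 500 epochs, stopping when the
#' loss improves by less than 1e-6); or a random forest of CART trees grown
#' to purity with bootstrap sampling and `mtry` features tried per split.
#' Training is deterministic given `seed`.
#'
#' @param data A `pl_dataset` or `list(X, y)` with labels in {0, 1}.
#' @param params A `pl_params` from [hyperparams()].
#' @param seed Integer seed.
#' @param epochs,tol_loss NN-only overrides for the epoch cap and stopping
#'   delta.
#' @return A `pl_model` carrying the fitted state.
#' @export
train <- function(data, params, seed = 1, epochs = 500, tol_loss = 1e-6) {
  stopifnot(inherits(params, "pl_params"))
  d <- .as_xy(data)
  if (!length(d$y)) stop("empty training data", call. = FALSE)
  if (length(unique(d$y)) < 2)
    stop("training data contains a single class", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- switch(params$algorithm,
    svm = .train_svm(d$X, d$y, params),
    nn = .train_nn(d$X, d$y, params, epochs, tol_loss),
    rf = .train_rf(d$X, d$y, params)
  )
  structure(list(algorithm = params$algorithm, params = params, fit = fit,
                 dim = ncol(d$X), seed = as.integer(seed)),
            class = "pl_model")
}

.kernel_denom <- function(params) {
  if (identical(params$kernel_variant, "plain")) params$sigma^2
  else 2 * params$sigma^2
}

.train_svm <- function(X, y, params) {
  ys <- ifelse(y == 1, 1, -1)
  K <- rbf_kernel_matrix(X, X, .kernel_denom(params))
  sol <- smo_train(K, ys, params$C)
  sv <- which(sol$alpha > 1e-8)
  list(sv = X[sv, , drop = FALSE], coef = sol$alpha[sv] * ys[sv], b = sol$b,
       denom = .kernel_denom(params))
}

.train_nn <- function(X, y, params, epochs, tol_loss) {
  d <- ncol(X); h <- params$hidden_nodes; n <- nrow(X)
  W1 <- matrix(stats::rnorm(d * h, sd = 1 / sqrt(d)), d, h)
  b1 <- numeric(h)
  W2 <- stats::rnorm(h, sd = 1 / sqrt(h))
  b2 <- 0
  lr <- params$learning_rate
  sig <- function(z) 1 / (1 + exp(-z))
  prev <- Inf
  for (ep in seq_len(epochs)) {
    H <- sig(sweep(X %*% W1, 2, b1, `+`))
    yhat <- as.numeric(sig(H %*% W2 + b2))
    loss <- mean((yhat - y)^2)
    if (is.finite(prev) && abs(prev - loss) < tol_loss) break
    prev <- loss
    do <- 2 * (yhat - y) * yhat * (1 - yhat) / n
    gW2 <- as.numeric(crossprod(H, do))
    gb2 <- sum(do)
    dh <- (do %o% W2) * H * (1 - H)
    gW1 <- crossprod(X, dh)
    gb1 <- colSums(dh)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, final_loss = prev)
}

.train_rf <- function(X, y, params) {
  list(trees = forest_train(X, as.integer(y), params$n_trees,
                            min(params$mtry, ncol(X))))
}

#' Score examples with a trained model
#'
#' Higher scores mean more binding-like. SVM returns signed decision values,
#' NN sigmoid outputs in (0, 1), RF positive-vote fractions in \[0, 1\].
#'
#' @param model A `pl_model`.
#' @param X Feature matrix (or `pl_dataset`) with the model's feature
#'   dimension.
#' @return Numeric score per row.
#' @export
score <- function(model, X) {
  stopifnot(inherits(model, "pl_model"))
  if (inherits(X, "pl_dataset")) X <- X$X
  X <- as.matrix(X)
  if (!nrow(X)) return(numeric(0))
  if (ncol(X) != model$dim)
    stop("feature dimension mismatch", call. = FALSE)
  switch(model$algorithm,
    svm = {
      K <- rbf_kernel_matrix(X, model$fit$sv, model$fit$denom)
      as.numeric(K %*% model$fit$coef + model$fit$b)
    },
    nn = {
      sig <- function(z) 1 / (1 + exp(-z))
      H <- sig(sweep(X %*% model$fit$W1, 2, model$fit$b1, `+`))
      as.numeric(sig(H %*% model$fit$W2 + model$fit$b2))
    },
    rf = as.numeric(forest_score(model$fit$trees, X))
  )
}

#' Natural classification threshold for a model's score type
#'
#' 0 for SVM decision values, 0.5 for NN/RF probabilities or vote fractions.
#' @param model A `pl_model` (or algorithm name).
#' @return Numeric threshold.
#' @export
score_threshold <- function(model) {
  alg <- if (inherits(model, "pl_model")) model$algorithm else model
  if (alg == "svm") 0 else 0.5
}

#' Save / load a trained model as a versioned JSON container
#'
#' A shippable predictor artifact: JSON with a format version, the
#' algorithm, hyperparameters, seed, feature dimension and the full numeric
#' state (support vectors, network weights or forest tables).
#' @param model A `pl_model`.
#' @param path Output path.
#' @return `save_model`: `path` invisibly; `load_model`: the restored
#'   `pl_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "plbpred-model", version = 1L,
    algorithm = model$algorithm, params = unclass(model$params),
    dim = model$dim, seed = model$seed, fit = model$fit
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(p$format, "plbpred-model"))
    stop("not a plbpred model file", call. = FALSE)
  params <- structure(p$params, class = "pl_params")
  fit <- p$fit
  as_mat <- function(x, ncol) {
    if (is.matrix(x)) x else matrix(x, ncol = ncol, byrow = TRUE)
  }
  if (p$algorithm == "svm") {
    fit$sv <- as_mat(fit$sv, p$dim)
  } else if (p$algorithm == "nn") {
    fit$W1 <- as_mat(fit$W1, params$hidden_nodes)
    fit$W2 <- as.numeric(fit$W2)
    fit$b1 <- as.numeric(fit$b1)
  } else if (p$algorithm == "rf") {
    fit$trees <- lapply(fit$trees, as_mat, ncol = 5)
  }
  structure(list(algorithm = p$algorithm, params = params, fit = fit,
                 dim = p$dim, seed = p$seed), class = "pl_model")
}

#' @export
print.pl_model <- function(x, ...) {
  cat(sprintf("pl_model: %s, %d features, seed %d\n", x$algorithm, x$dim,
              x$seed))
  invisible(x)
}
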