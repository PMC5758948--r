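# Feed-forward neural predictor of biogas yield and methane content:
# tanh hidden layer, linear outputs, trained by Levenberg-Marquardt with a
# 70/15/15 split and validation-based early stopping.

#' Random 70/15/15 train/validation/test assignment
#'
#' Sizes are floored and any remainder rows are given out in the order
#' train, validation, test (so 20 rows split 14/3/3). Deterministic under a
#' fixed seed.
#'
#' @param n Number of rows (>= 10).
#' @param seed Integer RNG seed.
#' @param fractions Split fractions summing to 1.
#' @return Factor of length `n` with levels `train`, `validation`, `test`.
#' @export
split_assign <- function(n, seed = 1,
                         fractions = c(train = 0.70, validation = 0.15,
                                       test = 0.15)) {
  if (n < 10L) stop("need at least 10 rows to split", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    for (i in seq_len(rem)) {
      j <- ((i - 1L) %% length(sizes)) + 1L
      sizes[j] <- sizes[j] + 1L
    }
  }
  set.seed(seed)
  perm <- sample.int(n)
  assign <- rep(c("train", "validation", "test"), times = sizes)
  out <- character(n)
  out[perm] <- assign
  factor(out, levels = c("train", "validation", "test"))
}

#' Mean squared error
#'
#' @param pred,obs Equal-length numeric vectors (or matrices flattened).
#' @return `mean((pred - obs)^2)`.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  mean((as.numeric(pred) - as.numeric(obs))^2)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSres/SStot` with `SStot` about the mean of the observations.
#'
#' @param pred,obs Equal-length numeric vectors, `n >= 2`.
#' @return R-squared (<= 1; can be negative for a poor fit).
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) {
    stop("R-squared is undefined for zero-variance observations",
         call. = FALSE)
  }
  1 - sum((obs - pred)^2) / sstot
}

#' Pearson correlation between predictions and observations
#'
#' @param pred,obs Equal-length numeric vectors, `n >= 2`.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  stats::cor(as.numeric(pred), as.numeric(obs))
}

# Per-column affine map to [-1, 1]; constant columns map to 0.
norm_fit <- function(x) {
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  list(min = mins, max = maxs)
}

norm_apply <- function(x, nm) {
  span <- nm$max - nm$min
  span[span == 0] <- 1
  sweep(sweep(x, 2L, nm$min), 2L, span / 2, "/") - 1
}

norm_invert <- function(z, nm) {
  span <- nm$max - nm$min
  span[span == 0] <- 1
  sweep(sweep(z + 1, 2L, span / 2, "*"), 2L, nm$min, "+")
}

#' Number of parameters of a p-h-q perceptron
#'
#' Weights plus biases: `p*h + h + q*h + q` (for the 9-input, 2-output
#' digester model this is `9h + h + 2h + 2`).
#'
#' @param hidden Hidden-layer size h.
#' @param inputs,outputs Input and output dimensions.
#' @return Integer parameter count.
#' @export
mlp_n_params <- function(hidden, inputs = 9, outputs = 2) {
  inputs * hidden + hidden + outputs * hidden + outputs
}

mlp_init <- function(inputs, hidden, outputs, seed) {
  set.seed(seed)
  n <- mlp_n_params(hidden, inputs, outputs)
  theta <- stats::runif(n, -0.5, 0.5)
  list(theta = theta, sizes = c(inputs, hidden, outputs))
}

mlp_unpack <- function(theta, sizes) {
  p <- sizes[1]; h <- sizes[2]; q <- sizes[3]
  i <- 0L
  W1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(q * h)], q, h); i <- i + q * h
  b2 <- theta[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# Forward pass on normalized inputs; returns hidden activations and outputs.
mlp_forward <- function(theta, sizes, X) {
  w <- mlp_unpack(theta, sizes)
  A <- tanh(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  Y <- sweep(A %*% t(w$W2), 2L, w$b2, "+")
  list(A = A, Y = Y)
}

# Jacobian of the stacked residual vector (outputs stacked block-wise by
# output unit) with respect to the packed parameter vector.
mlp_jacobian <- function(theta, sizes, X, A) {
  p <- sizes[1]; h <- sizes[2]; q <- sizes[3]
  n <- nrow(X)
  w <- mlp_unpack(theta, sizes)
  G <- 1 - A^2
  P <- mlp_n_params(h, p, q)
  J <- matrix(0, q * n, P)
  for (k in seq_len(q)) {
    rows <- (k - 1L) * n + seq_len(n)
    for (j in seq_len(h)) {
      gj <- w$W2[k, j] * G[, j]
      for (i in seq_len(p)) {
        J[rows, (i - 1L) * h + j] <- gj * X[, i]
      }
      J[rows, h * p + j] <- gj
      J[rows, h * p + h + (j - 1L) * q + k] <- A[, j]
    }
    J[rows, h * p + h + q * h + k] <- 1
  }
  J
}

#' Train the digester perceptron by Levenberg-Marquardt
#'
#' Fits a `ncol(x)`-`hidden`-`ncol(y)` network (tanh hidden units, linear
#' outputs, both outputs trained jointly) by damped Gauss-Newton:
#' `delta = (J'J + lambda I)^-1 J' e` on the training rows, with `lambda`
#' multiplied by 10 after a rejected step and by 0.1 after an accepted one.
#' Inputs and targets are normalized per variable to `[-1, 1]`; the
#' normalization constants travel with the model and predictions are
#' returned on the original scale. Training stops at `max_epochs`, when the
#' gradient vanishes, or when the validation MSE has not improved for
#' `patience` consecutive epochs (weights revert to the best validation
#' epoch). All randomness (weight initialization) is governed by `seed`.
#'
#' @param x Numeric input matrix (rows = observations).
#' @param y Numeric target matrix (1 or more output columns).
#' @param hidden Hidden-layer size (>= 1).
#' @param split Factor from [split_assign()]; by default a fresh 70/15/15
#'   split under `seed`.
#' @param seed Integer seed for the split and the weight initialization.
#' @param max_epochs Maximum accepted LM steps (0 returns the initialized
#'   network untouched).
#' @param patience Early-stopping patience in epochs.
#' @param lambda0 Initial damping parameter.
#' @return An object of class `trained_mlp`: parameter vector, layer sizes,
#'   normalization constants, per-epoch train/validation MSE trace
#'   (normalized scale), stopping epoch, and [ann_metrics()] fit metrics.
#' @export
train_lm <- function(x, y, hidden, split = NULL, seed = 1,
                     max_epochs = 1000, patience = 6, lambda0 = 1e-3) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y row counts differ", call. = FALSE)
  if (hidden < 1) stop("hidden-layer size must be >= 1", call. = FALSE)
  if (is.null(split)) split <- split_assign(nrow(x), seed = seed)

  nx <- norm_fit(x); ny <- norm_fit(y)
  Xn <- norm_apply(x, nx); Yn <- norm_apply(y, ny)
  tr <- split == "train"; va <- split == "validation"
  sizes <- c(ncol(x), hidden, ncol(y))
  net <- mlp_init(ncol(x), hidden, ncol(y), seed = seed)
  theta <- net$theta

  Xtr <- Xn[tr, , drop = FALSE]; Ytr <- Yn[tr, , drop = FALSE]
  Xva <- Xn[va, , drop = FALSE]; Yva <- Yn[va, , drop = FALSE]

  sse <- function(th, X, Y) {
    fw <- mlp_forward(th, sizes, X)
    sum((fw$Y - Y)^2)
  }
  val_mse <- function(th) {
    if (nrow(Xva) == 0L) return(NA_real_)
    sse(th, Xva, Yva) / length(Yva)
  }

  lambda <- lambda0
  trace <- data.frame(epoch = integer(), mse_train = numeric(),
                      mse_validation = numeric())
  best_theta <- theta
  best_val <- val_mse(theta)
  stall <- 0L
  epoch <- 0L
  converged <- FALSE

  while (epoch < max_epochs) {
    fw <- mlp_forward(theta, sizes, Xtr)
    e <- as.numeric(fw$Y - Ytr)  # column-major = output-block stacking
    sse_cur <- sum(e^2)
    J <- mlp_jacobian(theta, sizes, Xtr, fw$A)
    g <- crossprod(J, e)
    if (sqrt(sum(g^2)) < 1e-12 || sse_cur < 1e-20) {
      converged <- TRUE
      break
    }
    H <- crossprod(J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(H + diag(lambda, ncol(H)), g),
        error = function(err) NULL)
      if (!is.null(step)) {
        cand <- theta - as.numeric(step)
        if (sum((mlp_forward(cand, sizes, Xtr)$Y - Ytr)^2) < sse_cur) {
          theta <- cand
          lambda <- max(lambda * 0.1, 1e-12)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
    }
    if (!accepted) {
      # damping exhausted: at (numerical) minimum this is convergence,
      # otherwise a genuine failure
      if (sse_cur / length(e) < 1e-12) converged <- TRUE
      if (!converged) {
        stop("Levenberg-Marquardt failed to find a descending step ",
             "(damping exhausted)", call. = FALSE)
      }
      break
    }
    epoch <- epoch + 1L
    mtr <- sum((mlp_forward(theta, sizes, Xtr)$Y - Ytr)^2) / length(Ytr)
    mva <- val_mse(theta)
    trace <- rbind(trace, data.frame(epoch = epoch, mse_train = mtr,
                                     mse_validation = mva))
    if (!is.na(mva)) {
      if (is.na(best_val) || mva < best_val - 1e-12) {
        best_val <- mva
        best_theta <- theta
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    } else {
      best_theta <- theta
    }
  }
  if (!is.na(best_val)) theta <- best_theta

  model <- structure(
    list(theta = theta, sizes = sizes, norm_x = nx, norm_y = ny,
         split = split, trace = trace,
         stopping_epoch = if (nrow(trace)) trace$epoch[which.min(
           if (all(is.na(trace$mse_validation))) trace$mse_train
           else trace$mse_validation)] else 0L,
         converged = converged, seed = seed,
         output_names = colnames(y)),
    class = "trained_mlp")
  model$metrics <- ann_metrics(model, x, y, split)
  model
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf("Feed-forward network %s (%d parameters), LM-trained\n",
              paste(x$sizes, collapse = "-"),
              mlp_n_params(x$sizes[2], x$sizes[1], x$sizes[3])))
  cat(sprintf("stopping epoch %d; overall R = %.4f\n",
              x$stopping_epoch, x$metrics$r["all"]))
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object A `trained_mlp`.
#' @param newdata Input matrix with the training columns.
#' @param ... Unused.
#' @return Matrix of predictions on the original target scale.
#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  Xn <- norm_apply(as.matrix(newdata), object$norm_x)
  Yn <- mlp_forward(object$theta, object$sizes, Xn)$Y
  Y <- norm_invert(Yn, object$norm_y)
  colnames(Y) <- object$output_names
  Y
}

#' Fit metrics of a trained network
#'
#' MSE per split, pooled Pearson R per split and overall (predictions and
#' observations pooled across both outputs, the convention of regression
#' plots for multi-output networks), and per-output R-squared on the full
#' data set. All on the original target scale.
#'
#' @param model A `trained_mlp`.
#' @param x,y The data the split refers to.
#' @param split Factor from [split_assign()].
#' @return List with elements `mse` (train/validation/test), `r`
#'   (train/validation/test/all) and `r2` (per output column).
#' @export
ann_metrics <- function(model, x, y, split = model$split) {
  y <- as.matrix(y)
  pred <- predict(model, x)
  splits <- c("train", "validation", "test")
  mse_s <- vapply(splits, function(s) {
    idx <- split == s
    if (!any(idx)) return(NA_real_)
    mse(pred[idx, ], y[idx, ])
  }, numeric(1))
  r_s <- vapply(splits, function(s) {
    idx <- split == s
    if (sum(idx) < 2L) return(NA_real_)
    pearson_r(pred[idx, ], y[idx, ])
  }, numeric(1))
  r_all <- pearson_r(pred, y)
  r2 <- vapply(seq_len(ncol(y)), function(k) {
    r_squared(pred[, k], y[, k])
  }, numeric(1))
  names(r2) <- colnames(y)
  list(mse = mse_s, r = c(r_s, all = r_all), r2 = r2)
}

#' Hidden-layer size search
#'
#' Trains one network per candidate hidden-layer size on a shared split,
#' tabulates MSE and pooled R per split plus overall R — the layout of a
#' hidden-neuron selection table — and applies [select_architecture()] to
#' pick the winner. Candidates whose training fails are recorded and
#' skipped. The default candidate list follows the coarse-grid-then-refine
#' protocol (5 to 50 by 5, then 16-19).
#'
#' @param x,y Data matrices.
#' @param candidates Integer vector of hidden-layer sizes.
#' @param seed Seed for the shared split and the per-candidate weight
#'   initializations.
#' @param kappa Overfit flag threshold passed to [select_architecture()].
#' @param ... Passed to [train_lm()] (e.g. `max_epochs`).
#' @return List with `metrics` (one row per trained candidate), `selection`
#'   from [select_architecture()], `failed` (candidate sizes whose training
#'   errored) and `models` (the trained networks, named by size).
#' @export
architecture_search <- function(x, y,
                                candidates = c(seq(5, 50, by = 5), 16:19),
                                seed = 1, kappa = 10, ...) {
  if (length(candidates) == 0L) {
    stop("candidate list must be nonempty", call. = FALSE)
  }
  split <- split_assign(nrow(as.matrix(x)), seed = seed)
  rows <- list(); models <- list(); failed <- integer()
  for (h in candidates) {
    fit <- tryCatch(
      train_lm(x, y, hidden = h, split = split, seed = seed, ...),
      error = function(err) NULL)
    if (is.null(fit)) {
      failed <- c(failed, h)
      next
    }
    m <- fit$metrics
    rows[[as.character(h)]] <- data.frame(
      hidden_neurons = h,
      mse_train = m$mse["train"], mse_validation = m$mse["validation"],
      mse_test = m$mse["test"],
      r_train = m$r["train"], r_validation = m$r["validation"],
      r_test = m$r["test"], r_all = m$r["all"])
    models[[as.character(h)]] <- fit
  }
  if (length(rows) == 0L) {
    stop("training failed for every candidate", call. = FALSE)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics,
       selection = select_architecture(metrics, kappa = kappa),
       failed = failed, models = models)
}

#' Select the hidden-layer size from a search metrics table
#'
#' A candidate is flagged as overfit when its validation or test MSE
#' exceeds `kappa` times its training MSE — the pattern of a network that
#' memorizes the training rows (tiny training error, exploding holdout
#' error). Among the unflagged candidates the one with the highest overall
#' R wins; if every candidate is flagged, the highest overall R wins
#' regardless.
#'
#' @param metrics Data frame with columns `hidden_neurons`, `mse_train`,
#'   `mse_validation`, `mse_test`, `r_all` (the layout written by
#'   [architecture_search()]; the packaged `hidden_neuron_search.csv`
#'   fixture has the same shape).
#' @param kappa Overfit ratio threshold (default 10).
#' @return List with `hidden` (the winning size), `overfit` (flagged
#'   sizes) and `table` (metrics plus an `overfit` column).
#' @export
select_architecture <- function(metrics, kappa = 10) {
  need <- c("hidden_neurons", "mse_train", "mse_validation", "mse_test",
            "r_all")
  if (!all(need %in% names(metrics))) {
    stop("metrics table lacks columns: ",
         paste(setdiff(need, names(metrics)), collapse = ", "),
         call. = FALSE)
  }
  over <- metrics$mse_validation > kappa * metrics$mse_train |
    metrics$mse_test > kappa * metrics$mse_train
  pool <- if (all(over)) metrics else metrics[!over, ]
  best <- pool$hidden_neurons[which.max(pool$r_all)]
  list(hidden = best,
       overfit = metrics$hidden_neurons[over],
       table = cbind(metrics, overfit = over))
}

#' Load the packaged hidden-neuron search table
#'
#' The printed metrics of the original study's hidden-layer search
#' (training/validation/test MSE and R for candidate sizes 5-50), on which
#' [select_architecture()] reproduces the choice of 19 hidden neurons.
#'
#' @return Data frame in the [architecture_search()] metrics layout.
#' @export
load_hidden_search <- function() {
  path <- system.file("extdata", "hidden_neuron_search.csv",
                      package = "codigest", mustWork = TRUE)
  utils::read.csv(path)
}
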