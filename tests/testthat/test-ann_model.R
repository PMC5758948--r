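test_that("the 70/15/15 split floors sizes, tops up train-first, and is seeded", {
  s100 <- split_assign(100, seed = 1)
  expect_equal(as.integer(table(s100)), c(70L, 15L, 15L))
  s20 <- split_assign(20, seed = 1)
  expect_equal(as.integer(table(s20)), c(14L, 3L, 3L))
  s21 <- split_assign(21, seed = 1)  # remainder row goes to train
  expect_equal(as.integer(table(s21)), c(15L, 3L, 3L))
  expect_identical(split_assign(57, seed = 9), split_assign(57, seed = 9))
  expect_false(identical(split_assign(57, seed = 9),
                         split_assign(57, seed = 10)))
  expect_error(split_assign(9), "at least 10")
})

test_that("fit metrics follow their definitions", {
  obs <- c(1, 2, 3)
  expect_equal(mse(obs, obs), 0)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(mse(c(1, 2, 4), obs), 1 / 3)
  expect_equal(r_squared(c(1, 2, 4), obs), 0.5)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0)
  expect_equal(pearson_r(c(2, 4, 6), obs), 1)
  expect_error(mse(1:3, 1:4), "equal length")
  expect_error(r_squared(c(1, 2), c(5, 5)), "zero-variance")
})

test_that("parameter count is 9h + h + 2h + 2 for every h", {
  for (h in c(1, 5, 19, 50)) {
    expect_equal(mlp_n_params(h), 9 * h + h + 2 * h + 2)
    net <- codigest:::mlp_init(9, h, 2, seed = 1)
    expect_length(net$theta, mlp_n_params(h))
  }
})

test_that("normalization to [-1,1] is invertible", {
  set.seed(2)
  x <- cbind(rnorm(30, 100, 20), runif(30, -5, 5), rep(3, 30))
  nm <- codigest:::norm_fit(x)
  z <- codigest:::norm_apply(x, nm)
  expect_true(all(z >= -1 - 1e-12 & z <= 1 + 1e-12))
  expect_equal(codigest:::norm_invert(z, nm)[, 1:2], x[, 1:2])
})

make_linear_data <- function(n = 150, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * 9), n, 9)
  list(x = x, y = cbind(target = rowSums(x) / 9))
}

test_that("LM drives a noiseless linear target below 1e-3 training MSE", {
  d <- make_linear_data()
  fit <- train_lm(d$x, d$y, hidden = 5, seed = 3, max_epochs = 100)
  expect_lt(fit$metrics$mse[["train"]], 1e-3)
  expect_lte(nrow(fit$trace), 100)
})

test_that("zero allowed epochs returns the initialized network unchanged", {
  d <- make_linear_data(n = 40)
  fit <- train_lm(d$x, d$y, hidden = 3, seed = 5, max_epochs = 0)
  net <- codigest:::mlp_init(9, 3, 1, seed = 5)
  expect_identical(fit$theta, net$theta)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("training is bit-identical under a fixed seed and data", {
  d <- make_linear_data(n = 60)
  f1 <- train_lm(d$x, d$y, hidden = 4, seed = 11, max_epochs = 25)
  f2 <- train_lm(d$x, d$y, hidden = 4, seed = 11, max_epochs = 25)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$trace, f2$trace)
})

test_that("training MSE at the returned weights never exceeds the initial MSE", {
  d <- make_linear_data(n = 80, seed = 13)
  split <- split_assign(80, seed = 13)
  init <- train_lm(d$x, d$y, hidden = 4, split = split, seed = 2,
                   max_epochs = 0)
  fit <- train_lm(d$x, d$y, hidden = 4, split = split, seed = 2,
                  max_epochs = 30)
  tr <- split == "train"
  expect_lte(mse(predict(fit, d$x)[tr, ], d$y[tr, ]),
             mse(predict(init, d$x)[tr, ], d$y[tr, ]))
})

test_that("LM limit behaviour: large damping is gradient descent, zero damping solves a linear problem", {
  # direction check at large lambda on the network objective
  d <- make_linear_data(n = 50, seed = 17)
  sizes <- c(9, 3, 1)
  net <- codigest:::mlp_init(9, 3, 1, seed = 4)
  X <- d$x; Y <- d$y
  fw <- codigest:::mlp_forward(net$theta, sizes, X)
  e <- as.numeric(fw$Y - Y)
  J <- codigest:::mlp_jacobian(net$theta, sizes, X, fw$A)
  g <- as.numeric(crossprod(J, e))
  lambda <- 1e9
  step <- solve(crossprod(J) + diag(lambda, length(g)), g)
  cosine <- sum(-step * -g) / sqrt(sum(step^2) * sum(g^2))
  expect_gt(cosine, 0.999)

  # lambda -> 0 on a purely linear model: one step reaches the
  # closed-form least-squares solution
  set.seed(18)
  A <- cbind(1, matrix(rnorm(40 * 3), 40, 3))
  beta_true <- c(0.5, -1, 2, 0.25)
  yy <- A %*% beta_true
  beta0 <- rep(0, 4)
  resid <- as.numeric(A %*% beta0 - yy)
  delta <- solve(crossprod(A) + diag(1e-12, 4), crossprod(A, resid))
  beta1 <- beta0 - as.numeric(delta)
  oracle <- as.numeric(qr.solve(A, yy))
  expect_equal(beta1, oracle, tolerance = 1e-6)
})

test_that("architecture search tabulates candidates and flags overfits", {
  tab <- load_hidden_search()
  sel <- select_architecture(tab)
  expect_equal(sel$hidden, 19)
  expect_true(all(c(30, 50) %in% sel$overfit))
  expect_false(19 %in% sel$overfit)
  # the 50-neuron row: validation MSE 14269.6 vs training 18.0
  expect_true(sel$table$overfit[sel$table$hidden_neurons == 50])
  # single candidate -> that candidate selected
  one <- select_architecture(tab[tab$hidden_neurons == 10, ])
  expect_equal(one$hidden, 10)
  expect_error(select_architecture(data.frame(a = 1)), "lacks columns")
})

test_that("architecture search trains candidates end to end on small data", {
  d <- make_linear_data(n = 60, seed = 23)
  out <- architecture_search(d$x, d$y, candidates = c(2, 4), seed = 6,
                             max_epochs = 15)
  expect_equal(nrow(out$metrics), 2)
  expect_true(out$selection$hidden %in% c(2, 4))
  expect_named(out$models, as.character(c(2, 4)))
  expect_error(architecture_search(d$x, d$y, candidates = integer(0)),
               "nonempty")
})
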