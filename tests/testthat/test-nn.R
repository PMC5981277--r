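test_that("conv1d matches hand-computed rectified cross-correlation", {
  # valid length n - k + 1 = 2; pre-activations [1-3, 2-1] -> ReLU [0, 1]
  expect_equal(conv1d_forward(c(1, 2, 3, 1), c(1, 0, -1)), c(0, 1))
  # one position further needs a length-5 input: [1-3, 2-1, 3-1] -> [0, 1, 2]
  expect_equal(conv1d_forward(c(1, 2, 3, 1, 1), c(1, 0, -1)), c(0, 1, 2))
  # all-zero input stays zero; forced-negative pre-activation clamps to 0
  expect_equal(conv1d_forward(rep(0, 6), c(1, 2, 3)), rep(0, 4))
  expect_equal(conv1d_forward(c(1, 1, 1), c(-1, -1, -1)), 0)
  expect_error(conv1d_forward(c(1, 2), c(1, 0, -1)), class = "habsuit_shape_error")
})

test_that("conv2d matches hand-computed examples", {
  x <- matrix(1:9, 3, 3)
  # identity 1x1 kernel returns ReLU of the input
  expect_equal(conv2d_forward(x, matrix(1, 1, 1)), pmax(x, 0))
  # zero weights give zero maps
  expect_equal(conv2d_forward(x, matrix(0, 2, 2)), matrix(0, 2, 2))
  # 2x2 kernel of ones computes window sums
  sums <- matrix(c(1 + 2 + 4 + 5, 2 + 3 + 5 + 6, 4 + 5 + 7 + 8, 5 + 6 + 8 + 9),
                 2, 2)
  expect_equal(conv2d_forward(x, matrix(1, 2, 2)), sums)
  expect_error(conv2d_forward(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "habsuit_shape_error")
})

test_that("convolution primitives agree with naive nested-loop oracles", {
  set.seed(101)
  for (r in 1:10) {
    len <- sample(6:15, 1); k <- sample(2:4, 1)
    cin <- sample(1:3, 1); fout <- sample(1:3, 1)
    x <- matrix(rnorm(len * cin), len, cin)
    w <- array(rnorm(k * cin * fout), c(k, cin, fout))
    expect_equal(conv1d_forward(x, w), naive_conv1d(x, w), tolerance = 1e-6)
  }
  for (r in 1:10) {
    H <- sample(5:9, 1); W <- sample(5:9, 1)
    kh <- sample(2:3, 1); kw <- sample(2:3, 1)
    cin <- sample(1:3, 1); fout <- sample(1:2, 1)
    x <- array(rnorm(H * W * cin), c(H, W, cin))
    w <- array(rnorm(kh * kw * cin * fout), c(kh, kw, cin, fout))
    expect_equal(conv2d_forward(x, w), naive_conv2d(x, w), tolerance = 1e-6)
  }
})

test_that("pooling layers compute window maxima and means", {
  ly <- habsuit:::layer_maxpool2(c(4L, 4L, 1L))
  x <- matrix(as.double(1:16), 16, 1)   # 4x4 grid, column-major
  out <- ly$fwd(x, training = TRUE)
  m <- matrix(as.double(1:16), 4, 4)
  expect_equal(matrix(out, 2, 2),
               matrix(c(max(m[1:2, 1:2]), max(m[3:4, 1:2]),
                        max(m[1:2, 3:4]), max(m[3:4, 3:4])), 2, 2))
  # backward routes gradient only to the argmax positions
  g <- ly$bwd(matrix(c(1, 10, 100, 1000), 4, 1))
  expect_equal(sum(g != 0), 4L)
  expect_equal(sum(g), 1111)
  la <- habsuit:::layer_avgpool2(c(4L, 4L, 1L))
  outa <- la$fwd(x)
  expect_equal(matrix(outa, 2, 2)[1, 1], mean(m[1:2, 1:2]))
  gap <- habsuit:::layer_global_avgpool(c(4L, 4L, 2L))
  x2 <- matrix(as.double(1:32), 32, 1)
  expect_equal(as.vector(gap$fwd(x2)), c(mean(1:16), mean(17:32)))
})

test_that("softmax cross-entropy normalizes and differentiates correctly", {
  set.seed(3)
  logits <- matrix(rnorm(20), 2, 10)
  p <- habsuit:::softmax_probs(logits)
  expect_equal(colSums(p), rep(1, 10), tolerance = 1e-12)
  y <- sample(1:2, 10, replace = TRUE)
  ce <- habsuit:::softmax_ce(logits, y)
  expect_gt(ce$loss, 0)
  # finite-difference check of the loss gradient
  for (trial in 1:5) {
    i <- sample(2, 1); j <- sample(10, 1)
    eps <- 1e-6
    lp <- logits; lp[i, j] <- lp[i, j] + eps
    lm <- logits; lm[i, j] <- lm[i, j] - eps
    num <- (habsuit:::softmax_ce(lp, y)$loss -
              habsuit:::softmax_ce(lm, y)$loss) / (2 * eps)
    expect_equal(ce$dlogits[i, j], num, tolerance = 1e-5)
  }
})

test_that("backpropagation matches numerical gradients on a small dual-branch net", {
  cfg <- mcnn_config(fc_width = 6L, inception_filters = c(2L, 2L, 2L),
                     conv_filters = 3L, temp_filters = 2L,
                     input_image = c(16L, 16L, 2L))
  m <- build_mcnn(cfg, seed = 31)
  set.seed(2)
  N <- 3
  Xi <- matrix(rnorm(16 * 16 * 2 * N), 16 * 16 * 2, N)
  Xt <- matrix(rnorm(15 * N), 15, N)
  y <- c(1L, 2L, 1L)
  loss_fn <- function() {
    habsuit:::softmax_ce(habsuit:::forward_model(m, Xi, Xt, TRUE)$logits, y)$loss
  }
  ce <- habsuit:::softmax_ce(habsuit:::forward_model(m, Xi, Xt, TRUE)$logits, y)
  habsuit:::backward_model(m, ce$dlogits)
  layers <- habsuit:::model_param_layers(m)
  set.seed(4)
  for (ly in layers) {
    for (p in ly$param_names) {
      g <- ly[[paste0("d", p)]]
      for (ii in sample(length(g), min(2, length(g)))) {
        eps <- 1e-5
        orig <- ly[[p]][ii]
        ly[[p]][ii] <- orig + eps; lp <- loss_fn()
        ly[[p]][ii] <- orig - eps; lm <- loss_fn()
        ly[[p]][ii] <- orig
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[ii]) / max(abs(num) + abs(g[ii]), 1e-6), 5e-3)
      }
    }
  }
})
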