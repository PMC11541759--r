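# Spatial attention scoring, trajectory heat maps, Dice supervision, and
# the two attending schemes.

test_that("equal features give uniform attention and constant shifts cancel", {
  set.seed(1)
  params <- make_attention_params(C_e = 6, C_att = 4, seed = 2)
  f <- array(rep(rnorm(6), each = 12), c(3, 4, 6))  # identical cell vectors
  a <- spatial_attention_scores(f, params)
  expect_equal(dim(a), c(3, 4))
  expect_equal(as.vector(a), rep(1 / 12, 12), tolerance = 1e-12)
  # softmax shift invariance: scores shifted by +c leave weights unchanged
  id_params <- list(Ma = matrix(1, 1, 1), Ms = NULL, Mo = 1)
  p1 <- array(c(0.3, 1.1, 0.7, 2.0), c(2, 2, 1))
  p2 <- p1 + 5  # stays in the ReLU linear region, shifts all scores by +5
  expect_equal(spatial_attention_scores(p1, id_params),
               spatial_attention_scores(p2, id_params), tolerance = 1e-12)
})

test_that("hand-evaluated softmax weights are reproduced on a 2x2 grid", {
  # with identity maps the overall scores equal the (nonnegative) feature
  # values; scores {0, ln2, ln3, ln4} must give weights {.1, .2, .3, .4}
  id_params <- list(Ma = matrix(1, 1, 1), Ms = NULL, Mo = 1)
  f <- array(0, c(2, 2, 1))
  f[1, 1, 1] <- 0; f[1, 2, 1] <- log(2)
  f[2, 1, 1] <- log(3); f[2, 2, 1] <- log(4)
  a <- spatial_attention_scores(f, id_params)
  expect_equal(a, matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2), tolerance = 1e-12)
})

test_that("attention weights always normalize to one", {
  set.seed(3)
  params <- make_attention_params(C_e = 5, C_att = 7, C_h = 4, seed = 4)
  for (i in 1:20) {
    f <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
    h <- rnorm(4)
    a <- spatial_attention_scores(f, params, h)
    expect_true(all(a >= 0))
    expect_lt(abs(sum(a) - 1), 1e-5)
  }
  expect_error(spatial_attention_scores(array(0, c(2, 2, 3)), params),
               "does not match")
})

test_that("trajectory heat maps follow the equal-cell partition rule", {
  # 224-px image, 7x7 grid, tip at (100, 40): integer division by 32
  B <- build_trajectory_heatmap(data.frame(x = 100, y = 40), 224, 7)
  expect_equal(which(B == 1, arr.ind = TRUE)[1, ], c(row = 2, col = 4))
  expect_equal(sum(B), 1)
  # no keypoints: all zero (legal, e.g. no instrument in the frame)
  expect_equal(sum(build_trajectory_heatmap(NULL, 224, 7)), 0)
  # two tips in one cell clamp to binary 1
  B2 <- build_trajectory_heatmap(data.frame(x = c(1, 2), y = c(1, 2)),
                                 224, 7)
  expect_equal(B2[1, 1], 1)
  expect_equal(sum(B2), 1)
  # out-of-bounds keypoints are dropped with a warning
  expect_warning(B3 <- build_trajectory_heatmap(
    data.frame(x = c(500, 10), y = c(10, 10)), 224, 7), "dropped")
  expect_equal(sum(B3), 1)
})

test_that("heat-map cell mapping matches a coordinate-arithmetic oracle", {
  set.seed(5)
  for (i in 1:50) {
    fs <- sample(c(64, 127, 224), 1)
    H <- sample(5:9, 1)
    x <- runif(1, 0, fs - 1e-9)
    y <- runif(1, 0, fs - 1e-9)
    B <- build_trajectory_heatmap(data.frame(x = x, y = y), fs, H)
    # oracle: brute-force scan over all cells' pixel ranges
    cell <- NULL
    for (m in 0:(H - 1)) {
      for (n in 0:(H - 1)) {
        if (x >= n * fs / H && x < (n + 1) * fs / H &&
            y >= m * fs / H && y < (m + 1) * fs / H) {
          cell <- c(m + 1, n + 1)
        }
      }
    }
    expect_equal(unname(which(B == 1, arr.ind = TRUE)[1, ]), cell)
  }
})

test_that("soft Dice loss matches hand-evaluated values", {
  # perfect overlap with a binary one-hot attention
  A <- array(0, c(3, 2, 2)); A[cbind(1:3, c(1, 2, 1), c(2, 1, 1))] <- 1
  expect_equal(soft_dice_loss(A, A, eps = 1e-9), 0, tolerance = 1e-8)
  # disjoint support: loss tends to 1 as eps tends to 0
  B <- array(0, c(3, 2, 2)); B[cbind(1:3, c(2, 1, 2), c(1, 2, 2))] <- 1
  expect_equal(soft_dice_loss(A, B, eps = 1e-9), 1, tolerance = 1e-8)
  expect_lt(soft_dice_loss(A, B, eps = 1), 1)
  # uniform attention on a 2x2 grid against a one-cell target
  U <- matrix(0.25, 2, 2)
  Tgt <- matrix(c(1, 0, 0, 0), 2, 2)
  eps <- 1e-9
  expect_equal(soft_dice_loss(U, Tgt, eps = eps),
               1 - (2 * 0.25 + eps) / (1 + 1 + eps), tolerance = 1e-9)
  expect_error(soft_dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shapes differ")
})

test_that("combined loss is BCE plus lambda times Dice", {
  expect_equal(combined_loss(0, 0), 0)
  expect_equal(combined_loss(0.3, 0.4, lambda = 0.5), 0.5)
  expect_equal(combined_loss(0.3, 0.9, lambda = 0), 0.3)
  expect_error(combined_loss(0.1, 0.1, lambda = -1))
})

test_that("aggregation is the attention-weighted feature sum", {
  set.seed(6)
  f <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  # uniform attention equals the cell mean
  u <- matrix(0.25, 2, 2)
  expect_equal(attend_aggregate(u, f),
               colMeans(surgskill:::grid_to_cells(f)), tolerance = 1e-12)
  # two cells with weights (0.25, 0.75)
  P <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE)
  expect_equal(attend_aggregate(c(0.25, 0.75), P),
               0.25 * P[1, ] + 0.75 * P[2, ])
  # one-hot attention reduces aggregation to selection
  oh <- matrix(0, 2, 2); oh[2, 1] <- 1
  expect_equal(attend_aggregate(oh, f),
               as.vector(attend_select(oh, f)), tolerance = 1e-12)
})

test_that("selection picks the arg-max cell with row-major tie-breaking", {
  f <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  P <- surgskill:::grid_to_cells(f)
  # weights {0.1, 0.2, 0.6, 0.1} row-major: cell (row 2, col 1) wins
  a <- matrix(c(0.1, 0.6, 0.2, 0.1), 2, 2)
  s <- attend_select(a, f)
  expect_equal(as.vector(s), P[3, ])
  expect_equal(attr(s, "cell"), 2L)
  # uniform weights: first cell by the documented row-major tie rule
  s0 <- attend_select(matrix(0.25, 2, 2), f)
  expect_equal(attr(s0, "cell"), 0L)
  expect_equal(as.vector(s0), P[1, ])
})

test_that("selection equals an exhaustive-scan arg-max on random grids", {
  set.seed(7)
  for (i in 1:100) {
    H <- sample(2:5, 1); W <- sample(2:5, 1); C <- sample(2:4, 1)
    P <- matrix(rnorm(H * W * C), H * W, C)
    a <- runif(H * W); a <- a / sum(a)
    s <- attend_select(a, P)
    # brute-force scan oracle
    best <- 1
    for (j in seq_len(H * W)) if (a[j] > a[best]) best <- j
    expect_equal(as.vector(s), P[best, ])
    expect_equal(attr(s, "cell"), best - 1L)
  }
})

test_that("optimizing the Dice loss alone pulls the attention arg-max into the target cells", {
  # short pull check (the full 100-trial suite runs with the acceptance
  # properties); 20 trials, 200 steps each
  set.seed(8)
  hits <- 0
  for (trial in 1:20) {
    cells <- 49; Ce <- 8; Catt <- 8
    P <- matrix(rnorm(cells * Ce), cells, Ce)
    target <- sample(cells, 2)
    Bv <- numeric(cells); Bv[target] <- 1
    leaves <- leafify(make_attention_params(Ce, Catt))
    opt <- surgskill:::adam_init(leaves)
    for (step in 1:200) {
      surgskill:::ag_zero_grad(leaves)
      surgskill:::tape_begin()
      att <- surgskill:::ag_attention_step(P, NULL, leaves$Ma, NULL,
                                           leaves$Mo)
      inter <- surgskill:::ag_dot(att, Bv)
      num <- surgskill:::ag_add(surgskill:::ag_scale(inter, 2), 1)
      den <- surgskill:::ag_add(surgskill:::ag_sum(att), sum(Bv) + 1)
      dice <- surgskill:::ag_sub(1, surgskill:::ag_div(num, den))
      surgskill:::ag_backward(dice)
      surgskill:::tape_end()
      grads <- lapply(leaves, function(l) l$g)
      opt <- surgskill:::adam_step(opt, leaves, grads, lr = 0.01)
    }
    att <- surgskill:::ag_attention_step(P, NULL, leaves$Ma$v, NULL,
                                         leaves$Mo$v)
    if (which.max(att) %in% target) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
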