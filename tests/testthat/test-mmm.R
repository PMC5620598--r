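test_that("fitted boxes are the per-class min/max/mean/sd matrices", {
  ds <- labeled_dataset(rbind(c(1, 2), c(3, 4), c(5, 5)), c(1, 1, 2))
  m <- fit_mmm(ds)
  expect_equal(m$Q[1, ], c(3, 4))
  expect_equal(m$V[1, ], c(1, 2))
  expect_equal(m$U[1, ], c(2, 3))
  expect_equal(m$S[1, ], c(sd(c(1, 3)), sd(c(2, 4))))
  # degenerate single-point class: Q = V = U = the point, S = 0
  expect_equal(m$Q[2, ], c(5, 5))
  expect_equal(m$V[2, ], c(5, 5))
  expect_equal(m$S[2, ], c(0, 0))
  expect_equal(m$expansion, 0)

  # mean rows equal independently computed column means
  ds2 <- make_gaussian_ds(matrix(c(0, 3, 6, 1, 4, 7), 3, 2), n = 8, seed = 5)
  m2 <- fit_mmm(ds2)
  for (cl in 1:3)
    expect_equal(m2$U[cl, ],
                 unname(colMeans(ds2$features[ds2$labels == cl, ])))
})

test_that("every training row lies inside its own unexpanded box", {
  ds <- make_gaussian_ds(matrix(runif(24), 4, 6), n = 12, seed = 8)
  m <- fit_mmm(ds)
  for (i in seq_len(nrow(ds$features))) {
    cl <- ds$labels[i]
    expect_true(all(ds$features[i, ] >= m$V[cl, ] &
                      ds$features[i, ] <= m$Q[cl, ]))
  }
})

test_that("classification handles interior, rejected and tied inputs", {
  # two disjoint boxes
  ds <- labeled_dataset(rbind(c(0, 0), c(1, 1), c(5, 5), c(6, 6)),
                        c(1, 1, 2, 2))
  m <- fit_mmm(ds)
  expect_equal(classify_mmm(m, c(0.5, 0.5))$outcome, 1L)
  p <- classify_mmm(m, c(10, 0.5))  # outside every box on sensor 1
  expect_true(is_rejected(p))
  expect_error(classify_mmm(m, c(1, 2, 3)), "length")

  # overlapping boxes: nearest mean wins; ties reported
  ds2 <- labeled_dataset(rbind(c(0, 0), c(4, 4), c(2, 2), c(6, 6)),
                         c(1, 1, 2, 2))
  m2 <- fit_mmm(ds2)
  p2 <- classify_mmm(m2, c(3, 3))  # inside both; means (2,2) and (4,4)
  expect_setequal(p2$tie_classes, c(1L, 2L))
  expect_equal(p2$outcome, 1L)    # equidistant -> lowest label
  p3 <- classify_mmm(m2, c(3.4, 3.4))
  expect_equal(p3$outcome, 2L)    # nearer to mean (4,4)
})

test_that("predictions agree with a brute-force box oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    means <- matrix(runif(9, 0, 4), 3, 3)
    ds <- make_gaussian_ds(means, n = sample(3:10, 1), s = 0.8, seed = seed)
    m <- fit_mmm(ds)
    probes <- matrix(runif(60 * 3, -1, 5), 60, 3)
    for (r in seq_len(nrow(probes))) {
      got <- classify_mmm(m, probes[r, ])
      want <- oracle_box_predict(m$Q, m$V, m$U, m$class_labels, probes[r, ])
      expect_equal(is_rejected(got), want$rejected)
      if (!want$rejected) expect_equal(got$outcome, want$outcome)
    }
  }
})

test_that("classification is invariant to training row order", {
  ds <- make_gaussian_ds(matrix(c(0, 3, 0, 3), 2, 2), n = 9, seed = 3)
  perm <- sample(nrow(ds$features))
  ds_perm <- labeled_dataset(ds$features[perm, ], ds$labels[perm])
  m1 <- fit_mmm(ds); m2 <- fit_mmm(ds_perm)
  probes <- matrix(runif(40, -1, 4), 20, 2)
  for (r in 1:20)
    expect_identical(classify_mmm(m1, probes[r, ]),
                     classify_mmm(m2, probes[r, ]))
})

test_that("boundary expansion is additive, S-scaled, and never evicts a point", {
  ds <- labeled_dataset(rbind(c(1, 2), c(2.8, 5.6), c(1.9, 3.8)), c(1, 1, 1))
  m <- fit_mmm(ds)
  s_row <- m$S[1, ]
  e1 <- expand_boundaries(m, 0.1111)
  expect_equal(e1$Q[1, ] - m$Q[1, ], 0.1111 * s_row)
  expect_equal(m$V[1, ] - e1$V[1, ], 0.1111 * s_row)
  expect_equal(e1$expansion, 0.1111)

  # two half-steps equal one full step
  e_half <- expand_boundaries(expand_boundaries(m, 0.05), 0.05)
  e_full <- expand_boundaries(m, 0.1)
  expect_equal(e_half$Q, e_full$Q)
  expect_equal(e_half$V, e_full$V)
  expect_equal(e_half$expansion, e_full$expansion)

  # zero dispersion: boxes unchanged
  ds0 <- labeled_dataset(rbind(c(1, 1), c(1, 1)), c(1, 1))
  m0 <- fit_mmm(ds0)
  e0 <- expand_boundaries(m0, 5)
  expect_equal(e0$Q, m0$Q)
  expect_equal(e0$V, m0$V)

  # monotonicity: accepted points stay accepted after expansion
  dsr <- make_gaussian_ds(matrix(c(0, 4), 2, 1), n = 10, seed = 6)
  mr <- fit_mmm(dsr)
  probes <- matrix(seq(-1, 5, length.out = 50), 50, 1)
  before <- sapply(1:50, function(i) !is_rejected(classify_mmm(mr, probes[i, ])))
  mre <- expand_boundaries(mr, 0.5)
  after <- sapply(1:50, function(i) !is_rejected(classify_mmm(mre, probes[i, ])))
  expect_true(all(after[before]))
})

test_that("validation error is the misassignment fraction", {
  ds <- labeled_dataset(rbind(c(0, 0), c(1, 1), c(5, 5), c(6, 6)),
                        c(1, 1, 2, 2))
  m <- fit_mmm(ds)
  val_in <- labeled_dataset(rbind(c(0.5, 0.5), c(5.5, 5.5)), c(1, 2))
  expect_equal(mmm_validation_error(m, val_in), 0)
  val_out <- labeled_dataset(rbind(c(10, 10), c(-5, -5)), c(1, 2))
  expect_equal(mmm_validation_error(m, val_out), 1)

  # recount oracle on a random mix
  set.seed(9)
  val_mix <- labeled_dataset(matrix(runif(40, -1, 7), 20, 2),
                             sample(1:2, 20, replace = TRUE))
  preds <- predict_all(m, val_mix)
  manual <- mean(sapply(seq_len(20), function(i) {
    p <- preds[[i]]
    is_rejected(p) || p$outcome != val_mix$labels[i]
  }))
  expect_equal(mmm_validation_error(m, val_mix), manual)
})

test_that("training expands until the validation error target is met", {
  # validation drawn inside the initial boxes: zero expansions needed
  ds <- labeled_dataset(rbind(c(0, 0), c(2, 2), c(5, 5), c(7, 7)),
                        c(1, 1, 2, 2))
  val_in <- labeled_dataset(rbind(c(1, 1), c(6, 6)), c(1, 2))
  m <- train_mmm(ds, val_in, eta = 0.1, error_threshold = 0)
  expect_equal(attr(m, "rounds"), 0L)
  expect_equal(m$expansion, 0)

  # points just outside by less than eta * S: one expansion suffices
  m0 <- fit_mmm(ds)
  off <- 0.5 * 0.1111 * m0$S[1, 1]  # half an expansion step
  val_near <- labeled_dataset(rbind(c(2 + off, 2 + off), c(5 - off, 5 - off)),
                              c(1, 2))
  m1 <- train_mmm(ds, val_near, eta = 0.1111, error_threshold = 0)
  expect_equal(attr(m1, "rounds"), 1L)
  expect_true(isTRUE(attr(m1, "converged")))

  # rejection-only validation: the error history is non-increasing
  val_far <- labeled_dataset(rbind(c(2.2, 2.2), c(2.4, 2.4), c(4.6, 4.6)),
                             c(1, 1, 2))
  suppressMessages(m2 <- train_mmm(ds, val_far, eta = 0.05,
                                   error_threshold = 0, max_rounds = 20))
  expect_true(all(diff(attr(m2, "error_history")) <= 0))
})

test_that("hyperbox models survive a bit-exact JSON round trip", {
  ds <- make_gaussian_ds(matrix(runif(12), 3, 4), n = 7, seed = 10)
  m <- expand_boundaries(fit_mmm(ds), 0.1111)
  path <- withr::local_tempfile(fileext = ".json")
  mmm_to_json(m, path)
  back <- mmm_from_json(path)
  expect_identical(back$Q, m$Q)
  expect_identical(back$V, m$V)
  expect_identical(back$U, m$U)
  expect_identical(back$S, m$S)
  expect_identical(back$expansion, m$expansion)
  expect_identical(back$class_labels, m$class_labels)
})
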