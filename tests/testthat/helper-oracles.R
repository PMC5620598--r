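# Independent brute-force oracles and fixture builders shared across tests.
# Oracles are deliberately written as plain loops, separate from the package
# implementations they check.

# Build a small Gaussian-cluster dataset: one isotropic cluster per row of
# `means`, `n` rows each, sd `s`.
make_gaussian_ds <- function(means, n = 10, s = 0.2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(means)), function(m)
    matrix(rnorm(n * ncol(means), mean = rep(means[m, ], each = n), sd = s),
           n, ncol(means))))
  labeled_dataset(X, rep(seq_len(nrow(means)), each = n))
}

# Brute-force hyperbox classification: box membership by explicit loops,
# nearest-mean tie break, lowest label on exact distance ties.
oracle_box_predict <- function(Q, V, U, labels, x) {
  cand <- integer(0)
  for (m in seq_len(nrow(Q))) {
    ok <- TRUE
    for (n in seq_len(ncol(Q)))
      if (x[n] > Q[m, n] || x[n] < V[m, n]) { ok <- FALSE; break }
    if (ok) cand <- c(cand, m)
  }
  if (length(cand) == 0) return(list(rejected = TRUE, outcome = NA))
  dists <- sapply(cand, function(m) sqrt(sum((x - U[m, ])^2)))
  winners <- cand[dists == min(dists)]
  list(rejected = FALSE, outcome = labels[min(winners)], cand = labels[cand])
}

# Exhaustive sort-and-vote k-NN.
oracle_knn_predict <- function(X, labels, k, x) {
  d <- sqrt(rowSums(sweep(X, 2, x)^2))
  nn <- order(d)[1:k]
  votes <- table(labels[nn])
  top <- as.integer(names(votes)[votes == max(votes)])
  if (length(top) == 1) return(top)
  for (i in nn) if (labels[i] %in% top) return(labels[i])
}

# Brute-force maximum geometric margin between two separable 2-D point sets:
# scan unit directions and take the best half-gap between the projections.
oracle_margin_2d <- function(A, B, n_angles = 40000) {
  best <- -Inf
  for (th in seq(0, pi, length.out = n_angles)) {
    u <- c(cos(th), sin(th))
    pa <- A %*% u; pb <- B %*% u
    gap <- max((min(pb) - max(pa)) / 2, (min(pa) - max(pb)) / 2)
    if (gap > best) best <- gap
  }
  best
}

# Is row x inside the axis-aligned box [V[m,], Q[m,]] of any class m?
inside_any_box <- function(x, Q, V) {
  for (m in seq_len(nrow(Q)))
    if (all(x >= V[m, ] & x <= Q[m, ])) return(TRUE)
  FALSE
}

# Default-design dataset with margin-separated irrelevant rows, plus the
# split and hyperboxes used to separate them: the standard open-set fixture.
make_openset_fixture <- function(seed = 1, margin = 3) {
  cfg <- default_design(seed = seed, separation_margin = margin)
  ds0 <- generate_features(cfg)
  trained0 <- ds_subset(ds0, which(!ds0$irrelevant))
  sp <- stratified_split(trained0, c(0.7, 0.15, 0.15),
                         seed = derive_seed(seed, "split"))
  boxes <- fit_mmm(ds_subset(trained0, sp$train_idx))
  cfg2 <- enforce_separation(cfg, boxes)
  ds <- generate_features(cfg2)
  trained <- ds_subset(ds, which(!ds$irrelevant))
  list(cfg = cfg2, ds = ds, trained = trained, split = sp, boxes = boxes,
       irrelevant_X = ds$features[ds$irrelevant, , drop = FALSE],
       train = ds_subset(trained, sp$train_idx),
       val = ds_subset(trained, sp$val_idx),
       test = ds_subset(trained, sp$test_idx))
}
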