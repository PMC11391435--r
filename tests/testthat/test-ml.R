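test_that("correlation pruning keeps one of any redundant group, deterministically", {
  set.seed(41)
  base <- rnorm(200)
  x <- cbind(a = base, b = base, c = rnorm(200))
  pr <- prune_correlated(x, seed = 1)
  expect_equal(length(pr$kept), 2L)
  expect_true(3L %in% pr$kept)

  # independent columns all survive
  xi <- matrix(rnorm(200 * 5), 200)
  expect_equal(length(prune_correlated(xi, seed = 2)$kept), 5L)

  # r = {0.95, 0.95, 0.2}: exactly 2 kept for every visiting order
  x1 <- rnorm(2000)
  x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(2000)
  resid <- rnorm(2000)
  x3 <- 0.2 * scale(x1 + x2)[, 1] + sqrt(1 - 0.2^2) * resid
  xx <- cbind(x1, x2, x3)
  stopifnot(abs(cor(xx)[1, 2]) > 0.9, abs(cor(xx)[1, 3]) < 0.9,
            abs(cor(xx)[2, 3]) < 0.9)
  # enumeration oracle: greedy keep over all 6 visiting orders
  orders <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cm <- abs(cor(xx))
  for (ord in orders) {
    kept <- integer(0)
    for (j in ord) if (!length(kept) || all(cm[j, kept] <= 0.9)) kept <- c(kept, j)
    expect_equal(length(kept), 2L)
  }
  for (s in 1:6) expect_equal(length(prune_correlated(xx, seed = s)$kept), 2L)

  # same seed is bit-identical; pruning never grows the column count
  expect_identical(prune_correlated(xx, seed = 4), prune_correlated(xx, seed = 4))
  expect_lte(length(prune_correlated(xx, seed = 4)$kept), ncol(xx))
})

test_that("a single separating feature dominates importance in all three models", {
  set.seed(42)
  n <- 400
  labels <- factor(rep(c("s1", "s2"), each = n / 2))
  signal <- ifelse(labels == "s1", -1, 1) + rnorm(n, sd = 0.1)
  x <- cbind(sig = scale(signal)[, 1],
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("n", 1:6))))
  m <- train_models(x, labels, seed = 3)
  expect_equal(unname(m$accuracy), rep(1, 3), tolerance = 1e-9)
  for (mod in c("lr", "rf", "mlp")) {
    expect_equal(names(which.max(m$importance[[mod]])), "sig")
    expect_true(all(m$importance[[mod]] >= 0))
  }
  expect_error(train_models(x, factor(rep("s1", n)), seed = 1), "two classes")
})

test_that("label-shuffled data cannot be separated and raises the accuracy warning", {
  set.seed(43)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  labels <- factor(sample(rep(c("s1", "s2"), each = n / 2)))
  expect_warning(m <- train_models(x, labels, seed = 2, mlp_restarts = 1),
                 "accuracy below 1")
  expect_lt(m$accuracy["lr"], 1)
})

test_that("importance aggregation sums pairs onto residues and normalizes per model", {
  pairs <- data.frame(res_a = c("A1", "A1", "A2"), res_b = c("B1", "B2", "B2"),
                      stringsAsFactors = FALSE)
  fake_iter <- function(imp_full, kept = 1:3) {
    list(kept = kept,
         models = structure(list(
           importance = list(lr = imp_full[kept], rf = imp_full[kept],
                             mlp = imp_full[kept]),
           accuracy = c(lr = 1, rf = 1, mlp = 1)), class = "trained_models"))
  }

  # only pair 1 carries signal: both its residues at the normalized max
  t1 <- aggregate_importance(list(fake_iter(c(5, 0, 0))), pairs)
  expect_equal(t1$lr[t1$residue == "A1"], 1)
  expect_equal(t1$lr[t1$residue == "B1"], 1)
  expect_equal(t1$lr[t1$residue == "A2"], 0)

  # a residue in two signal pairs beats one in a single pair pre-normalization
  t2 <- aggregate_importance(list(fake_iter(c(1, 1, 1))), pairs)
  expect_equal(t2$lr[t2$residue == "A1"], 1)      # 2 pairs
  expect_equal(t2$lr[t2$residue == "B1"], 0.5)    # 1 pair

  # zero signal everywhere: all-zero table, no normalization applied
  t0 <- aggregate_importance(list(fake_iter(c(0, 0, 0))), pairs)
  expect_true(all(t0$lr == 0))

  # dropped pairs contribute nothing
  t3 <- aggregate_importance(list(fake_iter(c(7, 0, 7), kept = c(1L, 3L))), pairs)
  expect_equal(t3$lr[t3$residue == "B2"], 1)
  expect_equal(t3$lr[t3$residue == "B1"], t3$lr[t3$residue == "B2"])

  # relabeling residues permutes but does not change scores
  pairs_perm <- data.frame(res_a = c("Z9", "Z9", "Z8"),
                           res_b = c("Y1", "Y2", "Y2"))
  tp <- aggregate_importance(list(fake_iter(c(1, 1, 1))), pairs_perm)
  expect_equal(sort(tp$lr), sort(t2$lr))
})

test_that("category assignment combines the three criteria with the stated cutoffs", {
  imp <- structure(data.frame(residue = paste0("r", 1:5),
                              lr = c(0.9, 0.9, 0.79, 0.9, 0.5),
                              rf = 0, mlp = 0, stringsAsFactors = FALSE),
                   class = c("importance_table", "data.frame"))
  ddg <- data.frame(residue = paste0("r", 1:5),
                    delta_bfe = c(5, 5, 5, 1.2, 8))
  drmsf <- data.frame(residue = paste0("r", 1:5),
                      delta_rmsf = c(1.2, 0.2, 2, 0.5, 4),
                      order = c("ordered", "ordered", "ordered", "ordered",
                                "disordered"), stringsAsFactors = FALSE)
  cats <- classify_categories(imp, ddg, drmsf)
  expect_equal(cats$category, c("3", "2", "none", "1", "none"))
  # r3: importance 0.79 (strict > 0.8 fails) regardless of other criteria
  expect_false(cats$ml_flag[3])
  # r5: disordered 4 >= 3 flags rmsf but no ml importance
  expect_true(cats$rmsf_flag[5])

  # exact threshold 0.8 is NOT flagged (strict)
  imp$lr[4] <- 0.8
  cats2 <- classify_categories(imp, ddg, drmsf)
  expect_equal(cats2$category[4], "none")

  # missing residue in one table: partial flags with a warning
  expect_warning(c3 <- classify_categories(imp, ddg[-1, ], drmsf), "missing")
  expect_false(c3$energy_flag[1])
})

test_that("features standardize to mean 0, sd 1 and honor the eligibility cutoff", {
  spec <- tiny_spec(frames_per_replicate = 40, seed = 51,
                    planted_contacts = data.frame(resno_a = 4, resno_b = 104,
                                                  mean_a = 6, mean_b = 9,
                                                  jitter = 0.6))
  g <- generate_ensembles(spec)
  f <- extract_pair_features(g$ensemble_a, g$ensemble_b, toy_domain_map(spec), 1)
  expect_true(all(abs(colMeans(f$x)) < 1e-9))
  expect_true(all(abs(apply(f$x, 2, sd) - 1) < 1e-9))

  # brute-force eligibility scan
  top <- g$topology
  heavy <- which(top$atoms$elesy != "H")
  trajs <- c(g$ensemble_a$replicates, g$ensemble_b$replicates)
  ra <- top$residues[top$residues$chain == "A", "residue_id"]
  rb <- top$residues[top$residues$chain == "B", "residue_id"]
  dmin <- matrix(Inf, length(ra), length(rb))
  for (tr in trajs) for (fr in seq_len(n_frames(tr))) {
    xyz <- tr$coords[, , fr]
    for (i in seq_along(ra)) for (j in seq_along(rb)) {
      ai <- intersect(heavy, which(top$atoms$residue_id == ra[i]))
      bj <- intersect(heavy, which(top$atoms$residue_id == rb[j]))
      dmin[i, j] <- min(dmin[i, j], min(cross_dist(xyz[ai, ], xyz[bj, ])))
    }
  }
  expect_equal(ncol(f$x), sum(dmin < 10))

  # a pair never within cutoff is excluded
  far_pairs <- which(dmin >= 10, arr.ind = TRUE)
  if (nrow(far_pairs)) {
    lab <- paste(residue_labels(top, ra[far_pairs[1, 1]]),
                 residue_labels(top, rb[far_pairs[1, 2]]), sep = " | ")
    expect_false(lab %in% colnames(f$x))
  }
})
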