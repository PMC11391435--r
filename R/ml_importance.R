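# Ensemble ML scoring of interfacial residue importance.
#
# Frames from two states are featurized as standardized inverse minimum
# heavy-atom distances of eligible interfacial residue pairs; three
# classifiers (ridge logistic regression, random forest, multilayer
# perceptron) are trained to tell the states apart; per-feature
# importances are summed onto residues, averaged over shuffled-pruning
# iterations, and normalized per model per interface to a max of 1.

# Per-frame minimum heavy-atom distance between every residue of group
# a and every residue of group b. atoms_a/atoms_b: atom indices;
# rid_*: residue id per atom. Returns nResA x nResB matrix.
min_res_dist <- function(xyz, atoms_a, atoms_b, rid_a, rid_b,
                         ids_a, ids_b) {
  d <- cross_dist(xyz[atoms_a, , drop = FALSE], xyz[atoms_b, , drop = FALSE])
  na <- length(ids_a); nb <- length(ids_b)
  ga <- match(rid_a, ids_a); gb <- match(rid_b, ids_b)
  ca <- length(atoms_a) / na; cb <- length(atoms_b) / nb
  if (ca == as.integer(ca) && cb == as.integer(cb) &&
      identical(ga, rep(seq_len(na), each = ca)) &&
      identical(gb, rep(seq_len(nb), each = cb))) {
    # constant atoms per residue in contiguous blocks: min-pool via pmin
    out <- matrix(Inf, na, nb)
    for (i in seq_len(ca)) {
      ri <- seq.int(i, by = ca, length.out = na)
      for (j in seq_len(cb)) {
        out <- pmin(out, d[ri, seq.int(j, by = cb, length.out = nb), drop = FALSE])
      }
    }
    return(out)
  }
  out <- matrix(Inf, na, nb)
  for (i in seq_len(na)) {
    sub <- d[ga == i, , drop = FALSE]
    mins <- apply(sub, 2L, min)
    out[i, ] <- as.numeric(tapply(mins, gb, min))
  }
  out
}

#' Extract standardized contact features for an interface
#'
#' Eligible residue pairs are the cross-interface pairs whose minimum
#' heavy-atom distance drops below `contact_cutoff` (strict) in at
#' least one frame of any replicate of either state. Each frame
#' contributes one row: the inverse minimum heavy-atom distance
#' (Angstrom^-1) of every eligible pair, standardized column-wise over
#' all rows of both states to mean 0 and sd 1.
#'
#' @param ensemble_a,ensemble_b [md_ensemble()]s of the two states
#'   (shared topology)
#' @param domain_map a [load_domain_map()] result
#' @param interface_id interface id in the map
#' @param frames_per_replicate evenly spaced frames taken from each
#'   replicate (`NULL` = all frames)
#' @param window optional `c(t0, t1)` ns window applied per replicate
#'   before sampling
#' @param contact_cutoff eligibility cutoff, Angstrom (default 10)
#' @return object of class `contact_features`: `x` (rows = frames,
#'   columns = eligible pairs, standardized), `labels` (state factor
#'   per row), `replicate` (provenance), `pairs` (residue labels per
#'   column), `interface`, `scaling` (per-column mean/sd)
#' @export
extract_pair_features <- function(ensemble_a, ensemble_b, domain_map,
                                  interface_id, frames_per_replicate = NULL,
                                  window = NULL, contact_cutoff = 10) {
  top <- ensemble_a$topology
  ifc <- domain_map$interfaces
  row <- which(ifc$id == interface_id)
  if (!length(row)) stop("unknown interface id ", interface_id)
  da <- domain_residues(domain_map, ifc$a[row])
  db <- domain_residues(domain_map, ifc$b[row])
  sel_res <- function(d) {
    which(top$residues$chain == d$chain & top$residues$resno %in% d$resno)
  }
  ids_a <- top$residues$residue_id[sel_res(da)]
  ids_b <- top$residues$residue_id[sel_res(db)]
  if (!length(ids_a) || !length(ids_b)) stop("interface domains match no residues")
  heavy <- top$atoms$elesy != "H"
  atoms_a <- which(heavy & top$atoms$residue_id %in% ids_a)
  atoms_b <- which(heavy & top$atoms$residue_id %in% ids_b)
  rid_a <- top$atoms$residue_id[atoms_a]
  rid_b <- top$atoms$residue_id[atoms_b]

  take <- function(tr) {
    if (!is.null(window)) tr <- window_frames(tr, window, frames_per_replicate %||% n_frames(tr))
    else if (!is.null(frames_per_replicate)) {
      tr <- window_frames(tr, range(tr$times) + c(-1e-9, 1e-9), frames_per_replicate)
    }
    tr
  }
  trajs <- c(lapply(ensemble_a$replicates, take), lapply(ensemble_b$replicates, take))
  state <- c(rep(ensemble_a$state_label, length(ensemble_a$replicates)),
             rep(ensemble_b$state_label, length(ensemble_b$replicates)))

  npair <- length(ids_a) * length(ids_b)
  dmin_global <- matrix(Inf, length(ids_a), length(ids_b))
  per_frame <- list()
  labels <- character(0); repl <- integer(0)
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    nf <- n_frames(tr)
    block <- matrix(0, nf, npair)
    for (f in seq_len(nf)) {
      dm <- min_res_dist(tr$coords[, , f], atoms_a, atoms_b, rid_a, rid_b,
                         ids_a, ids_b)
      dmin_global <- pmin(dmin_global, dm)
      block[f, ] <- as.numeric(dm)
    }
    per_frame[[k]] <- block
    labels <- c(labels, rep(state[k], nf))
    repl <- c(repl, rep(k, nf))
  }
  eligible <- which(as.numeric(dmin_global) < contact_cutoff)
  if (!length(eligible)) stop("no eligible residue pairs at this interface")
  x <- 1 / do.call(rbind, per_frame)[, eligible, drop = FALSE]
  mu <- colMeans(x); sdev <- apply(x, 2L, stats::sd)
  sdev[sdev == 0] <- 1  # constant column: centered to 0
  x <- sweep(sweep(x, 2L, mu), 2L, sdev, "/")
  pair_idx <- arrayInd(eligible, dim(dmin_global))
  pairs <- data.frame(
    res_a = residue_labels(top, ids_a[pair_idx[, 1L]]),
    res_b = residue_labels(top, ids_b[pair_idx[, 2L]]),
    stringsAsFactors = FALSE)
  colnames(x) <- paste(pairs$res_a, pairs$res_b, sep = " | ")
  structure(list(x = x, labels = factor(labels), replicate = repl,
                 pairs = pairs, interface = interface_id,
                 scaling = list(mean = mu, sd = sdev)),
            class = "contact_features")
}

#' @export
print.contact_features <- function(x, ...) {
  cat(sprintf("contact_features: interface %s, %d frames x %d pairs (%s)\n",
              x$interface, nrow(x$x), ncol(x$x),
              paste(levels(x$labels), collapse = " vs ")))
  invisible(x)
}

#' Greedy pruning of highly correlated feature columns
#'
#' Columns are visited in a seeded random order; a column is kept iff
#' its absolute Pearson correlation with every already-kept column is
#' at most `r_max`. Deterministic given the seed; the visiting order is
#' reshuffled across importance iterations.
#'
#' @param x numeric feature matrix
#' @param r_max correlation threshold (default 0.9)
#' @param seed RNG seed for the visiting order
#' @return list with `kept` and `dropped` column indices (in original
#'   column order within each)
#' @export
prune_correlated <- function(x, r_max = 0.9, seed = 1L) {
  p <- ncol(x)
  if (p < 1L) stop("need at least one column")
  ord <- with_seed(seed, sample.int(p))
  cm <- abs(stats::cor(x))
  cm[is.na(cm)] <- 0
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(cm[j, kept] <= r_max)) kept <- c(kept, j)
  }
  list(kept = sort(kept), dropped = sort(setdiff(seq_len(p), kept)))
}

#' Train the three classifiers and extract feature importances
#'
#' Fits (i) ridge-penalized logistic regression, (ii) a random forest,
#' and (iii) a single-hidden-layer perceptron to predict each frame's
#' state from the feature matrix. Training accuracy is recorded per
#' model and a warning is raised if any falls below 1 (the pipeline's
#' separability check). Importances are all non-negative: LR = absolute
#' coefficient, RF = impurity importance, MLP = mean absolute
#' first-layer weight per input.
#'
#' @param x standardized feature matrix (rows = frames)
#' @param labels two-level factor of states per row
#' @param seed RNG seed (forest bootstrap, perceptron init)
#' @param num_trees random forest size
#' @param mlp_size,mlp_decay,mlp_maxit perceptron hyperparameters
#' @param mlp_restarts maximum perceptron re-initializations used to
#'   reach training accuracy 1.0
#' @return list of class `trained_models`: per model `importance`
#'   (named by feature) and `accuracy`
#' @export
train_models <- function(x, labels, seed = 1L, num_trees = 200,
                         mlp_size = 4, mlp_decay = 1e-4, mlp_maxit = 500,
                         mlp_restarts = 5) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("need exactly two classes in 'labels'")
  y <- as.integer(labels) - 1L
  p <- ncol(x)
  feat <- colnames(x) %||% paste0("f", seq_len(p))

  # ridge logistic regression (fixed small penalty for stability under
  # perfect separation)
  lam <- 1 / nrow(x)
  fit_lr <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                           lambda = sort(unique(c(1, 0.1, 0.01, lam)),
                                         decreasing = TRUE))
  co <- as.numeric(glmnet::coef.glmnet(fit_lr, s = lam))[-1L]
  pred_lr <- as.numeric(stats::predict(fit_lr, newx = x, s = lam,
                                       type = "response")) > 0.5
  acc_lr <- mean(pred_lr == (y == 1L))
  imp_lr <- abs(co)

  df <- data.frame(x, check.names = FALSE)
  df$.y <- labels
  fit_rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                           num.trees = num_trees, importance = "impurity",
                           seed = seed, num.threads = 1L)
  pred_rf <- stats::predict(fit_rf, data = df, num.threads = 1L)$predictions
  acc_rf <- mean(pred_rf == labels)
  imp_rf <- pmax(fit_rf$variable.importance[feat], 0)

  # the perceptron is re-initialized until it reproduces the training
  # labels (the procedure trains to accuracy 1.0); the best attempt is
  # kept if none fully separates
  fit_mlp <- NULL; acc_mlp <- -1
  for (attempt in seq_len(mlp_restarts)) {
    cand <- with_seed(seed + 7919L * (attempt - 1L),
                      nnet::nnet(x, y, size = mlp_size, decay = mlp_decay,
                                 maxit = mlp_maxit, entropy = TRUE,
                                 trace = FALSE, MaxNWts = 100000))
    acc_cand <- mean((as.numeric(stats::predict(cand, x)) > 0.5) == (y == 1L))
    if (acc_cand > acc_mlp) {
      fit_mlp <- cand
      acc_mlp <- acc_cand
    }
    if (acc_mlp >= 1) break
  }
  w1 <- matrix(fit_mlp$wts[seq_len((p + 1L) * mlp_size)], nrow = p + 1L)
  imp_mlp <- rowMeans(abs(w1[-1L, , drop = FALSE]))

  acc <- c(lr = acc_lr, rf = acc_rf, mlp = acc_mlp)
  if (any(acc < 1)) {
    warning(sprintf("training accuracy below 1.0 (lr %.3f, rf %.3f, mlp %.3f): states may not be separable at this interface",
                    acc_lr, acc_rf, acc_mlp))
  }
  imp <- list(lr = stats::setNames(imp_lr, feat),
              rf = stats::setNames(as.numeric(imp_rf), feat),
              mlp = stats::setNames(imp_mlp, feat))
  structure(list(importance = imp, accuracy = acc), class = "trained_models")
}

#' Aggregate per-pair importances onto residues across iterations
#'
#' Per iteration and model, a residue's importance is the sum of the
#' importances of the (kept) pairs containing it; pairs pruned in that
#' iteration contribute zero. Scores are averaged over iterations and
#' each model's vector is normalized to a maximum of 1 per interface
#' (all-zero vectors are left at zero).
#'
#' @param iterations list of per-iteration results, each with `models`
#'   (a `trained_models`) and `kept` (column indices retained by
#'   pruning)
#' @param pairs data.frame with `res_a`, `res_b` residue labels per
#'   original column
#' @return data.frame of class `importance_table` with `residue`, `lr`,
#'   `rf`, `mlp`; attribute `accuracy` holds the per-iteration training
#'   accuracies
#' @export
aggregate_importance <- function(iterations, pairs) {
  residues <- sort(unique(c(pairs$res_a, pairs$res_b)))
  acc <- NULL
  sums <- list(lr = 0, rf = 0, mlp = 0)
  for (it in iterations) {
    kept <- it$kept
    for (m in names(sums)) {
      impf <- numeric(nrow(pairs))
      impf[kept] <- it$models$importance[[m]]
      res_imp <- vapply(residues, function(r) {
        sum(impf[pairs$res_a == r | pairs$res_b == r])
      }, numeric(1))
      sums[[m]] <- sums[[m]] + res_imp
    }
    acc <- rbind(acc, it$models$accuracy)
  }
  n_iter <- length(iterations)
  out <- data.frame(residue = residues, stringsAsFactors = FALSE)
  for (m in names(sums)) {
    v <- sums[[m]] / n_iter
    if (max(v) > 0) v <- v / max(v)
    out[[m]] <- as.numeric(v)
  }
  attr(out, "accuracy") <- acc
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Full residue-importance procedure for one interface
#'
#' Runs `n_iter` iterations (seeds `seed + 0 ... seed + n_iter - 1`) of
#' shuffled correlation pruning followed by training of the three
#' classifiers, then aggregates importances onto residues via
#' [aggregate_importance()].
#'
#' @param features a [extract_pair_features()] result
#' @param n_iter number of iterations (default 20)
#' @param seed base seed
#' @param r_max pruning threshold
#' @param ... passed to [train_models()]
#' @return an `importance_table`
#' @export
residue_importance <- function(features, n_iter = 20, seed = 1L,
                               r_max = 0.9, ...) {
  iterations <- lapply(seq_len(n_iter) - 1L, function(k) {
    pr <- prune_correlated(features$x, r_max = r_max, seed = seed + k)
    models <- train_models(features$x[, pr$kept, drop = FALSE],
                           features$labels, seed = seed + k, ...)
    list(kept = pr$kept, models = models)
  })
  out <- aggregate_importance(iterations, features$pairs)
  attr(out, "interface") <- features$interface
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table: %d residues (interface %s)\n",
              nrow(x), attr(x, "interface") %||% "?"))
  top <- x[order(-pmax(x$lr, x$rf, x$mlp)), ][seq_len(min(5L, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Three-category classification of interfacial residues
#'
#' Combines three per-residue criteria: `ml_flag` = importance strictly
#' above `ml_threshold` in at least one model; `energy_flag` = absolute
#' per-residue binding-energy difference at least `ddg_threshold`
#' kJ/mol; `rmsf_flag` = absolute RMSF difference at least 1 Angstrom
#' (ordered) or 3 Angstrom (disordered), both inclusive. Category 3 =
#' all three flags; category 2 = ML flag plus exactly one of the other
#' two; category 1 = ML flag only; `none` otherwise.
#'
#' @param importance an `importance_table`
#' @param ddg data.frame with `residue` and `delta_bfe` or
#'   `delta_ddg_total` column (kJ/mol), e.g. from [residue_delta_bfe()]
#' @param drmsf a [flag_flexible_regions()] profile (uses `delta_rmsf`
#'   and `order`)
#' @param ml_threshold importance threshold (strict; default 0.8)
#' @param ddg_threshold energy threshold, kJ/mol (inclusive; default 2)
#' @param rmsf_thresholds Angstrom thresholds per order class
#' @return data.frame of class `category_assignment` with the three
#'   flags and `category` in `{none, 1, 2, 3}`; residues missing from
#'   any input get partial flags and a warning
#' @export
classify_categories <- function(importance, ddg, drmsf,
                                ml_threshold = 0.8, ddg_threshold = 2,
                                rmsf_thresholds = c(ordered = 1, disordered = 3)) {
  res <- importance$residue
  ml_flag <- apply(importance[c("lr", "rf", "mlp")], 1L, max) > ml_threshold
  dcol <- intersect(c("delta_ddg_total", "delta_bfe"), names(ddg))[1L]
  if (is.na(dcol)) stop("'ddg' needs a delta_bfe or delta_ddg_total column")
  hit_e <- match(res, ddg$residue)
  hit_r <- match(res, drmsf$residue)
  if (anyNA(hit_e) || anyNA(hit_r)) {
    warning(sum(is.na(hit_e) | is.na(hit_r)),
            " residue(s) missing from the energy or RMSF table: partial flags")
  }
  energy_flag <- !is.na(hit_e) & abs(ddg[[dcol]][hit_e]) >= ddg_threshold
  thr <- rmsf_thresholds[ifelse(is.na(hit_r), "ordered", drmsf$order[hit_r])]
  rmsf_flag <- !is.na(hit_r) & abs(drmsf$delta_rmsf[hit_r]) >= thr
  category <- ifelse(ml_flag & energy_flag & rmsf_flag, "3",
                     ifelse(ml_flag & (energy_flag | rmsf_flag), "2",
                            ifelse(ml_flag, "1", "none")))
  out <- data.frame(residue = res, ml_flag = ml_flag,
                    energy_flag = energy_flag, rmsf_flag = rmsf_flag,
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' @export
print.category_assignment <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("none", "1", "2", "3")))
  cat("category_assignment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
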