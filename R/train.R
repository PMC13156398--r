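# Augmented optimization objective (weighted main + auxiliary cross-entropies),
# class weighting, stratified splitting / cross-validation protocol, the Adam
# training loop with early stopping, and the accuracy + reliability metric
# panel.

#' Training configuration
#'
#' Defaults follow the experimental protocol: auxiliary-loss weights alpha = 2
#' (structured) and beta = 1 (notes), mini-batch size 32, at most 150 epochs
#' with early stopping on the validation overall loss, a 60/20/20
#' train/validation/test split and 5-fold stratified cross-validation.
#'
#' @param alpha,beta Weights of the structured / notes auxiliary losses.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param min_delta Minimum validation-loss improvement that counts.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled weight-decay coefficient lambda: after each
#'   Adam step every parameter is multiplied by `1 - lr * lambda`.  Shrinks
#'   uninformative evidence (memberships toward uniform, evidence strengths
#'   toward their neutral range), which is what makes the fused model robust
#'   when one modality carries no signal.
#' @param seed Integer seed for shuffling and dropout.
#' @param split Named fractions for train/validation/test (sum to 1).
#' @param n_folds Stratified cross-validation folds.
#' @param threshold Decision threshold on the positive-class probability.
#' @param use_class_weights Weight classes by inverse relative frequency.
#' @return An object of class `train_config`.
#' @export
train_config <- function(alpha = 2, beta = 1, batch_size = 32L,
                         max_epochs = 150L, patience = 10L, min_delta = 1e-4,
                         lr = 1e-3, weight_decay = 1, seed = 1L,
                         split = c(train = 0.6, val = 0.2, test = 0.2),
                         n_folds = 5L, threshold = 0.5,
                         use_class_weights = TRUE) {
  stopifnot(alpha >= 0, beta >= 0, weight_decay >= 0,
            abs(sum(split) - 1) < 1e-8)
  structure(list(alpha = alpha, beta = beta, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 lr = lr, weight_decay = weight_decay, seed = as.integer(seed),
                 split = split, n_folds = as.integer(n_folds),
                 threshold = threshold,
                 use_class_weights = use_class_weights),
            class = "train_config")
}

#' Balanced inverse-frequency class weights
#'
#' w_c = N / (M * N_c): each class's loss contribution is scaled inversely to
#' its frequency so the minority (outcome-positive) class is not drowned out.
#'
#' @param labels Binary 0/1 label vector (both classes must be present).
#' @return Named numeric vector `c(negative, positive)`.
#' @export
#' @examples
#' class_weights(c(rep(0, 90), rep(1, 10)))
class_weights <- function(labels) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L)
    stop("class weights need both classes present")
  c(negative = n / (2 * n_neg), positive = n / (2 * n_pos))
}

one_hot <- function(labels, M = 2L, positive_col = 2L) {
  Y <- matrix(0, length(labels), M)
  Y[cbind(seq_along(labels), ifelse(labels == 1, positive_col,
                                    setdiff(seq_len(M), positive_col)[1L]))] <- 1
  Y
}

#' Main, auxiliary and overall losses
#'
#' `main_loss` is the class-weighted cross-entropy on the pignistic
#' probabilities; `aux_loss` is the class-weighted softmax cross-entropy on an
#' auxiliary head's logits; `overall_loss` combines them as
#' main + alpha * aux_structured + beta * aux_notes.
#'
#' @param p N x M matrix of predicted probabilities (rows sum to 1).
#' @param y N x M one-hot label matrix.
#' @param w Length-M class weight vector (default unweighted).
#' @return Scalar loss.
#' @export
main_loss <- function(p, y, w = rep(1, ncol(y))) {
  stopifnot(all(dim(p) == dim(y)))
  W <- sweep(y, 2L, w, "*")
  -sum(W * log(pmax(p, 1e-12))) / nrow(y)
}

#' @rdname main_loss
#' @param logits N x M logit matrix.
#' @export
aux_loss <- function(logits, y, w = rep(1, ncol(y))) {
  stopifnot(all(dim(logits) == dim(y)))
  mx <- apply(logits, 1L, max)
  ls <- sweep(logits, 1L, mx + log(rowSums(exp(logits - mx))), "-")
  W <- sweep(y, 2L, w, "*")
  -sum(W * ls) / nrow(y)
}

#' @rdname main_loss
#' @param main,aux_s,aux_n Loss components.
#' @param cfg A [train_config()] supplying alpha and beta.
#' @export
overall_loss <- function(main, aux_s, aux_n, cfg = train_config()) {
  main + cfg$alpha * aux_s + cfg$beta * aux_n
}

#' Stratified holdout split
#'
#' Shuffles each class separately and allocates it to train/validation/test in
#' the configured fractions, so class prevalence is preserved within one
#' sample in every part.
#'
#' @param labels Binary label vector.
#' @param fractions Named train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, fractions = c(train = 0.6, val = 0.2, test = 0.2),
                             seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["val"]] * n)
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[n_tr + seq_len(min(n_va, n - n_tr))])
    out$test <- c(out$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(out, sort)
}

#' Stratified cross-validation folds
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of k disjoint index vectors partitioning `seq_along(labels)`,
#'   each with class proportions within one sample of the global proportions.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assignment <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assignment == f])
  }
  lapply(folds, sort)
}

# ---- training loop ----------------------------------------------------------

adam_init <- function(flat) list(m = lapply(flat, function(p) p * 0),
                                 v = lapply(flat, function(p) p * 0), t = 0L)

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# loss nodes for one batch on the tape
loss_graph <- function(tape, model, g, y, w, cfg) {
  n <- nrow(y)
  W <- sweep(y, 2L, w, "*")
  if (model$spec$strategy == "evidential") {
    lmain <- ad_smul(tape, ad_sum(tape, ad_mul_const(tape, ad_log(
      tape, ad_clamp_min(tape, g$p, 1e-12)), W)), -1 / n)
    total <- lmain
    for (k in seq_along(model$bundles)) {
      coef <- if (model$kinds[k] == "notes") cfg$beta else cfg$alpha
      if (coef == 0) next
      laux <- ad_smul(tape, ad_sum(tape, ad_mul_const(
        tape, ad_log_softmax(tape, g$aux[[k]]), W)), -1 / n)
      total <- ad_add(tape, total, ad_smul(tape, laux, coef))
    }
    total
  } else {
    ad_smul(tape, ad_sum(tape, ad_mul_const(
      tape, ad_log_softmax(tape, g$logits), W)), -1 / n)
  }
}

# evaluation-mode overall loss on a held-out index set
eval_loss <- function(model, inputs, labels, idx, w, cfg) {
  sub <- lapply(inputs, function(X) X[idx, , drop = FALSE])
  fw <- model_forward(model, sub)
  y <- one_hot(labels[idx], model$frame$M, model$positive_class)
  if (model$spec$strategy == "evidential") {
    l <- main_loss(fw$p, y, w)
    for (k in seq_along(model$bundles)) {
      coef <- if (model$kinds[k] == "notes") cfg$beta else cfg$alpha
      l <- l + coef * aux_loss(fw$aux_logits[[k]], y, w)
    }
    l
  } else {
    aux_loss(fw$logits, y, w)
  }
}

#' Train a fusion model
#'
#' Minimizes the overall loss (weighted main cross-entropy on the pignistic
#' output plus the weighted auxiliary cross-entropies for the evidential
#' strategy; plain weighted cross-entropy for baseline strategies) with Adam
#' over mini-batches, early-stopping on the validation overall loss and
#' returning the best-validation checkpoint.  Fully deterministic given the
#' configuration seed.
#'
#' @param model A [build_fusion_model()] object.
#' @param inputs Named list of full input matrices.
#' @param labels Binary 0/1 outcome vector (all rows).
#' @param cfg A [train_config()].
#' @param train_idx,val_idx Row indices of the training and validation sets.
#' @param verbose Print per-epoch losses.
#' @return List with the trained `model` (best checkpoint), a `history` data
#'   frame (epoch, train_loss, val_loss), `best_epoch`, and the class
#'   `weights` used.
#' @export
train_model <- function(model, inputs, labels, cfg = train_config(),
                        train_idx, val_idx, verbose = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  M <- model$frame$M
  w <- if (cfg$use_class_weights) unname(class_weights(labels[train_idx]))
       else rep(1, M)
  flat <- flatten_params(model)
  state <- adam_init(flat)
  best <- flat; best_loss <- Inf; best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  y_all <- one_hot(labels, M, model$positive_class)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_idx)
    batch_losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      tape <- tape_new()
      pids <- lapply(flat, function(v) ad_input(tape, v))
      sub <- lapply(inputs, function(X) X[bidx, , drop = FALSE])
      g <- model_graph(tape, model, sub, pids, training = TRUE)
      lnode <- loss_graph(tape, model, g, y_all[bidx, , drop = FALSE], w, cfg)
      lval <- ad_value(tape, lnode)[1L]
      if (!is.finite(lval))
        stop(sprintf("training diverged (loss = %s at epoch %d)", lval, epoch))
      grads <- ad_backward(tape, lnode)
      gflat <- lapply(pids, function(i) grads[[i]])
      upd <- adam_step(flat, gflat, state, cfg$lr)
      flat <- upd$flat; state <- upd$state
      if (cfg$weight_decay > 0) {
        decay <- 1 - cfg$lr * cfg$weight_decay
        flat <- lapply(flat, function(p) p * decay)
      }
      batch_losses <- c(batch_losses, lval)
    }
    model <- set_params(model, flat)
    vloss <- eval_loss(model, inputs, labels, val_idx, w, cfg)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = vloss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(batch_losses), vloss))
    if (vloss < best_loss - cfg$min_delta) {
      best_loss <- vloss; best <- flat; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
  }
  list(model = set_params(model, best), history = history,
       best_epoch = best_epoch, weights = w)
}

# ---- metrics ----------------------------------------------------------------

safe_div <- function(a, b) if (b == 0) NA_real_ else a / b

average_precision <- function(p, labels) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(p, decreasing = TRUE)
  y <- labels[ord]; ps <- p[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)  # last index of each tie group
  prec <- (tp / (tp + fp))[last]
  rec <- (tp / n_pos)[last]
  sum(diff(c(0, rec)) * prec)
}

#' Accuracy and reliability metric panel
#'
#' Computes the full 10-metric evaluation row: threshold-based class-specific
#' metrics (precision, recall, specificity, NPV), holistic metrics (BACC, F1,
#' AUROC, AUPRC) and reliability metrics (Brier score, NLL).  Metrics with a
#' zero denominator (e.g. precision with no predicted positives) are reported
#' as `NA` rather than 0 so fold averages are not silently deflated.
#'
#' @param p_positive Predicted positive-class probabilities in \[0, 1\].
#' @param labels Binary 0/1 outcome vector.
#' @param threshold Decision threshold (predict positive iff p >= threshold).
#' @return Named numeric vector of the 10 metrics plus the confusion counts.
#' @export
#' @examples
#' compute_metrics(c(0.8, 0.3, 0.6, 0.2), c(1, 0, 1, 0))
compute_metrics <- function(p_positive, labels, threshold = 0.5) {
  stopifnot(length(p_positive) == length(labels),
            all(p_positive >= 0 & p_positive <= 1))
  pred <- as.integer(p_positive >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  npv <- safe_div(tn, tn + fn)
  bacc <- if (is.na(recall) || is.na(specificity)) NA_real_
          else (recall + specificity) / 2
  f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  auroc <- if (length(unique(labels)) < 2L) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = p_positive,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  auprc <- average_precision(p_positive, labels)
  brier <- mean((p_positive - labels)^2)
  pc <- pmin(pmax(p_positive, 1e-12), 1 - 1e-12)
  nll <- -mean(labels * log(pc) + (1 - labels) * log(1 - pc))
  c(precision = precision, recall = recall, specificity = specificity,
    npv = npv, bacc = bacc, f1 = f1, auroc = auroc, auprc = auprc,
    brier = brier, nll = nll, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Summarize per-fold metric rows into a report
#'
#' @param rows List of metric vectors from [compute_metrics()], one per fold.
#' @return A data frame with one row per fold plus `mean` and `se` rows
#'   (standard error = sample SD / sqrt(number of non-missing folds)).
#' @export
eval_report <- function(rows) {
  mat <- do.call(rbind, rows)
  metric_cols <- setdiff(colnames(mat), c("tp", "fp", "fn", "tn"))
  mat <- mat[, metric_cols, drop = FALSE]
  means <- colMeans(mat, na.rm = TRUE)
  ses <- apply(mat, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  out <- as.data.frame(rbind(mat, mean = means, se = ses))
  out$fold <- c(as.character(seq_len(nrow(mat))), "mean", "se")
  out[, c("fold", metric_cols)]
}

#' Stratified cross-validated training and evaluation
#'
#' Runs the full protocol on a cohort: for each stratified fold, the fold is
#' held out as the test set, the remainder is split 75/25 into training and
#' validation (a 60/20/20 split overall), preprocessing is fitted on the
#' training rows only, a fresh model is trained, and the test metric row is
#' recorded.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param cfg A [train_config()].
#' @param spec A [fusion_spec()].
#' @param architecture Structured-encoder architecture.
#' @param n_prototypes Prototypes per evidential layer.
#' @param text_dim Hashing-embedding width.
#' @param folds Optional precomputed fold list (shared across strategies in
#'   fusion comparisons).
#' @param verbose Print progress.
#' @return List with `report` ([eval_report()] data frame), `rows`, `folds`,
#'   and per-fold `histories`.
#' @export
run_cv <- function(cohort, cfg = train_config(), spec = fusion_spec(),
                   architecture = "mlp", n_prototypes = 20L, text_dim = 256L,
                   folds = NULL, verbose = FALSE) {
  labels <- cohort$labels
  if (is.null(folds)) folds <- stratified_folds(labels, cfg$n_folds, cfg$seed)
  rows <- list(); histories <- list()
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    rest <- setdiff(seq_along(labels), test_idx)
    sp <- stratified_split(labels[rest],
                           c(train = 0.75, val = 0.25, test = 0),
                           seed = cfg$seed + f)
    train_idx <- rest[sp$train]; val_idx <- rest[sp$val]
    inputs <- prepare_bundle_inputs(cohort, spec$partition, train_idx,
                                    text_dim = text_dim)
    model <- build_fusion_model(inputs, cohort$frame, spec,
                                architecture = architecture,
                                n_prototypes = n_prototypes,
                                train_idx = train_idx,
                                threshold = cfg$threshold,
                                seed = cfg$seed + 1000L * f)
    fit <- train_model(model, inputs, labels, cfg, train_idx, val_idx)
    sub <- lapply(inputs, function(X) X[test_idx, , drop = FALSE])
    p <- model_forward(fit$model, sub)$p[, model$positive_class]
    rows[[f]] <- compute_metrics(p, labels[test_idx], cfg$threshold)
    histories[[f]] <- fit$history
    if (verbose) message(sprintf("fold %d: AUROC %.3f", f, rows[[f]]["auroc"]))
  }
  list(report = eval_report(rows), rows = rows, folds = folds,
       histories = histories)
}
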