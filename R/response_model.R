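#' Comparative-Ct relative expression
#'
#' Implements the comparative cycle-threshold method:
#' `2^-((Ct_gene,sample - Ct_ctrl,sample) - (Ct_gene,ref - Ct_ctrl,ref))`.
#'
#' @param ct_gene_sample,ct_ctrl_sample Gene and internal-control Ct in the
#'   sample of interest.
#' @param ct_gene_ref,ct_ctrl_ref Gene and internal-control Ct in the
#'   reference condition.
#' @return Relative expression `2^-ddCt` (> 0).  Vectorised; any missing Ct
#'   is an error.
#' @export
ddct <- function(ct_gene_sample, ct_ctrl_sample, ct_gene_ref, ct_ctrl_ref) {
  vals <- cbind(ct_gene_sample, ct_ctrl_sample, ct_gene_ref, ct_ctrl_ref)
  if (any(!is.finite(vals)))
    stop("missing or non-finite Ct value", call. = FALSE)
  ddct <- (ct_gene_sample - ct_ctrl_sample) - (ct_gene_ref - ct_ctrl_ref)
  2^(-ddct)
}

#' Delta-Ct expression features from a Ct table
#'
#' Converts a Ct matrix (genes x samples) to `-dCt = -(Ct_gene - Ct_ctrl)`
#' per sample, a log2-like abundance scale suitable as classifier input.
#'
#' @param ct Ct matrix from [simulate_qpcr()] or a parsed qPCR table.
#' @param genes Genes to extract (rows).
#' @param control Internal-control gene per extracted gene: either a single
#'   id recycled for all, or a named vector (e.g. `U6` for miRNA, `GAPDH` or
#'   `18S` for mRNA/lncRNA).
#' @return Samples x genes matrix of `-dCt` values.
#' @export
dct_features <- function(ct, genes, control = "GAPDH") {
  if (length(control) == 1L) control <- stats::setNames(
    rep(control, length(genes)), genes)
  missing <- setdiff(c(genes, unique(control)), rownames(ct))
  if (length(missing))
    stop("genes absent from Ct table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vapply(genes, function(g) -(ct[g, ] - ct[control[[g]], ]),
                numeric(ncol(ct)))
  rownames(out) <- colnames(ct)
  out
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(labels, c("responder", "nonresponder"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    return(as.numeric(labels == "responder"))
  }
  if (!all(labels %in% c(0, 1)))
    stop("numeric labels must be 0/1", call. = FALSE)
  as.numeric(labels)
}

#' Fit a partial-least-squares response classifier
#'
#' PLS1 regression (NIPALS) of the 0/1 responder label on the axis RNA
#' features.  Features are centred and scaled using training statistics
#' only; the fitted model stores them for prediction.  The operating point
#' for classification is the training-score threshold maximising Youden's J
#' and is applied unchanged to test data.
#'
#' @param X Training matrix, samples x features.
#' @param labels Training labels (`responder`/`nonresponder`, factor, or
#'   0/1; responder = 1).
#' @param n_components Number of latent components (default 2); capped at
#'   `min(n_features, n_train - 1)` with a warning.
#' @return Object of class `"pls_model"`: weights `W`, loadings `P`,
#'   y-loadings `q`, regression coefficients `coef`, centering/scaling
#'   vectors, training scores and Youden threshold.
#' @export
fit_pls <- function(X, labels, n_components = 2L) {
  X <- as.matrix(X)
  y <- encode_labels(labels)
  if (nrow(X) != length(y)) stop("X rows must match labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  cap <- min(ncol(X), nrow(X) - 1L)
  if (n_components > cap) {
    warning("n_components capped at ", cap, call. = FALSE)
    n_components <- cap
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv <= 0))
    stop("constant feature in training data", call. = FALSE)
  E <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  my <- mean(y)
  f <- y - my

  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {           # residual orthogonal to y: stop early
      W <- W[, seq_len(h - 1L), drop = FALSE]
      P <- P[, seq_len(h - 1L), drop = FALSE]
      q <- q[seq_len(h - 1L)]
      n_components <- h - 1L
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(E, tt)) / tt2
    qh <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pl)
    f <- f - tt * qh
    W[, h] <- w; P[, h] <- pl; q[h] <- qh
  }
  coef <- W %*% solve(crossprod(P, W), q)
  model <- list(features = colnames(X), W = W, P = P, q = q,
                coef = drop(coef), center = mu, scale = sdv,
                y_mean = my, n_components = n_components)
  class(model) <- "pls_model"
  train_scores <- predict(model, X)
  model$train_scores <- train_scores
  model$threshold <- youden_threshold(train_scores, y)
  model
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop(Z %*% object$coef) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS response model: %d feature(s), %d component(s)\n",
              length(x$coef), x$n_components))
  invisible(x)
}

#' Training-score threshold maximising Youden's J
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 or responder/nonresponder labels.
#' @return Threshold value; samples with `score >= threshold` are called
#'   responders.
#' @export
youden_threshold <- function(scores, labels) {
  y <- encode_labels(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, 0)
  cand[which.max(j)]
}

#' Mann-Whitney AUC of a score vector
#'
#' The area under the ROC curve computed as the Mann-Whitney concordance
#' probability (ties counted one half).
#'
#' @param scores Numeric scores (higher = more responder-like).
#' @param labels 0/1 or responder/nonresponder labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- encode_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: a class is empty", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a response model on an independent cohort
#'
#' @param model Fitted [fit_pls()] model.
#' @param X_test Test matrix, samples x features (cohort disjoint from
#'   training).
#' @param labels_test Test labels; both classes must be present.
#' @param operating_point Score threshold for accuracy; defaults to the
#'   training-set Youden threshold stored in the model.
#' @return Object of class `"roc_result"`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc` (Mann-Whitney), `accuracy`, `operating_point` and
#'   the test `scores`.
#' @export
evaluate_response_model <- function(model, X_test, labels_test,
                                    operating_point = NULL) {
  y <- encode_labels(labels_test)
  if (length(unique(y)) < 2L)
    stop("AUC undefined: test cohort contains one class", call. = FALSE)
  scores <- predict(model, X_test)
  if (is.null(operating_point)) operating_point <- model$threshold
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / sum(y == 1), 0)
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / sum(y == 0), 0)
  pred <- scores >= operating_point
  out <- list(thresholds = thr, sensitivity = sens, specificity = spec,
              auc = auc_mw(scores, y),
              accuracy = mean(pred == (y == 1)),
              operating_point = operating_point, scores = scores)
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, accuracy = %.3f at threshold %.3f\n",
              x$auc, x$accuracy, x$operating_point))
  invisible(x)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Two-sided DeLong test of the AUC difference between a score panel and a
#' single marker measured on the same samples.
#'
#' @param scores_panel,scores_single Score vectors on identical samples.
#' @param labels Shared labels.
#' @return List with `p`, `auc_panel`, `auc_single`.
#' @export
compare_roc <- function(scores_panel, scores_single, labels) {
  if (length(scores_panel) != length(scores_single) ||
      length(scores_panel) != length(labels))
    stop("score and label vectors must have identical length",
         call. = FALSE)
  y <- encode_labels(labels)
  a1 <- auc_mw(scores_panel, y)
  a2 <- auc_mw(scores_single, y)
  if (isTRUE(all.equal(scores_panel, scores_single)))
    return(list(p = 1, auc_panel = a1, auc_single = a2))
  r1 <- pROC::roc(y, scores_panel, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  r2 <- pROC::roc(y, scores_single, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  list(p = as.numeric(tst$p.value), auc_panel = a1, auc_single = a2)
}

#' Responder labels from paired severity scores
#'
#' A subject is a responder when the severity score improved, i.e. the
#' difference `before - after` is strictly positive; a zero difference is a
#' nonresponder.
#'
#' @param score_before,score_after Paired severity scores (e.g. arthritis
#'   scores at treatment start and after treatment).
#' @return Character vector of `responder`/`nonresponder`.
#' @export
label_responders <- function(score_before, score_after) {
  if (length(score_before) != length(score_after))
    stop("paired score vectors differ in length", call. = FALSE)
  ifelse(score_before - score_after > 0, "responder", "nonresponder")
}
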