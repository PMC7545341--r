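#' @name diffexpr
#' @title Random-variance-model differential expression screen
#'
#' @description
#' Small-cohort differential expression between responders and nonresponders
#' using the random-variance-model (RVM) moderated t-test of Wright and
#' Simon: feature precisions are modelled as Gamma(a, b), so that scaled
#' sample variances follow `s^2 * a * b ~ F(m, 2a)` across features with `m`
#' residual degrees of freedom each.  The moderated variance
#' `(m * s^2 + 2/b) / (m + 2a)` is tested on `m + 2a` degrees of freedom,
#' borrowing strength across features.  Features are screened by fold change
#' and p-value, with optional Benjamini-Hochberg FDR control per RNA class.
NULL

check_design <- function(mat, design) {
  if (!all(c("sample", "group") %in% names(design)))
    stop("design must have columns 'sample' and 'group'", call. = FALSE)
  bad <- setdiff(design$group, c("responder", "nonresponder"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!setequal(colnames(mat), design$sample) ||
      anyDuplicated(design$sample) || ncol(mat) != nrow(design))
    stop("design samples must cover matrix columns exactly once",
         call. = FALSE)
  if (any(table(factor(design$group,
                       c("responder", "nonresponder"))) < 2L))
    stop("each group needs >= 2 samples", call. = FALSE)
  invisible(TRUE)
}

group_cols <- function(mat, design, group) {
  mat[, design$sample[design$group == group], drop = FALSE]
}

#' Linear fold change between responder and nonresponder group means
#'
#' Expression is log2-scale, so the linear fold change is
#' `2^(mean_responder - mean_nonresponder)`.
#'
#' @param mat Log2 expression matrix (features x samples).
#' @param design Design data frame (`sample`, `group`).
#' @param feature Feature id (row name); if `NULL`, all features.
#' @return Named numeric vector of linear fold changes (> 0).
#' @export
fold_change <- function(mat, design, feature = NULL) {
  check_design(mat, design)
  if (!is.null(feature)) {
    missing <- setdiff(feature, rownames(mat))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    mat <- mat[feature, , drop = FALSE]
  }
  m1 <- rowMeans(group_cols(mat, design, "responder"))
  m0 <- rowMeans(group_cols(mat, design, "nonresponder"))
  2^(m1 - m0)
}

rvm_loglik <- function(log_ab, s2, m) {
  a <- exp(log_ab[1]); b <- exp(log_ab[2])
  sum(log(a) + log(b) + stats::df(s2 * a * b, df1 = m, df2 = 2 * a,
                                  log = TRUE))
}

#' Fit the random-variance model to per-feature sample variances
#'
#' Maximum-likelihood fit of the gamma prior on feature precisions, under
#' which `s^2 * a * b ~ F(m, 2a)` across features.
#'
#' @param variances Per-feature sample variances (>= 10 finite positive
#'   values).
#' @param m Residual degrees of freedom per feature (`n1 + n2 - 2`).
#' @return Object of class `"rvm_params"`: list with `a`, `b`, `m`,
#'   `converged` and the maximised `loglik`.
#' @export
fit_rvm <- function(variances, m) {
  variances <- as.numeric(variances)
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("variances must be finite and positive", call. = FALSE)
  if (length(variances) < 10L)
    stop("need >= 10 variances to fit the random-variance model",
         call. = FALSE)
  if (m < 1L) stop("'m' must be >= 1", call. = FALSE)
  if (diff(range(variances)) < 1e-12 * max(variances))
    stop(paste("all variances are identical: the precision prior is",
               "degenerate (infinite shape); disable moderation and use",
               "the ordinary t-test instead"), call. = FALSE)
  init <- c(log(2), log(1 / mean(variances)))
  fit <- stats::optim(init, rvm_loglik, s2 = variances, m = m,
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-10))
  out <- list(a = exp(fit$par[1]), b = exp(fit$par[2]), m = m,
              converged = fit$convergence == 0L, loglik = fit$value)
  class(out) <- "rvm_params"
  out
}

#' @export
print.rvm_params <- function(x, ...) {
  cat(sprintf("RVM fit: a = %.4g, b = %.4g, m = %d, df_mod = %.2f (%s)\n",
              x$a, x$b, x$m, x$m + 2 * x$a,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Moderated variance under a fitted random-variance model
#'
#' @param s2 Sample variance(s).
#' @param params An [fit_rvm()] object (or list with `a`, `b`, `m`).
#' @return Moderated variance `(m * s2 + 2/b) / (m + 2a)`.
#' @export
rvm_moderated_var <- function(s2, params) {
  (params$m * s2 + 2 / params$b) / (params$m + 2 * params$a)
}

#' RVM moderated t-test per feature
#'
#' @param mat Log2 expression matrix (features x samples).
#' @param design Design data frame.
#' @param params Fitted [fit_rvm()] parameters; must match the design's
#'   residual degrees of freedom.
#' @return Data frame with `feature`, `mean_diff`
#'   (responder - nonresponder, log2), `s2` (pooled within-group variance),
#'   `t_mod`, `df_mod` and two-sided `p`.
#' @export
rvm_t_test <- function(mat, design, params) {
  check_design(mat, design)
  x1 <- group_cols(mat, design, "responder")
  x0 <- group_cols(mat, design, "nonresponder")
  n1 <- ncol(x1); n0 <- ncol(x0)
  m <- n1 + n0 - 2L
  if (params$m != m)
    stop("RVM parameters were fitted for m = ", params$m,
         " but the design has m = ", m, call. = FALSE)
  diff <- rowMeans(x1) - rowMeans(x0)
  ss <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x0 - rowMeans(x0))^2))
  s2 <- ss / m
  v_mod <- rvm_moderated_var(s2, params)
  df_mod <- m + 2 * params$a
  t_mod <- diff / sqrt(v_mod * (1 / n1 + 1 / n0))
  p <- 2 * stats::pt(-abs(t_mod), df = df_mod)
  data.frame(feature = rownames(mat), mean_diff = diff, s2 = s2,
             t_mod = t_mod, df_mod = df_mod, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjusted values `q_(i) = min_(j >= i) p_(j) * n / j`, monotone in
#' p-rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Differential expression screen across RNA classes
#'
#' Applies [fold_change()], the RVM moderated t-test and BH FDR control to
#' each RNA class separately (the classes are profiled on separate
#' platforms), and flags features passing the configured cutoffs:
#' `fc > fc_up` or `fc < fc_down`, `p < p_cut`, and — unless
#' `fdr_mode = "none"`, which disables FDR filtering — `q < fdr_q`.
#'
#' @param matrices Named list of log2 expression matrices (names used as RNA
#'   class labels, e.g. `lncRNA`, `miRNA`, `mRNA`).
#' @param design Shared design data frame.
#' @param fc_up,fc_down Fold-change cutoffs (defaults 1.2 and 0.83).
#' @param p_cut P-value cutoff (default 0.05).
#' @param fdr_mode `"q_lt"` (filter `q < fdr_q`) or `"none"` (no
#'   FDR filter, matching a screen whose stated FDR bound excludes nothing).
#' @param fdr_q FDR threshold used when `fdr_mode = "q_lt"`.
#' @return List with `table` (data frame: `feature`, `class`, `fc`, `t`,
#'   `df`, `p`, `q`, `direction`, `passes`) and `counts` (data frame of
#'   up/down passing counts per class).
#' @export
de_screen <- function(matrices, design, fc_up = 1.2, fc_down = 0.83,
                      p_cut = 0.05, fdr_mode = c("q_lt", "none"),
                      fdr_q = 0.05) {
  fdr_mode <- match.arg(fdr_mode)
  if (!is.list(matrices) || is.null(names(matrices)))
    stop("'matrices' must be a named list", call. = FALSE)
  if (!(fc_up > 0 && fc_down > 0 && fc_down <= fc_up))
    stop("invalid fold-change thresholds", call. = FALSE)
  if (p_cut <= 0 || p_cut > 1 || fdr_q <= 0 || fdr_q > 1)
    stop("p/FDR thresholds must lie in (0, 1]", call. = FALSE)

  res <- lapply(names(matrices), function(cls) {
    mat <- matrices[[cls]]
    check_design(mat, design)
    tt <- rvm_t_test(mat, design,
                     fit_rvm(apply_s2(mat, design),
                             m = nrow(design) - 2L))
    fc <- fold_change(mat, design)
    q <- bh_fdr(tt$p)
    passes <- (fc > fc_up | fc < fc_down) & tt$p < p_cut &
      (fdr_mode == "none" | q < fdr_q)
    data.frame(feature = tt$feature, class = cls, fc = unname(fc),
               t = tt$t_mod, df = tt$df_mod, p = tt$p, q = q,
               direction = ifelse(fc >= 1, "up", "down"),
               passes = passes, row.names = NULL, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, res)
  counts <- do.call(rbind, lapply(split(table, table$class), function(d) {
    data.frame(class = d$class[1],
               n_up = sum(d$passes & d$direction == "up"),
               n_down = sum(d$passes & d$direction == "down"),
               row.names = NULL)
  }))
  rownames(counts) <- NULL
  list(table = table, counts = counts)
}

# pooled within-group sample variances for RVM fitting
apply_s2 <- function(mat, design) {
  x1 <- group_cols(mat, design, "responder")
  x0 <- group_cols(mat, design, "nonresponder")
  (rowSums((x1 - rowMeans(x1))^2) + rowSums((x0 - rowMeans(x0))^2)) /
    (ncol(x1) + ncol(x0) - 2L)
}
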