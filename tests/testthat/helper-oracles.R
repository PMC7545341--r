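# Independent brute-force oracles used to cross-check the package's
# implementations.  These are deliberately written from the definitions,
# not by reusing package code paths.

oracle_bh <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(ps[i:n] * n / (i:n))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

oracle_degrees <- function(edges, ids) {
  vapply(ids, function(v) sum(edges$lnc == v) + sum(edges$mrna == v), 0L)
}

oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]; neg <- scores[y01 == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

rc1 <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# sliding-window scan testing each canonical site-class pattern separately;
# returns sites keyed by the 6mer-core locus, most specific class winning
oracle_seed_sites <- function(mir, tgt) {
  L <- nchar(tgt)
  find_all <- function(pat) {
    w <- nchar(pat)
    which(vapply(seq_len(L - w + 1L),
                 function(p) substr(tgt, p, p + w - 1L) == pat, TRUE))
  }
  p8 <- paste0(rc1(substr(mir, 2, 8)), "A")
  p7m8 <- rc1(substr(mir, 2, 8))
  p7a1 <- paste0(rc1(substr(mir, 2, 7)), "A")
  p6 <- rc1(substr(mir, 2, 7))
  hits <- list()
  add <- function(core_pos, cls, start, end) {
    key <- as.character(core_pos)
    rank <- match(cls, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
    if (is.null(hits[[key]]) || rank < hits[[key]]$rank)
      hits[[key]] <<- list(rank = rank, cls = cls, start = start, end = end)
    hits
  }
  for (p in find_all(p8)) hits <- add(p + 1L, "8mer", p - 1L, p + 7L)
  for (p in find_all(p7m8)) hits <- add(p + 1L, "7mer-m8", p - 1L, p + 6L)
  for (p in find_all(p7a1)) hits <- add(p, "7mer-A1", p - 1L, p + 6L)
  for (p in find_all(p6)) hits <- add(p, "6mer", p - 1L, p + 5L)
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      seed_class = character(0), stringsAsFactors = FALSE))
  df <- data.frame(
    start = vapply(hits, function(h) h$start, 0L),
    end = vapply(hits, function(h) h$end, 0L),
    seed_class = vapply(hits, function(h) h$cls, ""),
    stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# exhaustive local alignment by memoised recursion over alignment moves
oracle_local_align_score <- function(mir, win) {
  x <- strsplit(mir, "")[[1]]
  y <- rev(strsplit(win, "")[[1]])
  nx <- length(x); ny <- length(y)
  wt <- ifelse(seq_len(nx) >= 2 & seq_len(nx) <= 8, 2, 1)
  pscore <- function(i, j) {
    a <- x[i]; b <- y[j]
    s <- if (paste0(a, b) %in% c("AU", "UA", "CG", "GC")) 5
         else if (paste0(a, b) %in% c("GU", "UG")) 1 else -3
    s * wt[i]
  }
  memo <- new.env(hash = TRUE)
  # best score of any alignment continuation starting at (i, j) given the
  # previous move; alignment may stop anywhere (local)
  f <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0
    if (i <= nx && j <= ny)
      best <- max(best, pscore(i, j) + f(i + 1L, j + 1L, "m"))
    if (i <= nx)
      best <- max(best, (if (prev == "gx") -4 else -9) + f(i + 1L, j, "gx"))
    if (j <= ny)
      best <- max(best, (if (prev == "gy") -4 else -9) + f(i, j + 1L, "gy"))
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      best <- max(best, pscore(i, j) + f(i + 1L, j + 1L, "m"))
    }
  }
  best
}

# re-walk a pairing and sum energy-table entries
oracle_dG <- function(aln, tab) {
  m <- strsplit(aln$mir_aln, "")[[1]]
  t <- strsplit(aln$target_aln, "")[[1]]
  pr <- strsplit(aln$pairing, "")[[1]]
  paired <- pr != " " & m != "-" & t != "-"
  if (!any(paired)) return(tab$init)
  total <- tab$init
  in_run <- FALSE
  run_start <- NA_integer_
  last <- NA_integer_
  close_run <- function(a, b) {
    pen <- 0
    if (paste0(m[a], t[a]) %in% c("AU", "UA", "GU", "UG"))
      pen <- pen + tab$terminal_au
    if (b > a && paste0(m[b], t[b]) %in% c("AU", "UA", "GU", "UG"))
      pen <- pen + tab$terminal_au
    pen
  }
  for (k in seq_along(m)) {
    if (paired[k]) {
      if (in_run) {
        wob <- pr[last] == ":" || pr[k] == ":"
        total <- total + if (wob) tab$wobble_stack else
          tab$stacks[[paste0(m[last], m[k], "/", t[last], t[k])]]
      } else {
        in_run <- TRUE
        run_start <- k
      }
      last <- k
    } else if (in_run) {
      total <- total + close_run(run_start, last)
      in_run <- FALSE
    }
  }
  if (in_run) total <- total + close_run(run_start, last)
  total
}

random_network <- function(n_lnc, n_mrna, p_edge) {
  lnc <- sprintf("L%02d", seq_len(n_lnc))
  mrna <- sprintf("M%02d", seq_len(n_mrna))
  pairs <- expand.grid(lnc = lnc, mrna = mrna, stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  net <- list(group = "responder",
              nodes = data.frame(id = c(lnc, mrna),
                                 class = rep(c("lncRNA", "mRNA"),
                                             c(n_lnc, n_mrna)),
                                 stringsAsFactors = FALSE),
              edges = data.frame(lnc = pairs$lnc, mrna = pairs$mrna,
                                 r = runif(nrow(pairs), -1, 1),
                                 p = runif(nrow(pairs)),
                                 stringsAsFactors = FALSE))
  class(net) <- "coexpression_network"
  net
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small labelled design helper
toy_design <- function(n1 = 3, n0 = 3, prefix = "s") {
  data.frame(sample = paste0(prefix, seq_len(n1 + n0)),
             group = rep(c("responder", "nonresponder"), c(n1, n0)),
             stringsAsFactors = FALSE)
}

toy_matrix <- function(n_feat, design, sd = 1, mean = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_feat * nrow(design), mean, sd), nrow = n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              design$sample))
  m
}
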