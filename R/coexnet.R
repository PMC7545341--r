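#' Pearson correlation with t-transform p-value
#'
#' @param x,y Numeric sample vectors of equal length >= 3; constant vectors
#'   are rejected rather than silently yielding NaN.
#' @return List with `r` (in `[-1, 1]`) and two-sided `p` from the t
#'   transform on `n - 2` degrees of freedom.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = min(1, p))
}

#' Build a group-specific bipartite lncRNA-mRNA coexpression network
#'
#' An edge links a lncRNA and an mRNA when the absolute Pearson correlation
#' of their expression across that group's samples reaches the cutoff; the
#' signed correlation is stored on the edge.
#'
#' @param lnc_ids,mrna_ids Candidate feature ids (typically the
#'   differentially expressed sets).
#' @param lnc_mat,mrna_mat Log2 expression matrices containing those
#'   features.
#' @param design Design data frame.
#' @param group `"responder"` or `"nonresponder"`.
#' @param cutoff Edge threshold on `|r|`, in `(0, 1]` (default 0.99).
#' @return Object of class `"coexpression_network"`: list with `group`,
#'   `nodes` (data frame `id`, `class`) and `edges` (data frame `lnc`,
#'   `mrna`, `r`, `p`).
#' @export
build_network <- function(lnc_ids, mrna_ids, lnc_mat, mrna_mat, design,
                          group = c("responder", "nonresponder"),
                          cutoff = 0.99) {
  group <- match.arg(group)
  if (cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  missing_l <- setdiff(lnc_ids, rownames(lnc_mat))
  missing_g <- setdiff(mrna_ids, rownames(mrna_mat))
  if (length(missing_l) || length(missing_g))
    stop("features absent from matrix: ",
         paste(c(missing_l, missing_g), collapse = ", "), call. = FALSE)
  samples <- design$sample[design$group == group]
  if (length(samples) < 3L)
    stop("group '", group, "' has fewer than 3 samples", call. = FALSE)

  edges <- data.frame(lnc = character(0), mrna = character(0),
                      r = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lnc_ids) && length(mrna_ids)) {
    xl <- t(lnc_mat[lnc_ids, samples, drop = FALSE])
    xg <- t(mrna_mat[mrna_ids, samples, drop = FALSE])
    rmat <- suppressWarnings(stats::cor(xl, xg))
    rmat[!is.finite(rmat)] <- 0  # constant features form no edges
    hit <- which(abs(rmat) >= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      n <- length(samples)
      r <- rmat[hit]
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      edges <- data.frame(lnc = lnc_ids[hit[, 1]], mrna = mrna_ids[hit[, 2]],
                          r = r, p = pmin(1, 2 * stats::pt(-abs(tstat),
                                                           df = n - 2)),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$lnc, edges$mrna), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  out <- list(group = group,
              nodes = data.frame(
                id = c(lnc_ids, mrna_ids),
                class = rep(c("lncRNA", "mRNA"),
                            c(length(lnc_ids), length(mrna_ids))),
                stringsAsFactors = FALSE),
              edges = edges)
  class(out) <- "coexpression_network"
  out
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression network [%s]: %d lncRNA, %d mRNA, %d edges\n",
              x$group, sum(x$nodes$class == "lncRNA"),
              sum(x$nodes$class == "mRNA"), nrow(x$edges)))
  invisible(x)
}

network_degrees <- function(net) {
  deg <- stats::setNames(rep(0L, nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$lnc, net$edges$mrna))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Relative degree centrality
#'
#' The relative degree of a node is its degree divided by the largest degree
#' in the same network, so every non-empty network has at least one node with
#' relative degree 1.
#'
#' @param net A [build_network()] object.
#' @return Named numeric vector of relative degrees in `[0, 1]`.
#' @export
relative_degree <- function(net) {
  deg <- network_degrees(net)
  mx <- max(deg)
  if (mx == 0)
    stop("network has no edges: relative degree undefined", call. = FALSE)
  deg / mx
}

#' Cross-group differential centrality table
#'
#' Relative degrees are computed within each group's network; a node absent
#' from (or isolated in) one network has relative degree 0 there.  Nodes are
#' ranked within each RNA class by the absolute relative-degree difference.
#' Empty networks are tolerated (all relative degrees 0).
#'
#' @param net_resp,net_nonresp Responder and nonresponder networks built
#'   from the same candidate feature universe.
#' @return Data frame with `id`, `class`, `degree_resp`, `degree_nonresp`,
#'   `rd_resp`, `rd_nonresp`, `delta_rd` and within-class `rank`
#'   (descending `delta_rd`; ties share the smaller rank region
#'   deterministically by higher max degree, then id).
#' @export
differential_centrality <- function(net_resp, net_nonresp) {
  ids <- union(net_resp$nodes$id, net_nonresp$nodes$id)
  cls <- stats::setNames(
    c(net_resp$nodes$class, net_nonresp$nodes$class),
    c(net_resp$nodes$id, net_nonresp$nodes$id))[ids]
  rd_of <- function(net) {
    deg <- network_degrees(net)
    mx <- max(deg, 0)
    rd <- if (mx > 0) deg / mx else deg * 0
    full <- stats::setNames(rep(0, length(ids)), ids)
    full[names(rd)] <- rd
    full
  }
  deg_of <- function(net) {
    full <- stats::setNames(rep(0L, length(ids)), ids)
    d <- network_degrees(net)
    full[names(d)] <- d
    full
  }
  tab <- data.frame(id = ids, class = unname(cls),
                    degree_resp = unname(deg_of(net_resp)),
                    degree_nonresp = unname(deg_of(net_nonresp)),
                    rd_resp = unname(rd_of(net_resp)),
                    rd_nonresp = unname(rd_of(net_nonresp)),
                    stringsAsFactors = FALSE)
  tab$delta_rd <- abs(tab$rd_resp - tab$rd_nonresp)
  tab$max_degree <- pmax(tab$degree_resp, tab$degree_nonresp)
  ord <- order(tab$class, -tab$delta_rd, -tab$max_degree, tab$id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- stats::ave(seq_len(nrow(tab)), tab$class,
                         FUN = seq_along)
  rownames(tab) <- NULL
  tab
}

#' Core-node selection by differential centrality
#'
#' Picks the top `k` nodes of each RNA class by relative-degree difference;
#' ties are broken by higher maximum degree, then lexicographic id, so the
#' selection is deterministic.
#'
#' @param table A [differential_centrality()] table.
#' @param k Number of core nodes per class (default 5).
#' @return List with `lnc` and `mrna` character vectors of core ids; if a
#'   class has at most `k` members, all are returned with a warning.
#' @export
core_nodes <- function(table, k = 5L) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  pick <- function(cls) {
    d <- table[table$class == cls, , drop = FALSE]
    if (nrow(d) < k && nrow(d) > 0L)
      warning("class ", cls, " has only ", nrow(d),
              " nodes (< k = ", k, "); returning all", call. = FALSE)
    d$id[seq_len(min(k, nrow(d)))]  # table is already rank-ordered
  }
  list(lnc = pick("lncRNA"), mrna = pick("mRNA"))
}
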