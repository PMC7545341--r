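#' @name cerna_screen
#' @title Three-criterion ceRNA axis screen
#'
#' @description
#' Assembles candidate (lncRNA, miRNA, mRNA) axes from the retained target
#' sites and applies the selection criteria: (1) lncRNA and mRNA are
#' targeted by the same miRNA; (2) both are negatively correlated with that
#' miRNA; (3) the lncRNA site has both the higher alignment score and the
#' higher thermal stability (more negative duplex free energy) than the
#' mRNA site, i.e. the lncRNA out-competes the mRNA for the miRNA.  Axes
#' whose lncRNA and mRNA are both core nodes of the differential
#' coexpression analysis are nominated as biomarker candidates.
NULL

#' Candidate triples sharing a miRNA recognition element
#'
#' @param site_table Retained-site table from [predict_targets()] (both
#'   target classes combined).
#' @return Data frame of all `(lnc, mir, mrna)` triples in which the miRNA
#'   has a retained site on both the lncRNA and the mRNA.
#' @export
shared_mre_triples <- function(site_table) {
  empty <- data.frame(lnc = character(0), mir = character(0),
                      mrna = character(0), stringsAsFactors = FALSE)
  if (!nrow(site_table)) return(empty)
  lnc_hits <- site_table[site_table$target_class == "lncRNA", , drop = FALSE]
  mrna_hits <- site_table[site_table$target_class == "mRNA-3'UTR", ,
                          drop = FALSE]
  out <- lapply(intersect(lnc_hits$mirna, mrna_hits$mirna), function(m) {
    expand.grid(lnc = lnc_hits$target[lnc_hits$mirna == m],
                mir = m,
                mrna = mrna_hits$target[mrna_hits$mirna == m],
                stringsAsFactors = FALSE)
  })
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)[, c("lnc", "mir", "mrna")]
  out <- out[order(out$mir, out$lnc, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anticorrelation criterion for one candidate triple
#'
#' True when the miRNA is negatively correlated with both the lncRNA and the
#' mRNA at or beyond the cutoff (signed: `r <= -cutoff_neg`).
#'
#' @param expr Named list of expression matrices (`lncRNA`, `miRNA`,
#'   `mRNA`).
#' @param triple Named character vector or list with `lnc`, `mir`, `mrna`.
#' @param cutoff_neg Magnitude of the required negative correlation
#'   (default 0.99).
#' @param samples Optional sample ids over which to correlate (default: all
#'   shared columns).
#' @return List with `ok`, `r_mir_lnc`, `r_mir_mrna`, `r_lnc_mrna`.
#' @export
anticorrelation_criterion <- function(expr, triple, cutoff_neg = 0.99,
                                      samples = NULL) {
  if (is.null(samples)) samples <- colnames(expr$miRNA)
  v_lnc <- expr$lncRNA[triple[["lnc"]], samples]
  v_mir <- expr$miRNA[triple[["mir"]], samples]
  v_mrna <- expr$mRNA[triple[["mrna"]], samples]
  r_ml <- pearson_r(v_mir, v_lnc)$r
  r_mg <- pearson_r(v_mir, v_mrna)$r
  r_lg <- pearson_r(v_lnc, v_mrna)$r
  list(ok = (r_ml <= -cutoff_neg) && (r_mg <= -cutoff_neg),
       r_mir_lnc = r_ml, r_mir_mrna = r_mg, r_lnc_mrna = r_lg)
}

#' Sponge-competition criterion
#'
#' True when the lncRNA site strictly beats the mRNA site on both alignment
#' score and thermal stability (`S_lnc > S_mrna` and `dG_lnc < dG_mrna`);
#' ties fail.
#'
#' @param lnc_site,mrna_site One-row data frames (or lists) with `S` and
#'   `dG`.
#' @return Logical scalar.
#' @export
competition_criterion <- function(lnc_site, mrna_site) {
  vals <- c(lnc_site$S, lnc_site$dG, mrna_site$S, mrna_site$dG)
  if (length(vals) != 4L || any(!is.finite(vals)))
    stop("both sites must carry finite S and dG scores", call. = FALSE)
  (lnc_site$S > mrna_site$S) && (lnc_site$dG < mrna_site$dG)
}

#' Screen and rank candidate ceRNA axes
#'
#' Evaluates all shared-MRE triples against the anticorrelation and
#' competition criteria and nominates axes whose lncRNA and mRNA are both
#' core nodes.  The full audit table carries every criterion column.
#' Ranking: both-core first, then the summed relative-degree difference of
#' the lncRNA and mRNA (when a centrality table is supplied), then
#' `|r_mir_lnc| + |r_mir_mrna|`, ties broken lexicographically.
#'
#' @param site_table Combined retained-site table from [predict_targets()].
#' @param expr Named list of expression matrices.
#' @param core_lnc,core_mrna Core node ids from [core_nodes()].
#' @param anticorr_cutoff Negative-correlation cutoff (default 0.99; with
#'   realistic noise and cohort sizes a value near 0.7 is a more practical
#'   choice, see the package vignette).
#' @param samples Optional sample ids used for correlations.
#' @param centrality Optional [differential_centrality()] table used for
#'   ranking.
#' @param apply_filters If `FALSE`, criteria are computed but not used to
#'   filter (all triples are candidates); used for auditing.
#' @return List with `axes` (full audit table), `candidates` (criteria 1-3
#'   satisfied) and `nominated` (candidates with both members core).  Empty
#'   candidate sets yield empty tables with a warning, not an error.
#' @export
screen_axes <- function(site_table, expr, core_lnc = character(0),
                        core_mrna = character(0), anticorr_cutoff = 0.99,
                        samples = NULL, centrality = NULL,
                        apply_filters = TRUE) {
  triples <- shared_mre_triples(site_table)
  if (!nrow(triples)) {
    warning("no shared-MRE triples: empty candidate set", call. = FALSE)
    return(list(axes = triples, candidates = triples, nominated = triples))
  }
  site_of <- function(mir, target, cls) {
    site_table[site_table$mirna == mir & site_table$target == target &
                 site_table$target_class == cls, , drop = FALSE][1, ]
  }
  rows <- lapply(seq_len(nrow(triples)), function(i) {
    tr <- triples[i, ]
    ls <- site_of(tr$mir, tr$lnc, "lncRNA")
    gs <- site_of(tr$mir, tr$mrna, "mRNA-3'UTR")
    ac <- anticorrelation_criterion(expr, tr, anticorr_cutoff, samples)
    delta <- 0
    if (!is.null(centrality)) {
      dl <- centrality$delta_rd[match(tr$lnc, centrality$id)]
      dg <- centrality$delta_rd[match(tr$mrna, centrality$id)]
      delta <- sum(c(dl, dg), na.rm = TRUE)
    }
    data.frame(tr,
               r_mir_lnc = ac$r_mir_lnc, r_mir_mrna = ac$r_mir_mrna,
               r_lnc_mrna = ac$r_lnc_mrna,
               S_lnc = ls$S, dG_lnc = ls$dG, S_mrna = gs$S, dG_mrna = gs$dG,
               crit_shared = TRUE,
               crit_anticorr = ac$ok,
               crit_competition = competition_criterion(ls, gs),
               lnc_is_core = tr$lnc %in% core_lnc,
               mrna_is_core = tr$mrna %in% core_mrna,
               delta_rd_sum = delta,
               stringsAsFactors = FALSE)
  })
  axes <- do.call(rbind, rows)
  axes$rank_score <- with(axes, 2 * (lnc_is_core & mrna_is_core) +
                            delta_rd_sum / (max(delta_rd_sum, 1)) +
                            (abs(r_mir_lnc) + abs(r_mir_mrna)) / 1000)
  ord <- order(-(axes$lnc_is_core & axes$mrna_is_core), -axes$delta_rd_sum,
               -(abs(axes$r_mir_lnc) + abs(axes$r_mir_mrna)),
               axes$lnc, axes$mir, axes$mrna)
  axes <- axes[ord, , drop = FALSE]
  rownames(axes) <- NULL
  pass <- axes$crit_shared & axes$crit_anticorr & axes$crit_competition
  candidates <- if (apply_filters) axes[pass, , drop = FALSE] else axes
  nominated <- axes[pass & axes$lnc_is_core & axes$mrna_is_core, ,
                    drop = FALSE]
  # contract: every nominated axis satisfies the full conjunction
  stopifnot(all(nominated$crit_shared & nominated$crit_anticorr &
                  nominated$crit_competition))
  rownames(candidates) <- NULL
  rownames(nominated) <- NULL
  if (!nrow(candidates))
    warning("no axis passed criteria 1-3: empty candidate set",
            call. = FALSE)
  list(axes = axes, candidates = candidates, nominated = nominated)
}
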