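#' @name target_predict
#' @title In-package miRNA target prediction
#'
#' @description
#' Self-contained detectors reproducing the mechanisms of the two classic
#' prediction tools: canonical seed-class matching (8mer, 7mer-m8, 7mer-A1,
#' 6mer over miRNA positions 2-8) and a position-weighted complementarity
#' alignment with nearest-neighbour duplex free energy.  A (miRNA, target)
#' pair is retained only when a site is supported by both detectors.
NULL

normalize_rna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop("empty ", what, call. = FALSE)
  x <- chartr("Tt", "Uu", toupper(x))
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) && nzchar(bad))
    stop("non-nucleotide character '", bad, "' at position ",
         regexpr("[^ACGU]", x), " in ", what, call. = FALSE)
  x
}

WC_PAIRS <- c(A = "U", U = "A", C = "G", G = "C")

is_wc <- function(a, b) WC_PAIRS[a] == b
is_wobble <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

#' Nearest-neighbour RNA duplex energy parameters
#'
#' Watson-Crick stack free energies (ΔG°37, kcal/mol) follow the published
#' nearest-neighbour set for RNA; any stack involving a G:U wobble pair is
#' assigned a single conservative constant.  The duplex initiation term is
#' set to zero because the pipeline uses ΔG comparatively (lncRNA site vs
#' mRNA site for the same miRNA), and terminal AU/GU helix ends carry the
#' standard destabilisation penalty.  All stack terms are negative and the
#' table is symmetric under 180-degree rotation of the duplex.
#'
#' @return List with `stacks` (named vector keyed `XY/WZ`: top strand 5'-XY-3'
#'   over bottom strand 3'-WZ-5'), `wobble_stack`, `init` and `terminal_au`
#'   (kcal/mol).
#' @export
rna_energy_table <- function() {
  base <- c("AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
            "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
            "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26,
            "GC/CG" = -3.42)
  stacks <- base
  for (k in names(base)) {
    # 180-degree rotation: 5'XY3'/3'WZ5'  ==  5'ZW3'/3'YX5'
    x <- strsplit(k, "")[[1]]
    rot <- paste0(x[5], x[4], "/", x[2], x[1])
    stacks[rot] <- base[[k]]
  }
  list(stacks = stacks, wobble_stack = -1.0, init = 0.0, terminal_au = 0.45)
}

#' Canonical seed-match sites of a miRNA on a target sequence
#'
#' Scans the target (sense strand, 5'->3') for matches to the miRNA seed
#' (positions 2-7/2-8 from the miRNA 5' end) and classifies each site:
#' `8mer` (positions 2-8 Watson-Crick paired plus target A opposite miRNA
#' position 1), `7mer-m8` (positions 2-8), `7mer-A1` (positions 2-7 plus the
#' A), `6mer` (positions 2-7).  Overlapping evidence at one locus is
#' reported once, at the most specific class.
#'
#' @param mirna_seq Mature miRNA sequence (>= 8 nt; T accepted as U).
#' @param target_seq Target sequence (lncRNA transcript or mRNA 3'UTR).
#' @return Data frame with `start`, `end` (0-based half-open on the target)
#'   and `seed_class`; zero rows when no site exists.
#' @export
seed_sites <- function(mirna_seq, target_seq) {
  mir <- normalize_rna(mirna_seq, "miRNA sequence")
  tgt <- normalize_rna(target_seq, "target sequence")
  if (nchar(mir) < 8L) stop("miRNA must be >= 8 nt", call. = FALSE)
  core <- rna_revcomp(substr(mir, 2, 7))      # 6mer seed core on the target
  m8_base <- WC_PAIRS[[substr(mir, 8, 8)]]    # target base pairing miRNA p8
  hits <- gregexpr(paste0("(?=", core, ")"), tgt, perl = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      seed_class = character(0), stringsAsFactors = FALSE))
  out <- lapply(as.integer(hits), function(i) {
    # core occupies target positions i..i+5 (1-based); the base 5' of the
    # core pairs miRNA position 8, the base 3' of it sits opposite position 1
    has_m8 <- i >= 2L && substr(tgt, i - 1L, i - 1L) == m8_base
    has_a1 <- i + 6L <= nchar(tgt) && substr(tgt, i + 6L, i + 6L) == "A"
    if (has_m8 && has_a1) {
      c(i - 2L, i + 6L, "8mer")
    } else if (has_m8) {
      c(i - 2L, i + 5L, "7mer-m8")
    } else if (has_a1) {
      c(i - 1L, i + 6L, "7mer-A1")
    } else {
      c(i - 1L, i + 5L, "6mer")
    }
  })
  data.frame(start = as.integer(vapply(out, `[`, "", 1)),
             end = as.integer(vapply(out, `[`, "", 2)),
             seed_class = vapply(out, `[`, "", 3),
             stringsAsFactors = FALSE)
}

pair_symbol <- function(a, b) {
  ifelse(is_wc(a, b), "|", ifelse(is_wobble(a, b), ":", " "))
}

#' Position-weighted complementarity alignment of a miRNA to a target window
#'
#' Local (Smith-Waterman) alignment with affine gaps of the miRNA (5'->3')
#' against the reversed target window, i.e. antiparallel hybridisation
#' geometry.  Complementary pairs score +5 (Watson-Crick) or +1 (G:U
#' wobble), mismatches -3; gap open -9, gap extend -4; scores at miRNA seed
#' positions 2-8 are doubled.
#'
#' @param mirna_seq Mature miRNA sequence.
#' @param target_window Target subsequence of length 6-40 nt.
#' @return List with `score` (optimal local score S >= 0), `mir_aln`
#'   (aligned miRNA, 5'->3'), `target_aln` (aligned target, 3'->5'),
#'   `pairing` (string of `|` Watson-Crick, `:` wobble, space otherwise) and
#'   `window_range` (1-based first/last window position covered).
#' @export
duplex_align <- function(mirna_seq, target_window) {
  mir <- normalize_rna(mirna_seq, "miRNA sequence")
  win <- normalize_rna(target_window, "target window")
  if (nchar(win) < 6L || nchar(win) > 40L)
    stop("target window must be 6-40 nt", call. = FALSE)
  x <- strsplit(mir, "")[[1]]
  y <- rev(strsplit(win, "")[[1]])  # window read 3'->5'
  nx <- length(x); ny <- length(y)
  GAP_OPEN <- -9; GAP_EXT <- -4; MATCH <- 5; WOBBLE <- 1; MISMATCH <- -3
  wt <- ifelse(seq_len(nx) >= 2 & seq_len(nx) <= 8, 2, 1)

  NEG <- -1e9
  M <- matrix(NEG, nx + 1, ny + 1)   # x[i] paired with y[j]
  Ix <- matrix(NEG, nx + 1, ny + 1)  # gap in target (x advances)
  Iy <- matrix(NEG, nx + 1, ny + 1)  # gap in miRNA (y advances)
  tb <- array(0L, dim = c(nx + 1, ny + 1, 3))  # traceback: prev state (0=start)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      s <- if (is_wc(x[i], y[j])) MATCH
           else if (is_wobble(x[i], y[j])) WOBBLE else MISMATCH
      s <- s * wt[i]
      prev <- c(M[i, j], Ix[i, j], Iy[i, j], 0)
      k <- which.max(prev)
      M[i + 1, j + 1] <- prev[k] + s
      tb[i + 1, j + 1, 1] <- if (k == 4L) 0L else k
      ox <- c(M[i, j + 1] + GAP_OPEN, Ix[i, j + 1] + GAP_EXT)
      kx <- which.max(ox)
      Ix[i + 1, j + 1] <- ox[kx]
      tb[i + 1, j + 1, 2] <- kx          # 1 from M, 2 from Ix
      oy <- c(M[i + 1, j] + GAP_OPEN, Iy[i + 1, j] + GAP_EXT)
      ky <- which.max(oy)
      Iy[i + 1, j + 1] <- oy[ky]
      tb[i + 1, j + 1, 3] <- ky          # 1 from M, 3 from Iy
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }

  mir_aln <- character(0); tgt_aln <- character(0)
  if (best > 0) {
    i <- bi + 1L; j <- bj + 1L; state <- 1L
    repeat {
      if (state == 1L) {
        mir_aln <- c(x[i - 1L], mir_aln)
        tgt_aln <- c(y[j - 1L], tgt_aln)
        nxt <- tb[i, j, 1]
        i <- i - 1L; j <- j - 1L
        if (nxt == 0L) break
        state <- nxt
      } else if (state == 2L) {
        mir_aln <- c(x[i - 1L], mir_aln)
        tgt_aln <- c("-", tgt_aln)
        nxt <- tb[i, j, 2]
        i <- i - 1L
        state <- if (nxt == 1L) 1L else 2L
      } else {
        mir_aln <- c("-", mir_aln)
        tgt_aln <- c(y[j - 1L], tgt_aln)
        nxt <- tb[i, j, 3]
        j <- j - 1L
        state <- if (nxt == 1L) 1L else 3L
      }
    }
  }
  pairing <- vapply(seq_along(mir_aln), function(k) {
    if (mir_aln[k] == "-" || tgt_aln[k] == "-") " "
    else pair_symbol(mir_aln[k], tgt_aln[k])
  }, "")
  # y index j corresponds to window position ny - j + 1
  wr <- if (best > 0) c(ny - bj + 1L, NA_integer_) else c(NA_integer_,
                                                          NA_integer_)
  if (best > 0) {
    used_j <- sum(tgt_aln != "-")
    wr[2] <- wr[1] + used_j - 1L
  }
  list(score = max(0, best),
       mir_aln = paste(mir_aln, collapse = ""),
       target_aln = paste(tgt_aln, collapse = ""),
       pairing = paste(pairing, collapse = ""),
       window_range = wr)
}

#' Nearest-neighbour free energy of an aligned miRNA:target duplex
#'
#' Sums stack free energies over runs of consecutive paired alignment
#' columns, adds the duplex initiation term and a terminal penalty for each
#' helix end closed by an AU or GU pair.  Interior loops and bulges
#' contribute no stacks (conservative simplification).
#'
#' @param alignment Result of [duplex_align()] (or a list with `mir_aln`,
#'   `target_aln`, `pairing`).
#' @param table Energy parameters from [rna_energy_table()].
#' @return Duplex free energy ΔG°37 in kcal/mol (more negative = more
#'   stable).
#' @export
duplex_dG <- function(alignment, table = rna_energy_table()) {
  m <- strsplit(alignment$mir_aln, "")[[1]]
  t <- strsplit(alignment$target_aln, "")[[1]]
  pr <- strsplit(alignment$pairing, "")[[1]]
  if (length(m) != length(t) || length(m) != length(pr))
    stop("alignment strings have mismatched lengths", call. = FALSE)
  paired <- pr %in% c("|", ":")
  if (!any(paired)) return(table$init)
  dg <- table$init
  runs <- rle(paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  term_pair <- function(k) {
    p <- paste0(m[k], t[k])
    p %in% c("AU", "UA", "GU", "UG")
  }
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    if (b > a) {
      for (k in a:(b - 1L)) {
        if (pr[k] == ":" || pr[k + 1L] == ":") {
          dg <- dg + table$wobble_stack
        } else {
          dg <- dg + table$stacks[[paste0(m[k], m[k + 1L], "/",
                                          t[k], t[k + 1L])]]
        }
      }
    }
    if (term_pair(a)) dg <- dg + table$terminal_au
    if (b > a && term_pair(b)) dg <- dg + table$terminal_au
  }
  dg
}

#' Predict retained miRNA-target pairs by seed and alignment evidence
#'
#' For every (miRNA, target) pair, seed sites are enumerated; each site is
#' then re-scored by local duplex alignment over a window extending 5' of
#' the site on the target (where the miRNA 3' end pairs) and by
#' nearest-neighbour free energy.  A pair is retained when at least one site
#' is supported by both detectors (`S >= s_min` and `dG <= dg_max`); the
#' best such site per pair is reported (max `S`, ties by min `dG`, then
#' leftmost).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param target_class `"lncRNA"` (full transcript searched) or
#'   `"mRNA-3'UTR"` (the supplied sequence is the 3'UTR).
#' @param s_min Minimum alignment score (default 60, the weighted score of a
#'   bare 6mer seed pairing).
#' @param dg_max Maximum (least negative) duplex free energy in kcal/mol
#'   (default -7).
#' @param energy Energy table, see [rna_energy_table()].
#' @return Data frame of retained sites: `mirna`, `target`, `target_class`,
#'   `start`, `end`, `seed_class`, `S`, `dG`, `detected_by`.
#' @export
predict_targets <- function(mirnas, targets,
                            target_class = c("lncRNA", "mRNA-3'UTR"),
                            s_min = 60, dg_max = -7,
                            energy = rna_energy_table()) {
  target_class <- match.arg(target_class)
  if (length(mirnas) == 0L || length(targets) == 0L)
    stop("empty sequence set", call. = FALSE)
  if (is.null(names(mirnas)) || is.null(names(targets)))
    stop("sequences must be named", call. = FALSE)
  rows <- list()
  for (mn in names(mirnas)) {
    mir <- mirnas[[mn]]
    for (tn in names(targets)) {
      tgt <- normalize_rna(targets[[tn]], "target sequence")
      sites <- seed_sites(mir, tgt)
      if (!nrow(sites)) next
      scored <- lapply(seq_len(nrow(sites)), function(si) {
        end1 <- sites$end[si]                       # 0-based end == 1-based last
        ws <- max(1L, end1 - 39L)
        aln <- duplex_align(mir, substr(tgt, ws, end1))
        c(S = aln$score, dG = duplex_dG(aln, energy))
      })
      S <- vapply(scored, `[[`, 0, "S")
      dG <- vapply(scored, `[[`, 0, "dG")
      ok <- S >= s_min & dG <= dg_max
      if (!any(ok)) next
      cand <- which(ok)
      cand <- cand[order(-S[cand], dG[cand], sites$start[cand])]
      bi <- cand[1]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mn, target = tn, target_class = target_class,
        start = sites$start[bi], end = sites$end[bi],
        seed_class = sites$seed_class[bi], S = S[bi], dG = dG[bi],
        detected_by = "seed+alignment", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna = character(0), target = character(0),
                      target_class = character(0), start = integer(0),
                      end = integer(0), seed_class = character(0),
                      S = numeric(0), dG = numeric(0),
                      detected_by = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
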