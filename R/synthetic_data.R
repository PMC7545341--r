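#' Configuration for synthetic responder/nonresponder cohorts
#'
#' Builds the parameter set for [simulate_cohort()], [simulate_sequences()]
#' and [simulate_qpcr()].  Defaults mirror a small-cohort transcriptomic
#' biomarker study: a 3 + 3 discovery cohort profiled on three RNA classes
#' (lncRNA, miRNA, mRNA) and a 27 + 18 validation cohort, with one planted
#' ceRNA axis in which the miRNA is up-regulated and the lncRNA and mRNA are
#' down-regulated in responders.
#'
#' @param n_responders,n_nonresponders Discovery-cohort group sizes.
#' @param n_val_responders,n_val_nonresponders Validation-cohort group sizes.
#' @param n_lnc,n_mir,n_mrna Number of features per RNA class.
#' @param n_planted_axes Number of planted (lncRNA, miRNA, mRNA) axes.  Axis
#'   `k` links the k-th feature of each class.
#' @param axis_effect Standardised mean difference (Cohen's d, unitless)
#'   between responders and nonresponders for each axis member: positive on
#'   the miRNA, negative on the lncRNA and mRNA.
#' @param axis_corr Loading magnitude in `[0, 1]` of the shared per-sample
#'   latent factor: `+axis_corr` on the lncRNA and mRNA, `-axis_corr` on the
#'   miRNA.
#' @param noise_sd Residual standard deviation on the log2 scale.  The
#'   default 0.1 emulates the high-precision strong-signal regime in which
#'   near-unity coexpression cutoffs are meaningful.
#' @param seq_len_mir Mature miRNA length in nt (default 22).
#' @param seq_len_target Length of simulated lncRNA transcripts and mRNA
#'   3'UTRs in nt.
#' @param qpcr_noise_sd Standard deviation of Ct measurement noise (cycles).
#' @param rng_seed Integer seed; with a fixed seed all generator outputs are
#'   bit-identical across runs.
#'
#' @return An object of class `"synth_config"` (a validated list).
#' @export
synth_config <- function(n_responders = 3L, n_nonresponders = 3L,
                         n_val_responders = 27L, n_val_nonresponders = 18L,
                         n_lnc = 50L, n_mir = 20L, n_mrna = 100L,
                         n_planted_axes = 1L,
                         axis_effect = 2, axis_corr = 0.9, noise_sd = 0.1,
                         seq_len_mir = 22L, seq_len_target = 300L,
                         qpcr_noise_sd = 0.05, rng_seed = 1L) {
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              n_val_responders = as.integer(n_val_responders),
              n_val_nonresponders = as.integer(n_val_nonresponders),
              n_lnc = as.integer(n_lnc), n_mir = as.integer(n_mir),
              n_mrna = as.integer(n_mrna),
              n_planted_axes = as.integer(n_planted_axes),
              axis_effect = as.numeric(axis_effect),
              axis_corr = as.numeric(axis_corr),
              noise_sd = as.numeric(noise_sd),
              seq_len_mir = as.integer(seq_len_mir),
              seq_len_target = as.integer(seq_len_target),
              qpcr_noise_sd = as.numeric(qpcr_noise_sd),
              rng_seed = as.integer(rng_seed))
  counts <- c("n_responders", "n_nonresponders", "n_val_responders",
              "n_val_nonresponders", "n_lnc", "n_mir", "n_mrna",
              "seq_len_mir", "seq_len_target")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be a positive count", call. = FALSE)
  }
  if (cfg$n_planted_axes < 0L)
    stop("'n_planted_axes' must be >= 0", call. = FALSE)
  if (cfg$n_planted_axes > min(cfg$n_lnc, cfg$n_mir, cfg$n_mrna))
    stop("'n_planted_axes' exceeds a feature-class size", call. = FALSE)
  if (cfg$axis_corr < 0 || cfg$axis_corr > 1)
    stop("'axis_corr' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(cfg$axis_effect))
    stop("'axis_effect' must be finite", call. = FALSE)
  if (cfg$noise_sd <= 0)
    stop("'noise_sd' must be > 0", call. = FALSE)
  if (cfg$qpcr_noise_sd < 0)
    stop("'qpcr_noise_sd' must be >= 0", call. = FALSE)
  if (cfg$seq_len_mir < 8L)
    stop("'seq_len_mir' must be >= 8", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

feature_ids <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))

synth_design <- function(config) {
  data.frame(
    sample = c(sprintf("D_R%02d", seq_len(config$n_responders)),
               sprintf("D_N%02d", seq_len(config$n_nonresponders)),
               sprintf("V_R%02d", seq_len(config$n_val_responders)),
               sprintf("V_N%02d", seq_len(config$n_val_nonresponders))),
    group = c(rep("responder", config$n_responders),
              rep("nonresponder", config$n_nonresponders),
              rep("responder", config$n_val_responders),
              rep("nonresponder", config$n_val_nonresponders)),
    cohort = c(rep("discovery", config$n_responders + config$n_nonresponders),
               rep("validation",
                   config$n_val_responders + config$n_val_nonresponders)),
    stringsAsFactors = FALSE)
}

#' Simulate a responder/nonresponder expression cohort with planted axes
#'
#' Generates log2-scale feature-by-sample matrices for three RNA classes over
#' a discovery and a validation cohort.  For each planted axis a shared
#' per-sample latent factor loads `+axis_corr` on the lncRNA and mRNA and
#' `-axis_corr` on the miRNA, inducing the sponge correlation pattern, and
#' responders receive a group shift of `+d` total-SD units on the miRNA and
#' `-d` on the lncRNA and mRNA (`d = axis_effect`).  All remaining (decoy)
#' features are independent Gaussian noise.
#'
#' @param config A [synth_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{expr}{named list of numeric matrices `lncRNA`, `miRNA`, `mRNA`
#'       (features x samples, log2 scale).}
#'     \item{design}{data frame with columns `sample`, `group`
#'       (`responder`/`nonresponder`), `cohort` (`discovery`/`validation`).}
#'     \item{truth}{ground truth: `planted_axes` (data frame of lnc/mir/mrna
#'       ids), `true_group_effects` (signed responder-minus-nonresponder log2
#'       difference per planted feature) and an empty
#'       `planted_site_positions` slot filled by [simulate_sequences()].}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  design <- synth_design(config)
  n_samp <- nrow(design)
  resp <- design$group == "responder"

  ids <- list(lncRNA = feature_ids("lnc", config$n_lnc),
              miRNA = feature_ids("mir", config$n_mir),
              mRNA = feature_ids("mrna", config$n_mrna))
  k <- config$n_planted_axes
  axes <- data.frame(lnc = ids$lncRNA[seq_len(k)],
                     mir = ids$miRNA[seq_len(k)],
                     mrna = ids$mRNA[seq_len(k)],
                     stringsAsFactors = FALSE)

  # total SD of a planted member; the group shift is calibrated so that the
  # standardised difference equals axis_effect
  sd_tot <- sqrt(config$axis_corr^2 + config$noise_sd^2)
  delta <- config$axis_effect * sd_tot
  shift <- ifelse(resp, delta / 2, -delta / 2)

  latent <- matrix(stats::rnorm(k * n_samp), nrow = k)  # one factor per axis

  make_class <- function(class, loading_sign, shift_sign) {
    n_feat <- length(ids[[class]])
    base <- stats::rnorm(n_feat, mean = 8, sd = 1.5)
    m <- matrix(stats::rnorm(n_feat * n_samp, sd = config$noise_sd),
                nrow = n_feat, dimnames = list(ids[[class]], design$sample))
    m <- m + base
    if (k > 0L) {
      for (a in seq_len(k)) {
        m[a, ] <- m[a, ] + loading_sign * config$axis_corr * latent[a, ] +
          shift_sign * shift
      }
    }
    m
  }

  expr <- list(lncRNA = make_class("lncRNA", +1, -1),
               miRNA = make_class("miRNA", -1, +1),
               mRNA = make_class("mRNA", +1, -1))

  effects <- numeric(0)
  if (k > 0L) {
    effects <- c(stats::setNames(rep(-delta, k), axes$lnc),
                 stats::setNames(rep(+delta, k), axes$mir),
                 stats::setNames(rep(-delta, k), axes$mrna))
  }
  truth <- list(planted_axes = axes,
                true_group_effects = effects,
                planted_site_positions = list())
  list(expr = expr, design = design, truth = truth)
}

RNA_ALPHABET <- c("A", "C", "G", "U")

random_rna <- function(n) paste(sample(RNA_ALPHABET, n, replace = TRUE),
                                collapse = "")

#' Reverse complement of an RNA string
#' @param x RNA sequence (character scalar over A/C/G/U; T accepted).
#' @return Reverse-complemented RNA string.
#' @export
rna_revcomp <- function(x) {
  x <- chartr("Tt", "Uu", x)
  comp <- chartr("ACGUacgu", "UGCAugca", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Simulate miRNA, lncRNA and 3'UTR sequences with planted binding sites
#'
#' Every miRNA is a uniformly random 22-nt RNA.  For each planted axis the
#' mRNA 3'UTR receives a canonical 8mer seed site (reverse complement of
#' miRNA positions 2-8 followed by an A), while the lncRNA receives an
#' extended, near-fully complementary site (reverse complement of miRNA
#' positions 2-22 followed by an A).  The asymmetry encodes the ceRNA sponge
#' premise that the lncRNA out-competes the mRNA for the shared miRNA: its
#' site always carries the higher alignment score and the more negative
#' duplex free energy.  Decoy targets are rejection-sampled until they
#' contain no 6mer seed match (reverse complement of miRNA positions 2-7) to
#' any planted miRNA.
#'
#' @param config A [synth_config()] object.
#' @param truth Ground-truth list from [simulate_cohort()].
#' @return A list with named character vectors `mirna`, `lncrna`, `utr3` and
#'   an updated `truth` whose `planted_site_positions` maps each planted
#'   target id to a one-row matrix of 0-based half-open `(start, end)` site
#'   coordinates.
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed + 1L)
  ids_lnc <- feature_ids("lnc", config$n_lnc)
  ids_mir <- feature_ids("mir", config$n_mir)
  ids_mrna <- feature_ids("mrna", config$n_mrna)
  axes <- truth$planted_axes

  mirna <- stats::setNames(
    vapply(ids_mir, function(i) random_rna(config$seq_len_mir), ""), ids_mir)

  planted_mirs <- mirna[axes$mir]
  cores6 <- vapply(planted_mirs, function(m) rna_revcomp(substr(m, 2, 7)), "")

  clean_decoy <- function(len) {
    # rejection-sample: no >=6mer seed-core match to any planted miRNA
    repeat {
      s <- random_rna(len)
      if (length(cores6) == 0L || !any(vapply(
        cores6, function(cc) grepl(cc, s, fixed = TRUE), logical(1))))
        return(s)
    }
  }

  plant_site <- function(mir_seq, len, full) {
    site <- if (full) {
      paste0(rna_revcomp(substr(mir_seq, 2, nchar(mir_seq))), "A")
    } else {
      paste0(rna_revcomp(substr(mir_seq, 2, 8)), "A")
    }
    w <- nchar(site)
    if (len < w + 2L)
      stop("target length too short to host a planted site", call. = FALSE)
    # keep one nt of flank on each side so the site never abuts an end
    start <- sample(seq.int(2L, len - w), 1L)       # 1-based insert position
    flank5 <- clean_decoy(start - 1L)
    flank3 <- clean_decoy(len - w - (start - 1L))
    list(seq = paste0(flank5, site, flank3),
         coords = c(start = start - 1L, end = start - 1L + w))  # 0-based
  }

  lncrna <- character(config$n_lnc); names(lncrna) <- ids_lnc
  utr3 <- character(config$n_mrna); names(utr3) <- ids_mrna
  sites <- list()

  for (j in seq_along(ids_lnc)) {
    a <- if (nrow(axes)) match(ids_lnc[j], axes$lnc) else NA_integer_
    if (!is.na(a)) {
      ps <- plant_site(mirna[[axes$mir[a]]], config$seq_len_target, TRUE)
      lncrna[j] <- ps$seq
      sites[[ids_lnc[j]]] <- matrix(ps$coords, nrow = 1,
                                    dimnames = list(NULL, c("start", "end")))
    } else {
      lncrna[j] <- clean_decoy(config$seq_len_target)
    }
  }
  for (j in seq_along(ids_mrna)) {
    a <- if (nrow(axes)) match(ids_mrna[j], axes$mrna) else NA_integer_
    if (!is.na(a)) {
      ps <- plant_site(mirna[[axes$mir[a]]], config$seq_len_target, FALSE)
      utr3[j] <- ps$seq
      sites[[ids_mrna[j]]] <- matrix(ps$coords, nrow = 1,
                                     dimnames = list(NULL, c("start", "end")))
    } else {
      utr3[j] <- clean_decoy(config$seq_len_target)
    }
  }

  truth$planted_site_positions <- sites
  list(mirna = mirna, lncrna = lncrna, utr3 = utr3, truth = truth)
}

#' Simulate qPCR Ct tables for the planted axis RNAs
#'
#' Generates a genes-by-samples cycle-threshold table for all planted-axis
#' RNAs plus the internal-control genes `GAPDH`, `18S` and `U6`.  Each gene's
#' Ct follows `Ct = baseline - log2(expression) + noise`; since the cohort
#' matrices are already log2-scale, `Ct = 35 - expr + noise`.  Control genes
#' have group-independent means (GAPDH 18, 18S 10, U6 20 cycles).
#'
#' @param config A [synth_config()] object.
#' @param cohort Result of [simulate_cohort()].
#' @return Numeric matrix (genes x samples) of Ct values.
#' @export
simulate_qpcr <- function(config, cohort) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed + 2L)
  axes <- cohort$truth$planted_axes
  genes <- unique(c(axes$lnc, axes$mir, axes$mrna))
  samples <- cohort$design$sample
  class_of <- function(g) {
    if (g %in% rownames(cohort$expr$lncRNA)) "lncRNA"
    else if (g %in% rownames(cohort$expr$miRNA)) "miRNA"
    else "mRNA"
  }
  ct <- matrix(NA_real_, nrow = length(genes) + 3L, ncol = length(samples),
               dimnames = list(c(genes, "GAPDH", "18S", "U6"), samples))
  for (g in genes) {
    expr <- cohort$expr[[class_of(g)]][g, samples]
    ct[g, ] <- 35 - expr +
      stats::rnorm(length(samples), sd = config$qpcr_noise_sd)
  }
  ctrl_mean <- c(GAPDH = 18, `18S` = 10, U6 = 20)
  for (g in names(ctrl_mean)) {
    ct[g, ] <- ctrl_mean[[g]] +
      stats::rnorm(length(samples), sd = config$qpcr_noise_sd)
  }
  ct
}
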