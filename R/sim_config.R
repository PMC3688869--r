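#' Configuration for the synthetic miRNA-seq cohort generator
#'
#' Bundles every tunable of the generator into a validated list. The defaults
#' describe a colorectal-tumour-like small RNA cohort: a top-heavy mature-miRNA
#' expression profile in which the five most abundant miRNAs carry about 54% of
#' all miRNA reads, read lengths concentrated in the 19-23 nt window typical of
#' Dicer products (97.9% of reads), and per-sample RNA-class proportions with a
#' median of roughly 61% mature miRNA, 33% intronic/intergenic, 4% precursor
#' hairpin and 2% snoRNA.
#'
#' @param n_mirnas Number of mature miRNA loci to simulate.
#' @param n_clusters Number of miRNA gene clusters: pairs of mature miRNAs
#'   placed fewer than 10,000 nt apart, mimicking polycistronic miRNA genes.
#' @param n_samples Number of tumour samples in the cohort.
#' @param reads_per_sample Mean sequencing depth per sample (reads are drawn
#'   Poisson around this mean).
#' @param length_weights Probability weights over read lengths 13-29 nt
#'   (named numeric of length 17). The default peaks at 22 nt.
#' @param frac_core_length Target fraction of reads with length in 19-23 nt.
#'   The `length_weights` are rescaled so the 19-23 nt window carries exactly
#'   this mass in expectation.
#' @param class_props Expected proportions of reads per RNA class, a named
#'   vector over `mature`, `premature`, `snoRNA`, `intergenic`. Must sum to 1.
#' @param class_concentration Dirichlet concentration controlling how much the
#'   per-sample class proportions scatter around `class_props`. The default of
#'   40 spreads the per-sample mature fraction over roughly 0.4-0.8, matching
#'   the 37-77% range seen in real tumour libraries.
#' @param top5_share Target expected share of miRNA reads carried by the five
#'   most expressed miRNAs. The Zipf exponent of the expression law is solved
#'   numerically from this single number.
#' @param multimap_frac Fraction of miRNA reads that align to more than one
#'   mature miRNA (paralogous loci sharing an identical subsequence).
#' @param n_paralog_groups Number of paralog groups (each of 2-4 mature miRNAs
#'   with identical mature subsequences) used to generate multi-mapped reads.
#' @param mismatch_rate Per-read probability that the alignment carries one
#'   mismatch (sequencing error); all other alignments are perfect.
#' @param highmulti_frac Fraction of intergenic reads that map to 10 or more
#'   repetitive loci and should therefore be discarded by the quantifier.
#' @param planted_expression `data.frame(mirna, covariate, level, fold_change)`
#'   or `NULL`. Each row multiplies the expected expression of `mirna` by
#'   `fold_change` in samples whose clinical `covariate` equals `level`.
#' @param planted_survival `data.frame(mirna, endpoint, log_hr)` or `NULL`.
#'   Each row contributes `log_hr` per standard deviation of the miRNA's log2
#'   expected expression to the linear predictor of the named endpoint
#'   (`"os"` overall survival or `"mfs"` metastasis-free survival).
#' @param event_rate Target fraction of uncensored observations per endpoint;
#'   censoring is independent uniform, calibrated in closed form.
#' @param median_survival_days Baseline median survival time in days.
#' @param genome_length Optional total genome length in nt. `NULL` (default)
#'   sizes the genome to fit all features; a value too small to place them
#'   raises an error.
#' @param seed Integer master seed; all randomness flows from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 4, reads_per_sample = 1000)
#' cfg$top5_share
sim_config <- function(n_mirnas = 300,
                       n_clusters = 3,
                       n_samples = 88,
                       reads_per_sample = 20000,
                       length_weights = NULL,
                       frac_core_length = 0.979,
                       class_props = c(mature = 0.61, premature = 0.04,
                                       snoRNA = 0.02, intergenic = 0.33),
                       class_concentration = 40,
                       top5_share = 0.537,
                       multimap_frac = 0.10,
                       n_paralog_groups = 10,
                       mismatch_rate = 0.05,
                       highmulti_frac = 0.02,
                       planted_expression = NULL,
                       planted_survival = NULL,
                       event_rate = 0.5,
                       median_survival_days = 1095,
                       genome_length = NULL,
                       seed = 1L) {
  if (is.null(length_weights)) {
    length_weights <- default_length_weights()
  }
  stopifnot(length(length_weights) == 17L)
  names(length_weights) <- as.character(13:29)

  counts <- c(n_mirnas = n_mirnas, n_clusters = n_clusters,
              n_samples = n_samples, reads_per_sample = reads_per_sample,
              n_paralog_groups = n_paralog_groups)
  if (any(counts <= 0) || any(counts != floor(counts) & names(counts) != "reads_per_sample"))
    stop("all counts in sim_config must be positive")
  fracs <- c(frac_core_length = frac_core_length, top5_share = top5_share,
             multimap_frac = multimap_frac, mismatch_rate = mismatch_rate,
             highmulti_frac = highmulti_frac, event_rate = event_rate)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions in sim_config must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (abs(sum(class_props) - 1) > 1e-9)
    stop("class_props must sum to 1 (got ", sum(class_props), ")")
  req <- c("mature", "premature", "snoRNA", "intergenic")
  if (!all(req %in% names(class_props)))
    stop("class_props must be named over: ", paste(req, collapse = ", "))
  if (2L * n_clusters > n_mirnas) stop("n_clusters too large for n_mirnas")
  if (4L * n_paralog_groups > n_mirnas)
    stop("n_paralog_groups too large for n_mirnas")

  if (!is.null(planted_expression)) {
    need <- c("mirna", "covariate", "level", "fold_change")
    if (!all(need %in% names(planted_expression)))
      stop("planted_expression needs columns: ", paste(need, collapse = ", "))
    if (any(planted_expression$fold_change <= 0))
      stop("planted fold changes must be positive")
  }
  if (!is.null(planted_survival)) {
    need <- c("mirna", "endpoint", "log_hr")
    if (!all(need %in% names(planted_survival)))
      stop("planted_survival needs columns: ", paste(need, collapse = ", "))
    if (!all(planted_survival$endpoint %in% c("os", "mfs")))
      stop("planted_survival$endpoint must be 'os' or 'mfs'")
  }

  structure(list(
    n_mirnas = as.integer(n_mirnas), n_clusters = as.integer(n_clusters),
    n_samples = as.integer(n_samples), reads_per_sample = reads_per_sample,
    length_weights = length_weights / sum(length_weights),
    frac_core_length = frac_core_length,
    class_props = class_props[req], class_concentration = class_concentration,
    top5_share = top5_share, multimap_frac = multimap_frac,
    n_paralog_groups = as.integer(n_paralog_groups),
    mismatch_rate = mismatch_rate, highmulti_frac = highmulti_frac,
    planted_expression = planted_expression,
    planted_survival = planted_survival,
    event_rate = event_rate, median_survival_days = median_survival_days,
    genome_length = genome_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# unimodal length profile peaked at 22 nt; mass outside 19-23 is spread thinly
default_length_weights <- function() {
  w <- stats::setNames(rep(1, 17), as.character(13:29))
  core <- as.character(19:23)
  w[core] <- c(0.08, 0.16, 0.28, 0.33, 0.15)
  w[setdiff(names(w), core)] <- 1 / 12
  w
}

# rescale length weights so the 19-23 nt window carries `frac_core` mass
scaled_length_weights <- function(cfg) {
  w <- cfg$length_weights
  core <- as.character(19:23)
  other <- setdiff(names(w), core)
  w[core] <- w[core] / sum(w[core]) * cfg$frac_core_length
  w[other] <- w[other] / sum(w[other]) * (1 - cfg$frac_core_length)
  w
}

#' Zipf exponent matching a target top-5 expression share
#'
#' Solves for the exponent `a` of a truncated power law `p_i ~ i^(-a)` over
#' ranks `1..n` such that the five top-ranked items carry `top5_share` of the
#' total mass. One parameter reproduces the extreme expression concentration
#' of small RNA libraries.
#'
#' @param n Number of ranked items.
#' @param top5_share Target mass of ranks 1-5, in (5/n, 1).
#' @return The exponent (positive numeric scalar).
#' @export
zipf_exponent <- function(n, top5_share) {
  stopifnot(n > 5, top5_share > 5 / n, top5_share < 1)
  f <- function(a) {
    w <- (seq_len(n))^(-a)
    sum(w[1:5]) / sum(w) - top5_share
  }
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

# expression weights over miRNA ranks for a config
zipf_weights <- function(cfg) {
  a <- zipf_exponent(cfg$n_mirnas, cfg$top5_share)
  w <- (seq_len(cfg$n_mirnas))^(-a)
  w / sum(w)
}

# deterministic per-sample sub-seed below 2^31
sample_seed <- function(seed, i) {
  (as.integer(seed) * 1013L + i * 7L) %% 2147483L + 1L
}
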