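#' Simulation configuration
#'
#' Builds the configuration object consumed by every `simulate_*` function.
#' Defaults emulate a four-cohort cassava breeding pedigree genotyped by
#' GBS: 18 chromosomes jointly spanning the 2412 cM reference map and a
#' 582.28 Mb genome, average read depth 7x, sequencing error 0.01, a
#' female/male map-length ratio of 1.2, and two *M. glaziovii*-like
#' introgression regions (chromosome 1 from 25 Mb to the chromosome end,
#' chromosome 4 from 5 to 25 Mb) whose carriers have recombination
#' suppressed by a per-copy multiplier of 0.32. Donor haplotypes differ
#' from the recipient pool at a 0.022 fraction of sites inside the
#' introgressed segments.
#'
#' @param n_founders Number of pedigree founders (no recorded parents).
#' @param cohort_sizes Integer vector of non-founder cohort sizes; cohort
#'   `k` is produced by crosses among individuals of cohorts `< k`
#'   (founders are cohort 0).
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_bp Physical chromosome length(s) in bp (recycled).
#' @param chrom_cM Genetic chromosome length(s) in cM (recycled); these are
#'   the reference lengths used for map scaling.
#' @param n_sites Number of SNP sites per chromosome.
#' @param female_rate_multiplier Scalar applied to map distances in female
#'   meioses (1 = no heterochiasmy).
#' @param interference_shape Gamma renewal shape \eqn{\nu \ge 1} for
#'   crossover interference; 1 gives a Poisson (no-interference) process.
#' @param introgression_regions `data.frame` with columns `chrom`, `start`,
#'   `end` (bp, 0-based half-open) of donor introgression segments, or
#'   `NULL` for none.
#' @param introgression_suppression Map-distance multiplier in `[0, 1]`
#'   applied inside a region once per carried donor copy (two copies give
#'   the squared multiplier).
#' @param donor_founder_freq Frequency of the donor haplotype among founder
#'   haplotypes in each introgression region.
#' @param donor_divergence Fraction of in-region sites at which the donor
#'   haplotype carries a donor-specific allele.
#' @param mean_depth Expected sequencing depth per site and individual.
#' @param error_rate Per-read sequencing error rate `e`.
#' @param missing_rate Extra fraction of site-by-individual cells zeroed to
#'   emulate GBS dropout beyond Poisson sampling.
#' @param large_family_frac Fraction of full-sib families drawn with more
#'   than two offspring.
#' @param obligate_crossover If `TRUE`, chromosomes with zero crossovers
#'   are resampled so every bivalent shows at least one.
#' @param seed Integer seed; identical configurations (including seed)
#'   yield bit-identical data.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_founders = 10, cohort_sizes = 40, n_chromosomes = 2,
#'                   n_sites = 50, seed = 1)
#' cfg$chrom_cM
#' @export
sim_config <- function(n_founders = 236,
                       cohort_sizes = c(258, 2334, 2515, 2089),
                       n_chromosomes = 18,
                       chrom_bp = round(582.28e6 / 18),
                       chrom_cM = 2412 / 18,
                       n_sites = 1950,
                       female_rate_multiplier = 1.2,
                       interference_shape = 1,
                       introgression_regions = NULL,
                       introgression_suppression = 0.32,
                       donor_founder_freq = 0.2,
                       donor_divergence = 0.022,
                       mean_depth = 7,
                       error_rate = 0.01,
                       missing_rate = 0.1,
                       large_family_frac = 0.5,
                       obligate_crossover = FALSE,
                       seed = 1L) {
  chrom_bp <- rep_len(as.numeric(chrom_bp), n_chromosomes)
  chrom_cM <- rep_len(as.numeric(chrom_cM), n_chromosomes)
  if (is.null(introgression_regions) && n_chromosomes >= 4) {
    introgression_regions <- data.frame(
      chrom = c(1L, 4L),
      start = c(25e6, 5e6),
      end   = c(chrom_bp[1], 25e6)
    )
  }
  cfg <- list(
    n_founders = as.integer(n_founders),
    cohort_sizes = as.integer(cohort_sizes),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_bp = chrom_bp,
    chrom_cM = chrom_cM,
    n_sites = as.integer(rep_len(n_sites, n_chromosomes)),
    female_rate_multiplier = female_rate_multiplier,
    interference_shape = interference_shape,
    introgression_regions = introgression_regions,
    introgression_suppression = introgression_suppression,
    donor_founder_freq = donor_founder_freq,
    donor_divergence = donor_divergence,
    mean_depth = mean_depth,
    error_rate = error_rate,
    missing_rate = missing_rate,
    large_family_frac = large_family_frac,
    obligate_crossover = isTRUE(obligate_crossover),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2)
    stop("at least two founders are required", call. = FALSE)
  if (any(cfg$cohort_sizes < 1))
    stop("every cohort size must be >= 1", call. = FALSE)
  if (any(cfg$chrom_bp <= 0) || any(cfg$chrom_cM < 0))
    stop("chromosome lengths must be positive (cM may be zero)", call. = FALSE)
  if (cfg$interference_shape < 1)
    stop("interference_shape must be >= 1", call. = FALSE)
  if (cfg$female_rate_multiplier < 0 || cfg$introgression_suppression < 0 ||
      cfg$introgression_suppression > 1)
    stop("rate multipliers must be >= 0; suppression must lie in [0, 1]",
         call. = FALSE)
  if (cfg$donor_divergence < 0 || cfg$donor_divergence > 1)
    stop("donor_divergence must lie in [0, 1]", call. = FALSE)
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  if (cfg$mean_depth < 0 || cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("mean_depth must be >= 0 and missing_rate in [0, 1]", call. = FALSE)
  reg <- cfg$introgression_regions
  if (!is.null(reg)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(reg)))
    if (any(reg$chrom < 1 | reg$chrom > cfg$n_chromosomes))
      stop("introgression region on a chromosome outside the genome",
           call. = FALSE)
    if (any(reg$start < 0) || any(reg$end > cfg$chrom_bp[reg$chrom]) ||
        any(reg$end <= reg$start))
      stop("introgression region outside chromosome bounds", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  individuals :", x$n_founders, "founders +",
      paste(x$cohort_sizes, collapse = " + "), "in",
      length(x$cohort_sizes), "cohorts\n")
  cat("  genome      :", x$n_chromosomes, "chromosomes,",
      format(sum(x$chrom_bp) / 1e6, digits = 4), "Mb /",
      format(sum(x$chrom_cM), digits = 5), "cM,",
      sum(x$n_sites), "sites\n")
  cat("  meiosis     : female multiplier", x$female_rate_multiplier,
      "| interference shape", x$interference_shape,
      "| suppression", x$introgression_suppression, "per donor copy\n")
  cat("  GBS         : depth", x$mean_depth, "x, error", x$error_rate,
      ", missing", x$missing_rate, "\n")
  invisible(x)
}

# deterministic per-stage substream seed derived from the master seed
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

set_stage_seed <- function(seed, stage) {
  s <- substream_seed(seed, stage)
  if (!is.null(s)) set.seed(s)
  invisible(s)
}
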