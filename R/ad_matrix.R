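#' Allele-depth matrix
#'
#' Container for per-site, per-individual reference/alternate read counts
#' at biallelic SNPs, the raw material of GBS genotype calling.
#'
#' @param sites `data.frame` with at least `chrom` and `pos` (1 row per
#'   site, sorted by chromosome then position); may be `NULL`, in which
#'   case placeholder sites are created.
#' @param ref,alt Integer matrices (sites x individuals) of reference and
#'   alternate read counts.
#' @param samples Character vector of sample names.
#' @return An object of class `ad_matrix`.
#' @export
ad_matrix <- function(sites, ref, alt, samples) {
  stopifnot(is.matrix(ref), is.matrix(alt), all(dim(ref) == dim(alt)))
  if (is.null(sites))
    sites <- data.frame(chrom = 1L, pos = seq_len(nrow(ref)))
  stopifnot(nrow(sites) == nrow(ref), length(samples) == ncol(ref))
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative", call. = FALSE)
  structure(list(sites = sites[, intersect(c("chrom", "pos", "ref", "alt",
                                             "id", "alt_freq", "diagnostic"),
                                           names(sites)), drop = FALSE],
                 ref = unname(ref), alt = unname(alt),
                 samples = as.character(samples)),
            class = "ad_matrix")
}

#' @export
print.ad_matrix <- function(x, ...) {
  dp <- x$ref + x$alt
  cat("<ad_matrix>", nrow(x$ref), "sites x", length(x$samples), "samples;",
      sprintf("mean depth %.2f, missing %.1f%%\n",
              mean(dp), 100 * mean(dp == 0)))
  invisible(x)
}

#' @export
dim.ad_matrix <- function(x) dim(x$ref)

# subset helper (sites i, samples j)
ad_subset <- function(ad, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(ad$ref))
  if (is.null(j)) j <- seq_along(ad$samples)
  ad_matrix(ad$sites[i, , drop = FALSE],
            ad$ref[i, j, drop = FALSE], ad$alt[i, j, drop = FALSE],
            ad$samples[j])
}

#' Depth-based filtering of an allele-depth matrix
#'
#' Applies, in order: removal of sites with more than `site_missing`
#' missing cells (missing = zero total depth), removal of individuals
#' with more than `indiv_missing` missing cells, and removal of sites
#' whose mean depth across all remaining samples exceeds
#' `max_mean_depth` (strict inequality; suspected repeat regions).
#'
#' @param ad An [ad_matrix()].
#' @param site_missing Maximum tolerated fraction of missing cells per
#'   site (default 0.7).
#' @param indiv_missing Maximum tolerated fraction of missing cells per
#'   individual (default 0.8).
#' @param max_mean_depth Maximum tolerated mean site depth (default 120).
#' @return List with the filtered `ad` and a `report` `data.frame` of
#'   per-filter removal counts.
#' @examples
#' ad <- ad_matrix(NULL, matrix(0:3, 2), matrix(1L, 2, 2), c("a", "b"))
#' filter_depth_matrix(ad)$report
#' @export
filter_depth_matrix <- function(ad, site_missing = 0.7, indiv_missing = 0.8,
                                max_mean_depth = 120) {
  stopifnot(inherits(ad, "ad_matrix"))
  n0 <- dim(ad)
  dp <- ad$ref + ad$alt
  keep_site <- rowMeans(dp == 0) <= site_missing
  ad <- ad_subset(ad, which(keep_site))
  dp <- dp[keep_site, , drop = FALSE]
  if (nrow(dp) == 0)
    stop("no data remain after depth filtering", call. = FALSE)
  keep_ind <- colMeans(dp == 0) <= indiv_missing
  ad <- ad_subset(ad, j = which(keep_ind))
  dp <- dp[, keep_ind, drop = FALSE]
  keep_depth <- rowMeans(dp) <= max_mean_depth
  ad <- ad_subset(ad, which(keep_depth))
  report <- data.frame(
    filter = c("site_missing", "indiv_missing", "site_mean_depth"),
    threshold = c(site_missing, indiv_missing, max_mean_depth),
    removed = c(sum(!keep_site), sum(!keep_ind), sum(!keep_depth)),
    unit = c("sites", "individuals", "sites"))
  if (nrow(ad$ref) == 0 || length(ad$samples) == 0)
    stop("no data remain after depth filtering", call. = FALSE)
  list(ad = ad, report = report)
}
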