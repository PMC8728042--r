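#' Identify introgression diagnostic markers from reference panels
#'
#' A site is an introgression diagnostic marker (IDM) when either (rule
#' 1) both the donor and recipient panels are fixed, for different
#' alleles, or (rule 2) the recipient panel is fixed while the donor
#' panel is polymorphic. The donor-specific allele is the donor's fixed
#' allele (rule 1) or the allele absent from the recipient panel (rule
#' 2). Sites with an all-missing panel are skipped and counted. "Fixed"
#' means a single allele is observed in the panel (all individuals
#' homozygous for it).
#'
#' @param donor,recipient Integer dosage matrices (sites x individuals,
#'   0/1/2, `NA` missing) for the two non-admixed panels (>= 2
#'   individuals each).
#' @param sites Site table (`chrom`, `pos`) aligned to the matrix rows.
#' @return `data.frame` of IDMs: `site` (row index), `chrom`, `pos`,
#'   `donor_allele` (`"ref"`/`"alt"`), `rule` (1 or 2); attribute
#'   `skipped` = number of all-missing sites.
#' @export
find_idms <- function(donor, recipient, sites) {
  stopifnot(nrow(donor) == nrow(recipient), nrow(donor) == nrow(sites))
  if (ncol(donor) < 2 || ncol(recipient) < 2)
    stop("each panel needs at least two individuals", call. = FALSE)
  panel_state <- function(g) {
    has_ref <- rowSums(g == 0L | g == 1L, na.rm = TRUE) > 0
    has_alt <- rowSums(g == 2L | g == 1L, na.rm = TRUE) > 0
    n_obs <- rowSums(!is.na(g))
    state <- rep(NA_character_, nrow(g))
    state[n_obs > 0 & has_ref & !has_alt] <- "fixed_ref"
    state[n_obs > 0 & !has_ref & has_alt] <- "fixed_alt"
    state[n_obs > 0 & has_ref & has_alt] <- "poly"
    state
  }
  ds <- panel_state(donor)
  rs <- panel_state(recipient)
  skipped <- sum(is.na(ds) | is.na(rs))
  rule1 <- (ds == "fixed_ref" & rs == "fixed_alt") |
    (ds == "fixed_alt" & rs == "fixed_ref")
  rule2 <- ds == "poly" & rs %in% c("fixed_ref", "fixed_alt")
  rule1[is.na(rule1)] <- FALSE
  rule2[is.na(rule2)] <- FALSE
  idx <- which(rule1 | rule2)
  donor_allele <- ifelse(rule1[idx],
                         ifelse(ds[idx] == "fixed_alt", "alt", "ref"),
                         ifelse(rs[idx] == "fixed_ref", "alt", "ref"))
  out <- data.frame(site = idx, chrom = sites$chrom[idx],
                    pos = sites$pos[idx], donor_allele = donor_allele,
                    rule = ifelse(rule1[idx], 1L, 2L))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mean donor-allele dosage in physical windows
#'
#' Tiles each chromosome in `window_bp` steps (0-based half-open) and
#' averages an individual's donor-allele dosage over the non-missing
#' IDMs in each window. Windows containing no IDM genotypes are
#' reported as `NA`.
#'
#' @param geno Integer vector of the individual's ALT-dosage calls at
#'   the IDM sites (same order as `idms`), `NA` = uncalled.
#' @param idms IDM table from [find_idms()].
#' @param chrom_bp Physical chromosome lengths (bp).
#' @param window_bp Window size (default 250 kb).
#' @return `data.frame`: `chrom`, `start`, `end`, `n_idms` (IDMs with a
#'   non-missing call in the window), `mean_dosage`.
#' @export
window_dosage <- function(geno, idms, chrom_bp, window_bp = 250e3) {
  stopifnot(length(geno) == nrow(idms))
  donor_dose <- ifelse(idms$donor_allele == "alt", geno, 2L - geno)
  rows <- list()
  for (ch in seq_along(chrom_bp)) {
    n_win <- ceiling(chrom_bp[ch] / window_bp)
    sel <- idms$chrom == ch
    w <- floor(idms$pos[sel] / window_bp) + 1L
    dd <- donor_dose[sel]
    ok <- !is.na(dd)
    n <- tabulate(w[ok], n_win)
    s <- rep(0, n_win)
    if (any(ok)) {
      agg <- tapply(dd[ok], w[ok], sum)
      s[as.integer(names(agg))] <- agg
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = (seq_len(n_win) - 1) * window_bp,
      end = pmin(seq_len(n_win) * window_bp, chrom_bp[ch]),
      n_idms = n, mean_dosage = ifelse(n > 0, s / n, NA_real_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a regional mean dosage to an introgression status
#'
#' Mean dosages in `[0, 0.5)`, `[0.5, 1.5)` and `[1.5, 2]` are rounded
#' to 0, 1 and 2 (boundaries round half-up).
#'
#' @param window_means Numeric vector of per-window mean dosages within
#'   the region (NA windows are dropped).
#' @param weights Optional weights (e.g. IDM counts) for a weighted
#'   regional mean; the default is the unweighted mean of window means.
#' @return List: `mean_dosage`, `status` (0/1/2, `NA` when every window
#'   is missing).
#' @export
classify_status <- function(window_means, weights = NULL) {
  ok <- !is.na(window_means)
  if (!any(ok)) return(list(mean_dosage = NA_real_, status = NA_integer_))
  mu <- if (is.null(weights)) mean(window_means[ok]) else
    sum(window_means[ok] * weights[ok]) / sum(weights[ok])
  status <- if (mu < 0.5) 0L else if (mu < 1.5) 1L else 2L
  list(mean_dosage = mu, status = status)
}

#' Classify introgression dosage for every individual and region
#'
#' Computes 250-kb window mean donor-allele dosages from called
#' genotypes at the IDMs and rounds the regional mean of window means to
#' a per-region status of 0, 1 or 2 donor copies. Individuals with no
#' scored window in a region get `NA` and are excluded from class
#' tests downstream.
#'
#' @param calls Sites x individuals call matrix (columns named).
#' @param idms IDM table from [find_idms()] (with `site` indexing
#'   `calls` rows).
#' @param regions `data.frame` (`region`, `chrom`, `start`, `end`).
#' @param chrom_bp Physical chromosome lengths (bp).
#' @param window_bp Window size (default 250 kb).
#' @return `data.frame`: `id`, `region`, `mean_dosage`, `status`.
#' @export
classify_introgression <- function(calls, idms, regions, chrom_bp,
                                   window_bp = 250e3) {
  out <- list()
  for (ind in colnames(calls)) {
    wd <- window_dosage(calls[idms$site, ind], idms, chrom_bp, window_bp)
    for (r in seq_len(nrow(regions))) {
      reg <- regions[r, ]
      sel <- wd$chrom == reg$chrom & wd$start < reg$end &
        wd$end > reg$start
      cs <- classify_status(wd$mean_dosage[sel])
      out[[length(out) + 1L]] <- data.frame(
        id = ind, region = reg$region, mean_dosage = cs$mean_dosage,
        status = cs$status, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
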