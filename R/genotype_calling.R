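#' Genotype-calling model
#'
#' Parameters of the binomial read-count likelihood used for GBS genotype
#' calling. Given `n_A` reference and `n_B` alternate reads, the
#' likelihood of genotype g is Binomial(n_A + n_B, n_B; p_B(g)) with
#' p_B = e, 0.5, 1 - e for g = AA, AB, BB, where e is the per-read
#' sequencing error rate. A genotype is called only when its posterior
#' reaches `call_threshold`.
#'
#' @param error_rate Sequencing error rate `e` in (0, 0.5).
#' @param call_threshold Posterior cutoff in (0.5, 1]; the call is made
#'   when the maximum posterior is greater than or equal to it.
#' @return An object of class `genotype_model`.
#' @export
genotype_model <- function(error_rate = 0.01, call_threshold = 0.99) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)", call. = FALSE)
  if (call_threshold <= 0.5 || call_threshold > 1)
    stop("call_threshold must lie in (0.5, 1]", call. = FALSE)
  structure(list(error_rate = error_rate, call_threshold = call_threshold,
                 p_B = c(AA = error_rate, AB = 0.5, BB = 1 - error_rate)),
            class = "genotype_model")
}

#' Binomial genotype likelihoods from allele read counts
#'
#' @param n_A,n_B Reference / alternate read counts (equal-length
#'   vectors).
#' @param model A [genotype_model()].
#' @return Matrix with columns `AA`, `AB`, `BB` of likelihoods (the
#'   binomial PMF, coefficient included). With zero reads every genotype
#'   has likelihood 1.
#' @examples
#' genotype_likelihood(0, 2)["BB"] # (1 - 0.01)^2 = 0.9801
#' @export
genotype_likelihood <- function(n_A, n_B, model = genotype_model()) {
  stopifnot(length(n_A) == length(n_B), all(n_A >= 0), all(n_B >= 0))
  n <- n_A + n_B
  out <- cbind(AA = dbinom(n_B, n, model$p_B[["AA"]]),
               AB = dbinom(n_B, n, model$p_B[["AB"]]),
               BB = dbinom(n_B, n, model$p_B[["BB"]]))
  if (length(n_A) == 1L) out[1, ] else out
}

# Mendelian transmission array T[gm, gf, gc] = P(child gc | parents)
mendelian_transmission <- function() {
  tr <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1)) # P(transmit ref/alt | genotype)
  TT <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    p <- outer(tr[i, ], tr[j, ]) # (allele from m, allele from f)
    TT[i, j, ] <- c(p[1, 1], p[1, 2] + p[2, 1], p[2, 2])
  }
  TT
}

#' Genotype prior from parental posteriors or allele frequency
#'
#' Trio case: prior = sum over parental genotype pairs of Mendelian
#' transmission probability times the product of parental posterior
#' probabilities. Founder / single-validated-parent case:
#' Hardy-Weinberg prior from the reference-allele frequency.
#'
#' @param parent1,parent2 Numeric length-3 posteriors `(AA, AB, BB)` of
#'   the two validated parents, or `NULL`.
#' @param ref_freq Reference-allele frequency in `[0, 1]`, used when
#'   fewer than two parental posteriors are supplied.
#' @return Length-3 prior `(AA, AB, BB)`.
#' @examples
#' genotype_prior(c(0, 1, 0), c(0, 1, 0))   # (0.25, 0.5, 0.25)
#' genotype_prior(ref_freq = 0.7)           # HWE: (0.49, 0.42, 0.09)
#' @export
genotype_prior <- function(parent1 = NULL, parent2 = NULL, ref_freq = NULL) {
  if (!is.null(parent1) && !is.null(parent2)) {
    TT <- mendelian_transmission()
    pr <- vapply(1:3, function(g) sum(outer(parent1, parent2) * TT[, , g]),
                 0)
    names(pr) <- c("AA", "AB", "BB")
    return(pr)
  }
  if (is.null(ref_freq) || ref_freq < 0 || ref_freq > 1)
    stop("ref_freq must lie in [0, 1]", call. = FALSE)
  p <- ref_freq
  c(AA = p^2, AB = 2 * p * (1 - p), BB = (1 - p)^2)
}

# flat-prior posterior-mean ALT dosage -> per-site REF allele frequency,
# over individuals with at least one read
estimate_ref_freq <- function(ad, model) {
  dp <- ad$ref + ad$alt
  m <- nrow(dp)
  lAA <- dbinom(ad$alt, dp, model$p_B[["AA"]])
  lAB <- dbinom(ad$alt, dp, model$p_B[["AB"]])
  lBB <- dbinom(ad$alt, dp, model$p_B[["BB"]])
  tot <- lAA + lAB + lBB
  dos <- (lAB + 2 * lBB) / tot
  dos[dp == 0] <- NA
  alt_freq <- rowMeans(dos, na.rm = TRUE) / 2
  alt_freq[is.nan(alt_freq)] <- 0.5
  pmin(pmax(1 - alt_freq, 1e-6), 1 - 1e-6)
}

topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  dam <- idx[ped$dam]; sire <- idx[ped$sire]
  indeg <- (!is.na(dam)) + (!is.na(sire))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam[i], sire[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c_ in children[[v]]) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) queue <- c(queue, c_)
    }
  }
  if (length(out) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), out)], collapse = ", "),
         call. = FALSE)
  out
}

#' Call genotypes down a pedigree from allele depths
#'
#' Processes individuals in topological order (founders first). Each
#' individual's posterior is proportional to the binomial read-count
#' likelihood times a prior: a Mendelian prior from both parents'
#' posteriors when both parents are present in the data, otherwise a
#' Hardy-Weinberg prior from the estimated reference-allele frequency
#' (estimated once, before propagation, as the flat-prior posterior-mean
#' dosage over individuals with reads). A genotype is called only when
#' the maximum posterior reaches the model's call threshold. After
#' calling, sites that are monomorphic, singleton (minor allele carried
#' by exactly one called individual) or more than `site_missing_calls`
#' missing are removed.
#'
#' @param ad An [ad_matrix()] (after depth filtering).
#' @param ped A pedigree `data.frame` (`id`, `dam`, `sire`); individuals
#'   absent from `ad` are treated as missing parents.
#' @param model A [genotype_model()].
#' @param site_missing_calls Post-call per-site missingness cutoff
#'   (default 0.3).
#' @return List with `calls` (sites x individuals integer matrix of ALT
#'   dosages 0/1/2, `NA` = no call), `posterior` (sites x individuals x 3
#'   array), `kept_sites` (indices into the input sites), `ref_freq`, and
#'   `report` (post-call filter counts).
#' @export
call_genotypes_down_pedigree <- function(ad, ped, model = genotype_model(),
                                         site_missing_calls = 0.3) {
  stopifnot(inherits(ad, "ad_matrix"))
  ord <- topo_order(ped)
  m <- nrow(ad$ref)
  idx_sample <- match(ped$id, ad$samples)
  ref_freq <- estimate_ref_freq(ad, model)
  hwe <- cbind(ref_freq^2, 2 * ref_freq * (1 - ref_freq), (1 - ref_freq)^2)
  TT <- mendelian_transmission()
  post <- array(NA_real_, c(m, nrow(ped), 3))
  for (i in ord) {
    si <- idx_sample[i]
    if (is.na(si)) next
    dam_i <- match(ped$dam[i], ped$id)
    sire_i <- match(ped$sire[i], ped$id)
    have_dam <- !is.na(dam_i) && !is.na(idx_sample[dam_i])
    have_sire <- !is.na(sire_i) && !is.na(idx_sample[sire_i])
    if (have_dam && have_sire) {
      pm <- post[, dam_i, ]; pf <- post[, sire_i, ]
      prior <- matrix(0, m, 3)
      for (a in 1:3) for (b in 1:3) {
        w <- pm[, a] * pf[, b]
        for (g in 1:3) if (TT[a, b, g] > 0)
          prior[, g] <- prior[, g] + w * TT[a, b, g]
      }
    } else {
      prior <- hwe
    }
    dp <- ad$ref[, si] + ad$alt[, si]
    lik <- cbind(dbinom(ad$alt[, si], dp, model$p_B[["AA"]]),
                 dbinom(ad$alt[, si], dp, model$p_B[["AB"]]),
                 dbinom(ad$alt[, si], dp, model$p_B[["BB"]]))
    un <- prior * lik
    post[, i, ] <- un / rowSums(un)
  }
  calls <- matrix(NA_integer_, m, nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (all(is.na(post[, i, 1]))) next
    p3 <- post[, i, , drop = FALSE]
    dim(p3) <- c(m, 3)
    mx <- pmax(p3[, 1], p3[, 2], p3[, 3])
    g <- max.col(p3, ties.method = "first") - 1L
    g[mx < model$call_threshold] <- NA_integer_
    calls[, i] <- g
  }
  colnames(calls) <- ped$id

  n_called <- rowSums(!is.na(calls))
  n_ref_carrier <- rowSums(calls == 0L | calls == 1L, na.rm = TRUE)
  n_alt_carrier <- rowSums(calls == 2L | calls == 1L, na.rm = TRUE)
  mono <- n_called > 0 & (n_ref_carrier == 0 | n_alt_carrier == 0)
  singleton <- !mono & n_called > 0 & pmin(n_ref_carrier, n_alt_carrier) == 1
  miss <- 1 - n_called / nrow(ped)
  too_missing <- miss > site_missing_calls
  keep <- !(mono | singleton | too_missing)
  report <- data.frame(
    filter = c("monomorphic", "singleton", "site_missing_calls"),
    threshold = c(NA, NA, site_missing_calls),
    removed = c(sum(mono), sum(singleton & !mono),
                sum(too_missing & !mono & !singleton)),
    unit = "sites")
  list(calls = calls[keep, , drop = FALSE],
       posterior = post[keep, , , drop = FALSE],
       kept_sites = which(keep), ref_freq = ref_freq, report = report)
}

#' Opposing-homozygote Mendelian conflict rate
#'
#' Lightweight parent-link validation: the fraction of co-called sites at
#' which a child and a putative parent are opposite homozygotes (AA vs
#' BB), which is Mendelian-impossible barring genotyping error.
#'
#' @param child,parent Integer call vectors (0/1/2, `NA` = uncalled).
#' @param min_sites Minimum co-called sites for a decision (default 50).
#' @param cutoff Conflict-rate cutoff above which the link is flagged
#'   invalid (default 0.02).
#' @return List: `rate`, `n_sites`, `valid` (`NA` when there are too few
#'   co-called sites).
#' @export
mendelian_conflict_rate <- function(child, parent, min_sites = 50,
                                    cutoff = 0.02) {
  ok <- !is.na(child) & !is.na(parent)
  n <- sum(ok)
  if (n < min_sites)
    return(list(rate = NA_real_, n_sites = n, valid = NA))
  rate <- mean(abs(child[ok] - parent[ok]) == 2)
  list(rate = rate, n_sites = n, valid = rate <= cutoff)
}

#' Merge technical replicate samples by depth concordance
#'
#' Replicate samples whose quick flat-prior calls conflict at fewer than
#' `cutoff` of co-called sites are merged by summing their allele depths;
#' groups that cannot be unambiguously verified as identical are excluded
#' entirely.
#'
#' @param ad An [ad_matrix()].
#' @param groups Named list: output sample name -> character vector of
#'   replicate sample names in `ad`.
#' @param model A [genotype_model()].
#' @param cutoff Maximum tolerated call-conflict fraction between any
#'   pair of replicates (default 0.05).
#' @return List with the merged `ad` and `excluded` (group names dropped).
#' @export
merge_replicates <- function(ad, groups, model = genotype_model(),
                             cutoff = 0.05) {
  quick_call <- function(j) {
    dp <- ad$ref[, j] + ad$alt[, j]
    lik <- cbind(dbinom(ad$alt[, j], dp, model$p_B[["AA"]]),
                 dbinom(ad$alt[, j], dp, model$p_B[["AB"]]),
                 dbinom(ad$alt[, j], dp, model$p_B[["BB"]]))
    g <- max.col(lik, ties.method = "first") - 1L
    g[dp == 0] <- NA_integer_
    g
  }
  drop_samples <- character(0)
  excluded <- character(0)
  new_cols <- list()
  for (nm in names(groups)) {
    js <- match(groups[[nm]], ad$samples)
    if (anyNA(js)) stop("unknown replicate sample in group ", nm)
    calls <- lapply(js, quick_call)
    ok <- TRUE
    if (length(js) > 1) {
      for (a in seq_along(js)) for (b in seq_len(a - 1L)) {
        co <- !is.na(calls[[a]]) & !is.na(calls[[b]])
        if (sum(co) > 0 &&
            mean(calls[[a]][co] != calls[[b]][co]) > cutoff) ok <- FALSE
      }
    }
    drop_samples <- c(drop_samples, groups[[nm]])
    if (ok) {
      new_cols[[nm]] <- list(ref = rowSums(ad$ref[, js, drop = FALSE]),
                             alt = rowSums(ad$alt[, js, drop = FALSE]))
    } else {
      excluded <- c(excluded, nm)
    }
  }
  keep <- !(ad$samples %in% drop_samples)
  ref <- cbind(ad$ref[, keep, drop = FALSE],
               do.call(cbind, lapply(new_cols, `[[`, "ref")))
  alt <- cbind(ad$alt[, keep, drop = FALSE],
               do.call(cbind, lapply(new_cols, `[[`, "alt")))
  list(ad = ad_matrix(ad$sites, ref, alt,
                      c(ad$samples[keep], names(new_cols))),
       excluded = excluded)
}
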