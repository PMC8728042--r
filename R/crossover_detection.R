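#' Duo-HMM parameters
#'
#' @param epsilon Emission error rate in (0, 0.5): probability that the
#'   child's deduced transmitted allele mismatches the transmitted
#'   parental haplotype allele.
#' @param threshold Posterior probability `t` at or above which an
#'   inter-SNP interval is emitted as a crossover (default 0.5).
#' @param n_iterations Number of HMM passes whose per-interval posteriors
#'   are averaged (runs differ only when phasing is stochastic).
#' @param max_correction_rounds Cap on switch-error correction rounds.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(epsilon = 0.01, threshold = 0.5, n_iterations = 10,
                       max_correction_rounds = 10) {
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  structure(list(epsilon = epsilon, threshold = threshold,
                 n_iterations = as.integer(n_iterations),
                 max_correction_rounds = as.integer(max_correction_rounds)),
            class = "hmm_params")
}

#' Deduce the allele a focal parent transmitted to a child
#'
#' Duo reduction: given child and co-parent genotype calls, the allele the
#' focal parent transmitted is determined whenever the Mendelian
#' arithmetic has a unique solution. Ambiguous sites (e.g. het child with
#' het or missing co-parent) return `NA`; Mendelian-impossible
#' configurations return `-1`.
#'
#' @param child,coparent Integer vectors of ALT-dosage calls (0/1/2,
#'   `NA` = uncalled).
#' @return Integer vector: transmitted ALT dosage (0/1), `NA` if
#'   undetermined, `-1` on Mendelian conflict.
#' @export
transmitted_allele <- function(child, coparent) {
  # lookup[child + 1, coparent + 1]; 4th column = co-parent missing
  lookup <- matrix(c(0L,  0L, -1L,  0L,
                     1L,  NA,  0L,  NA,
                     -1L, 1L,  1L,  1L),
                   nrow = 3, byrow = TRUE)
  cop <- ifelse(is.na(coparent), 3L, coparent)
  out <- rep(NA_integer_, length(child))
  ok <- !is.na(child)
  out[ok] <- lookup[cbind(child[ok] + 1L, cop[ok] + 1L)]
  out
}

# emission matrix (m x 2) for the two transmitted-haplotype states
duo_emissions <- function(phase, evidence, epsilon) {
  m <- ncol(phase)
  em <- matrix(1, m, 2)
  ev <- evidence
  ev[!is.na(ev) & ev < 0] <- NA # conflicts treated as missing
  use <- !is.na(ev) & !is.na(phase[1, ]) & !is.na(phase[2, ])
  if (any(use)) {
    em[use, 1] <- ifelse(ev[use] == phase[1, use], 1 - epsilon, epsilon)
    em[use, 2] <- ifelse(ev[use] == phase[2, use], 1 - epsilon, epsilon)
  }
  em
}

haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Per-interval recombination posteriors for one parent-offspring duo
#'
#' Two-state inheritance HMM: the hidden state is which parental
#' haplotype is transmitted. Transition probability between adjacent
#' sites is the Haldane recombination fraction of their map distance;
#' emissions match the child's deduced transmitted allele to the
#' transmitted haplotype's allele with probability `1 - epsilon`.
#' Posteriors of a state change between adjacent sites are computed by
#' the scaled forward-backward algorithm.
#'
#' @param phase 2 x m matrix of parental haplotype alleles (0/1, `NA`
#'   unphased).
#' @param evidence Length-m vector from [transmitted_allele()].
#' @param map_cM Length-m non-decreasing cumulative map positions (cM).
#' @param params An [hmm_params()].
#' @param collapse If `TRUE` (default) the chain is restricted to
#'   informative sites (parent heterozygous with evidence present), with
#'   transition probabilities from the summed map distance between them,
#'   so a crossover's posterior concentrates in the interval between its
#'   flanking informative markers — the resolution at which a duo can
#'   localize an event. With `FALSE` the full site chain is used and the
#'   posterior of a crossover is spread across the uninformative
#'   sub-intervals in proportion to their map length.
#' @return List: `post_change` (posterior of recombination per interval),
#'   `interval_left`/`interval_right` (site indices bounding each
#'   interval), `loglik`, `n_informative`.
#' @export
duo_hmm_posteriors <- function(phase, evidence, map_cM,
                               params = hmm_params(), collapse = TRUE) {
  m <- ncol(phase)
  stopifnot(length(evidence) == m, length(map_cM) == m)
  em <- duo_emissions(phase, evidence, params$epsilon)
  informative <- which(em[, 1] != em[, 2])
  if (length(informative) < 2) {
    warning("fewer than two informative sites; meiosis counted as zero crossovers")
    return(list(post_change = numeric(0), interval_left = integer(0),
                interval_right = integer(0), loglik = 0,
                n_informative = length(informative)))
  }
  idx <- if (collapse) informative else seq_len(m)
  r <- haldane_r(pmax(diff(map_cM[idx]), 0))
  fb <- duo_forward_backward(em[idx, , drop = FALSE], r)
  list(post_change = fb$post_change,
       interval_left = idx[-length(idx)], interval_right = idx[-1],
       loglik = fb$loglik, n_informative = length(informative))
}

duo_forward_backward <- function(em, r) {
  m <- nrow(em)
  f <- matrix(0, m, 2)
  s <- numeric(m)
  f[1, ] <- 0.5 * em[1, ]
  s[1] <- f[1, 1] + f[1, 2]
  f[1, ] <- f[1, ] / s[1]
  for (i in 2:m) {
    ri <- r[i - 1]
    a <- f[i - 1, 1]; b <- f[i - 1, 2]
    x1 <- (a * (1 - ri) + b * ri) * em[i, 1]
    x2 <- (a * ri + b * (1 - ri)) * em[i, 2]
    s[i] <- x1 + x2
    f[i, 1] <- x1 / s[i]; f[i, 2] <- x2 / s[i]
  }
  b1 <- 1; b2 <- 1
  post_change <- numeric(m - 1)
  for (i in (m - 1):1) {
    ri <- r[i]
    e1 <- em[i + 1, 1] * b1
    e2 <- em[i + 1, 2] * b2
    post_change[i] <- (f[i, 1] * ri * e2 + f[i, 2] * ri * e1) / s[i + 1]
    nb1 <- ((1 - ri) * e1 + ri * e2) / s[i + 1]
    nb2 <- (ri * e1 + (1 - ri) * e2) / s[i + 1]
    b1 <- nb1; b2 <- nb2
  }
  list(post_change = post_change, loglik = sum(log(s)))
}

# most likely state path (1/2) for switch-error detection
duo_viterbi <- function(phase, evidence, map_cM, params) {
  em <- duo_emissions(phase, evidence, params$epsilon)
  m <- nrow(em)
  r <- haldane_r(pmax(diff(map_cM), 0))
  r <- pmin(pmax(r, 1e-12), 0.5)
  lem <- log(em)
  d1 <- log(0.5) + lem[1, 1]; d2 <- log(0.5) + lem[1, 2]
  ptr <- matrix(0L, m, 2)
  for (i in 2:m) {
    lr <- log(r[i - 1]); l1r <- log(1 - r[i - 1])
    c11 <- d1 + l1r; c21 <- d2 + lr
    c12 <- d1 + lr;  c22 <- d2 + l1r
    if (c11 >= c21) { n1 <- c11; ptr[i, 1] <- 1L } else { n1 <- c21; ptr[i, 1] <- 2L }
    if (c22 >= c12) { n2 <- c22; ptr[i, 2] <- 2L } else { n2 <- c12; ptr[i, 2] <- 1L }
    d1 <- n1 + lem[i, 1]; d2 <- n2 + lem[i, 2]
  }
  path <- integer(m)
  path[m] <- if (d1 >= d2) 1L else 2L
  for (i in m:2) path[i - 1] <- ptr[i, path[i]]
  path
}

#' Phase a parent's haplotypes from its mates and children
#'
#' Mendelian duo/trio phasing that replaces population phasing:
#' heterozygous parental sites are assigned to haplotypes using the
#' allele transmitted to a reference child (deduced from the child's and
#' its other parent's genotype calls); sites where the transmission is
#' ambiguous are phased arbitrarily and flagged. When two or more
#' children are available, switch errors in this raw phase (including
#' those induced by the reference child's own crossovers) are corrected
#' by [correct_switch_errors()].
#'
#' @param parent_calls Length-m call vector of the focal parent.
#' @param coparent_calls m x k matrix: column j is the other parent of
#'   child j (`NA` column if unknown).
#' @param children_calls m x k matrix of the children's calls.
#' @param map_cM Cumulative map positions of the m sites (one
#'   chromosome).
#' @param params An [hmm_params()].
#' @return List of class `phased_parent`: `haplotypes` (2 x m),
#'   `flagged` (logical, arbitrarily phased sites), `evidence` (m x k
#'   deduced transmissions), `provenance = "trio"`, `n_corrections`.
#' @export
trio_phase_parent <- function(parent_calls, coparent_calls, children_calls,
                              map_cM, params = hmm_params()) {
  if (is.null(dim(children_calls)))
    children_calls <- matrix(children_calls, ncol = 1)
  if (is.null(dim(coparent_calls)))
    coparent_calls <- matrix(coparent_calls, ncol = ncol(children_calls))
  m <- length(parent_calls)
  k <- ncol(children_calls)
  ev <- matrix(NA_integer_, m, k)
  for (j in seq_len(k))
    ev[, j] <- transmitted_allele(children_calls[, j], coparent_calls[, j])
  ev[!is.na(ev) & ev < 0] <- NA_integer_ # Mendelian conflicts -> missing
  het <- !is.na(parent_calls) & parent_calls == 1L
  hap <- matrix(NA_integer_, 2, m)
  hom <- !is.na(parent_calls) & parent_calls != 1L
  hap[1, hom] <- hap[2, hom] <- as.integer(parent_calls[hom] / 2L)
  # initial phase by sequential two-point linkage consensus: for each
  # pair of adjacent evidence-bearing het sites, the majority of
  # offspring are non-recombinant in the interval, so the majority
  # pattern of co-transmitted alleles fixes the relative phase. This
  # avoids seeding whole mis-phased blocks, which a Viterbi-majority
  # correction cannot undo (a flipped block is self-consistent: every
  # offspring path flips with it).
  n_ev <- rowSums(!is.na(ev))
  inf <- which(het & n_ev > 0)
  flagged <- het & n_ev == 0
  if (length(inf)) {
    first <- inf[1]
    j1 <- which(!is.na(ev[first, ]))[1]
    hap[1, first] <- ev[first, j1] # gauge choice
    if (length(inf) > 1) {
      # chain left to right: offspring whose evidence at a nearby
      # already-phased anchor site matches haplotype 1 are
      # (majority-)non-recombinant across the short gap, so haplotype 1
      # here is the majority allele they received; offspring on
      # haplotype 2 vote with the complement. Several anchors are
      # pooled so that no single offspring's crossover (or an empty
      # overlap with the immediate neighbour) can flip the chain.
      for (q in 2:length(inf)) {
        s <- inf[q]
        votes <- integer(0)
        for (back in seq_len(min(q - 1L, 8L))) {
          a <- inf[q - back]
          both <- which(!is.na(ev[a, ]) & !is.na(ev[s, ]))
          if (length(both)) {
            on1 <- ev[a, both] == hap[1, a]
            votes <- c(votes, ev[s, both][on1], 1L - ev[s, both][!on1])
          }
          if (length(votes) >= 5) break
        }
        if (length(votes)) {
          hap[1, s] <- as.integer(mean(votes) >= 0.5)
        } else {
          hap[1, s] <- 0L # relative phase unknown across this gap
          flagged[s] <- TRUE
        }
      }
    }
    hap[2, inf] <- 1L - hap[1, inf]
    # bilateral re-vote: the forward chain leaves the first sites with
    # few (left-only) anchors; revisit every site with the nearest
    # anchors on both sides until the vote is well supported
    for (sweep in 1:2) {
      for (q in seq_along(inf)) {
        s <- inf[q]
        votes <- integer(0)
        for (off in 1:8) {
          for (a_q in c(q - off, q + off)) {
            if (a_q < 1 || a_q > length(inf) || a_q == q) next
            a <- inf[a_q]
            both <- which(!is.na(ev[a, ]) & !is.na(ev[s, ]))
            if (length(both)) {
              on1 <- ev[a, both] == hap[1, a]
              votes <- c(votes, ev[s, both][on1], 1L - ev[s, both][!on1])
            }
          }
          if (length(votes) >= 6) break
        }
        if (length(votes)) hap[1, s] <- as.integer(mean(votes) >= 0.5)
      }
      hap[2, inf] <- 1L - hap[1, inf]
    }
  }
  hap[1, flagged & het] <- 0L
  hap[2, flagged & het] <- 1L
  n_corr <- 0L
  if (k >= 2 && any(het)) {
    # consensus refinement: the raw phase equals the reference child's
    # gamete, so its crossovers masquerade as switch errors, and sites
    # phased from different children disagree. Alternate (a) flipping
    # phase downstream of intervals where a strict majority of offspring
    # Viterbi paths change state and (b) per-site majority re-phasing of
    # het sites from the offspring evidence given their current paths.
    for (round in seq_len(params$max_correction_rounds)) {
      paths <- vapply(seq_len(k), function(j)
        duo_viterbi(hap, ev[, j], map_cM, params), integer(m))
      changes <- paths[-1, , drop = FALSE] != paths[-m, , drop = FALSE]
      flag <- rowSums(changes) > k / 2
      if (any(flag)) {
        parity <- c(0L, cumsum(as.integer(flag))) %% 2L
        swap <- parity == 1L & het
        tmp <- hap[1, swap]
        hap[1, swap] <- hap[2, swap]
        hap[2, swap] <- tmp
        sw <- parity == 1L
        paths[sw, ] <- 3L - paths[sw, ]
        n_corr <- n_corr + sum(flag)
      }
      # majority vote for haplotype-1 allele at each het site
      implied <- ifelse(paths == 1L, ev, 1L - ev)
      votes <- rowMeans(implied, na.rm = TRUE)
      new1 <- hap[1, ]
      hs <- which(het & !is.nan(votes) & votes != 0.5)
      new1[hs] <- as.integer(votes[hs] > 0.5)
      changed <- any(flag) || any(new1[het] != hap[1, het])
      hap[1, het] <- new1[het]
      hap[2, het] <- 1L - hap[1, het]
      if (!changed) break
    }
    # mask het sites whose phase lacks cross-offspring support: fewer
    # than two informative offspring, or a weak vote margin. A site
    # phased from a single child is tautological evidence for that
    # child and would drag its own path.
    paths <- vapply(seq_len(k), function(j)
      duo_viterbi(hap, ev[, j], map_cM, params), integer(m))
    implied <- ifelse(paths == 1L, ev, 1L - ev)
    n_votes <- rowSums(!is.na(implied))
    votes <- rowMeans(implied, na.rm = TRUE)
    margin <- pmax(votes, 1 - votes)
    unreliable <- het & (n_votes < 2 | is.nan(votes) | margin < 0.7)
    hap[1, unreliable] <- NA_integer_
    hap[2, unreliable] <- NA_integer_
    flagged <- flagged | unreliable
  }
  if (k == 1 && any(het)) {
    # a single duo cannot be phased against itself
    hap[1, het] <- NA_integer_
    hap[2, het] <- NA_integer_
    flagged <- flagged | het
  }
  res <- list(haplotypes = hap, flagged = flagged, evidence = ev,
              provenance = "trio", n_corrections = n_corr)
  class(res) <- "phased_parent"
  res
}

#' Correct parental phasing switch errors using all offspring
#'
#' A switch error in the parent's phase flips the apparent transmitted
#' haplotype in every offspring simultaneously, whereas a genuine
#' crossover appears in one offspring only. Intervals where a strict
#' majority of offspring Viterbi paths change state are declared switch
#' errors; the parental phase is flipped for all downstream loci and the
#' HMM re-run, iterating to a fixed point (capped; on oscillation the
#' phase with the best total likelihood is kept, with a warning).
#'
#' @param phase 2 x m parental haplotype matrix.
#' @param evidence m x k matrix of per-offspring transmitted-allele
#'   evidence (k >= 2).
#' @param map_cM Cumulative map positions (cM).
#' @param params An [hmm_params()].
#' @return List: corrected `haplotypes`, `n_corrections` (total flipped
#'   intervals), `corrected_intervals` (left site indices).
#' @export
correct_switch_errors <- function(phase, evidence, map_cM,
                                  params = hmm_params()) {
  k <- ncol(evidence)
  if (k < 2) stop("switch-error correction requires >= 2 offspring",
                  call. = FALSE)
  m <- ncol(phase)
  total_loglik <- function(ph) {
    sum(vapply(seq_len(k), function(j) {
      em <- duo_emissions(ph, evidence[, j], params$epsilon)
      r <- haldane_r(pmax(diff(map_cM), 0))
      duo_forward_backward(em, r)$loglik
    }, 0))
  }
  best <- phase; best_ll <- -Inf
  corrected <- integer(0)
  n_corr <- 0L
  for (round in seq_len(params$max_correction_rounds)) {
    paths <- vapply(seq_len(k), function(j)
      duo_viterbi(phase, evidence[, j], map_cM, params), integer(m))
    changes <- paths[-1, , drop = FALSE] != paths[-m, , drop = FALSE]
    flag <- rowSums(changes) > k / 2
    ll <- total_loglik(phase)
    if (ll > best_ll) { best_ll <- ll; best <- phase }
    if (!any(flag)) break
    parity <- c(0L, cumsum(as.integer(flag))) %% 2L
    swap <- parity == 1L
    tmp <- phase[1, swap]
    phase[1, swap] <- phase[2, swap]
    phase[2, swap] <- tmp
    corrected <- c(corrected, which(flag))
    n_corr <- n_corr + sum(flag)
    if (round == params$max_correction_rounds) {
      ll <- total_loglik(phase)
      if (ll > best_ll) { best_ll <- ll; best <- phase }
      warning("switch-error correction did not converge; keeping the ",
              "highest-likelihood phase")
    }
  }
  list(haplotypes = best, n_corrections = n_corr,
       corrected_intervals = unique(corrected))
}

#' Threshold and merge interval posteriors into crossover calls
#'
#' Per-interval recombination posteriors (averaged across `n_iterations`
#' HMM passes when several are supplied) at or above the threshold `t`
#' are emitted; runs of adjacent super-threshold intervals are merged
#' into a single crossover spanning them, so one event spread over
#' sparse markers is not double-counted.
#'
#' @param post Numeric vector of per-interval posteriors, or a matrix
#'   (iterations x intervals) to be column-averaged.
#' @param pos Site bp positions (length intervals + 1).
#' @param params An [hmm_params()].
#' @return `data.frame` with `left_idx`, `right_idx` (site indices,
#'   half-open on the site list), `left_bp`, `right_bp`, `posterior`
#'   (maximum within the merged run).
#' @export
call_crossovers <- function(post, pos, params = hmm_params()) {
  if (is.matrix(post)) post <- colMeans(post)
  stopifnot(length(pos) == length(post) + 1L)
  sel <- post >= params$threshold
  if (!any(sel))
    return(data.frame(left_idx = integer(0), right_idx = integer(0),
                      left_bp = numeric(0), right_bp = numeric(0),
                      posterior = numeric(0)))
  rl <- rle(sel)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  data.frame(left_idx = starts[runs], right_idx = ends[runs] + 1L,
             left_bp = pos[starts[runs]], right_bp = pos[ends[runs] + 1L],
             posterior = vapply(runs, function(q)
               max(post[starts[q]:ends[q]]), 0))
}

#' Enumerate meioses and classify informativeness
#'
#' A meiosis (one parent-to-child transmission) is informative toward
#' recombination when its nuclear family has more than two offspring, or
#' when it is embedded in a three-generation structure: the parent has a
#' recorded parent, or the child has offspring of its own.
#'
#' @param ped Pedigree `data.frame` (`id`, `dam`, `sire`).
#' @return `data.frame` with one row per meiosis: `parent`, `child`,
#'   `parental_sex`, `family_size`, `informative`.
#' @export
informative_meioses <- function(ped) {
  kids <- ped[!is.na(ped$dam) | !is.na(ped$sire), ]
  fam_key <- paste(kids$dam, kids$sire)
  fam_size <- ave(seq_len(nrow(kids)), fam_key, FUN = length)
  has_parent <- setNames(!is.na(ped$dam) | !is.na(ped$sire), ped$id)
  has_kids <- setNames(ped$id %in% c(kids$dam, kids$sire), ped$id)
  rows <- list()
  for (role in c("dam", "sire")) {
    p <- kids[[role]]
    keep <- !is.na(p)
    hp <- unname(has_parent[p[keep]])
    hp[is.na(hp)] <- FALSE
    inf <- fam_size[keep] > 2 | hp | unname(has_kids[kids$id[keep]])
    rows[[role]] <- data.frame(
      parent = p[keep], child = kids$id[keep],
      parental_sex = if (role == "dam") "female" else "male",
      family_size = fam_size[keep], informative = inf,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect crossovers in every informative meiosis of a dataset
#'
#' Orchestrates the duo HMM over a full call set: phases each informative
#' parent (from simulation truth or by Mendelian trio phasing with
#' switch-error correction), deduces each child's transmitted-allele
#' evidence, runs the forward-backward pass per chromosome, and emits
#' thresholded, merged crossover intervals.
#'
#' @param calls Sites x individuals call matrix (columns named by
#'   individual).
#' @param sites Site table (`chrom`, `pos`) aligned to `calls` rows.
#' @param ped Pedigree `data.frame`.
#' @param map Reference `genetic_map` used for transition distances;
#'   marker positions absent from it are linearly interpolated.
#' @param params An [hmm_params()].
#' @param phase `"trio"` (default) or `"truth"` (requires `sim`).
#' @param sim A `sim_data` object supplying true parental haplotypes
#'   when `phase = "truth"`.
#' @param informative_only Restrict to informative meioses (default
#'   `TRUE`).
#' @return List: `events` (crossover table: `parent`, `child`, `chrom`,
#'   `left_idx`, `right_idx`, `left_bp`, `right_bp`, `posterior`,
#'   `parental_sex`), `meioses` (the meiosis table used, with per-meiosis
#'   expected crossover counts `expected_xo` = sum of interval
#'   posteriors).
#' @export
detect_crossovers <- function(calls, sites, ped, map,
                              params = hmm_params(),
                              phase = c("trio", "truth"), sim = NULL,
                              informative_only = TRUE) {
  phase <- match.arg(phase)
  if (phase == "truth" && is.null(sim))
    stop("phase = \"truth\" requires the sim_data object", call. = FALSE)
  mei <- informative_meioses(ped)
  if (informative_only) mei <- mei[mei$informative, , drop = FALSE]
  mei <- mei[mei$parent %in% colnames(calls) &
               mei$child %in% colnames(calls), , drop = FALSE]
  chroms <- unique(sites$chrom)
  map_cM <- interpolate_genetic_map(map, sites$chrom, sites$pos)
  events <- list()
  mei$expected_xo <- 0
  coparent_of <- function(child, parent) {
    row <- ped[ped$id == child, ]
    cp <- if (!is.na(row$dam) && row$dam == parent) row$sire else row$dam
    if (is.na(cp) || !(cp %in% colnames(calls))) NA_character_ else cp
  }
  for (p in unique(mei$parent)) {
    rows_p <- which(mei$parent == p)
    children <- mei$child[rows_p]
    ev_all <- matrix(NA_integer_, nrow(sites), length(children))
    for (j in seq_along(children)) {
      cp <- coparent_of(children[j], p)
      cop_calls <- if (is.na(cp)) rep(NA_integer_, nrow(sites)) else
        calls[, cp]
      ev_all[, j] <- transmitted_allele(calls[, children[j]], cop_calls)
    }
    pidx <- if (phase == "truth") match(p, sim$ped$id) else NA
    for (ch in chroms) {
      si <- which(sites$chrom == ch)
      if (length(si) < 2) next
      if (phase == "truth") {
        ph <- sim$haps[[ch]][c(2L * pidx - 1L, 2L * pidx), , drop = FALSE]
        # truth haplotypes are over the sim site list; map to call sites
        ph <- ph[, match(sites$pos[si],
                         sim$sites$pos[sim$sites$chrom == ch]),
                 drop = FALSE]
      } else {
        # switch-error correction runs inside trio_phase_parent when the
        # parent has two or more offspring
        tp <- trio_phase_parent(calls[si, p],
                                NULL_to_na(ev_all, si, children, calls,
                                           ped, p),
                                calls[si, children, drop = FALSE],
                                map_cM[si], params)
        ph <- tp$haplotypes
      }
      for (j in seq_along(children)) {
        res <- withCallingHandlers(
          duo_hmm_posteriors(ph, ev_all[si, j], map_cM[si], params),
          warning = function(w) invokeRestart("muffleWarning"))
        mi <- rows_p[j]
        mei$expected_xo[mi] <- mei$expected_xo[mi] + sum(res$post_change)
        if (!length(res$post_change)) next
        bound <- c(res$interval_left,
                   res$interval_right[length(res$interval_right)])
        cx <- call_crossovers(res$post_change, sites$pos[si][bound], params)
        cx$left_idx <- bound[cx$left_idx]
        cx$right_idx <- bound[cx$right_idx]
        if (nrow(cx))
          events[[length(events) + 1L]] <- data.frame(
            parent = p, child = children[j], chrom = ch,
            left_idx = cx$left_idx, right_idx = cx$right_idx,
            left_bp = cx$left_bp, right_bp = cx$right_bp,
            posterior = cx$posterior,
            parental_sex = mei$parental_sex[mi],
            stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(parent = character(0), child = character(0),
               chrom = integer(0), left_idx = integer(0),
               right_idx = integer(0), left_bp = numeric(0),
               right_bp = numeric(0), posterior = numeric(0),
               parental_sex = character(0))
  rownames(ev) <- NULL
  list(events = ev, meioses = mei)
}

# internal: co-parent call matrix for trio phasing (NA where unknown)
NULL_to_na <- function(ev_all, si, children, calls, ped, parent) {
  out <- matrix(NA_integer_, length(si), length(children))
  for (j in seq_along(children)) {
    row <- ped[ped$id == children[j], ]
    cp <- if (!is.na(row$dam) && row$dam == parent) row$sire else row$dam
    if (!is.na(cp) && cp %in% colnames(calls)) out[, j] <- calls[si, cp]
  }
  out
}
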