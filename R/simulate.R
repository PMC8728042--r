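#' Simulate a multigenerational breeding pedigree
#'
#' Founders (cohort 0) have no recorded parents. Each later cohort is
#' filled with full-sib families whose two parents are drawn from all
#' earlier cohorts, so the pedigree contains both parent-offspring duos
#' and three-generation structures. Sex is a property of the meiosis, not
#' the individual: the same individual may act as dam in one cross and as
#' sire in another, as in monoecious cassava.
#'
#' @param config A [sim_config()] object.
#' @return A `pedigree` object: a `data.frame` with columns `id`, `dam`,
#'   `sire` (`NA` for founders) and `cohort`.
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 4, cohort_sizes = c(6),
#'                                     n_chromosomes = 1, seed = 2))
#' table(ped$cohort)
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set_stage_seed(config$seed, "pedigree")
  ids <- sprintf("F%04d", seq_len(config$n_founders))
  ped <- data.frame(id = ids, dam = NA_character_, sire = NA_character_,
                    cohort = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(config$cohort_sizes)) {
    pool <- ped$id[ped$cohort < k]
    if (length(pool) < 2)
      stop("cohort ", k, " has fewer than two candidate parents",
           call. = FALSE)
    n <- config$cohort_sizes[k]
    sizes <- integer(0)
    while (sum(sizes) < n) {
      big <- runif(1) < config$large_family_frac
      sizes <- c(sizes, if (big) sample(3:6, 1) else sample(1:2, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0]
    dam <- character(n); sire <- character(n)
    at <- 0
    for (s in sizes) {
      pr <- sample(pool, 2)
      dam[at + seq_len(s)] <- pr[1]
      sire[at + seq_len(s)] <- pr[2]
      at <- at + s
    }
    ped <- rbind(ped, data.frame(
      id = sprintf("C%d_%04d", k, seq_len(n)), dam = dam, sire = sire,
      cohort = k, stringsAsFactors = FALSE))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Draw SNP site positions
#'
#' Uniformly scattered, sorted, unique positions per chromosome, plus a
#' population alternate-allele frequency per site used when drawing
#' founder haplotypes.
#'
#' @inheritParams simulate_pedigree
#' @return `data.frame` with columns `chrom`, `pos`, `alt_freq` and the
#'   logical `diagnostic` marking donor-diagnostic sites (recipient pool
#'   fixed for the reference allele, donor haplotype carries the
#'   alternate), drawn at rate `donor_divergence` inside introgression
#'   regions.
#' @export
simulate_sites <- function(config) {
  validate_sim_config(config)
  set_stage_seed(config$seed, "sites")
  out <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chrom_bp[ch], config$n_sites[ch]))
    df <- data.frame(chrom = ch, pos = as.numeric(pos),
                     alt_freq = runif(length(pos), 0.05, 0.95),
                     diagnostic = FALSE)
    out[[ch]] <- df
  }
  sites <- do.call(rbind, out)
  reg <- config$introgression_regions
  if (!is.null(reg) && config$donor_divergence > 0) {
    for (r in seq_len(nrow(reg))) {
      inr <- sites$chrom == reg$chrom[r] &
        sites$pos >= reg$start[r] & sites$pos < reg$end[r]
      sites$diagnostic[inr] <- runif(sum(inr)) < config$donor_divergence
    }
  }
  # recipient pool is fixed for REF at diagnostic sites
  sites$alt_freq[sites$diagnostic] <- 0
  rownames(sites) <- NULL
  sites
}

#' Linear baseline genetic map for simulated sites
#'
#' The simulator's ground-truth (reference-style) map: genetic position is
#' linear in physical position, with each chromosome spanning its
#' configured reference length.
#'
#' @inheritParams simulate_pedigree
#' @param sites Site table from [simulate_sites()].
#' @return A `genetic_map` `data.frame` with columns `chrom`, `pos`, `cM`.
#' @export
sim_base_map <- function(config, sites) {
  map <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    cM = config$chrom_cM[sites$chrom] * sites$pos /
                      config$chrom_bp[sites$chrom])
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate founder haplotypes with donor introgression segments
#'
#' Each founder receives two haplotypes drawn site-wise from the
#' population allele frequencies. In each introgression region, every
#' founder haplotype is independently replaced by the donor haplotype with
#' probability `donor_founder_freq`; donor segments carry the
#' donor-specific alternate allele at the region's diagnostic sites and
#' recipient-like alleles elsewhere.
#'
#' @inheritParams sim_base_map
#' @return A list with per-chromosome entries `haps` (integer matrix,
#'   `2 * n_founders` rows of 0/1 alleles) and `ancestry` (logical matrix,
#'   `TRUE` where the allele is donor-derived).
#' @export
simulate_founder_haplotypes <- function(config, sites) {
  validate_sim_config(config)
  set_stage_seed(config$seed, "founders")
  nh <- 2L * config$n_founders
  haps <- vector("list", config$n_chromosomes)
  anc <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    s <- sites[sites$chrom == ch, ]
    m <- nrow(s)
    H <- matrix(rbinom(nh * m, 1L, rep(s$alt_freq, each = nh)), nh, m)
    A <- matrix(FALSE, nh, m)
    reg <- config$introgression_regions
    if (!is.null(reg)) {
      for (r in which(reg$chrom == ch)) {
        idx <- which(s$pos >= reg$start[r] & s$pos < reg$end[r])
        if (!length(idx)) next
        donor <- as.integer(s$diagnostic[idx]) # donor-specific allele = ALT
        # non-diagnostic donor alleles look recipient-like
        nd <- which(donor == 0L)
        if (length(nd))
          donor[nd] <- rbinom(length(nd), 1L, s$alt_freq[idx][nd])
        carrier <- runif(nh) < config$donor_founder_freq
        if (any(carrier)) {
          H[carrier, idx] <- rep(donor, each = sum(carrier))
          A[carrier, idx] <- TRUE
        }
      }
    }
    haps[[ch]] <- H
    anc[[ch]] <- A
  }
  list(haps = haps, ancestry = anc)
}

# Stationary renewal process positions on [0, L] (Morgans) for many
# sequences at once. shape == 1 is an exact homogeneous Poisson process;
# shape > 1 uses a 12-Morgan burn-in start, which is stationary to
# numerical accuracy for the map lengths used here.
sample_renewal_positions <- function(L, shape = 1) {
  n <- length(L)
  if (n == 0L || all(L <= 0))
    return(data.frame(seq = integer(0), pos = numeric(0)))
  if (shape == 1) {
    k <- rpois(n, pmax(L, 0))
    seqi <- rep.int(seq_len(n), k)
    pos <- runif(length(seqi)) * L[seqi]
    o <- order(seqi, pos)
    return(data.frame(seq = seqi[o], pos = pos[o]))
  }
  burn <- 12
  target <- burn + pmax(L, 0)
  nc <- ceiling(max(target) + 6 * sqrt(max(target) / shape) + 8)
  cum <- apply(matrix(rgamma(n * nc, shape = shape, rate = shape), n, nc),
               1, cumsum) # nc x n
  while (any(cum[nrow(cum), ] < target)) {
    extra <- apply(matrix(rgamma(n * 8, shape = shape, rate = shape), n, 8),
                   1, cumsum)
    cum <- rbind(cum, sweep(extra, 2, cum[nrow(cum), ], `+`))
  }
  seqi <- rep(seq_len(n), each = nrow(cum))
  pos <- as.vector(cum) - burn
  keep <- pos > 0 & pos <= L[seqi]
  data.frame(seq = seqi[keep], pos = pos[keep])
}

# Piecewise-linear adjusted map for one meiosis on one chromosome.
# Returns knot positions (bp) and adjusted cumulative cM at the knots.
adjusted_map_knots <- function(config, chrom, sex, dosage) {
  bp <- config$chrom_bp[chrom]
  cm <- config$chrom_cM[chrom]
  sexmult <- if (identical(sex, "female")) config$female_rate_multiplier else 1
  knots <- c(0, bp)
  reg <- config$introgression_regions
  rows <- if (is.null(reg)) integer(0) else which(reg$chrom == chrom)
  if (length(rows))
    knots <- sort(unique(c(knots, reg$start[rows], reg$end[rows])))
  dens <- rep(cm / bp * sexmult, length(knots) - 1)
  if (length(rows) && !is.null(dosage)) {
    mids <- (knots[-1] + knots[-length(knots)]) / 2
    for (r in rows) {
      d <- dosage[[as.character(r)]]
      if (is.null(d) || is.na(d) || d <= 0) next
      inside <- mids >= reg$start[r] & mids < reg$end[r]
      dens[inside] <- dens[inside] * config$introgression_suppression^d
    }
  }
  list(knots = knots, cum = c(0, cumsum(dens * diff(knots))))
}

#' Simulate one meiosis
#'
#' Draws crossover positions from a stationary gamma renewal process on
#' the adjusted genetic-map scale (female multiplier applied to female
#' meioses; introgression suppression applied once per donor copy carried
#' by the parent inside each region) and assembles the transmitted gamete
#' by alternating the two parental haplotypes at the crossover points.
#' With `interference_shape = 1` the crossover process is exactly Poisson.
#'
#' This function draws from the current RNG stream (no reseeding) so that
#' many meioses can be simulated in sequence reproducibly.
#'
#' @param haps List (per chromosome) of 2-row 0/1 matrices: the parent's
#'   haplotypes over the chromosome's sites.
#' @param parental_sex `"male"` or `"female"` (the role in this cross).
#' @param sites Site table from [simulate_sites()].
#' @param config A [sim_config()] object.
#' @param ancestry Optional list like `haps` of logical donor-origin
#'   matrices, used to determine carried introgression copies.
#' @return A list with `crossovers` (`data.frame` `chrom`, `pos` in bp),
#'   `gamete` and `gamete_ancestry` (per-chromosome vectors), and
#'   `dosage` (carried donor copies per introgression region).
#' @export
simulate_meiosis <- function(haps, parental_sex, sites, config,
                             ancestry = NULL) {
  reg <- config$introgression_regions
  dosage <- NULL
  if (!is.null(reg) && !is.null(ancestry)) {
    dosage <- list()
    for (r in seq_len(nrow(reg))) {
      ch <- reg$chrom[r]
      s <- sites[sites$chrom == ch, ]
      idx <- which(s$pos >= reg$start[r] & s$pos < reg$end[r])
      dosage[[as.character(r)]] <- if (length(idx))
        sum(rowMeans(ancestry[[ch]][, idx, drop = FALSE]) > 0.5) else 0L
    }
  }
  xo <- vector("list", config$n_chromosomes)
  gam <- vector("list", config$n_chromosomes)
  ganc <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    km <- adjusted_map_knots(config, ch, parental_sex, dosage)
    L <- km$cum[length(km$cum)] / 100 # Morgans
    pos_cm <- sample_renewal_positions(L, config$interference_shape)$pos * 100
    if (config$obligate_crossover && L > 0) {
      tries <- 0
      while (length(pos_cm) == 0 && tries < 100) {
        pos_cm <- sample_renewal_positions(L, config$interference_shape)$pos * 100
        tries <- tries + 1
      }
    }
    pos_bp <- if (length(pos_cm))
      approx(km$cum, km$knots, xout = sort(pos_cm), ties = "ordered")$y
    else numeric(0)
    s <- sites[sites$chrom == ch, ]
    start <- sample(1:2, 1)
    nb <- findInterval(s$pos, pos_bp)
    hi <- ((start - 1L + nb) %% 2L) + 1L
    pick <- cbind(hi, seq_len(nrow(s)))
    gam[[ch]] <- haps[[ch]][pick]
    ganc[[ch]] <- if (!is.null(ancestry)) ancestry[[ch]][pick] else
      rep(FALSE, nrow(s))
    xo[[ch]] <- if (length(pos_bp))
      data.frame(chrom = ch, pos = pos_bp) else NULL
  }
  list(crossovers = if (length(cxo <- do.call(rbind, xo))) cxo else
         data.frame(chrom = integer(0), pos = numeric(0)),
       gamete = gam, gamete_ancestry = ganc, dosage = dosage)
}

#' Simulate GBS allele depths from true genotypes
#'
#' Per site-by-individual cell, total depth is Poisson(`mean_depth`),
#' zeroed with probability `missing_rate`; the alternate-read count is
#' Binomial(depth, \eqn{p_B}) with \eqn{p_B = e, 0.5, 1 - e} for genotypes
#' AA, AB, BB — the generative inverse of the genotype-calling likelihood.
#'
#' @param geno Integer matrix (sites x individuals) of alternate-allele
#'   dosages 0/1/2.
#' @param config A [sim_config()] object.
#' @param sites Optional site table to attach.
#' @param samples Optional sample names.
#' @return An [ad_matrix()] object.
#' @export
simulate_gbs_reads <- function(geno, config, sites = NULL, samples = NULL) {
  set_stage_seed(config$seed, "gbs")
  m <- nrow(geno); n <- ncol(geno)
  depth <- rpois(m * n, config$mean_depth)
  if (config$missing_rate > 0)
    depth[runif(m * n) < config$missing_rate] <- 0L
  pB <- c(config$error_rate, 0.5, 1 - config$error_rate)[as.vector(geno) + 1L]
  alt <- rbinom(m * n, depth, pB)
  ref <- matrix(depth - alt, m, n)
  alt <- matrix(alt, m, n)
  if (is.null(samples)) samples <- colnames(geno)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))
  ad_matrix(sites = sites, ref = ref, alt = alt, samples = samples)
}

#' Simulate a complete pedigree-GBS dataset with ground truth
#'
#' End-to-end generator: pedigree, sites, founder haplotypes (with donor
#' introgression segments), per-meiosis crossovers dropped down the
#' pedigree, true genotypes, and GBS-like allele depths. All ground truth
#' (crossover positions, haplotypes, donor ancestry, introgression
#' dosages) is returned so detector recall and false discovery are
#' computable exactly.
#'
#' @inheritParams simulate_pedigree
#' @return A `sim_data` list: `config`, `ped`, `sites`, `map` (baseline
#'   [sim_base_map()]), `haps` and `ancestry` (per-chromosome matrices
#'   with two rows per individual, in pedigree order), `geno`
#'   (sites x individuals truth dosage matrix), `ad` (GBS depths),
#'   `truth_crossovers` (`parent`, `child`, `chrom`, `pos`,
#'   `parental_sex`), and `truth_dosage` (`id`, `region`, `dosage`).
#' @examples
#' sim <- simulate_cross_data(sim_config(n_founders = 6, cohort_sizes = 8,
#'   n_chromosomes = 1, n_sites = 40, introgression_regions = NULL, seed = 3))
#' dim(sim$geno)
#' @export
simulate_cross_data <- function(config) {
  validate_sim_config(config)
  ped <- simulate_pedigree(config)
  sites <- simulate_sites(config)
  map <- sim_base_map(config, sites)
  fh <- simulate_founder_haplotypes(config, sites)
  set_stage_seed(config$seed, "meiosis")

  n_ind <- nrow(ped)
  idx_of <- setNames(seq_len(n_ind), ped$id)
  m_by_chrom <- tabulate(sites$chrom, config$n_chromosomes)
  haps <- lapply(seq_len(config$n_chromosomes), function(ch)
    matrix(NA_integer_, 2L * n_ind, m_by_chrom[ch]))
  anc <- lapply(seq_len(config$n_chromosomes), function(ch)
    matrix(FALSE, 2L * n_ind, m_by_chrom[ch]))
  nf <- config$n_founders
  for (ch in seq_len(config$n_chromosomes)) {
    haps[[ch]][seq_len(2L * nf), ] <- fh$haps[[ch]]
    anc[[ch]][seq_len(2L * nf), ] <- fh$ancestry[[ch]]
  }

  xo_list <- list()
  for (i in which(!is.na(ped$dam))) {
    child <- ped$id[i]
    for (role in c("dam", "sire")) {
      par <- ped[[role]][i]
      pi <- idx_of[[par]]
      ph <- lapply(haps, function(H) H[c(2L * pi - 1L, 2L * pi), , drop = FALSE])
      pa <- lapply(anc, function(A) A[c(2L * pi - 1L, 2L * pi), , drop = FALSE])
      sex <- if (role == "dam") "female" else "male"
      mei <- simulate_meiosis(ph, sex, sites, config, ancestry = pa)
      row <- if (role == "dam") 2L * i - 1L else 2L * i
      for (ch in seq_len(config$n_chromosomes)) {
        haps[[ch]][row, ] <- mei$gamete[[ch]]
        anc[[ch]][row, ] <- mei$gamete_ancestry[[ch]]
      }
      if (nrow(mei$crossovers))
        xo_list[[length(xo_list) + 1L]] <- data.frame(
          parent = par, child = child, chrom = mei$crossovers$chrom,
          pos = mei$crossovers$pos, parental_sex = sex,
          stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(xo_list)) do.call(rbind, xo_list) else
    data.frame(parent = character(0), child = character(0),
               chrom = integer(0), pos = numeric(0),
               parental_sex = character(0))

  geno <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
    H <- haps[[ch]]
    t(H[seq(1, nrow(H), 2), , drop = FALSE] +
        H[seq(2, nrow(H), 2), , drop = FALSE])
  })) # sites x individuals, chromosomes stacked in order
  colnames(geno) <- ped$id

  ad <- simulate_gbs_reads(geno, config, sites = sites, samples = ped$id)

  reg <- config$introgression_regions
  td <- NULL
  if (!is.null(reg)) {
    rows <- list()
    for (r in seq_len(nrow(reg))) {
      ch <- reg$chrom[r]
      s <- sites[sites$chrom == ch, ]
      idx <- which(s$pos >= reg$start[r] & s$pos < reg$end[r])
      if (!length(idx)) next
      A <- anc[[ch]]
      # mean donor dosage over region sites, rounded with the same
      # half-up ranges the classifier uses; recombinant gametes make
      # integer "copies" ill-defined, the rounded dosage is not
      d1 <- rowMeans(A[seq(1, nrow(A), 2), idx, drop = FALSE])
      d2 <- rowMeans(A[seq(2, nrow(A), 2), idx, drop = FALSE])
      mu <- d1 + d2
      rows[[r]] <- data.frame(id = ped$id, region = r,
                              mean_dosage = mu,
                              dosage = ifelse(mu < 0.5, 0L,
                                              ifelse(mu < 1.5, 1L, 2L)),
                              stringsAsFactors = FALSE)
    }
    td <- do.call(rbind, rows)
  }

  structure(list(config = config, ped = ped, sites = sites, map = map,
                 haps = haps, ancestry = anc, geno = geno, ad = ad,
                 truth_crossovers = truth, truth_dosage = td),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("<sim_data>", nrow(x$ped), "individuals,", nrow(x$sites), "sites,",
      nrow(x$truth_crossovers), "true crossovers\n")
  invisible(x)
}

#' Simulate ground-truth crossover events for many meioses at once
#'
#' Fast batch generator used for statistical power and calibration work:
#' draws only the crossover positions (no haplotypes or reads) for a set
#' of meioses, assigning meioses to parents round-robin. Events are
#' returned in the same table shape as detected crossovers, with
#' degenerate (zero-width) intervals at the true positions and posterior
#' 1, so they feed directly into the map-building and statistics
#' functions.
#'
#' @param config A [sim_config()] object.
#' @param n_female,n_male Number of female / male meioses.
#' @param n_parents Number of distinct parents the meioses are spread
#'   over (split evenly between the sexes in role).
#' @param parent_dosage Optional `data.frame` (`parent`, `region`,
#'   `dosage`) of carried donor copies per introgression region; parents
#'   absent from the table carry none.
#' @param seed Optional seed (defaults to the config's).
#' @return A list: `events` (crossover table with `parent`, `child`,
#'   `chrom`, `left_bp`, `right_bp`, `posterior`, `parental_sex`),
#'   `meioses` (`parent`, `child`, `parental_sex` — one row per meiosis,
#'   including zero-crossover ones).
#' @export
simulate_crossover_events <- function(config, n_female, n_male,
                                      n_parents = 20L,
                                      parent_dosage = NULL,
                                      seed = config$seed) {
  validate_sim_config(config)
  set_stage_seed(seed, "events")
  n <- n_female + n_male
  sex <- rep(c("female", "male"), c(n_female, n_male))
  parent <- sprintf("P%03d", rep_len(seq_len(n_parents), n))
  # keep each parent's meioses within one sex-of-role half where possible
  meio <- data.frame(parent = parent,
                     child = sprintf("M%05d", seq_len(n)),
                     parental_sex = sex, stringsAsFactors = FALSE)
  dos_of <- function(p, r) {
    if (is.null(parent_dosage)) return(0)
    hit <- parent_dosage$parent == p & parent_dosage$region == r
    if (any(hit)) parent_dosage$dosage[which(hit)[1]] else 0
  }
  # group meioses by (sex, dosage signature) so lengths are shared
  reg <- config$introgression_regions
  sig <- vapply(seq_len(n), function(i) {
    if (is.null(reg)) return(meio$parental_sex[i])
    paste(meio$parental_sex[i],
          paste(vapply(seq_len(nrow(reg)),
                       function(r) dos_of(meio$parent[i], r), 0),
                collapse = ","))
  }, "")
  out <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    for (g in unique(sig)) {
      ii <- which(sig == g)
      dosage <- NULL
      if (!is.null(reg)) {
        dosage <- as.list(as.numeric(strsplit(strsplit(g, " ")[[1]][2],
                                              ",")[[1]]))
        names(dosage) <- as.character(seq_len(nrow(reg)))
      }
      km <- adjusted_map_knots(config, ch, meio$parental_sex[ii[1]], dosage)
      L <- km$cum[length(km$cum)] / 100
      rp <- sample_renewal_positions(rep(L, length(ii)),
                                     config$interference_shape)
      if (!nrow(rp)) next
      bp <- approx(km$cum, km$knots, xout = rp$pos * 100, ties = "ordered")$y
      out[[length(out) + 1L]] <- data.frame(
        parent = meio$parent[ii[rp$seq]], child = meio$child[ii[rp$seq]],
        chrom = ch, left_bp = bp, right_bp = bp, posterior = 1,
        parental_sex = meio$parental_sex[ii[rp$seq]],
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(parent = character(0), child = character(0),
               chrom = integer(0), left_bp = numeric(0),
               right_bp = numeric(0), posterior = numeric(0),
               parental_sex = character(0))
  rownames(events) <- NULL
  list(events = events, meioses = meio)
}

#' Simulate donor and recipient reference panels
#'
#' Draws non-admixed panel genotypes for identifying introgression
#' diagnostic markers: recipient individuals from the recipient allele
#' frequencies; donor individuals carry the donor-specific alternate
#' allele at all diagnostic sites and recipient-like draws elsewhere.
#'
#' @inheritParams sim_base_map
#' @param n_donor,n_recipient Panel sizes. The recipient panel must be
#'   large enough that chance fixation of a polymorphic site is rare
#'   (at 30 individuals the probability is below 0.1%), otherwise
#'   spurious rule-2 diagnostic markers appear.
#' @return List of two integer dosage matrices (sites x individuals):
#'   `donor`, `recipient`.
#' @export
simulate_reference_panels <- function(config, sites, n_donor = 12,
                                      n_recipient = 30) {
  set_stage_seed(config$seed, "panels")
  m <- nrow(sites)
  draw <- function(n) {
    matrix(rbinom(m * n, 1L, rep(sites$alt_freq, n)) +
             rbinom(m * n, 1L, rep(sites$alt_freq, n)), m, n)
  }
  recip <- draw(n_recipient)
  donor <- draw(n_donor)
  donor[sites$diagnostic, ] <- 2L
  list(donor = donor, recipient = recip)
}
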