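test_that("pedigree structure follows the configured cohorts", {
  # minimal family: two founders, one cohort of three full sibs
  cfg <- sim_config(n_founders = 2, cohort_sizes = 3, n_chromosomes = 1,
                    n_sites = 10, introgression_regions = NULL, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 5)
  kids <- ped[!is.na(ped$dam), ]
  expect_equal(nrow(kids), 3)
  expect_equal(length(unique(paste(pmin(kids$dam, kids$sire),
                                   pmax(kids$dam, kids$sire)))), 1)
  expect_true(all(is.na(ped$dam[ped$cohort == 0])))

  # four-cohort breeding-program shape: 7432 individuals in total
  big <- sim_config(seed = 2)
  ped4 <- simulate_pedigree(big)
  expect_equal(nrow(ped4), 7432)
  expect_equal(as.vector(table(ped4$cohort)),
               c(236, 258, 2334, 2515, 2089))
  # every parent comes from an earlier cohort
  idx <- setNames(ped4$cohort, ped4$id)
  kids4 <- ped4[!is.na(ped4$dam), ]
  expect_true(all(idx[kids4$dam] < kids4$cohort))
  expect_true(all(idx[kids4$sire] < kids4$cohort))

  # determinism and seed sensitivity
  expect_identical(simulate_pedigree(big), ped4)
  expect_false(identical(simulate_pedigree(sim_config(seed = 3)), ped4))

  # impossible structure errors
  expect_error(sim_config(n_founders = 1), "two founders")
})

test_that("founder haplotypes carry donor segments at the configured divergence", {
  base <- function(div, seed = 1) {
    sim_config(n_founders = 20, cohort_sizes = 2, n_chromosomes = 1,
               chrom_bp = 10e6, n_sites = 1000,
               introgression_regions = data.frame(chrom = 1, start = 0,
                                                  end = 10e6),
               donor_divergence = div, donor_founder_freq = 0.5,
               seed = seed)
  }
  # degenerate divergence: no diagnostic sites, donor == recipient pool
  s0 <- simulate_sites(base(0))
  expect_equal(sum(s0$diagnostic), 0)

  # saturation: every in-region site is donor-diagnostic
  s1 <- simulate_sites(base(1))
  expect_equal(sum(s1$diagnostic), 1000)
  fh <- simulate_founder_haplotypes(base(1), s1)
  carriers <- rowMeans(fh$ancestry[[1]]) > 0.5
  expect_true(all(fh$haps[[1]][carriers, ] == 1L))
  expect_true(all(fh$haps[[1]][!carriers, s1$diagnostic] == 0L))

  # binomial count of diagnostic sites at the cassava-like divergence,
  # pooled over seeds against the exact binomial 99% interval
  n_diag <- vapply(1:10, function(s)
    sum(simulate_sites(base(0.022, seed = s))$diagnostic), 0)
  lo <- qbinom(0.005, 10 * 1000, 0.022)
  hi <- qbinom(0.995, 10 * 1000, 0.022)
  expect_gte(sum(n_diag), lo)
  expect_lte(sum(n_diag), hi)

  # region outside chromosome bounds is a configuration error
  expect_error(sim_config(n_chromosomes = 1, chrom_bp = 1e6,
                          introgression_regions = data.frame(
                            chrom = 1, start = 0, end = 2e6)),
               "bounds")
})

test_that("meiosis crossover counts follow the configured renewal process", {
  cfg <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                    chrom_bp = 10e6, chrom_cM = 100, n_sites = 20,
                    introgression_regions = NULL, seed = 11)
  # 100 cM Poisson chromosome: mean 1 crossover per meiosis
  ev <- simulate_crossover_events(cfg, n_female = 0, n_male = 10000,
                                  n_parents = 10)
  n <- nrow(ev$events)
  expect_gte(n, qpois(0.005, 10000))
  expect_lte(n, qpois(0.995, 10000))

  # zero-length map: never a crossover
  cfg0 <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                     chrom_bp = 10e6, chrom_cM = 0, n_sites = 20,
                     introgression_regions = NULL, seed = 1)
  ev0 <- simulate_crossover_events(cfg0, 500, 500)
  expect_equal(nrow(ev0$events), 0)

  # female multiplier recovered from 10,000 paired draws
  cfgf <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                     chrom_bp = 10e6, chrom_cM = 200, n_sites = 20,
                     female_rate_multiplier = 1.2,
                     introgression_regions = NULL, seed = 12)
  evf <- simulate_crossover_events(cfgf, 10000, 10000)
  ratio <- sum(evf$events$parental_sex == "female") /
    sum(evf$events$parental_sex == "male")
  expect_gt(ratio, 1.13)
  expect_lt(ratio, 1.27)
})

test_that("renewal spacings are exponential without interference and
           regularized by it", {
  set.seed(42)
  # one long Poisson sequence: spacings should look exponential
  pos <- pedrec:::sample_renewal_positions(5300, 1)$pos
  sp <- diff(sort(pos))[1:5000]
  ks <- suppressWarnings(ks.test(sp, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
  # interference reduces the coefficient of variation of spacings
  pos5 <- pedrec:::sample_renewal_positions(5300, 5)$pos
  sp5 <- diff(sort(pos5))[1:5000]
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(sp5), cv(sp))
  expect_equal(cv(sp5), sqrt(1 / 5), tolerance = 0.1)
})

test_that("gamete alleles come from the parental haplotypes and switch only
           at crossovers", {
  sim <- shared_sim()
  ped <- sim$ped
  tr <- sim$truth_crossovers
  for (i in which(!is.na(ped$dam))[1:10]) {
    child <- ped$id[i]
    for (role in c("dam", "sire")) {
      par <- ped[[role]][i]
      pi <- match(par, ped$id)
      for (ch in 1:2) {
        gam <- sim$haps[[ch]][if (role == "dam") 2L * i - 1L else 2L * i, ]
        ph <- sim$haps[[ch]][c(2L * pi - 1L, 2L * pi), ]
        expect_true(all(gam == ph[1, ] | gam == ph[2, ]))
        # switches only at recorded crossover positions
        xo <- sort(tr$pos[tr$parent == par & tr$child == child &
                            tr$chrom == ch &
                            tr$parental_sex ==
                            ifelse(role == "dam", "female", "male")])
        pos <- sim$sites$pos[sim$sites$chrom == ch]
        segment <- findInterval(pos, xo)
        hetp <- ph[1, ] != ph[2, ]
        # within a segment the gamete sticks to one haplotype
        for (s in unique(segment)) {
          sel <- segment == s & hetp
          if (sum(sel) > 1)
            expect_equal(length(unique((gam == ph[1, ])[sel])), 1)
        }
      }
    }
  }
})

test_that("GBS read depths follow the binomial emission model", {
  cfg <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                    n_sites = 10, introgression_regions = NULL,
                    mean_depth = 100, missing_rate = 0, seed = 5)
  geno <- matrix(1L, 1000, 1) # heterozygous cells
  ad <- simulate_gbs_reads(geno, cfg)
  frac <- sum(ad$alt) / sum(ad$ref + ad$alt)
  n <- sum(ad$ref + ad$alt)
  expect_gt(frac, qbinom(0.005, n, 0.5) / n)
  expect_lt(frac, qbinom(0.995, n, 0.5) / n)

  # no coverage at all
  cfg0 <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                     n_sites = 10, introgression_regions = NULL,
                     mean_depth = 0, seed = 5)
  ad0 <- simulate_gbs_reads(matrix(1L, 50, 4), cfg0)
  expect_true(all(ad0$ref == 0L & ad0$alt == 0L))

  # error-free limit: homozygous reference never yields alternate reads
  cfge <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                     n_sites = 10, introgression_regions = NULL,
                     mean_depth = 30, error_rate = 0, missing_rate = 0,
                     seed = 5)
  ade <- simulate_gbs_reads(matrix(0L, 200, 2), cfge)
  expect_true(all(ade$alt == 0L))
})

test_that("identical configurations give bit-identical datasets", {
  cfg <- small_config(seed = 99)
  a <- simulate_cross_data(cfg)
  b <- simulate_cross_data(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$ad$ref, b$ad$ref)
  expect_identical(a$truth_crossovers, b$truth_crossovers)
  c_ <- simulate_cross_data(small_config(seed = 100))
  expect_false(identical(a$geno, c_$geno))
})

test_that("introgression suppression shrinks in-region map length per copy", {
  cfg <- sim_config(n_founders = 2, cohort_sizes = 2, n_chromosomes = 1,
                    chrom_bp = 30e6, chrom_cM = 100, n_sites = 20,
                    introgression_regions = data.frame(chrom = 1,
                                                       start = 10e6,
                                                       end = 20e6),
                    introgression_suppression = 0.3, seed = 21)
  in_region <- function(dos) {
    pd <- data.frame(parent = "P001", region = 1, dosage = dos)
    ev <- simulate_crossover_events(cfg, 4000, 0, n_parents = 1,
                                    parent_dosage = pd)$events
    sum(ev$left_bp >= 10e6 & ev$left_bp < 20e6)
  }
  n0 <- in_region(0); n1 <- in_region(1); n2 <- in_region(2)
  # region holds 1/3 of the map; multiplier 0.3 per carried copy
  expect_equal(n1 / n0, 0.3, tolerance = 0.25)
  expect_equal(n2 / n0, 0.09, tolerance = 0.5)
})
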