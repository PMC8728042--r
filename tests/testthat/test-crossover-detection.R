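test_that("transmitted-allele deduction follows Mendelian arithmetic", {
  # focal parent AB throughout; co-parent AA
  expect_equal(transmitted_allele(2L, 0L), -1L)  # child BB impossible
  expect_equal(transmitted_allele(1L, 0L), 1L)   # child AB -> B transmitted
  expect_equal(transmitted_allele(0L, 0L), 0L)
  # het or missing co-parent leaves a het child ambiguous
  expect_true(is.na(transmitted_allele(1L, 1L)))
  expect_true(is.na(transmitted_allele(1L, NA)))
  expect_equal(transmitted_allele(2L, NA), 1L)
  expect_equal(transmitted_allele(c(0L, 1L, 2L), c(2L, 2L, 2L)),
               c(-1L, 0L, 1L))
})

test_that("duo HMM posteriors behave at the limits", {
  m <- 10
  phase <- rbind(rep(0L, m), rep(1L, m))
  map <- seq(0, 18, by = 2)
  # uninformative evidence everywhere: too few informative sites
  expect_warning(res <- duo_hmm_posteriors(phase, rep(NA_integer_, m), map),
                 "informative")
  expect_equal(res$n_informative, 0)

  # full-chain mode with evidence only at the ends: interior interval
  # posteriors equal the map transition probabilities (prior dominates)
  ev <- rep(NA_integer_, m); ev[1] <- 0L; ev[m] <- 0L
  res2 <- duo_hmm_posteriors(phase, ev, map, collapse = FALSE)
  r <- 0.5 * (1 - exp(-2 * 2 / 100))
  expect_equal(res2$post_change[5], r, tolerance = 0.02)

  # zero map distance means zero recombination posterior
  map0 <- rep(0, m)
  ev3 <- c(0L, 1L, rep(NA_integer_, m - 2))
  res3 <- duo_hmm_posteriors(phase, ev3, map0, collapse = FALSE)
  expect_equal(res3$post_change, rep(0, m - 1))

  # 20 informative error-free sites switching haplotype between 10 and 11
  m2 <- 20
  ph2 <- rbind(rep(0L, m2), rep(1L, m2))
  ev4 <- c(rep(0L, 10), rep(1L, 10))
  map2 <- seq(0, by = 1, length.out = m2)
  res4 <- duo_hmm_posteriors(ph2, ev4, map2, hmm_params(epsilon = 0.001))
  expect_gt(res4$post_change[10], 0.99)
  expect_true(all(res4$post_change[-10] < 0.01))
  # expected crossover count is the posterior sum, close to one here
  expect_equal(sum(res4$post_change), 1, tolerance = 0.05)
})

test_that("crossover calling thresholds and merges interval posteriors", {
  pos <- c(0, 100, 200, 300, 400)
  # exactly at threshold is emitted
  cx <- call_crossovers(c(0, 0.5, 0, 0), pos)
  expect_equal(nrow(cx), 1)
  expect_equal(cx$left_idx, 2L)
  expect_equal(cx$right_idx, 3L)
  # nothing super-threshold, nothing emitted
  expect_equal(nrow(call_crossovers(rep(0, 4), pos)), 0)
  # adjacent super-threshold intervals merge into one event
  cx2 <- call_crossovers(c(0.6, 0.7, 0, 0.9), pos)
  expect_equal(nrow(cx2), 2)
  expect_equal(cx2$left_idx[1], 1L)
  expect_equal(cx2$right_idx[1], 3L)
  expect_equal(cx2$posterior[1], 0.7)
  # iteration averaging: a matrix of repeated posteriors equals one pass
  expect_equal(call_crossovers(rbind(c(0, 0.6, 0, 0), c(0, 0.6, 0, 0)), pos),
               call_crossovers(c(0, 0.6, 0, 0), pos))
})

test_that("trio phasing recovers parental haplotypes from five offspring", {
  cfg <- sim_config(n_founders = 2, cohort_sizes = 5, n_chromosomes = 1,
                    chrom_bp = 20e6, chrom_cM = 100, n_sites = 200,
                    introgression_regions = NULL, seed = 41)
  sim <- simulate_cross_data(cfg)
  calls <- sim$geno; colnames(calls) <- sim$ped$id # error-free genotypes
  p <- "F0001"
  kids <- sim$ped$id[!is.na(sim$ped$dam)]
  cop <- matrix(calls[, "F0002"], nrow(calls), length(kids))
  map_cM <- interpolate_genetic_map(sim$map, sim$sites$chrom, sim$sites$pos)
  tp <- trio_phase_parent(calls[, p], cop, calls[, kids], map_cM)
  truth <- sim$haps[[1]][1:2, ]
  het <- calls[, p] == 1L
  ok <- het & !is.na(tp$haplotypes[1, ])
  agree <- mean(tp$haplotypes[1, ok] == truth[1, ok])
  # phase defined up to a chromosome-wide flip
  expect_gte(max(agree, 1 - agree), 0.99)
  expect_gte(mean(ok[het]), 0.5)
})

test_that("switch errors are detected and corrected by offspring majority", {
  cfg <- sim_config(n_founders = 2, cohort_sizes = 6, n_chromosomes = 1,
                    chrom_bp = 20e6, chrom_cM = 50, n_sites = 120,
                    introgression_regions = NULL, seed = 43)
  sim <- simulate_cross_data(cfg)
  calls <- sim$geno; colnames(calls) <- sim$ped$id
  kids <- sim$ped$id[!is.na(sim$ped$dam)]
  map_cM <- interpolate_genetic_map(sim$map, sim$sites$chrom, sim$sites$pos)
  truth <- sim$haps[[1]][1:2, ] # parent F0001
  ev <- sapply(kids, function(k)
    transmitted_allele(calls[, k], calls[, "F0002"]))
  # inject one switch error halfway
  bad <- truth
  bad[, 100:ncol(bad)] <- truth[2:1, 100:ncol(bad)]
  cor <- correct_switch_errors(bad, ev, map_cM)
  het <- truth[1, ] != truth[2, ]
  expect_equal(cor$haplotypes[, het], truth[, het])
  expect_gte(cor$n_corrections, 1)
  # without injection nothing is corrected
  cor0 <- correct_switch_errors(truth, ev, map_cM)
  expect_equal(cor0$n_corrections, 0)
  expect_error(correct_switch_errors(truth, ev[, 1, drop = FALSE], map_cM),
               ">= 2 offspring")
})

test_that("meiosis informativeness follows family size and generations", {
  ped <- data.frame(
    id   = c("g", "p1", "p2", "a", "b", "c", "q1", "q2", "d", "e"),
    dam  = c(NA, "g", NA, "p1", "p1", "p1", NA, NA, "q1", "d"),
    sire = c(NA, NA, NA, "p2", "p2", "p2", NA, NA, "q2", "q2"),
    stringsAsFactors = FALSE)
  mei <- informative_meioses(ped)
  # family with three offspring: all six parental meioses informative
  fam3 <- mei[mei$child %in% c("a", "b", "c"), ]
  expect_true(all(fam3$informative))
  # p1 itself has a recorded parent (g): p1 -> child meioses informative
  # even in a small family; and "d" has offspring so q-family meioses count
  expect_true(all(mei$informative[mei$parent == "p1"]))
  expect_true(mei$informative[mei$parent == "q1" & mei$child == "d"])
  # two-offspring family with no third generation is uninformative:
  ped2 <- data.frame(id = c("x", "y", "k1", "k2"),
                     dam = c(NA, NA, "x", "x"),
                     sire = c(NA, NA, "y", "y"), stringsAsFactors = FALSE)
  mei2 <- informative_meioses(ped2)
  expect_false(any(mei2$informative))
  # single offspring with a grandparent present is informative
  ped3 <- data.frame(id = c("gp", "x", "y", "k"),
                     dam = c(NA, "gp", NA, "x"),
                     sire = c(NA, NA, NA, "y"), stringsAsFactors = FALSE)
  mei3 <- informative_meioses(ped3)
  expect_true(mei3$informative[mei3$parent == "x"])
})

test_that("haplotype relabeling leaves emitted intervals unchanged", {
  m <- 30
  set.seed(9)
  h1 <- rbinom(m, 1, 0.5)
  phase <- rbind(h1, 1L - h1)
  ev <- ifelse(runif(m) < 0.5, h1, NA)
  ev[10:m] <- ifelse(is.na(ev[10:m]), NA, 1L - h1[10:m])
  map <- cumsum(runif(m, 0.5, 2))
  a <- duo_hmm_posteriors(phase, ev, map)
  b <- duo_hmm_posteriors(phase[2:1, ], ev, map)
  expect_equal(a$post_change, b$post_change)
  expect_equal(a$interval_left, b$interval_left)
})

test_that("detected intervals bracket the truth on simulated data", {
  sim <- shared_sim()
  calls <- sim$geno; colnames(calls) <- sim$ped$id
  det <- detect_crossovers(calls, sim$sites, sim$ped, sim$map,
                           phase = "truth", sim = sim)
  ev <- det$events
  expect_true(all(ev$posterior >= 0.5 & ev$posterior <= 1))
  expect_true(all(ev$right_idx > ev$left_idx))
  expect_true(all(ev$right_bp > ev$left_bp))
  # every emitted interval for a meiosis contains a true crossover
  hits <- event_hits(ev, sim$truth_crossovers)
  expect_equal(mean(hits), 1)
  # expected crossover counts are finite and non-negative
  expect_true(all(is.finite(det$meioses$expected_xo)))
  expect_true(all(det$meioses$expected_xo >= 0))
})
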