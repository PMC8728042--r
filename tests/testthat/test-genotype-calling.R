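test_that("binomial genotype likelihoods match closed forms", {
  lik <- genotype_likelihood(0, 2)
  expect_equal(unname(lik["BB"]), 0.99^2)           # (1 - e)^2
  expect_equal(unname(lik["AA"]), 0.01^2)
  lik2 <- genotype_likelihood(3, 2)
  expect_equal(unname(lik2["AB"]), choose(5, 2) * 0.5^5) # 0.3125
  # no reads carry no information
  expect_equal(unname(genotype_likelihood(0, 0)), c(1, 1, 1))
  # vectorized form agrees with scalar calls
  mat <- genotype_likelihood(c(0, 3), c(2, 2))
  expect_equal(mat[1, ], genotype_likelihood(0, 2))
})

test_that("genotype priors implement Mendelian and HWE closed forms", {
  expect_equal(unname(genotype_prior(c(0, 1, 0), c(0, 1, 0))),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(genotype_prior(c(1, 0, 0), c(0, 0, 1))),
               c(0, 1, 0))
  expect_equal(unname(genotype_prior(ref_freq = 0.7)),
               c(0.49, 0.42, 0.09))
  # no mass on Mendelian-impossible genotypes under certain parents
  expect_equal(unname(genotype_prior(c(1, 0, 0), c(1, 0, 0))),
               c(1, 0, 0))
  expect_error(genotype_prior(ref_freq = 1.2), "ref_freq")
})

test_that("depth filters apply the missingness and mean-depth rules in order", {
  # site missing in 71 of 100 individuals is removed (> 70%)
  ref <- matrix(5L, 3, 100); alt <- matrix(0L, 3, 100)
  ref[2, 1:71] <- 0L
  fd <- filter_depth_matrix(ad_matrix(NULL, ref, alt, sprintf("i%03d", 1:100)))
  expect_equal(nrow(fd$ad$ref), 2)
  expect_equal(fd$report$removed[fd$report$filter == "site_missing"], 1)

  # mean depth exactly 120 is retained (strictly greater than removes)
  ref <- matrix(c(120L, 121L), 2, 10)
  fd2 <- filter_depth_matrix(ad_matrix(NULL, ref, matrix(0L, 2, 10),
                                       sprintf("i%d", 1:10)))
  expect_equal(nrow(fd2$ad$ref), 1)
  expect_equal(fd2$ad$ref[1, 1], 120L)

  # individual with > 80% missing cells is removed
  ref3 <- matrix(4L, 10, 3); ref3[1:9, 2] <- 0L
  fd3 <- filter_depth_matrix(ad_matrix(NULL, ref3, matrix(0L, 10, 3),
                                       c("a", "b", "c")))
  expect_equal(fd3$ad$samples, c("a", "c"))

  # an all-zero matrix leaves no data
  expect_error(filter_depth_matrix(
    ad_matrix(NULL, matrix(0L, 4, 4), matrix(0L, 4, 4), letters[1:4])),
    "no data")
})

test_that("posterior calling respects the 0.99 threshold", {
  # prior (0.25, 0.5, 0.25) with reads (0, 5): posterior(BB) ~ 0.938 -> no call
  lik <- genotype_likelihood(0, 5)
  post <- c(0.25, 0.5, 0.25) * lik / sum(c(0.25, 0.5, 0.25) * lik)
  expect_equal(unname(post["BB"]),
               0.25 * 0.99^5 / (0.25 * 1e-10 + 0.5 * 0.5^5 + 0.25 * 0.99^5),
               tolerance = 1e-10)
  expect_lt(max(post), 0.99)

  # the same situation inside the caller yields NA; overwhelming evidence
  # yields a hom call
  ped <- data.frame(id = c("m", "f", "kid"),
                    dam = c(NA, NA, "m"), sire = c(NA, NA, "f"),
                    stringsAsFactors = FALSE)
  ad <- ad_matrix(NULL,
                  ref = cbind(m = c(30L, 0L), f = c(0L, 50L),
                              kid = c(0L, 50L)),
                  alt = cbind(m = c(0L, 30L), f = c(30L, 0L),
                              kid = c(5L, 0L)),
                  samples = c("m", "f", "kid"))
  res <- call_genotypes_down_pedigree(ad, ped, site_missing_calls = 1)
  # site 1: parents AA x BB force kid AB even with (0,5) reads;
  # site 2 drops as monomorphic after the kid's call follows its parents
  expect_equal(unname(res$calls[1, "kid"]), 1L)
  expect_equal(res$kept_sites, 1L)
  # posteriors normalize
  expect_true(all(abs(apply(res$posterior, c(1, 2), sum) - 1) < 1e-12))

  # founders with overwhelming evidence are called through the HWE prior
  adf <- ad_matrix(NULL, ref = cbind(f1 = 50L, f2 = 25L, f3 = 0L),
                   alt = cbind(f1 = 0L, f2 = 25L, f3 = 50L),
                   samples = c("f1", "f2", "f3"))
  pedf <- data.frame(id = c("f1", "f2", "f3"), dam = NA_character_,
                     sire = NA_character_, stringsAsFactors = FALSE)
  resf <- call_genotypes_down_pedigree(adf, pedf)
  expect_equal(unname(resf$calls[1, ]), c(0L, 1L, 2L))
})

test_that("call-based site filters remove monomorphic and singleton sites", {
  ped <- data.frame(id = sprintf("i%02d", 1:12), dam = NA_character_,
                    sire = NA_character_, stringsAsFactors = FALSE)
  dp <- 60L
  mk <- function(dosages) { # high-depth reads forcing the wanted calls
    alt <- matrix(as.integer(dp * dosages / 2), 1, 12)
    ref <- dp - alt
    list(ref = ref, alt = alt)
  }
  rows <- list(
    all_ab  = rep(1, 12),          # polymorphic, kept
    mono    = rep(0, 12),          # monomorphic, removed
    single  = c(1, rep(0, 11)),    # minor allele in one individual, removed
    one_aa  = c(0, rep(1, 11))     # minor ALLELE carried by all hets, kept
  )
  ref <- do.call(rbind, lapply(rows, function(d) mk(d)$ref))
  alt <- do.call(rbind, lapply(rows, function(d) mk(d)$alt))
  ad <- ad_matrix(NULL, ref, alt, ped$id)
  res <- call_genotypes_down_pedigree(ad, ped)
  expect_equal(res$kept_sites, c(1L, 4L))
  rep_rm <- setNames(res$report$removed, res$report$filter)
  expect_equal(unname(rep_rm["monomorphic"]), 1)
  expect_equal(unname(rep_rm["singleton"]), 1)
})

test_that("posteriors are invariant to pedigree row order", {
  sim <- shared_sim()
  fd <- filter_depth_matrix(sim$ad)
  a <- call_genotypes_down_pedigree(fd$ad, sim$ped)
  set.seed(1)
  perm <- sample(nrow(sim$ped))
  b <- call_genotypes_down_pedigree(fd$ad, sim$ped[perm, ])
  back <- match(seq_len(nrow(sim$ped)), perm)
  expect_equal(a$posterior, b$posterior[, back, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(a$calls, b$calls[, colnames(a$calls)], ignore_attr = TRUE)
})

test_that("pedigree cycles are reported by name", {
  ped <- data.frame(id = c("a", "b"), dam = c("b", "a"),
                    sire = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(pedrec:::topo_order(ped), "cycle")
})

test_that("deep sequencing recovers the simulated truth exactly", {
  cfg <- small_config(mean_depth = 200, missing_rate = 0, seed = 31)
  sim <- simulate_cross_data(cfg)
  res <- call_genotypes_down_pedigree(sim$ad, sim$ped,
                                      site_missing_calls = 1)
  truth <- sim$geno[res$kept_sites, ]
  expect_equal(mean(res$calls == truth, na.rm = TRUE), 1)
  expect_gt(mean(!is.na(res$calls)), 0.999)
})

test_that("opposing-homozygote conflict rate flags wrong parent links", {
  g <- rep(c(0L, 1L, 2L), length.out = 120)
  expect_equal(mendelian_conflict_rate(g, g)$rate, 0)
  expect_equal(mendelian_conflict_rate(rep(0L, 100), rep(2L, 100))$rate, 1)
  few <- mendelian_conflict_rate(rep(0L, 10), rep(0L, 10))
  expect_true(is.na(few$valid))
  # true trios simulated at 7x stay under the 2% cutoff
  sim <- shared_sim()
  fd <- filter_depth_matrix(sim$ad)
  calls <- call_genotypes_down_pedigree(fd$ad, sim$ped,
                                        site_missing_calls = 1)$calls
  kids <- sim$ped[!is.na(sim$ped$dam), ]
  ok <- vapply(seq_len(min(nrow(kids), 30)), function(i) {
    r <- mendelian_conflict_rate(calls[, kids$id[i]], calls[, kids$dam[i]])
    isTRUE(r$valid)
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("technical replicates merge by depth concordance", {
  sites <- NULL
  ref <- cbind(a1 = c(10L, 0L, 5L), a2 = c(8L, 0L, 6L), b = c(0L, 9L, 4L))
  alt <- cbind(a1 = c(0L, 10L, 5L), a2 = c(0L, 11L, 5L), b = c(9L, 0L, 4L))
  ad <- ad_matrix(sites, ref, alt, c("a1", "a2", "b"))
  mr <- merge_replicates(ad, list(A = c("a1", "a2")))
  expect_equal(mr$excluded, character(0))
  expect_equal(mr$ad$samples, c("b", "A"))
  expect_equal(mr$ad$ref[, 2], c(18L, 0L, 11L))
  # discordant replicates are excluded entirely
  mr2 <- merge_replicates(ad, list(X = c("a1", "b")))
  expect_equal(mr2$excluded, "X")
  expect_equal(mr2$ad$samples, "a2")
})
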