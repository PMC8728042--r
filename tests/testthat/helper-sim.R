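# Shared fixtures: small simulated datasets built once per test run.

small_config <- function(seed = 7, ...) {
  args <- list(n_founders = 8, cohort_sizes = c(30, 30), n_chromosomes = 2,
               chrom_bp = 20e6, chrom_cM = 100, n_sites = 150,
               introgression_regions = NULL, missing_rate = 0.1,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# one moderately sized dataset reused across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cross_data(small_config())
    cache
  }
})

# compare each emitted event to the truth table
event_hits <- function(events, truth) {
  if (!nrow(events)) return(logical(0))
  mapply(function(p, c, ch, l, r)
    any(truth$parent == p & truth$child == c & truth$chrom == ch &
          truth$pos >= l & truth$pos <= r),
    events$parent, events$child, events$chrom,
    events$left_bp, events$right_bp)
}

# fraction of true crossovers covered by an emitted event of their meiosis
truth_detected <- function(events, truth) {
  if (!nrow(truth)) return(logical(0))
  mapply(function(p, c, ch, pos)
    any(events$parent == p & events$child == c & events$chrom == ch &
          events$left_bp <= pos & events$right_bp >= pos),
    truth$parent, truth$child, truth$chrom, truth$pos)
}

# truth restricted to a set of meioses
truth_for_meioses <- function(truth, meioses) {
  truth[paste(truth$parent, truth$child) %in%
          paste(meioses$parent, meioses$child), , drop = FALSE]
}

# independent Pearson GOF oracle: hand formula + regularized upper
# incomplete gamma for the tail (pracma), no calls into the package
oracle_chisq <- function(obs, props) {
  p <- props / sum(props)
  expd <- sum(obs) * p
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1
  pval <- pracma::gammainc(stat / 2, df / 2)[["uppinc"]] / gamma(df / 2)
  list(statistic = stat, p_value = unname(pval))
}
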