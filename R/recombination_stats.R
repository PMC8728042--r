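# Pearson goodness-of-fit chi-square on a count vector with fixed
# expected proportions (normalized), df = classes - 1, no continuity
# correction. Thin wrapper over stats::chisq.test.
chisq_count_test <- function(observed, proportions) {
  p <- proportions / sum(proportions)
  if (length(observed) != length(p) || any(p < 0))
    stop("observed counts and proportions must match", call. = FALSE)
  res <- suppressWarnings(chisq.test(observed, p = p, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = unname(res$expected))
}

event_midpoint <- function(events) (events$left_bp + events$right_bp) / 2

#' Heterochiasmy chi-square tests in 1-Mb windows
#'
#' Tiles each chromosome from 0 in `window_bp` steps and compares male
#' and female crossover counts per window against expectations from the
#' exact sex proportions of informative meioses. Terminal windows
#' shorter than `window_bp` are excluded, as are windows with any
#' expected count below `min_expected`; exclusions are reported, never
#' silently dropped. Significance uses a Bonferroni threshold
#' `alpha / N` over the N tested windows. Events are assigned to windows
#' by interval midpoint.
#'
#' @param events Crossover table with `chrom`, `left_bp`, `right_bp`,
#'   `parental_sex`.
#' @param meioses_by_sex Named numeric vector
#'   `c(male = ..., female = ...)` of informative meiosis counts.
#' @param chrom_bp Physical chromosome lengths (bp), indexed by
#'   chromosome.
#' @param window_bp Window size (default 1e6).
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_expected Minimum expected count per class (default 5).
#' @return List: `windows` (`data.frame` with observed/expected counts,
#'   statistic, p, `excluded` + `exclude_reason`), `n_tested`,
#'   `bonferroni` threshold, `proportions` used.
#' @export
sex_window_tests <- function(events, meioses_by_sex, chrom_bp,
                             window_bp = 1e6, alpha = 0.05,
                             min_expected = 5) {
  if (any(meioses_by_sex <= 0))
    stop("both sexes need a positive meiosis count", call. = FALSE)
  pr <- meioses_by_sex[c("male", "female")] / sum(meioses_by_sex)
  mid <- event_midpoint(events)
  rows <- list()
  for (ch in seq_along(chrom_bp)) {
    bp <- chrom_bp[ch]
    n_full <- floor(bp / window_bp)
    has_partial <- bp > n_full * window_bp
    e <- events[events$chrom == ch, , drop = FALSE]
    w <- floor(mid[events$chrom == ch] / window_bp) + 1L
    n_win <- n_full + has_partial
    for (k in seq_len(n_win)) {
      obs_m <- sum(w == k & e$parental_sex == "male")
      obs_f <- sum(w == k & e$parental_sex == "female")
      tot <- obs_m + obs_f
      exp_m <- tot * pr[["male"]]; exp_f <- tot * pr[["female"]]
      terminal <- k > n_full
      low <- min(exp_m, exp_f) < min_expected
      excluded <- terminal || low
      stat <- p <- NA_real_
      if (!excluded) {
        ct <- chisq_count_test(c(obs_m, obs_f),
                               c(pr[["male"]], pr[["female"]]))
        stat <- ct$statistic; p <- ct$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = (k - 1) * window_bp,
        end = min(k * window_bp, bp),
        obs_male = obs_m, obs_female = obs_f,
        exp_male = exp_m, exp_female = exp_f,
        statistic = stat, p_value = p, excluded = excluded,
        exclude_reason = if (terminal) "terminal_sub_window"
        else if (low) "expected_below_min" else "")
    }
  }
  win <- do.call(rbind, rows)
  rownames(win) <- NULL
  n_tested <- sum(!win$excluded)
  bon <- if (n_tested > 0) alpha / n_tested else NA_real_
  win$significant <- !win$excluded & win$p_value < bon
  list(windows = win, n_tested = n_tested, bonferroni = bon,
       proportions = pr)
}

#' Genome-wide heterochiasmy chi-square test
#'
#' Compares total male and female crossover counts against expectations
#' from the exact sex proportions of informative meioses, and reports
#' the female-to-male ratio of crossovers per meiosis and each sex's
#' percent excess relative to expectation.
#'
#' @inheritParams sex_window_tests
#' @return List: `observed`, `expected`, `statistic`, `df`, `p_value`,
#'   `ratio_female_male` (per-meiosis), `percent_excess` (named, percent
#'   above/below expectation), `significant` at `alpha`.
#' @export
sex_genomewide_test <- function(events, meioses_by_sex, alpha = 0.05) {
  if (any(meioses_by_sex <= 0))
    stop("both sexes need a positive meiosis count", call. = FALSE)
  obs <- c(male = sum(events$parental_sex == "male"),
           female = sum(events$parental_sex == "female"))
  sex_count_summary(obs, meioses_by_sex, alpha)
}

#' Heterochiasmy summary from crossover totals
#'
#' Same computation as [sex_genomewide_test()] but starting from
#' genome-wide crossover totals per sex rather than an event table —
#' useful when only published totals are available.
#'
#' @param obs Named counts `c(male = ..., female = ...)`.
#' @inheritParams sex_window_tests
#' @inherit sex_genomewide_test return
#' @export
sex_count_summary <- function(obs, meioses_by_sex, alpha = 0.05) {
  pr <- meioses_by_sex[c("male", "female")] / sum(meioses_by_sex)
  ct <- chisq_count_test(obs[c("male", "female")],
                         c(pr[["male"]], pr[["female"]]))
  expected <- setNames(ct$expected, c("male", "female"))
  ratio <- (obs[["female"]] / meioses_by_sex[["female"]]) /
    (obs[["male"]] / meioses_by_sex[["male"]])
  excess <- 100 * (obs[c("male", "female")] / expected - 1)
  list(observed = obs[c("male", "female")], expected = expected,
       statistic = ct$statistic, df = ct$df, p_value = ct$p_value,
       ratio_female_male = unname(ratio), percent_excess = excess,
       significant = ct$p_value < alpha)
}

#' Poisson-regression deviance goodness-of-fit test for interference
#'
#' Per chromosome, fits a log-linear Poisson regression of per-meiosis
#' crossover counts on parent (categorical) and parental sex, and
#' compares the residual deviance with its chi-square reference
#' (df = meioses - parameters). Crossover interference makes counts
#' underdispersed relative to Poisson, so the reported p-value is
#' two-sided (twice the smaller tail); significant lack of fit at the
#' Bonferroni threshold `alpha / m` over the m chromosomes indicates
#' non-Poisson placement. Parents with fewer than two meioses are
#' dropped with a warning.
#'
#' @param counts `data.frame` with one row per meiosis and chromosome:
#'   `chrom`, `parent`, `parental_sex`, `count` (zero-crossover meioses
#'   included).
#' @param alpha Family-wise significance level (default 0.05).
#' @return `data.frame` per chromosome: `chrom`, `deviance`, `df`,
#'   `p_value` (two-sided), `bonferroni`, `significant`, `n_meioses`.
#' @export
interference_gof <- function(counts, alpha = 0.05) {
  stopifnot(all(c("chrom", "parent", "parental_sex", "count") %in%
                  names(counts)))
  chroms <- sort(unique(counts$chrom))
  m <- length(chroms)
  rows <- list()
  for (ch in chroms) {
    d <- counts[counts$chrom == ch, , drop = FALSE]
    keep_parents <- names(which(table(d$parent) >= 2))
    if (length(keep_parents) < length(unique(d$parent)))
      warning("chromosome ", ch, ": dropping parents with a single meiosis")
    d <- d[d$parent %in% keep_parents, , drop = FALSE]
    if (length(unique(d$parent)) < 2 ||
        length(unique(d$parental_sex)) < 2) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, deviance = NA_real_, df = NA_real_,
        p_value = NA_real_, bonferroni = alpha / m, significant = NA,
        n_meioses = nrow(d))
      next
    }
    fit <- glm(count ~ factor(parent) + factor(parental_sex),
               family = poisson(), data = d)
    dev <- fit$deviance
    df <- fit$df.residual
    lo <- pchisq(dev, df)
    hi <- pchisq(dev, df, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, deviance = dev, df = df, p_value = p,
      bonferroni = alpha / m, significant = p < alpha / m,
      n_meioses = nrow(d))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-meiosis crossover count table
#'
#' Expands a crossover event table into one row per meiosis and
#' chromosome with the event count, including zero-crossover meioses,
#' ready for [interference_gof()].
#'
#' @param events Crossover table (`parent`, `child`, `chrom`,
#'   `parental_sex`).
#' @param meioses Meiosis table (`parent`, `child`, `parental_sex`), one
#'   row per observed meiosis.
#' @param chroms Chromosomes to tabulate (default: those in `events`).
#' @return `data.frame`: `chrom`, `parent`, `child`, `parental_sex`,
#'   `count`.
#' @export
crossover_counts <- function(events, meioses,
                             chroms = sort(unique(events$chrom))) {
  key <- paste(meioses$parent, meioses$child)
  rows <- lapply(chroms, function(ch) {
    e <- events[events$chrom == ch, , drop = FALSE]
    cnt <- table(factor(paste(e$parent, e$child), levels = key))
    data.frame(chrom = ch, parent = meioses$parent, child = meioses$child,
               parental_sex = meioses$parental_sex,
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Introgression-class crossover count tests
#'
#' For each introgression region, tests whether crossover counts within
#' the region (and, separately, in the rest of the chromosome) are
#' distributed across introgression-dosage classes in proportion to the
#' classes' informative meiosis counts. Events are assigned by interval
#' midpoint. Classes with zero meioses are omitted (df reduced);
#' parents without a class label are excluded from that chromosome's
#' tests. Bonferroni threshold is `alpha /` (number of tests).
#'
#' @param events Crossover table (`parent`, `chrom`, `left_bp`,
#'   `right_bp`).
#' @param parent_status `data.frame` (`parent`, `region`, `status`) of
#'   per-region introgression dosage classes (0/1/2).
#' @param regions `data.frame` (`region`, `chrom`, `start`, `end`), bp,
#'   0-based half-open.
#' @param meioses_by_parent Named numeric vector: informative meioses
#'   per parent.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List: `tests` (`data.frame` per region x side: statistic, df,
#'   p, bonferroni, significant), `counts` (per region x side x class
#'   observed and expected).
#' @export
introgression_count_tests <- function(events, parent_status, regions,
                                      meioses_by_parent, alpha = 0.05) {
  mid <- event_midpoint(events)
  n_tests <- 2L * nrow(regions)
  bon <- alpha / n_tests
  tests <- list(); counts <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    st <- parent_status[parent_status$region == reg$region, , drop = FALSE]
    lab <- setNames(st$status, st$parent)
    classes <- sort(unique(st$status[!is.na(st$status)]))
    meio <- vapply(classes, function(cl)
      sum(meioses_by_parent[st$parent[!is.na(st$status) &
                                        st$status == cl]], na.rm = TRUE), 0)
    keep_cl <- classes[meio > 0]
    meio <- meio[meio > 0]
    if (length(keep_cl) < 2) {
      warning("region ", reg$region, ": fewer than two classes with ",
              "meioses; test skipped")
      for (side in c("within", "outside"))
        tests[[length(tests) + 1L]] <- data.frame(
          region = reg$region, chrom = reg$chrom, side = side,
          statistic = NA_real_, df = NA_real_, p_value = NA_real_,
          bonferroni = bon, significant = NA, total = NA_real_)
      next
    }
    prop <- meio / sum(meio)
    e_ch <- events$chrom == reg$chrom &
      events$parent %in% st$parent[!is.na(st$status)]
    inside <- e_ch & mid >= reg$start & mid < reg$end
    for (side in c("within", "outside")) {
      sel <- if (side == "within") inside else (e_ch & !inside)
      cls_of_ev <- lab[events$parent[sel]]
      obs <- vapply(keep_cl, function(cl) sum(cls_of_ev == cl), 0)
      ct <- if (sum(obs) > 0) chisq_count_test(obs, prop) else
        list(statistic = NA_real_, df = length(obs) - 1,
             p_value = NA_real_, expected = obs * 0)
      tests[[length(tests) + 1L]] <- data.frame(
        region = reg$region, chrom = reg$chrom, side = side,
        statistic = ct$statistic, df = ct$df, p_value = ct$p_value,
        bonferroni = bon, significant = ct$p_value < bon,
        total = sum(obs))
      counts[[length(counts) + 1L]] <- data.frame(
        region = reg$region, side = side, status = keep_cl,
        observed = obs, expected = ct$expected,
        meioses = unname(meio),
        percent_vs_expected = 100 * (obs / ct$expected - 1))
    }
  }
  list(tests = do.call(rbind, tests), counts = do.call(rbind, counts))
}
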