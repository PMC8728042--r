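#' Interpolate genetic positions from a reference map
#'
#' Linear interpolation in physical position between flanking map points,
#' constant extrapolation beyond the map ends.
#'
#' @param map A `genetic_map` `data.frame` (`chrom`, `pos`, `cM`).
#' @param chrom,pos Vectors of query positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_genetic_map <- function(map, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    q <- chrom == ch
    ref <- map[map$chrom == ch, ]
    if (nrow(ref) == 0) stop("no map entries for chromosome ", ch,
                             call. = FALSE)
    if (nrow(ref) == 1) { out[q] <- ref$cM; next }
    out[q] <- approx(ref$pos, ref$cM, xout = pos[q], rule = 2,
                     ties = "ordered")$y
  }
  out
}

#' Assign crossover events fractionally to SNP intervals
#'
#' An event resolved to a single inter-SNP interval contributes 1 to it;
#' an event spanning k intervals contributes shares that sum to exactly
#' 1 across them — proportional to physical interval length by default,
#' or uniform `1/k` shares.
#'
#' @param events Crossover table with `chrom` and either site indices
#'   (`left_idx`, `right_idx`, half-open on the chromosome's site list)
#'   or positions only (`left_bp`, `right_bp`), in which case each event
#'   is placed in the interval containing its midpoint. Events whose
#'   midpoint falls outside the flanked range are dropped (and counted).
#' @param sites Site table (`chrom`, `pos`).
#' @param method `"proportional"` (default) or `"uniform"`.
#' @return `data.frame` with one row per inter-SNP interval: `chrom`,
#'   `interval` (index of the left site within its chromosome),
#'   `left_bp`, `right_bp`, `count`; attribute `dropped` counts events
#'   outside the site range.
#' @export
assign_fractional_crossovers <- function(events, sites,
                                         method = c("proportional",
                                                    "uniform")) {
  method <- match.arg(method)
  chroms <- sort(unique(sites$chrom))
  out <- list()
  dropped <- 0L
  has_idx <- all(c("left_idx", "right_idx") %in% names(events))
  for (ch in chroms) {
    pos <- sites$pos[sites$chrom == ch]
    m <- length(pos)
    counts <- numeric(max(m - 1L, 0L))
    ev <- events[events$chrom == ch, , drop = FALSE]
    if (m >= 2 && nrow(ev)) {
      if (has_idx) {
        li <- ev$left_idx; ri <- ev$right_idx
        if (any(li < 1 | ri > m | ri <= li))
          stop("event indices outside the chromosome site list",
               call. = FALSE)
        for (e in seq_len(nrow(ev))) {
          span <- li[e]:(ri[e] - 1L)
          w <- if (method == "proportional") {
            len <- diff(pos)[span]
            if (sum(len) > 0) len / sum(len) else
              rep(1 / length(span), length(span))
          } else rep(1 / length(span), length(span))
          counts[span] <- counts[span] + w
        }
      } else {
        mid <- (ev$left_bp + ev$right_bp) / 2
        j <- findInterval(mid, pos)
        ok <- j >= 1 & j <= m - 1L
        dropped <- dropped + sum(!ok)
        tab <- tabulate(j[ok], m - 1L)
        counts <- counts + tab
      }
    }
    if (m >= 2)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, interval = seq_len(m - 1L),
        left_bp = pos[-m], right_bp = pos[-1], count = counts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Build a genetic map scaled to reference chromosome lengths
#'
#' Converts fractional crossover counts per inter-SNP interval into
#' genetic lengths: interval cM = count x L_y / (total count on
#' chromosome y), i.e. count divided by the scaling factor
#' n_y = (total count on y) / L_y, so every chromosome's total equals
#' its reference length L_y exactly.
#'
#' @param frac Interval count table from [assign_fractional_crossovers()].
#' @param ref_lengths Named (by chromosome) or positional numeric vector
#'   of reference chromosome lengths L_y in cM.
#' @return A `scaled_map` list: `map` (`genetic_map` of cumulative cM at
#'   site positions, first site at 0), `intervals` (with `cM` per
#'   interval), `scaling` (`chrom`, `total`, `L`, `n_y`).
#' @export
build_scaled_map <- function(frac, ref_lengths) {
  chroms <- unique(frac$chrom)
  maps <- list(); ints <- list(); sc <- list()
  for (ch in chroms) {
    f <- frac[frac$chrom == ch, , drop = FALSE]
    L <- if (!is.null(names(ref_lengths))) ref_lengths[[as.character(ch)]]
    else ref_lengths[ch]
    tot <- sum(f$count)
    if (tot <= 0) {
      warning("no crossovers on chromosome ", ch, "; zero-length map")
      cm <- rep(0, nrow(f))
    } else {
      cm <- f$count * L / tot
    }
    f$cM <- cm
    ints[[length(ints) + 1L]] <- f
    maps[[length(maps) + 1L]] <- data.frame(
      chrom = ch, pos = c(f$left_bp[1], f$right_bp),
      cM = c(0, cumsum(cm)))
    sc[[length(sc) + 1L]] <- data.frame(
      chrom = ch, total = tot, L = L,
      n_y = if (L > 0) tot / L else NA_real_)
  }
  map <- do.call(rbind, maps)
  class(map) <- c("genetic_map", "data.frame")
  structure(list(map = map, intervals = do.call(rbind, ints),
                 scaling = do.call(rbind, sc)),
            class = "scaled_map")
}

#' @export
print.scaled_map <- function(x, ...) {
  cat("<scaled_map>", length(unique(x$map$chrom)), "chromosomes,",
      sprintf("%.1f cM total\n", sum(x$intervals$cM)))
  invisible(x)
}

#' Build class-specific genetic maps sharing the pooled scaling
#'
#' For each class (sex, or introgression dosage), interval cM =
#' (class count / n_y) x m, where n_y is the pooled map's scaling factor
#' and m = (total informative meioses) / (class informative meioses).
#' By construction the meiosis-weighted average of the class maps equals
#' the pooled map interval-by-interval.
#'
#' @param frac_by_class Named list of interval count tables (one per
#'   class, same intervals as the pooled table).
#' @param meioses_by_class Named numeric vector of informative meiosis
#'   counts per class; classes with zero meioses are omitted.
#' @param pooled A `scaled_map` built from all classes' events combined.
#' @return Named list of `scaled_map` objects, each with an `m` column in
#'   its `scaling` table.
#' @export
build_class_maps <- function(frac_by_class, meioses_by_class, pooled) {
  stopifnot(all(names(frac_by_class) %in% names(meioses_by_class)))
  keep <- names(frac_by_class)[meioses_by_class[names(frac_by_class)] > 0]
  total_meioses <- sum(meioses_by_class[keep])
  out <- list()
  for (cl in keep) {
    m_cl <- total_meioses / meioses_by_class[[cl]]
    f <- frac_by_class[[cl]]
    ints <- list(); maps <- list(); sc <- list()
    for (ch in unique(f$chrom)) {
      fi <- f[f$chrom == ch, , drop = FALSE]
      srow <- pooled$scaling[pooled$scaling$chrom == ch, ]
      n_y <- srow$n_y
      cm <- if (is.na(n_y) || n_y <= 0) rep(0, nrow(fi)) else
        fi$count / n_y * m_cl
      fi$cM <- cm
      ints[[length(ints) + 1L]] <- fi
      maps[[length(maps) + 1L]] <- data.frame(
        chrom = ch, pos = c(fi$left_bp[1], fi$right_bp),
        cM = c(0, cumsum(cm)))
      sc[[length(sc) + 1L]] <- data.frame(
        chrom = ch, total = sum(fi$count), L = srow$L, n_y = n_y,
        m = m_cl)
    }
    map <- do.call(rbind, maps)
    class(map) <- c("genetic_map", "data.frame")
    out[[cl]] <- structure(list(map = map,
                                intervals = do.call(rbind, ints),
                                scaling = do.call(rbind, sc)),
                           class = "scaled_map")
  }
  out
}
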