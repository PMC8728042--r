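#' Read an allele-depth matrix from a VCF
#'
#' Parses a VCF (v4.2) with a per-sample `AD` FORMAT field on biallelic
#' SNPs into an [ad_matrix()]. Multiallelic records are rejected and
#' counted. Positions are stored 1-based as in the VCF; sites are sorted
#' by (chrom, pos).
#'
#' @param path VCF file path (plain text or gzipped).
#' @return An [ad_matrix()]; attribute `n_multiallelic` gives the number
#'   of rejected records.
#' @export
read_vcf_ad <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] == "."
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no AD FORMAT field", call. = FALSE)
  keep <- which(!multi)
  ref_d <- matrix(0L, length(keep), ncol(ad))
  alt_d <- matrix(0L, length(keep), ncol(ad))
  for (k in seq_along(keep)) {
    parts <- strsplit(ad[keep[k], ], ",", fixed = TRUE)
    r <- suppressWarnings(vapply(parts, function(x)
      as.integer(x[1]), 0L))
    a <- suppressWarnings(vapply(parts, function(x)
      if (length(x) >= 2) as.integer(x[2]) else NA_integer_, 0L))
    r[is.na(r)] <- 0L; a[is.na(a)] <- 0L
    ref_d[k, ] <- r; alt_d[k, ] <- a
  }
  chrom <- suppressWarnings(as.integer(fix[keep, "CHROM"]))
  if (anyNA(chrom)) chrom <- as.integer(factor(fix[keep, "CHROM"]))
  sites <- data.frame(chrom = chrom,
                      pos = as.numeric(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"])
  o <- order(sites$chrom, sites$pos)
  out <- ad_matrix(sites[o, , drop = FALSE], ref_d[o, , drop = FALSE],
                   alt_d[o, , drop = FALSE], colnames(ad))
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write an allele-depth matrix (and optional calls) to VCF
#'
#' Emits a minimal VCF v4.2 with `GT:AD` per sample (plus `GP` genotype
#' posteriors when supplied).
#'
#' @param ad An [ad_matrix()].
#' @param path Output path.
#' @param calls Optional sites x samples dosage matrix (0/1/2/NA) for
#'   the GT field; defaults to missing genotypes.
#' @param posterior Optional sites x samples x 3 posterior array for GP.
#' @return `path`, invisibly.
#' @export
write_vcf_ad <- function(ad, path, calls = NULL, posterior = NULL) {
  gt_codes <- c("0/0", "0/1", "1/1")
  m <- nrow(ad$ref); n <- length(ad$samples)
  header <- c("##fileformat=VCFv4.2",
              "##source=pedrec",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">")
  fmt <- "GT:AD"
  if (!is.null(posterior)) {
    header <- c(header,
                "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior (AA,AB,BB)\">")
    fmt <- "GT:AD:GP"
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", ad$samples),
                            collapse = "\t"))
  ref_al <- if ("ref" %in% names(ad$sites)) ad$sites$ref else rep("A", m)
  alt_al <- if ("alt" %in% names(ad$sites)) ad$sites$alt else rep("T", m)
  gt <- matrix("./.", m, n)
  if (!is.null(calls)) {
    ok <- !is.na(calls)
    gt[ok] <- gt_codes[calls[ok] + 1L]
  }
  cell <- matrix(paste0(gt, ":", ad$ref, ",", ad$alt), m, n)
  if (!is.null(posterior)) {
    gp <- matrix(sprintf("%.4g,%.4g,%.4g", posterior[, , 1],
                         posterior[, , 2], posterior[, , 3]), m, n)
    cell <- matrix(paste0(cell, ":", gp), m, n)
  }
  body <- paste(ad$sites$chrom, format(ad$sites$pos, scientific = FALSE,
                                       trim = TRUE),
                sprintf("S%d_%d", ad$sites$chrom, ad$sites$pos),
                ref_al, alt_al, ".", "PASS", ".", fmt,
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pedigree file
#'
#' Tab-delimited with columns child, dam, sire, cohort; `"0"`, `""` or
#' `NA` denote an unknown parent. The same individual may appear as dam
#' in one row and sire in another (monoecious species). Validates
#' acyclicity, self-parentage and duplicate child rows.
#'
#' @param path File path.
#' @return A `pedigree` `data.frame` (`id`, `dam`, `sire`, `cohort`).
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = "character")
  names(df)[1:3] <- c("id", "dam", "sire")
  if (!"cohort" %in% names(df)) df$cohort <- NA_integer_
  for (col in c("dam", "sire"))
    df[[col]][df[[col]] %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(df$id))
    stop("duplicate child rows: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  self <- !is.na(df$dam) & df$dam == df$id |
    !is.na(df$sire) & df$sire == df$id
  if (any(self))
    stop("individual listed as its own parent: ",
         paste(df$id[self], collapse = ", "), call. = FALSE)
  # parents referenced but not listed become founder rows
  extra <- setdiff(stats::na.omit(c(df$dam, df$sire)), df$id)
  if (length(extra))
    df <- rbind(data.frame(id = extra, dam = NA_character_,
                           sire = NA_character_, cohort = NA_integer_,
                           stringsAsFactors = FALSE),
                df[, c("id", "dam", "sire", "cohort")])
  df$cohort <- suppressWarnings(as.integer(df$cohort))
  topo_order(df) # errors on cycles
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @rdname read_pedigree
#' @param ped A pedigree `data.frame`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("id", "dam", "sire", "cohort")]
  out$dam[is.na(out$dam)] <- "0"
  out$sire[is.na(out$sire)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write crossover event tables
#'
#' Tab-delimited: parent, child, chrom, left_bp, right_bp, left_idx,
#' right_idx, posterior, parental_sex.
#'
#' @param events Crossover table.
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_crossovers <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crossovers
#' @export
read_crossovers <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read/write genetic maps
#'
#' Tab-delimited `chrom`, `pos` (bp), `cM` (cumulative).
#'
#' @param map A `genetic_map` `data.frame`.
#' @param path File path.
#' @return The map (read) or `path` invisibly (write).
#' @export
write_genetic_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  map <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("chrom", "pos", "cM") %in% names(map)))
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Read BED-like region definitions
#'
#' Three or four tab-separated columns: chrom, start, end (0-based
#' half-open), optional name.
#'
#' @param path File path.
#' @return `data.frame` (`region`, `chrom`, `start`, `end`).
#' @export
read_regions <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$region <- if (ncol(df) >= 4) df[[4]] else
    paste0("region", seq_len(nrow(df)))
  df$chrom <- suppressWarnings(as.integer(df$chrom))
  df[, c("region", "chrom", "start", "end")]
}

#' Run the full simulate-to-statistics pipeline
#'
#' Simulates a pedigree-GBS dataset, calls genotypes down the pedigree,
#' detects crossovers in informative meioses with the duo HMM, builds
#' pooled / sex-specific / introgression-dosage genetic maps, classifies
#' introgression status from diagnostic markers, and runs the
#' heterochiasmy, interference and introgression test batteries.
#'
#' @param config A [sim_config()].
#' @param params An [hmm_params()].
#' @param model A [genotype_model()].
#' @param phase `"trio"` or `"truth"` parental phasing for detection.
#' @param out_dir Optional directory; when given, the VCF, pedigree,
#'   crossover, map and report files are written there.
#' @return A `pedrec_run` list: `sim`, `calls`, `detection`, `maps`
#'   (`pooled`, `by_sex`, `by_dosage`), `status`, `stats`
#'   (`genomewide`, `windows`, `interference`, `introgression`), and a
#'   `report` of stage counts.
#' @export
run_all <- function(config = sim_config(), params = hmm_params(),
                    model = genotype_model(), phase = c("trio", "truth"),
                    out_dir = NULL) {
  phase <- match.arg(phase)
  sim <- simulate_cross_data(config)
  fd <- filter_depth_matrix(sim$ad)
  called <- call_genotypes_down_pedigree(fd$ad, sim$ped, model)
  sites_kept <- fd$ad$sites[called$kept_sites, , drop = FALSE]
  det <- detect_crossovers(called$calls[, , drop = FALSE], sites_kept,
                           sim$ped, sim$map, params, phase = phase,
                           sim = sim)
  mei <- det$meioses
  meio_by_sex <- c(male = sum(mei$parental_sex == "male"),
                   female = sum(mei$parental_sex == "female"))
  frac <- assign_fractional_crossovers(det$events, sites_kept)
  pooled <- build_scaled_map(frac, config$chrom_cM)
  by_sex <- build_class_maps(
    list(male = assign_fractional_crossovers(
      det$events[det$events$parental_sex == "male", ], sites_kept),
      female = assign_fractional_crossovers(
        det$events[det$events$parental_sex == "female", ], sites_kept)),
    meio_by_sex, pooled)
  gw <- sex_genomewide_test(det$events, meio_by_sex)
  win <- sex_window_tests(det$events, meio_by_sex, config$chrom_bp)
  cnt <- crossover_counts(det$events, mei,
                          chroms = seq_len(config$n_chromosomes))
  intf <- interference_gof(cnt)
  status <- NULL; intro <- NULL; by_dosage <- NULL
  reg <- config$introgression_regions
  if (!is.null(reg)) {
    regions <- data.frame(region = seq_len(nrow(reg)), chrom = reg$chrom,
                          start = reg$start, end = reg$end)
    panels <- simulate_reference_panels(config, sim$sites)
    kept_global <- match(paste(sites_kept$chrom, sites_kept$pos),
                         paste(sim$sites$chrom, sim$sites$pos))
    idms <- find_idms(panels$donor[kept_global, , drop = FALSE],
                      panels$recipient[kept_global, , drop = FALSE],
                      sites_kept)
    status <- classify_introgression(called$calls, idms, regions,
                                     config$chrom_bp)
    parents <- unique(mei$parent)
    ps <- status[status$id %in% parents, ]
    names(ps)[names(ps) == "id"] <- "parent"
    meio_by_parent <- table(mei$parent)
    intro <- introgression_count_tests(det$events, ps, regions,
                                       setNames(as.numeric(meio_by_parent),
                                                names(meio_by_parent)))
    dos_classes <- sort(unique(ps$status[!is.na(ps$status)]))
    # dosage classes per region differ; maps built for region 1's labels
    ps1 <- ps[ps$region == regions$region[1], ]
    lab1 <- setNames(ps1$status, ps1$parent)
    frac_by <- list(); meio_by <- numeric(0)
    for (cl in dos_classes) {
      pcl <- names(lab1)[!is.na(lab1) & lab1 == cl]
      frac_by[[as.character(cl)]] <- assign_fractional_crossovers(
        det$events[det$events$parent %in% pcl, ], sites_kept)
      meio_by[as.character(cl)] <- sum(mei$parent %in% pcl)
    }
    if (length(frac_by) && sum(meio_by) > 0) {
      pooled_dos <- build_scaled_map(
        assign_fractional_crossovers(
          det$events[det$events$parent %in% names(lab1)[!is.na(lab1)], ],
          sites_kept), config$chrom_cM)
      by_dosage <- build_class_maps(frac_by, meio_by, pooled_dos)
    }
  }
  report <- data.frame(
    stage = c("individuals_simulated", "individuals_with_data",
              "sites_simulated", "sites_after_depth_filter",
              "sites_after_call_filter", "meioses_total",
              "meioses_informative", "crossovers_detected"),
    n = c(nrow(sim$ped), length(fd$ad$samples), nrow(sim$sites),
          nrow(fd$ad$ref), nrow(called$calls),
          nrow(informative_meioses(sim$ped)), nrow(mei),
          nrow(det$events)))
  res <- structure(list(sim = sim, calls = called, detection = det,
                        maps = list(pooled = pooled, by_sex = by_sex,
                                    by_dosage = by_dosage),
                        status = status,
                        stats = list(genomewide = gw, windows = win,
                                     interference = intf,
                                     introgression = intro),
                        report = report),
                   class = "pedrec_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf_ad(sim$ad, file.path(out_dir, "simulated.vcf"))
    write_pedigree(sim$ped, file.path(out_dir, "pedigree.tsv"))
    write_crossovers(det$events, file.path(out_dir, "crossovers.tsv"))
    write_genetic_map(pooled$map, file.path(out_dir, "map_pooled.tsv"))
    write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.pedrec_run <- function(x, ...) {
  cat("<pedrec_run>\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("genome-wide female/male per-meiosis ratio: %.3f (p = %.3g)\n",
              x$stats$genomewide$ratio_female_male,
              x$stats$genomewide$p_value))
  invisible(x)
}
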