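# Genomic context of locus positions on a reference genome: nearest
# annotated feature per locus, per-chromosome locus density, and a
# goodness-of-fit test of spacing randomness. All intervals are 0-based
# half-open (BED dialect).

FEATURE_CLASSES <- c("CDS", "TE", "UTR5", "UTR3")

# gap between two 0-based half-open intervals; 0 when they overlap or are
# bookended; signed: positive when the feature lies downstream of the
# locus, negative upstream
signed_gap <- function(l_start, l_end, f_start, f_end) {
  ifelse(f_start >= l_end, f_start - l_end,
         ifelse(f_end <= l_start, -(l_start - f_end), 0L))
}

#' Nearest annotated feature per locus
#'
#' For each locus interval, the closest feature across all classes and the
#' per-class closest distances. Distance is 0 for overlaps, otherwise the
#' gap between the nearest interval ends (the `bedtools closest`
#' convention), signed positive when the feature is downstream of the
#' locus. Ties are broken by smaller feature start, then by feature class
#' name order. Loci on chromosomes absent from the feature table get class
#' `"none"`.
#'
#' @param loci `data.frame` with `chrom`, `start`, `end`, `name` (0-based
#'   half-open, e.g. from [read_bed()]).
#' @param features `data.frame` with `chrom`, `start`, `end`, `class`
#'   (e.g. from [read_gff3()]).
#' @return `data.frame`, one row per locus (input order): `name`,
#'   `chrom`, `nearest_class`, `distance` (signed; `NA` when none), plus
#'   one signed distance column `dist_<class>` per feature class present.
#' @export
nearest_feature <- function(loci, features) {
  stopifnot(all(c("chrom", "start", "end") %in% names(loci)),
            all(c("chrom", "start", "end", "class") %in% names(features)))
  if (is.null(loci$name)) loci$name <- sprintf("locus%05d", seq_len(nrow(loci)))
  classes <- intersect(FEATURE_CLASSES, unique(features$class))
  n <- nrow(loci)
  out <- data.frame(name = loci$name, chrom = loci$chrom,
                    nearest_class = rep("none", n),
                    distance = rep(NA_real_, n), stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("dist_", cl)]] <- rep(NA_real_, n)
  # class rank for deterministic tie-breaking
  crank <- stats::setNames(seq_along(FEATURE_CLASSES), FEATURE_CLASSES)
  for (chrom in unique(loci$chrom)) {
    li <- which(loci$chrom == chrom)
    fi <- which(features$chrom == chrom)
    if (length(fi) == 0L) next
    lgr <- IRanges::IRanges(loci$start[li] + 1L, loci$end[li])
    fgr <- IRanges::IRanges(features$start[fi] + 1L, features$end[fi])
    d <- IRanges::distance(rep(lgr, each = length(fgr)),
                           rep(fgr, length(lgr)))
    dm <- matrix(d, nrow = length(fgr))  # features x loci
    for (k in seq_along(li)) {
      dk <- dm[, k]
      # per-class minima (signed)
      for (cl in classes) {
        sel <- features$class[fi] == cl
        if (!any(sel)) next
        j <- which(sel)[which.min(dk[sel])]
        out[[paste0("dist_", cl)]][li[k]] <-
          signed_gap(loci$start[li[k]], loci$end[li[k]],
                     features$start[fi[j]], features$end[fi[j]])
      }
      # global closest with deterministic tie-breaks
      best <- which(dk == min(dk))
      if (length(best) > 1L) {
        o <- order(features$start[fi[best]],
                   crank[features$class[fi[best]]])
        best <- best[o[1L]]
      }
      out$nearest_class[li[k]] <- features$class[fi[best]]
      out$distance[li[k]] <-
        signed_gap(loci$start[li[k]], loci$end[li[k]],
                   features$start[fi[best]], features$end[fi[best]])
    }
  }
  out
}

#' Count loci near features
#'
#' @param nearest Output of [nearest_feature()].
#' @param near_bp Distance threshold in bp defining "near".
#' @return Named integer vector: per class, the number of loci whose
#'   nearest feature is of that class and within `near_bp`.
#' @export
near_feature_counts <- function(nearest, near_bp = 5000L) {
  near <- !is.na(nearest$distance) & abs(nearest$distance) <= near_bp
  table(factor(nearest$nearest_class[near], levels = FEATURE_CLASSES))
}

#' Per-chromosome locus density
#'
#' @param loci Locus interval `data.frame` (`chrom`, `start`, `end`).
#' @param chrom_sizes Named numeric vector of chromosome sizes in bp.
#' @return List with `per_chromosome` (`data.frame`: `chrom`, `size_mb`,
#'   `n_loci`, `loci_per_mb`), `mean_density`, `sd_density`, `correlation`
#'   and `r_squared` of locus count against chromosome length (`NA` when
#'   undefined, e.g. no loci or fewer than 2 chromosomes).
#' @export
locus_density <- function(loci, chrom_sizes) {
  if (any(chrom_sizes <= 0)) stop("zero-length chromosome")
  chroms <- names(chrom_sizes)
  n <- vapply(chroms, function(ch) sum(loci$chrom == ch), integer(1))
  size_mb <- as.numeric(chrom_sizes) / 1e6
  dens <- n / size_mb
  corr <- if (length(chroms) >= 2L && stats::sd(n) > 0)
    stats::cor(as.numeric(chrom_sizes), n) else NA_real_
  list(per_chromosome = data.frame(chrom = chroms, size_mb = size_mb,
                                   n_loci = n, loci_per_mb = dens,
                                   stringsAsFactors = FALSE,
                                   row.names = NULL),
       mean_density = mean(dens), sd_density = stats::sd(dens),
       correlation = corr,
       r_squared = if (is.na(corr)) NA_real_ else corr^2)
}

#' Test locus spacing against a homogeneous Poisson process
#'
#' Gaps between consecutive locus midpoints are computed per chromosome,
#' scaled by the per-chromosome locus density (so that under a homogeneous
#' Poisson placement the scaled gaps are approximately unit-exponential),
#' pooled, and tested against the exponential distribution with a
#' Kolmogorov-Smirnov test. Regular or clustered placements reject the
#' null.
#'
#' @param loci Locus interval `data.frame`.
#' @param chrom_sizes Named numeric vector of chromosome sizes.
#' @return List with `statistic`, `p_value` and `n_gaps`.
#' @export
spacing_randomness_test <- function(loci, chrom_sizes) {
  scaled <- unlist(lapply(names(chrom_sizes), function(ch) {
    mids <- sort((loci$start[loci$chrom == ch] +
                  loci$end[loci$chrom == ch]) / 2)
    if (length(mids) < 2L) return(numeric(0))
    diff(mids) * length(mids) / chrom_sizes[[ch]]
  }), use.names = FALSE)
  if (length(scaled) < 30L)
    stop("fewer than 30 inter-locus gaps; the spacing test needs more loci")
  ks <- suppressWarnings(stats::ks.test(scaled, "pexp", 1))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n_gaps = length(scaled))
}
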