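# Zone-based genomic divergence: per-locus pairwise p-distances pooled
# over loci, labeled intra- vs inter-zone under the 2/4/6-zone
# configurations, summarized and tested with a two-way ANOVA (type-II sums
# of squares) and Tukey HSD.

#' Uncorrected pairwise p-distance
#'
#' Sites where either sequence carries a gap, `N` or any IUPAC ambiguity
#' code are excluded; the distance is the proportion of differing sites
#' among the remaining shared unambiguous sites. Heterozygous ambiguity
#' codes are excluded rather than scored so that within-individual
#' heterozygosity is not counted as divergence.
#'
#' @param seq_a,seq_b Equal-length aligned sequences.
#' @return List with `distance` (`NA` when no shared sites) and
#'   `shared_sites`.
#' @export
p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned to equal length")
  a <- utf8ToInt(toupper(seq_a))
  b <- utf8ToInt(toupper(seq_b))
  acgt <- utf8ToInt("ACGT")
  ok <- (a %in% acgt) & (b %in% acgt)
  shared <- sum(ok)
  if (shared == 0L) return(list(distance = NA_real_, shared_sites = 0L))
  list(distance = sum(a[ok] != b[ok]) / shared, shared_sites = shared)
}

#' Pool per-locus pairwise distances
#'
#' One record per (locus, sample pair) for every pair of samples sharing
#' the locus; records are pooled without per-pair averaging. Pairs with no
#' shared comparable sites are dropped (their count is reported in the
#' `n_dropped` attribute).
#'
#' @param loci Locus list (each with `id` and `seqs` named by sample).
#' @return `data.frame` with `locus`, `sample_a`, `sample_b` (unordered
#'   pair, `sample_a` < `sample_b`), `distance`, `shared_sites`.
#' @export
pool_pairwise_distances <- function(loci) {
  recs <- list()
  dropped <- 0L
  for (lc in loci) {
    ids <- sort(names(lc$seqs))
    if (length(ids) < 2L) next
    prs <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(prs))) {
      pd <- p_distance(lc$seqs[[prs[1L, k]]], lc$seqs[[prs[2L, k]]])
      if (is.na(pd$distance)) { dropped <- dropped + 1L; next }
      recs[[length(recs) + 1L]] <-
        data.frame(locus = lc$id, sample_a = prs[1L, k],
                   sample_b = prs[2L, k], distance = pd$distance,
                   shared_sites = pd$shared_sites, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(locus = character(), sample_a = character(),
               sample_b = character(), distance = numeric(),
               shared_sites = integer(), stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Zone configuration
#'
#' @param name One of `"zones2"`, `"zones4"`, `"zones6"` (or any label).
#' @param zone_map Named list (or vector) mapping each species/sample to
#'   its set of zones.
#' @param exclude_multizone Should records involving a species assigned to
#'   more than one zone be labeled `excluded`? (The convention for the
#'   continent/island configuration.)
#' @return A `zone_config` list.
#' @export
zone_config <- function(name, zone_map, exclude_multizone = TRUE) {
  if (!is.list(zone_map)) zone_map <- as.list(zone_map)
  structure(list(name = name, zone_map = zone_map,
                 exclude_multizone = exclude_multizone),
            class = "zone_config")
}

#' Label distance records as intra- or inter-zone
#'
#' A record is `intra` when the two samples share at least one zone,
#' `inter` when their zone sets are disjoint, and `excluded` when either
#' sample belongs to more than one zone and the configuration's exclusion
#' policy applies.
#'
#' @param records Distance records from [pool_pairwise_distances()].
#' @param config A [zone_config()].
#' @return `records` with added columns `type` (`intra`/`inter`/
#'   `excluded`) and `zones` (comma-joined zones of the pair, used to
#'   expand records per zone).
#' @export
label_zone_pairs <- function(records, config) {
  zm <- config$zone_map
  missing <- setdiff(unique(c(records$sample_a, records$sample_b)),
                     names(zm))
  if (length(missing) > 0L)
    stop("species missing from the zone map: ",
         paste(missing, collapse = ", "))
  za <- zm[records$sample_a]
  zb <- zm[records$sample_b]
  multi <- vapply(za, length, 0L) > 1L | vapply(zb, length, 0L) > 1L
  shared <- mapply(function(x, y) length(intersect(x, y)) > 0L, za, zb)
  type <- ifelse(config$exclude_multizone & multi, "excluded",
                 ifelse(shared, "intra", "inter"))
  records$type <- type
  records$zones <- mapply(function(x, y, ty) {
    if (ty == "intra") paste(intersect(x, y), collapse = ",")
    else paste(sort(unique(c(x, y))), collapse = ",")
  }, za, zb, type)
  records
}

# one row per (record, involved zone); excluded records are dropped
expand_by_zone <- function(labeled) {
  keep <- labeled$type != "excluded"
  lab <- labeled[keep, , drop = FALSE]
  zs <- strsplit(lab$zones, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(lab)), vapply(zs, length, 0L))
  out <- lab[idx, c("locus", "sample_a", "sample_b", "distance", "type")]
  out$zone <- unlist(zs)
  rownames(out) <- NULL
  out
}

#' Group summaries of labeled distances
#'
#' Medians, quartiles and counts per (zone, distance type) group, the
#' groups plotted in the zone-divergence density histograms.
#'
#' @param labeled Labeled records from [label_zone_pairs()].
#' @return `data.frame` with `zone`, `type`, `n`, `median`, `q1`, `q3`
#'   (`NA` summaries for empty groups).
#' @export
group_summaries <- function(labeled) {
  ex <- expand_by_zone(labeled)
  zones <- sort(unique(ex$zone))
  out <- do.call(rbind, lapply(zones, function(z) {
    do.call(rbind, lapply(c("intra", "inter"), function(ty) {
      d <- ex$distance[ex$zone == z & ex$type == ty]
      data.frame(zone = z, type = ty, n = length(d),
                 median = if (length(d)) stats::median(d) else NA_real_,
                 q1 = if (length(d)) unname(stats::quantile(d, 0.25))
                      else NA_real_,
                 q3 = if (length(d)) unname(stats::quantile(d, 0.75))
                      else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA of distance type and zone
#'
#' Genomic distance is modeled on distance type (intra/inter) and zone,
#' with their interaction, using type-II sums of squares (the records are
#' unbalanced: pairs per group vary).
#'
#' @param labeled Labeled records from [label_zone_pairs()].
#' @return `data.frame` with one row per term (`type`, `zone`,
#'   `type:zone`, `Residuals`): `df`, `sum_sq`, `f_value`, `p_value`.
#' @export
two_way_anova <- function(labeled) {
  ex <- expand_by_zone(labeled)
  ex$type <- factor(ex$type)
  ex$zone <- factor(ex$zone)
  if (nlevels(ex$type) < 2L || nlevels(ex$zone) < 2L)
    stop("both factors need at least two levels")
  fit <- stats::lm(distance ~ type * zone, data = ex)
  a <- tryCatch({
    # capture car's console note about aliased coefficients
    utils::capture.output(
      utils::capture.output(res <- car::Anova(fit, type = 2),
                            type = "message"))
    res
  }, error = function(e) NULL)
  if (is.null(a)) {
    # degenerate data (zero residual variance): type-II SS by explicit
    # model comparison; F is then infinite for non-null terms
    sse <- function(form) sum(stats::residuals(stats::lm(form,
                                                         data = ex))^2)
    s_full <- sse(distance ~ type * zone)
    s_add <- sse(distance ~ type + zone)
    ss <- c(type = sse(distance ~ zone) - s_add,
            zone = sse(distance ~ type) - s_add,
            `type:zone` = s_add - s_full)
    dfs <- c(nlevels(ex$type) - 1L, nlevels(ex$zone) - 1L,
             (nlevels(ex$type) - 1L) * (nlevels(ex$zone) - 1L))
    df_res <- nrow(ex) - sum(dfs) - 1L
    ms_res <- s_full / df_res
    f <- ifelse(ms_res > 0, (ss / dfs) / ms_res, Inf)
    p <- ifelse(is.finite(f), stats::pf(f, dfs, df_res, lower.tail = FALSE),
                0)
    a <- data.frame(Df = c(dfs, df_res), `Sum Sq` = c(ss, s_full),
                    `F value` = c(f, NA), `Pr(>F)` = c(p, NA),
                    check.names = FALSE,
                    row.names = c(names(ss), "Residuals"))
  }
  out <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    f_value = a$`F value`, p_value = a$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group-mean differences for a factor after the two-way
#' model, with studentized-range family-wise adjusted p-values and a
#' significance flag at 0.01.
#'
#' @param labeled Labeled records from [label_zone_pairs()].
#' @param factor_name `"zone"`, `"type"` or `"type:zone"`.
#' @param alpha Significance threshold for the flag (default 0.01).
#' @return `data.frame` with `comparison`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(labeled, factor_name = "zone", alpha = 0.01) {
  ex <- expand_by_zone(labeled)
  ex$type <- factor(ex$type)
  ex$zone <- factor(ex$zone)
  fit <- stats::aov(distance ~ type * zone, data = ex)
  tk <- stats::TukeyHSD(fit, which = factor_name)[[factor_name]]
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
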