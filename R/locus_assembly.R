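# Locus assembly: read quality filtering, greedy within-sample clustering,
# joint ML estimation of heterozygosity and sequencing error, statistical
# consensus calling, across-sample clustering, and the explicit filter
# cascade (depth / alleles / N / heterozygous sites / indels / taxon
# occupancy) with a per-reason FilterReport.

#' Assembly parameter set
#'
#' Defaults follow the conservative reduced-representation settings used
#' for multi-species MIGseq assemblies: minimum depth 5 for statistical
#' base calling, at most 2 alleles per locus (diploids; more indicates a
#' collapsed paralog), at most 5 N and 8 heterozygous sites per consensus,
#' at most 40 indels per locus, loci kept when found in at least
#' `min_taxa` (default 4) samples, clustering identity 0.85, and reads
#' discarded when more than 50 bases fall below Phred 20.
#'
#' @param min_depth,max_alleles,max_N,max_het,max_indels,min_taxa Counts.
#' @param identity Within- and across-sample clustering identity in (0.5, 1].
#' @param max_low_quality_bases Maximum number of low-quality bases per read.
#' @param low_quality_threshold Phred threshold defining a low-quality base.
#' @return A list of class `assembly_params`.
#' @export
assembly_params <- function(min_depth = 5L, max_alleles = 2L, max_N = 5L,
                            max_het = 8L, max_indels = 40L, min_taxa = 4L,
                            identity = 0.85, max_low_quality_bases = 50L,
                            low_quality_threshold = 20L) {
  p <- list(min_depth = min_depth, max_alleles = max_alleles, max_N = max_N,
            max_het = max_het, max_indels = max_indels, min_taxa = min_taxa,
            identity = identity,
            max_low_quality_bases = max_low_quality_bases,
            low_quality_threshold = low_quality_threshold)
  counts <- unlist(p[c("min_depth", "max_alleles", "max_N", "max_het",
                       "max_indels", "min_taxa", "max_low_quality_bases")])
  if (any(counts < 0)) stop("count parameters must be >= 0")
  if (identity <= 0.5 || identity > 1) stop("identity must be in (0.5, 1]")
  class(p) <- "assembly_params"
  p
}

FILTER_REASONS <- c("low_taxa", "excess_alleles", "excess_N", "excess_het",
                    "excess_indels", "low_depth")

#' Filter reads on base quality
#'
#' Removes reads carrying more than `max_low_quality_bases` bases with
#' Phred quality below `low_quality_threshold`.
#'
#' @param reads Read-set `data.frame` (`id`, `seq`, `qual`).
#' @param params An [assembly_params()] list.
#' @return List with `reads` (kept reads), `reads_raw` and
#'   `reads_passed_filter` counts.
#' @export
quality_filter_reads <- function(reads, params = assembly_params()) {
  if (is.null(reads$qual) || any(is.na(reads$qual)) ||
      any(nchar(reads$qual) == 0L & nchar(reads$seq) > 0L))
    stop("reads are missing base qualities")
  n_low <- vapply(reads$qual, function(q)
    sum(utf8ToInt(q) - 33L < params$low_quality_threshold), integer(1),
    USE.NAMES = FALSE)
  keep <- n_low <= params$max_low_quality_bases
  list(reads = reads[keep, , drop = FALSE],
       reads_raw = nrow(reads),
       reads_passed_filter = sum(keep))
}

#' Greedy within-sample read clustering
#'
#' Reads are dereplicated, sorted by abundance then lexicographically, and
#' assigned greedily: each sequence joins the first centroid whose
#' ungapped, end-anchored identity over the overlap reaches `identity`,
#' otherwise it founds a new cluster. Fully deterministic.
#'
#' @param reads Read-set `data.frame` from one sample.
#' @param identity Identity threshold.
#' @return List of clusters; each has `centroid` (sequence), `members`
#'   (`data.frame` with `seq`, `count`) and `depth` (total read count).
#' @export
cluster_within_sample <- function(reads, identity = 0.85) {
  if (nrow(reads) == 0L) return(list())
  tab <- table(reads$seq)
  seqs <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, seqs)
  seqs <- seqs[ord]; cnt <- cnt[ord]
  ints <- lapply(seqs, utf8ToInt)
  cent_idx <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(cent_idx)) {
      a <- ints[[cent_idx[ci]]]; b <- ints[[i]]
      n <- min(length(a), length(b))
      if (n > 0L && sum(a[seq_len(n)] == b[seq_len(n)]) / n >= identity) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      assign[i] <- length(cent_idx)
    }
  }
  lapply(seq_along(cent_idx), function(ci) {
    m <- which(assign == ci)
    list(centroid = seqs[cent_idx[ci]],
         members = data.frame(seq = seqs[m], count = cnt[m],
                              stringsAsFactors = FALSE),
         depth = sum(cnt[m]))
  })
}

# Per-site base count matrix (rows = sites, cols = A,C,G,T) for a cluster,
# truncated to the centroid length; member counts weight the tallies.
cluster_site_counts <- function(cluster) {
  L <- nchar(cluster$centroid)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(nrow(cluster$members))) {
    s <- cluster$members$seq[i]
    n <- min(nchar(s), L)
    ch <- strsplit(substr(s, 1L, n), "", fixed = TRUE)[[1L]]
    j <- match(ch, BASES)
    ok <- !is.na(j)
    idx <- cbind(seq_len(n)[ok], j[ok])
    counts[idx] <- counts[idx] + cluster$members$count[i]
  }
  counts
}

# Log-likelihood of aggregated site count patterns under the diploid site
# model: a site is heterozygous with probability h (two alleles at 50:50)
# or homozygous; each read base is miscalled with probability e, uniformly
# to the three other bases. Multinomial coefficients are constant in (h, e)
# and omitted.
het_error_loglik <- function(h, e, patterns, weights) {
  n_tot <- rowSums(patterns)
  p_hit <- 1 - e            # P(read allele base | homozygous)
  p_err <- e / 3
  p_het <- (1 - e) / 2 + e / 6  # P(read one named allele | heterozygous)
  # homozygous: sum over the 4 candidate true bases
  l_homo <- rowSums(exp(patterns * log(p_hit) +
                        (n_tot - patterns) * log(p_err))) / 4
  # heterozygous: sum over the 6 unordered base pairs
  pairs <- utils::combn(4L, 2L)
  l_het <- 0
  for (k in seq_len(ncol(pairs))) {
    nb <- patterns[, pairs[1L, k]] + patterns[, pairs[2L, k]]
    l_het <- l_het + exp(nb * log(p_het) + (n_tot - nb) * log(p_err))
  }
  l_het <- l_het / 6
  sum(weights * log((1 - h) * l_homo + h * l_het))
}

#' Joint ML estimation of heterozygosity and sequencing error
#'
#' Maximizes the diploid site-model likelihood over `(h, e)`: each site is
#' heterozygous with probability `h` (two true bases at 50:50) or
#' homozygous, and each read base is miscalled with probability `e`
#' (uniformly to the three other bases). Only clusters at or above
#' `min_depth` contribute.
#'
#' @param clusters Cluster list from [cluster_within_sample()].
#' @param min_depth Minimum cluster depth.
#' @return Named numeric vector `c(hetero_est =, error_est =)`.
#' @export
estimate_het_error <- function(clusters, min_depth = 5L) {
  use <- Filter(function(cl) cl$depth >= min_depth, clusters)
  if (length(use) == 0L)
    stop("no cluster reaches min_depth = ", min_depth)
  counts <- do.call(rbind, lapply(use, cluster_site_counts))
  # aggregate sites sharing a sorted count pattern (the likelihood is
  # symmetric under base permutation)
  key <- apply(counts, 1L, function(r) paste(sort(r), collapse = ","))
  agg <- rowsum(rep(1L, nrow(counts)), key)
  patterns <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.integer))
  weights <- agg[, 1L]
  obj <- function(par) {
    h <- stats::plogis(par[1L]); e <- stats::plogis(par[2L])
    -het_error_loglik(h, e, patterns, weights)
  }
  fit <- stats::optim(c(stats::qlogis(0.01), stats::qlogis(0.005)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  c(hetero_est = stats::plogis(fit$par[1L]),
    error_est = stats::plogis(fit$par[2L]))
}

# Site posterior over the 10 genotype states (4 homozygous + 6
# heterozygous); returns the called character (base, IUPAC code) and
# whether the call is heterozygous.
call_site <- function(counts, h, e) {
  n_tot <- sum(counts)
  lp_homo <- log((1 - h) / 4) + counts * log(1 - e) +
    (n_tot - counts) * log(e / 3)
  pairs <- utils::combn(4L, 2L)
  p_het <- (1 - e) / 2 + e / 6
  lp_het <- vapply(seq_len(ncol(pairs)), function(k) {
    nb <- counts[pairs[1L, k]] + counts[pairs[2L, k]]
    log(h / 6) + nb * log(p_het) + (n_tot - nb) * log(e / 3)
  }, numeric(1))
  if (max(lp_het) > max(lp_homo)) {
    k <- which.max(lp_het)
    pair <- sort(BASES[pairs[, k]])
    list(call = HET_CODE[[paste(pair, collapse = "")]], het = TRUE,
         alleles = pair)
  } else {
    b <- BASES[which.max(lp_homo)]
    list(call = b, het = FALSE, alleles = b)
  }
}

#' Call a consensus sequence from a read cluster
#'
#' Per site, the maximum-posterior genotype under the `(h, e)` site model
#' is called: a homozygous base or a two-base IUPAC ambiguity code; sites
#' whose coverage falls below `min_depth` are called `N`. The cluster is
#' rejected (a tagged return, not an error) when its depth is below
#' `min_depth`, when the phased allele count exceeds `max_alleles`, or
#' when the N or heterozygous-site counts exceed their caps.
#'
#' @param cluster Cluster from [cluster_within_sample()].
#' @param hetero_est,error_est Estimates from [estimate_het_error()].
#' @param params An [assembly_params()] list.
#' @return List with `status` (`"ok"` or `"rejected"`), `reason` (one of
#'   low_depth/excess_alleles/excess_N/excess_het when rejected),
#'   `consensus`, `depth`, `n_het`, `n_N`, `n_alleles`.
#' @export
call_consensus <- function(cluster, hetero_est, error_est,
                           params = assembly_params()) {
  h <- min(max(hetero_est, 1e-9), 1 - 1e-9)
  e <- min(max(error_est, 1e-9), 1 - 1e-9)
  counts <- cluster_site_counts(cluster)
  L <- nrow(counts)
  cov <- rowSums(counts)
  call <- character(L)
  het <- logical(L)
  allele_bases <- vector("list", L)
  for (i in seq_len(L)) {
    if (cov[i] < params$min_depth) {
      call[i] <- "N"
    } else {
      s <- call_site(counts[i, ], h, e)
      call[i] <- s$call
      het[i] <- s$het
      allele_bases[[i]] <- s$alleles
    }
  }
  n_N <- sum(call == "N")
  n_het <- sum(het)
  # phase reads across heterozygous sites to count distinct alleles
  n_alleles <- 1L
  het_pos <- which(het)
  if (length(het_pos) > 0L) {
    haps <- character(0)
    for (i in seq_len(nrow(cluster$members))) {
      s <- cluster$members$seq[i]
      if (nchar(s) < max(het_pos)) next
      hp <- paste(vapply(het_pos, function(p) substr(s, p, p), character(1)),
                  collapse = "")
      ok <- all(vapply(seq_along(het_pos), function(k)
        substr(hp, k, k) %in% allele_bases[[het_pos[k]]], logical(1)))
      if (ok) haps <- c(haps, rep(hp, cluster$members$count[i]))
    }
    ht <- table(haps)
    n_alleles <- max(1L, sum(ht >= 2L))
  }
  res <- list(consensus = chars_to_seq(call), depth = cluster$depth,
              n_het = n_het, n_N = n_N, n_alleles = n_alleles)
  reason <- if (cluster$depth < params$min_depth) "low_depth"
    else if (n_alleles > params$max_alleles) "excess_alleles"
    else if (n_N > params$max_N) "excess_N"
    else if (n_het > params$max_het) "excess_het"
    else NA_character_
  c(list(status = if (is.na(reason)) "ok" else "rejected", reason = reason),
    res)
}

# End-anchored (free end-gap) alignment of a member sequence onto centroid
# coordinates; returns the projected member (centroid length, "-" at
# deletions/uncovered ends) and the total indel count.
project_onto_centroid <- function(member, centroid) {
  if (nchar(member) == nchar(centroid))
    return(list(aligned = member, indels = 0L))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(member), Biostrings::DNAString(centroid),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  out <- rep("-", nchar(centroid))
  pos <- 0L
  indels <- 0L
  for (k in seq_along(s)) {
    if (s[k] == "-") {          # insertion relative to the centroid
      indels <- indels + 1L
    } else {
      pos <- pos + 1L
      out[pos] <- p[k]
      if (p[k] == "-") indels <- indels + 1L
    }
  }
  list(aligned = chars_to_seq(out), indels = indels)
}

#' Greedy across-sample clustering of consensus sequences
#'
#' Consensus sequences (one per sample and candidate locus) are sorted by
#' depth then lexicographically and clustered greedily at
#' `params$identity`; members are aligned onto the centroid by
#' end-anchored alignment with gaps and the locus-level indel total is
#' recorded. When a sample contributes several consensuses to one cluster
#' only the deepest is kept.
#'
#' @param consensus `data.frame` with columns `sample_id`, `seq`, `depth`
#'   and optionally `status`/`reason` carried from [call_consensus()].
#' @param params An [assembly_params()] list.
#' @return List of candidate loci: `id`, `centroid`, `members`
#'   (`data.frame`: `sample_id`, `seq` aligned to centroid coordinates,
#'   `depth`, `status`, `reason`), `n_indels`.
#' @export
cluster_across_samples <- function(consensus, params = assembly_params()) {
  if (nrow(consensus) < 1L) return(list())
  if (is.null(consensus$status)) consensus$status <- "ok"
  if (is.null(consensus$reason)) consensus$reason <- NA_character_
  ord <- order(-consensus$depth, consensus$seq)
  consensus <- consensus[ord, , drop = FALSE]
  ints <- lapply(consensus$seq, utf8ToInt)
  cent_idx <- integer(0)
  assign <- integer(nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    placed <- FALSE
    for (ci in seq_along(cent_idx)) {
      a <- ints[[cent_idx[ci]]]; b <- ints[[i]]
      n <- min(length(a), length(b))
      if (n > 0L && sum(a[seq_len(n)] == b[seq_len(n)]) / n >=
          params$identity) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      cent_idx <- c(cent_idx, i)
      assign[i] <- length(cent_idx)
    }
  }
  lapply(seq_along(cent_idx), function(ci) {
    m <- which(assign == ci)
    centroid <- consensus$seq[cent_idx[ci]]
    # one consensus per sample: keep the deepest (rows are depth-sorted)
    m <- m[!duplicated(consensus$sample_id[m])]
    indels <- 0L
    aligned <- character(length(m))
    for (k in seq_along(m)) {
      pr <- project_onto_centroid(consensus$seq[m[k]], centroid)
      aligned[k] <- pr$aligned
      indels <- indels + pr$indels
    }
    list(id = sprintf("locus%04d", ci), centroid = centroid,
         members = data.frame(sample_id = consensus$sample_id[m],
                              seq = aligned, depth = consensus$depth[m],
                              status = consensus$status[m],
                              reason = consensus$reason[m],
                              stringsAsFactors = FALSE),
         n_indels = indels)
  })
}

new_filter_report <- function(input, removed_by, union_removed, retained) {
  rb <- stats::setNames(integer(length(FILTER_REASONS)), FILTER_REASONS)
  rb[names(removed_by)] <- removed_by
  structure(list(input = input, removed = as.list(rb),
                 n_removed = union_removed, retained = retained,
                 non_exclusive = TRUE),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Locus filter report\n")
  cat("  candidate loci:", x$input, "\n")
  for (r in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  cat("  removed (union of reasons):", x$n_removed, "\n")
  cat("  retained:", x$retained, "\n")
  cat("  per-reason counts are non-exclusive:", x$non_exclusive, "\n")
  invisible(x)
}

#' Apply the locus filter cascade
#'
#' Candidate loci (from [cluster_across_samples()]) pass through the full
#' cascade: member consensuses rejected at consensus calling are dropped
#' (their reasons attach to the locus), loci with more than `max_indels`
#' indels are removed (`excess_indels`), and loci left with fewer than
#' `min_taxa` samples are removed (`low_taxa`). A locus removed for
#' several reasons counts under each of them, so per-reason counts are
#' non-exclusive and need not sum to `input - retained`; the report flags
#' this.
#'
#' @param candidates Candidate locus list.
#' @param params An [assembly_params()] list.
#' @return List with `loci` (retained locus alignments: `id`, `seqs`
#'   named by sample, `depths`) and `report` (a `filter_report`).
#' @export
filter_loci <- function(candidates, params = assembly_params()) {
  reasons <- lapply(candidates, function(lc) {
    r <- unique(stats::na.omit(lc$members$reason[lc$members$status !=
                                                 "ok"]))
    keep <- lc$members$status == "ok"
    if (lc$n_indels > params$max_indels) r <- c(r, "excess_indels")
    if (sum(keep) < params$min_taxa) r <- c(r, "low_taxa")
    list(reasons = r, keep = keep,
         rejected = lc$n_indels > params$max_indels ||
                    sum(keep) < params$min_taxa)
  })
  rejected <- vapply(reasons, `[[`, logical(1), "rejected")
  reason_counts <- table(factor(unlist(lapply(reasons[rejected],
                                              `[[`, "reasons")),
                                levels = FILTER_REASONS))
  retained <- which(!rejected)
  loci <- lapply(retained, function(i) {
    lc <- candidates[[i]]
    keep <- reasons[[i]]$keep
    list(id = lc$id,
         seqs = stats::setNames(lc$members$seq[keep],
                                lc$members$sample_id[keep]),
         depths = stats::setNames(lc$members$depth[keep],
                                  lc$members$sample_id[keep]))
  })
  report <- new_filter_report(length(candidates),
                              as.integer(reason_counts)[
                                match(FILTER_REASONS,
                                      names(reason_counts))] |>
                                stats::setNames(FILTER_REASONS),
                              sum(rejected), length(retained))
  list(loci = loci, report = report)
}

#' Remove loci found in too few samples
#'
#' The final cascade step in isolation: loci present in fewer than
#' `min_taxa` samples are removed and counted as `low_taxa`. Prior-stage
#' reason counts may be passed in to aggregate a full report.
#'
#' @param loci Locus list (each with `seqs` named by sample).
#' @param min_taxa Minimum number of samples per locus.
#' @param prior_removed Optional named integer vector of earlier
#'   per-reason removal counts.
#' @param input Total candidate count entering the cascade (defaults to
#'   `length(loci)` plus prior removals).
#' @return List with `loci` (retained) and `report`.
#' @export
filter_min_taxa <- function(loci, min_taxa = 4L, prior_removed = NULL,
                            input = NULL) {
  n_samp <- vapply(loci, function(l) length(l$seqs), integer(1))
  keep <- n_samp >= min_taxa
  removed <- stats::setNames(integer(length(FILTER_REASONS)), FILTER_REASONS)
  if (!is.null(prior_removed))
    removed[names(prior_removed)] <- as.integer(prior_removed)
  removed["low_taxa"] <- removed["low_taxa"] + sum(!keep)
  input <- input %||% (length(loci) + sum(removed) - sum(!keep))
  report <- new_filter_report(input, removed,
                              union_removed = input - sum(keep),
                              retained = sum(keep))
  list(loci = loci[keep], report = report)
}

#' Run the full assembly pipeline for a set of samples
#'
#' Chains quality filtering, within-sample clustering, heterozygosity and
#' error estimation, consensus calling, across-sample clustering and the
#' filter cascade, and tabulates per-sample assembly statistics.
#'
#' @param reads_by_sample Named list (by sample id) of read-set
#'   `data.frame`s.
#' @param params An [assembly_params()] list.
#' @return List with `loci`, `report`, `stats` (a `data.frame` of
#'   [compute_assembly_stats()]) and `per_sample` intermediates.
#' @export
assemble_loci <- function(reads_by_sample, params = assembly_params()) {
  per_sample <- lapply(names(reads_by_sample), function(s) {
    qf <- quality_filter_reads(reads_by_sample[[s]], params)
    clusters <- cluster_within_sample(qf$reads, params$identity)
    he <- tryCatch(estimate_het_error(clusters, params$min_depth),
                   error = function(e) c(hetero_est = NA_real_,
                                         error_est = NA_real_))
    cons <- lapply(clusters, function(cl)
      call_consensus(cl, he[["hetero_est"]] %|na|% 0.001,
                     he[["error_est"]] %|na|% 0.001, params))
    list(sample_id = s, reads_raw = qf$reads_raw,
         reads_passed_filter = qf$reads_passed_filter,
         clusters = clusters, hetero_est = he[["hetero_est"]],
         error_est = he[["error_est"]], consensus = cons)
  })
  names(per_sample) <- names(reads_by_sample)
  cons_df <- do.call(rbind, lapply(per_sample, function(ps) {
    if (length(ps$consensus) == 0L) return(NULL)
    data.frame(sample_id = ps$sample_id,
               seq = vapply(ps$consensus, `[[`, "", "consensus"),
               depth = vapply(ps$consensus, `[[`, 0, "depth"),
               status = vapply(ps$consensus, `[[`, "", "status"),
               reason = vapply(ps$consensus, function(x)
                 x$reason %||% NA_character_, NA_character_),
               stringsAsFactors = FALSE)
  }))
  candidates <- if (is.null(cons_df)) list() else
    cluster_across_samples(cons_df, params)
  fl <- filter_loci(candidates, params)
  stats_df <- compute_assembly_stats(per_sample, fl$loci, params)
  list(loci = fl$loci, report = fl$report, stats = stats_df,
       per_sample = per_sample, candidates = candidates)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Per-sample assembly statistics
#'
#' One row per sample: raw and quality-passed read counts, total clusters,
#' clusters at or above the depth threshold, the heterozygosity and error
#' estimates, reads incorporated into accepted consensuses and the final
#' number of retained loci containing the sample.
#'
#' @param per_sample Per-sample intermediates from [assemble_loci()].
#' @param loci Retained loci.
#' @param params An [assembly_params()] list.
#' @return `data.frame` with columns `sample_id`, `reads_raw`,
#'   `reads_passed_filter`, `clusters_total`, `clusters_hidepth`,
#'   `hetero_est`, `error_est`, `reads_consens`, `loci_in_assembly`.
#' @export
compute_assembly_stats <- function(per_sample, loci,
                                   params = assembly_params()) {
  loci_count <- table(unlist(lapply(loci, function(l) names(l$seqs))))
  out <- do.call(rbind, lapply(per_sample, function(ps) {
    depths <- vapply(ps$clusters, `[[`, 0, "depth")
    ok <- vapply(ps$consensus, `[[`, "", "status") == "ok"
    data.frame(
      sample_id = ps$sample_id,
      reads_raw = ps$reads_raw,
      reads_passed_filter = ps$reads_passed_filter,
      clusters_total = length(ps$clusters),
      clusters_hidepth = sum(depths >= params$min_depth),
      hetero_est = ps$hetero_est,
      error_est = ps$error_est,
      reads_consens = sum(depths[ok]),
      loci_in_assembly = as.integer(loci_count[ps$sample_id] %|na0|% 0L),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%|na0|%` <- function(a, b) if (is.na(a) || length(a) == 0L) b else a

#' Compare assembly statistics between two sample groups
#'
#' Per statistic: group means and a two-sided test p-value. The default is
#' the Mann-Whitney U (Wilcoxon rank-sum) test, robust for the small,
#' skewed per-sample statistics typical of mixed herbarium/silica
#' samplings; Welch's t is available. P-values are reported raw, without
#' multiplicity correction.
#'
#' @param stats_df Statistics table from [compute_assembly_stats()].
#' @param groups Named character vector (or factor) mapping `sample_id` to
#'   one of exactly two groups, each with n >= 3.
#' @param test `"wilcox"` or `"welch"`.
#' @return `data.frame` with one row per statistic: group means and
#'   `p_value`.
#' @export
compare_groups <- function(stats_df, groups, test = c("wilcox", "welch")) {
  test <- match.arg(test)
  g <- groups[stats_df$sample_id]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 3L)) stop("each group needs at least 3 samples")
  stat_cols <- setdiff(names(stats_df), "sample_id")
  out <- do.call(rbind, lapply(stat_cols, function(cn) {
    x <- stats_df[[cn]][g == lev[1L]]
    y <- stats_df[[cn]][g == lev[2L]]
    p <- if (all(is.na(x)) || all(is.na(y))) NA_real_
      else if (test == "wilcox")
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      else stats::t.test(x, y)$p.value
    d <- data.frame(statistic = cn, m1 = mean(x, na.rm = TRUE),
                    m2 = mean(y, na.rm = TRUE), p_value = p,
                    stringsAsFactors = FALSE)
    names(d)[2:3] <- paste0("mean_", lev)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Correlation matrix over assembly statistics
#'
#' Signed Pearson correlations across the assembly statistics plus sample
#' age when supplied; zero-variance columns yield `NA` correlations.
#'
#' @param stats_df Statistics table from [compute_assembly_stats()].
#' @param age Optional numeric vector of sample ages (aligned with rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlogram_stats <- function(stats_df, age = NULL) {
  if (nrow(stats_df) < 4L) stop("need at least 4 samples")
  m <- as.matrix(stats_df[setdiff(names(stats_df), "sample_id")])
  if (!is.null(age)) m <- cbind(m, age = age)
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cc[sds == 0 | is.na(sds), ] <- NA
  cc[, sds == 0 | is.na(sds)] <- NA
  diag(cc) <- ifelse(sds > 0 & !is.na(sds), 1, NA)
  cc
}
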