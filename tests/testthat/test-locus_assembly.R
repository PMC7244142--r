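make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))  # Phred 40
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

test_that("quality filtering drops reads exceeding the low-quality cap", {
  p <- assembly_params()
  # 51 bases at Phred 2 (quality char '#'), threshold 20, cap 50: removed
  bad <- make_reads(strrep("A", 60), paste0(strrep("#", 51), strrep("I", 9)))
  good <- make_reads(strrep("A", 60))
  qf <- quality_filter_reads(rbind(bad, good), p)
  expect_equal(qf$reads_raw, 2L)
  expect_equal(qf$reads_passed_filter, 1L)
  # exactly 50 low-quality bases is still allowed
  edge <- make_reads(strrep("A", 60), paste0(strrep("#", 50), strrep("I", 10)))
  expect_equal(quality_filter_reads(edge, p)$reads_passed_filter, 1L)
  expect_error(quality_filter_reads(data.frame(id = "r", seq = "ACGT",
                                               stringsAsFactors = FALSE), p),
               "qualit")
})

test_that("kept read set equals a brute-force low-quality recount", {
  set.seed(31)
  n <- 1000
  lens <- sample(50:80, n, replace = TRUE)
  reads <- make_reads(
    vapply(lens, function(L) paste(sample(c("A", "C", "G", "T"), L,
                                          replace = TRUE), collapse = ""),
           character(1)),
    vapply(lens, function(L) paste(sample(c("#", "5", "I"), L, replace = TRUE,
                                          prob = c(0.45, 0.1, 0.45)),
                                   collapse = ""), character(1)))
  p <- assembly_params(max_low_quality_bases = 30L)
  qf <- quality_filter_reads(reads, p)
  oracle_keep <- vapply(reads$qual, function(q) {
    sum(vapply(strsplit(q, "")[[1]],
               function(ch) utf8ToInt(ch) - 33 < 20, logical(1))) <= 30
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(qf$reads$id, reads$id[oracle_keep])
})

test_that("within-sample clustering is greedy, deterministic and abundance-led", {
  reads <- make_reads(rep("ACGTACGTAC", 10))
  cl <- cluster_within_sample(reads, 0.85)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$depth, 10L)
  # 30% divergent groups split at identity 0.85
  a <- strrep("ACGTACGTAC", 3)
  b <- paste0(strrep("ACGTACGTAC", 2), strrep("GTCAGTCAGT", 1))
  cl <- cluster_within_sample(make_reads(c(rep(a, 5), rep(b, 4))), 0.85)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$depth, 5L)  # most abundant sequence founds first
})

test_that("clustering matches the brute-force all-pairs greedy oracle", {
  set.seed(77)
  for (rep in 1:5) {
    base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    seqs <- vapply(1:40, function(i) {
      ch <- strsplit(base, "")[[1]]
      k <- sample(0:20, 1)
      pos <- sample(60, k)
      ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    reads <- make_reads(seqs[sample(40, 120, replace = TRUE)])
    got <- cluster_within_sample(reads, 0.9)
    tab <- table(reads$seq)
    orc <- oracle_greedy_clusters(names(tab), as.integer(tab), 0.9)
    expect_length(got, orc$n_clusters)
    got_sizes <- sort(vapply(got, `[[`, 0L, "depth"))
    orc_sizes <- sort(as.integer(tapply(orc$counts, orc$assign, sum)))
    expect_equal(got_sizes, orc_sizes)
  }
})

test_that("heterozygosity/error ML behaves at the boundaries", {
  # unanimous sites: both estimates collapse to the numerical floor
  cl <- list(list(centroid = strrep("ACGT", 25),
                  members = data.frame(seq = strrep("ACGT", 25), count = 20L),
                  depth = 20L))
  est <- estimate_het_error(cl, 5L)
  expect_lt(est[["hetero_est"]], 1e-4)
  expect_lt(est[["error_est"]], 1e-4)
  expect_error(estimate_het_error(list(), 5L), "min_depth")
  # an exact 15:15 two-base split is called heterozygous, not two errors
  site <- c(paste(rep("A", 30), collapse = ""))
  cl <- list(list(centroid = "A",
                  members = data.frame(seq = c("A", "C"), count = c(15L, 15L)),
                  depth = 30L))
  cons <- call_consensus(cl[[1]], hetero_est = 0.01, error_est = 1e-4,
                         params = assembly_params(max_alleles = 4L))
  expect_equal(cons$consensus, "M")
})

test_that("ML estimates recover simulated h and e within 25% (grid-checked)", {
  clusters <- simulate_het_clusters(120, depth = 30, len = 40,
                                    h = 0.01, e = 0.005, seed = 5)
  est <- estimate_het_error(clusters, 5L)
  expect_lt(abs(est[["hetero_est"]] - 0.01) / 0.01, 0.25)
  expect_lt(abs(est[["error_est"]] - 0.005) / 0.005, 0.25)
  # grid-search oracle with independent likelihood code agrees to grid
  # resolution
  counts <- do.call(rbind, lapply(clusters, migseqr:::cluster_site_counts))
  h_grid <- seq(0.004, 0.02, by = 0.002)
  e_grid <- seq(0.002, 0.01, by = 0.001)
  orc <- oracle_het_error_grid(counts, h_grid, e_grid)
  expect_lt(abs(est[["hetero_est"]] - orc[["h"]]), 0.002)
  expect_lt(abs(est[["error_est"]] - orc[["e"]]), 0.001)
})

test_that("consensus calling rejects clusters per the depth/allele/N/het caps", {
  p <- assembly_params()
  mk <- function(seqs, counts) list(centroid = seqs[1],
                                    members = data.frame(seq = seqs,
                                                         count = counts),
                                    depth = sum(counts))
  # depth 4 < 5: low_depth
  r <- call_consensus(mk(strrep("ACGT", 20), 4L), 0.01, 0.005, p)
  expect_equal(r$status, "rejected")
  expect_equal(r$reason, "low_depth")
  # 10 A / 10 C column: IUPAC M
  s1 <- paste0("A", strrep("ACGT", 10))
  s2 <- paste0("C", strrep("ACGT", 10))
  r <- call_consensus(mk(c(s1, s2), c(10L, 10L)), 0.01, 0.005, p)
  expect_equal(r$status, "ok")
  expect_equal(substr(r$consensus, 1, 1), "M")
  expect_equal(r$n_het, 1L)
  # three phased haplotypes across two het sites: excess_alleles
  h1 <- paste0("AA", strrep("ACGT", 10))
  h2 <- paste0("CC", strrep("ACGT", 10))
  h3 <- paste0("AC", strrep("ACGT", 10))
  r <- call_consensus(mk(c(h1, h2, h3), c(8L, 8L, 8L)), 0.01, 0.005, p)
  expect_equal(r$status, "rejected")
  expect_equal(r$reason, "excess_alleles")
})

test_that("across-sample clustering separates divergent consensuses", {
  cons <- data.frame(sample_id = sprintf("s%d", 1:5),
                     seq = rep(strrep("ACGTT", 20), 5),
                     depth = rep(10, 5), stringsAsFactors = FALSE)
  loci <- cluster_across_samples(cons, assembly_params())
  expect_length(loci, 1L)
  expect_equal(nrow(loci[[1]]$members), 5L)
  # 30% divergent pair at threshold 0.85 splits
  cons2 <- data.frame(
    sample_id = c("s1", "s2"),
    seq = c(strrep("ACGTACGTAC", 5),
            paste0(strrep("ACGTACGTAC", 3), strrep("TGCATGCATG", 2))),
    depth = c(10, 8), stringsAsFactors = FALSE)
  expect_length(cluster_across_samples(cons2, assembly_params()), 2L)
})

test_that("filter cascade counts every reason and is idempotent", {
  p <- assembly_params(min_taxa = 4L)
  base <- strrep("ACGTG", 30)
  mk_member <- function(s, status = "ok", reason = NA_character_,
                        depth = 10)
    data.frame(sample_id = s, seq = base, depth = depth, status = status,
               reason = reason, stringsAsFactors = FALSE)
  mk_locus <- function(id, members, n_indels = 0L)
    list(id = id, centroid = base, members = do.call(rbind, members),
         n_indels = n_indels)
  cands <- list(
    mk_locus("L1", lapply(sprintf("s%d", 1:5), mk_member)),          # clean
    mk_locus("L2", lapply(sprintf("s%d", 1:3), mk_member)),          # low_taxa
    mk_locus("L3", c(lapply(sprintf("s%d", 1:3), mk_member),
                     list(mk_member("s4", "rejected", "excess_N")))), # N
    mk_locus("L4", lapply(sprintf("s%d", 1:6), mk_member),
             n_indels = 41L))                                        # indels
  fl <- filter_loci(cands, p)
  expect_equal(fl$report$input, 4L)
  expect_equal(fl$report$retained, 1L)
  expect_equal(fl$report$removed$low_taxa, 2L)  # L2, and L3 after drop
  expect_equal(fl$report$removed$excess_N, 1L)
  expect_equal(fl$report$removed$excess_indels, 1L)
  expect_equal(fl$report$n_removed, 3L)
  expect_equal(fl$report$input, fl$report$n_removed + fl$report$retained)
  # idempotent: refiltering the retained loci removes nothing
  again <- filter_loci(lapply(fl$loci, function(l)
    list(id = l$id, centroid = base,
         members = data.frame(sample_id = names(l$seqs), seq = l$seqs,
                              depth = l$depths, status = "ok",
                              reason = NA_character_,
                              stringsAsFactors = FALSE),
         n_indels = 0L)), p)
  expect_equal(again$report$retained, length(fl$loci))
  expect_equal(again$report$n_removed, 0L)
})

test_that("min-taxa boundary keeps loci in exactly min_taxa samples", {
  mk <- function(id, n) list(id = id,
                             seqs = stats::setNames(rep("ACGT", n),
                                                    sprintf("s%d", 1:n)))
  fm <- filter_min_taxa(list(mk("a", 3), mk("b", 4), mk("c", 5)),
                        min_taxa = 4L)
  expect_equal(vapply(fm$loci, `[[`, "", "id"), c("b", "c"))
  expect_equal(fm$report$removed$low_taxa, 1L)
})

test_that("assembly statistics are consistent with the retained loci", {
  cfg <- pipeline_config(master_seed = 11,
                         simulate = list(n_species = 6L, n_loci = 10L,
                                         depth = 8L, error_rate = 0,
                                         length_range = c(60L, 90L)))
  sim <- simulate_migseq(cfg)
  asm <- assemble_loci(sim$reads)
  st <- asm$stats
  expect_equal(st$sample_id, rownames(sim$presence))
  expect_true(all(st$reads_passed_filter <= st$reads_raw))
  expect_true(all(st$clusters_hidepth <= st$clusters_total))
  expect_true(all(st$loci_in_assembly <= st$clusters_hidepth))
  # loci_in_assembly equals a recount over the retained loci
  recount <- vapply(st$sample_id, function(s)
    sum(vapply(asm$loci, function(l) s %in% names(l$seqs), logical(1))),
    integer(1))
  expect_equal(st$loci_in_assembly, unname(recount))
  # a sample with zero passing reads yields all-zero statistics
  empty <- assemble_loci(list(sX = make_reads(character(0))))
  expect_equal(empty$stats$clusters_total, 0L)
  expect_equal(empty$stats$reads_consens, 0)
  expect_equal(empty$stats$loci_in_assembly, 0L)
})

test_that("group comparisons detect shifts and hold their size", {
  set.seed(19)
  mk_stats <- function(x, y) data.frame(
    sample_id = sprintf("s%02d", seq_along(c(x, y))), stat = c(x, y),
    stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(c("herbarium", "silica"), each = 15),
                            sprintf("s%02d", 1:30))
  # identical groups: p close to 1
  cg <- compare_groups(mk_stats(rep(1:5, 3), rep(1:5, 3)), groups)
  expect_gt(cg$p_value, 0.9)
  # 3-sd shift: detected
  x <- rnorm(15); y <- rnorm(15) + 3
  cg <- compare_groups(mk_stats(x, y), groups)
  expect_lt(cg$p_value, 0.01)
  expect_error(compare_groups(mk_stats(1:2, rnorm(15)),
                              stats::setNames(rep(c("a", "b"),
                                                  c(2, 15)),
                                              sprintf("s%02d", 1:17))),
               "at least 3")
  # permutation null: rejection rate at the nominal level (3 SEs)
  vals <- rnorm(30)
  rej <- vapply(1:200, function(i) {
    g <- stats::setNames(sample(rep(c("a", "b"), each = 15)),
                         sprintf("s%02d", 1:30))
    compare_groups(mk_stats(vals[1:15], vals[16:30]), g)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("the correlogram is symmetric with unit diagonal and NA on flats", {
  set.seed(23)
  df <- data.frame(sample_id = sprintf("s%d", 1:10), a = rnorm(10))
  df$b <- 2 * df$a
  df$c <- rnorm(10)
  df$flat <- rep(1, 10)
  cc <- correlogram_stats(df, age = rnorm(10))
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc, t(cc))
  expect_true(all(is.na(cc["flat", ])))
  expect_equal(unname(diag(cc)[c("a", "b", "c", "age")]), rep(1, 4))
})
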