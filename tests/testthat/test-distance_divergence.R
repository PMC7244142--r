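test_that("p-distance excludes gaps, N and ambiguity codes from shared sites", {
  expect_equal(p_distance("ACGT", "ACGT"), list(distance = 0, shared_sites = 4L))
  expect_equal(p_distance("ACGT", "ACGA"),
               list(distance = 0.25, shared_sites = 4L))
  # gap and N sites drop out; one difference among the 4 comparable sites
  expect_equal(p_distance("AC-GTN", "ACAGAC"),
               list(distance = 0.25, shared_sites = 4L))
  # heterozygous ambiguity codes are excluded, not scored
  expect_equal(p_distance("AMGT", "ACGT"),
               list(distance = 0, shared_sites = 3L))
  # no shared sites: undefined
  pd <- p_distance("NNNN", "ACGT")
  expect_true(is.na(pd$distance))
  expect_equal(pd$shared_sites, 0L)
  expect_error(p_distance("ACG", "ACGT"), "equal length")
  # symmetry and bounds on random pairs
  set.seed(3)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "N", "-", "R"), 50,
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-", "R"), 50,
                      replace = TRUE), collapse = "")
    ab <- p_distance(a, b); ba <- p_distance(b, a)
    expect_identical(ab, ba)
    if (!is.na(ab$distance))
      expect_true(ab$distance >= 0 && ab$distance <= 1)
  }
})

test_that("pooled records enumerate every locus-sharing sample pair", {
  mk <- function(id, samples) list(id = id,
                                   seqs = stats::setNames(rep("ACGT",
                                                              length(samples)),
                                                          samples))
  # 1 locus, 3 samples: 3 records
  expect_equal(nrow(pool_pairwise_distances(list(mk("a", c("x", "y", "z"))))),
               3L)
  # 2 loci with 4 samples each: 2 * C(4,2) = 12 records
  recs <- pool_pairwise_distances(list(mk("a", sprintf("s%d", 1:4)),
                                       mk("b", sprintf("s%d", 1:4))))
  expect_equal(nrow(recs), 12L)
  # combinatorial recount on simulated data with dropout
  cfg <- pipeline_config(master_seed = 3,
                         simulate = list(n_species = 6L, n_loci = 10L,
                                         length_range = c(50L, 60L),
                                         dropout = c(intercept = 1,
                                                     age = 0,
                                                     herbarium = 0)))
  sim <- simulate_migseq(cfg)
  present <- lapply(seq_len(ncol(sim$presence)), function(j)
    rownames(sim$presence)[sim$presence[, j] == 1L])
  loci_obs <- lapply(seq_along(sim$loci), function(j) {
    lc <- sim$loci[[j]]
    lc$seqs <- lc$seqs[present[[j]]]
    lc
  })
  recs <- pool_pairwise_distances(loci_obs)
  expect_equal(nrow(recs) + attr(recs, "n_dropped"),
               sum(vapply(present, function(p) choose(length(p), 2),
                          numeric(1))))
})

test_that("zone labeling partitions records into intra/inter/excluded", {
  recs <- data.frame(locus = "l1",
                     sample_a = c("sp1", "sp1", "sp3"),
                     sample_b = c("sp2", "sp3", "sp4"),
                     distance = c(0.1, 0.2, 0.3), shared_sites = 10L,
                     stringsAsFactors = FALSE)
  zc <- zone_config("zones4", list(sp1 = "III", sp2 = "III", sp3 = "I",
                                   sp4 = "IV"))
  lab <- label_zone_pairs(recs, zc)
  expect_equal(lab$type, c("intra", "inter", "inter"))
  # multi-zone species excluded under the continent/island policy
  zc2 <- zone_config("zones2", list(sp1 = c("continent", "island"),
                                    sp2 = "island", sp3 = "island",
                                    sp4 = "continent"),
                     exclude_multizone = TRUE)
  lab2 <- label_zone_pairs(recs, zc2)
  expect_equal(lab2$type, c("excluded", "excluded", "inter"))
  # every record gets exactly one label
  expect_true(all(lab2$type %in% c("intra", "inter", "excluded")))
  expect_error(label_zone_pairs(recs, zone_config("z", list(sp1 = "a"))),
               "sp2")
})

test_that("group summaries report medians per zone and type", {
  labeled <- data.frame(locus = "l", sample_a = "a", sample_b = "b",
                        distance = c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1),
                        type = rep(c("intra", "inter"), each = 3),
                        zones = rep("island", 6), stringsAsFactors = FALSE)
  gs <- group_summaries(labeled)
  expect_equal(gs$median[gs$type == "intra"], 0.2)
  expect_equal(gs$median[gs$type == "inter"], 0.1)
  expect_equal(gs$n, c(3L, 3L))
})

test_that("two-way ANOVA matches the closed-form balanced decomposition", {
  # balanced 2x2 with known cell means and unit noise
  set.seed(11)
  n_cell <- 50
  cells <- expand.grid(type = c("intra", "inter"),
                       zone = c("continent", "island"))
  mu <- c(0.10, 0.30, 0.20, 0.20)
  df <- do.call(rbind, lapply(1:4, function(k)
    data.frame(locus = "l", sample_a = "a", sample_b = "b",
               distance = rnorm(n_cell, mu[k], 1),
               type = as.character(cells$type[k]),
               zones = as.character(cells$zone[k]),
               stringsAsFactors = FALSE)))
  got <- two_way_anova(df)
  # hand-computed type-II sums of squares (balanced: equals type-I)
  y <- df$distance
  f1 <- factor(df$type); f2 <- factor(df$zones)
  ss <- function(x) sum((x - mean(x))^2)
  ss_a <- ss(ave(y, f1)) ; ss_b <- ss(ave(y, f2))
  ss_cells <- ss(ave(y, interaction(f1, f2)))
  ss_ab <- ss_cells - ss_a - ss_b
  expect_equal(got$sum_sq[got$term == "type"], ss_a, tolerance = 1e-8)
  expect_equal(got$sum_sq[got$term == "zone"], ss_b, tolerance = 1e-8)
  expect_equal(got$sum_sq[got$term == "type:zone"], ss_ab, tolerance = 1e-8)
  expect_equal(sum(got$df), length(y) - 1)
  # zero residual variance: F effectively infinite
  df0 <- df
  df0$distance <- mu[as.integer(interaction(f1, f2, lex.order = FALSE))]
  df0$distance <- ifelse(df0$type == "intra", 0.1, 0.4) +
    ifelse(df0$zones == "island", 0.05, 0)
  got0 <- two_way_anova(df0)
  expect_lt(got0$sum_sq[got0$term == "Residuals"], 1e-20)
  expect_error(two_way_anova(df[df$type == "intra", ]), "two levels")
})

test_that("Tukey HSD flags shifted groups and matches t in the 2-group case", {
  set.seed(21)
  mk <- function(zone_means, n = 40) do.call(rbind, lapply(
    names(zone_means), function(z)
      data.frame(locus = "l", sample_a = "a", sample_b = "b",
                 distance = rnorm(n, zone_means[[z]], 0.02),
                 type = rep(c("intra", "inter"), n / 2), zones = z,
                 stringsAsFactors = FALSE)))
  # identical groups: adjusted p near 1
  tk <- tukey_hsd(mk(c(I = 0.1, II = 0.1, III = 0.1)), "zone")
  expect_true(all(tk$p_adj > 0.5))
  # one group shifted by 5 pooled SDs: all its comparisons significant
  tk <- tukey_hsd(mk(c(I = 0.1, II = 0.1, III = 0.2)), "zone")
  hits <- grepl("III", tk$comparison)
  expect_true(all(tk$significant[hits]))
  expect_true(all(!tk$significant[!hits]))
  # two groups: Tukey reduces to the two-sample t within tolerance
  df2 <- mk(c(I = 0.1, II = 0.12))
  tk2 <- tukey_hsd(df2, "zone")
  tt <- stats::t.test(distance ~ zones, df2, var.equal = TRUE)$p.value
  expect_equal(tk2$p_adj, tt, tolerance = 0.05)
})

test_that("clade-structured zones yield inter > intra divergence", {
  lab <- simulate_zone_records(seed = 101)
  gs <- group_summaries(lab)
  expect_gt(min(gs$median[gs$type == "inter"], na.rm = TRUE),
            max(gs$median[gs$type == "intra"], na.rm = TRUE))
  an <- two_way_anova(lab)
  expect_lt(an$p_value[an$term == "type"], 0.01)
})
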