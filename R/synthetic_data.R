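# Seeded generators for every input the pipeline consumes: dated species
# trees, Jukes-Cantor locus alignments with SSR flanks, logistic locus
# dropout, damaged or damage-free sequencing reads, zone labellings and
# rate-heterogeneous phylograms, together with the truth tables used to
# score every downstream stage.

#' Simulate an ultrametric dated species tree
#'
#' Pure-birth tree conditioned on the number of tips, rescaled so the root
#' sits at `root_age` million years (Ma). Tips are labeled `sp01`, `sp02`,
#' ...
#'
#' @param n_species Number of tips (>= 3).
#' @param birth_rate Speciation rate of the pure-birth process (per Ma).
#' @param root_age Root age in Ma.
#' @param seed Integer seed; identical seeds give identical trees.
#' @return An ultrametric [ape::phylo] with branch lengths in Ma.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 0.1, root_age = 45,
                                  seed = 1L) {
  if (n_species < 3L) stop("n_species must be at least 3")
  stopifnot(birth_rate > 0, root_age > 0)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Node ages of an ultrametric tree
#'
#' @param tree Ultrametric [ape::phylo] with branch lengths in Ma.
#' @return Numeric vector of ages (Ma before present) for all nodes,
#'   indexed by ape node number (tips first).
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  round(max(d) - d, 12)
}

# One step of Jukes-Cantor evolution along a branch of duration t (Ma) at
# rate mu (substitutions/site/Ma): each site changes with probability
# (3/4)(1 - exp(-4/3 mu t)), uniformly to one of the other three bases.
jc_evolve_branch <- function(chars, mu, t) {
  p_change <- 0.75 * (1 - exp(-4 / 3 * mu * t))
  hit <- stats::runif(length(chars)) < p_change
  if (any(hit)) {
    k <- sample.int(3L, sum(hit), replace = TRUE)
    cur <- match(chars[hit], BASES)
    chars[hit] <- BASES[((cur - 1L + k) %% 4L) + 1L]
  }
  chars
}

#' Evolve locus alignments along a dated tree
#'
#' Each locus draws a length uniformly from `length_range` (default
#' 300-800 bp, the length range of ISSR-anchored MIGseq amplicons), draws a
#' random root sequence and evolves it along the tree under the
#' Jukes-Cantor model at `rate` substitutions/site/Ma. Each locus carries a
#' fixed pair of flanking SSR motifs, recorded in the truth tables.
#'
#' @param tree Dated [ape::phylo] with branch lengths in Ma.
#' @param n_loci Number of loci.
#' @param rate Substitution rate (substitutions/site/Ma), > 0 unless 0 is
#'   explicitly wanted for control runs.
#' @param length_range Integer vector `c(low, high)` of locus lengths.
#' @param ssr_motifs Character pair of 5' and 3' flanking SSR motifs.
#' @param seed Integer seed.
#' @return List of loci; each locus is a list with `id`, `seqs` (named
#'   character vector, one per tip, equal length), `length` and `ssr`
#'   (the flanking motif pair).
#' @export
evolve_loci <- function(tree, n_loci, rate, length_range = c(300L, 800L),
                        ssr_motifs = c("ACACACACAC", "GTGTGTGTGT"),
                        seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_loci >= 1L, rate >= 0)
  if (length_range[1] > length_range[2] || length_range[1] < 1L)
    stop("invalid locus length range")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # preorder traversal: parents before children
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  lapply(seq_len(n_loci), function(li) {
    L <- if (length_range[1] == length_range[2]) length_range[1] else
      sample(seq.int(length_range[1], length_range[2]), 1L)
    seqs_at <- vector("list", ntip + tree$Nnode)
    seqs_at[[root]] <- sample(BASES, L, replace = TRUE)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chi <- edges[e, 2L]
      seqs_at[[chi]] <- jc_evolve_branch(seqs_at[[par]], rate, elen[e])
    }
    tip_seqs <- vapply(seq_len(ntip), function(i) chars_to_seq(seqs_at[[i]]),
                       character(1))
    names(tip_seqs) <- tree$tip.label
    list(id = sprintf("locus%04d", li), seqs = tip_seqs, length = L,
         ssr = ssr_motifs)
  })
}

#' Apply logistic locus dropout
#'
#' Each (sample, locus) cell of the truth presence matrix is kept
#' independently with probability
#' `plogis(intercept + age_coef * age + herb_coef * is_herbarium)`, where
#' `age` is the sample age in years. The default coefficients keep
#' everything; negative `herb_coef` depresses recovery from herbarium
#' material, non-zero `age_coef` makes recovery age-dependent (the study
#' design this emulates found no age effect, so the null setting is the
#' default).
#'
#' @param presence_truth Binary samples-by-loci matrix (dimnames required).
#' @param samples Metadata `data.frame` with `sample_id`, `preservation`
#'   and `collection_year` (or a precomputed `age` column).
#' @param coefficients Named numeric vector `c(intercept=, age=,
#'   herbarium=)` on the logit scale.
#' @param seed Integer seed.
#' @param reference_year Year used to convert `collection_year` to age.
#' @return Binary matrix of observed presences (same shape as the truth).
#' @export
apply_dropout <- function(presence_truth, samples,
                          coefficients = c(intercept = Inf, age = 0,
                                           herbarium = 0),
                          seed = 1L, reference_year = 2020L) {
  stopifnot(is.matrix(presence_truth), !is.null(rownames(presence_truth)))
  co <- coefficients[c("intercept", "age", "herbarium")]
  if (anyNA(co)) stop("coefficients must name intercept, age and herbarium")
  if (any(!is.finite(co[c("age", "herbarium")])))
    stop("age and herbarium coefficients must be finite")
  idx <- match(rownames(presence_truth), samples$sample_id)
  if (anyNA(idx)) stop("presence matrix rows missing from samples table")
  age <- if (!is.null(samples$age)) samples$age[idx] else
    reference_year - samples$collection_year[idx]
  herb <- as.numeric(samples$preservation[idx] == "herbarium")
  keep_p <- stats::plogis(co[["intercept"]] + co[["age"]] * age +
                          co[["herbarium"]] * herb)
  set.seed(seed)
  u <- matrix(stats::runif(length(presence_truth)),
              nrow = nrow(presence_truth))
  obs <- presence_truth * (u < keep_p)  # keep_p recycles by row
  storage.mode(obs) <- "integer"
  dimnames(obs) <- dimnames(presence_truth)
  obs
}

#' Simulate sequencing reads from one locus copy
#'
#' Reads are full-length copies of the template (MIGseq amplicons share
#' anchored SSR primers, so reads are end-anchored on the locus). In
#' `genomic` mode, terminal deamination damage is injected before
#' sequencing error: template cytosines at 5' position `i` are read as T
#' with probability `p0_ct * exp(-decay * (i - 1))`, and template guanines
#' at 3' position `j` (counted from the 3' end) as A with probability
#' `p0_ga * exp(-decay * (j - 1))`. In `amplicon` mode no damage is
#' injected (PCR amplicons are damage free). Uniform per-base sequencing
#' error applies in both modes.
#'
#' @param sequence Template sequence (character scalar over ACGT).
#' @param depth Number of reads (>= 1).
#' @param error_rate Per-base sequencing error probability.
#' @param damage List with `p0_ct`, `p0_ga` (in `[0,1]`) and `decay` (>= 0).
#' @param mode `"genomic"` or `"amplicon"`.
#' @param seed Integer seed.
#' @param base_quality Constant Phred quality of simulated bases.
#' @param id_prefix Read identifier prefix.
#' @return List with `reads` (read-set `data.frame`: `id`, `seq`, `qual`)
#'   and `truth` (`data.frame` of every injected change: `read`, `pos`,
#'   `from`, `to`, `kind` in damage_ct/damage_ga/error).
#' @export
simulate_reads <- function(sequence, depth, error_rate = 0,
                           damage = list(p0_ct = 0.3, p0_ga = 0.3,
                                         decay = 0.4),
                           mode = c("amplicon", "genomic"), seed = 1L,
                           base_quality = 38L, id_prefix = "read") {
  mode <- match.arg(mode)
  stopifnot(depth >= 1L, error_rate >= 0, error_rate <= 1)
  if (mode == "genomic")
    stopifnot(damage$p0_ct >= 0, damage$p0_ct <= 1,
              damage$p0_ga >= 0, damage$p0_ga <= 1, damage$decay >= 0)
  set.seed(seed)
  tmpl <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(tmpl)
  m <- matrix(rep(tmpl, each = depth), nrow = depth)  # reads x positions
  truth <- list()
  if (mode == "genomic") {
    p5 <- damage$p0_ct * exp(-damage$decay * (seq_len(L) - 1))
    hit <- which(matrix(stats::runif(depth * L), depth) <
                 rep(p5, each = depth) &
                 rep(tmpl == "C", each = depth))
    if (length(hit)) {
      truth[["ct"]] <- data.frame(
        read = (hit - 1L) %% depth + 1L, pos = (hit - 1L) %/% depth + 1L,
        from = "C", to = "T", kind = "damage_ct", stringsAsFactors = FALSE)
      m[hit] <- "T"
    }
    p3 <- damage$p0_ga * exp(-damage$decay * (rev(seq_len(L)) - 1))
    hit <- which(matrix(stats::runif(depth * L), depth) <
                 rep(p3, each = depth) &
                 rep(tmpl == "G", each = depth))
    if (length(hit)) {
      truth[["ga"]] <- data.frame(
        read = (hit - 1L) %% depth + 1L, pos = (hit - 1L) %/% depth + 1L,
        from = "G", to = "A", kind = "damage_ga", stringsAsFactors = FALSE)
      m[hit] <- "A"
    }
  }
  if (error_rate > 0) {
    hit <- which(matrix(stats::runif(depth * L), depth) < error_rate)
    if (length(hit)) {
      cur <- match(m[hit], BASES)
      k <- sample.int(3L, length(hit), replace = TRUE)
      newb <- BASES[((cur - 1L + k) %% 4L) + 1L]
      truth[["err"]] <- data.frame(
        read = (hit - 1L) %% depth + 1L, pos = (hit - 1L) %/% depth + 1L,
        from = m[hit], to = newb, kind = "error", stringsAsFactors = FALSE)
      m[hit] <- newb
    }
  }
  q <- strrep(intToUtf8(base_quality + 33L), L)
  reads <- data.frame(id = sprintf("%s%05d", id_prefix, seq_len(depth)),
                      seq = apply(m, 1L, paste, collapse = ""),
                      qual = q, stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read = integer(), pos = integer(), from = character(),
               to = character(), kind = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

zone_labels_for <- function(n_zones) {
  switch(as.character(n_zones),
         "2" = c("continent", "island"),
         "4" = c("I", "II", "III", "IV"),
         "6" = c("I", "II", "IIIa", "IIIb", "IIIc", "IV"),
         sprintf("Z%d", seq_len(n_zones)))
}

#' Assign species to biogeographic zones
#'
#' The `clade` scheme cuts the dated tree at the time when exactly
#' `n_zones` lineages exist and assigns each resulting clade one zone, so
#' intra-zone path lengths are stochastically smaller than inter-zone ones.
#' The `random` scheme permutes labels over species (a null assignment with
#' no phylogenetic structure); both zones are guaranteed non-empty.
#'
#' @param tree Ultrametric dated [ape::phylo].
#' @param n_zones Number of zones (>= 2); 2/4/6 get the conventional label
#'   vocabularies (continent/island; I-IV; I, II, IIIa-c, IV).
#' @param scheme `"clade"` or `"random"`.
#' @param seed Integer seed (used by the random scheme).
#' @return Named character vector mapping each tip label to a zone.
#' @export
assign_zones <- function(tree, n_zones = 2L, scheme = c("clade", "random"),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  if (n_zones < 2L) stop("need at least 2 zones")
  ntip <- length(tree$tip.label)
  if (n_zones > ntip) stop("more zones than species")
  labels <- zone_labels_for(n_zones)
  if (scheme == "random") {
    set.seed(seed)
    repeat {
      z <- sample(labels, ntip, replace = TRUE)
      if (length(unique(z)) == n_zones) break
    }
    return(stats::setNames(z, tree$tip.label))
  }
  # clade scheme: the n_zones subtrees hanging below the cut where the
  # lineage count first reaches n_zones
  bt <- sort(ape::branching.times(tree), decreasing = TRUE)
  cut_age <- if (n_zones == ntip) 0 else
    (bt[n_zones - 1L] + bt[n_zones]) / 2
  ages <- node_ages(tree)
  edge_sub <- which(ages[tree$edge[, 1L]] > cut_age &
                    ages[tree$edge[, 2L]] <= cut_age)
  zmap <- stats::setNames(rep(NA_character_, ntip), tree$tip.label)
  for (i in seq_along(edge_sub)) {
    node <- tree$edge[edge_sub[i], 2L]
    tips <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    zmap[tips] <- labels[i]
  }
  zmap
}

#' Simulate branch-rate phylograms for dating analyses
#'
#' Converts a dated tree into a phylogram whose branch lengths are realized
#' substitutions/site: per-branch rates follow a strict clock, an
#' uncorrelated lognormal, or an autocorrelated lognormal (child rate
#' lognormal around the parent rate), and realized substitution counts are
#' Poisson with mean `rate * duration * n_sites`.
#'
#' @param tree Dated [ape::phylo] (branch lengths in Ma).
#' @param base_rate Mean substitution rate (substitutions/site/Ma).
#' @param rate_model `"clock"`, `"uncorrelated"` or `"autocorrelated"`.
#' @param sigma Lognormal standard deviation of log-rates (ignored for the
#'   clock).
#' @param n_sites Number of sites behind the phylogram.
#' @param seed Integer seed.
#' @return List with `phylogram` ([ape::phylo], branch lengths in
#'   substitutions/site) and `rates` (true per-edge rates).
#' @export
simulate_rate_phylogram <- function(tree, base_rate = 0.002,
                                    rate_model = c("clock", "uncorrelated",
                                                   "autocorrelated"),
                                    sigma = 0.5, n_sites = 10000L,
                                    seed = 1L) {
  rate_model <- match.arg(rate_model)
  set.seed(seed)
  ne <- nrow(tree$edge)
  rates <- switch(rate_model,
    clock = rep(base_rate, ne),
    uncorrelated = base_rate * exp(stats::rnorm(ne, -sigma^2 / 2, sigma)),
    autocorrelated = {
      r <- numeric(ne)
      ord <- order(tree$edge[, 1L])  # not a traversal; use explicit one
      pre <- ape::reorder.phylo(tree, "cladewise")
      idx <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                   paste(tree$edge[, 1], tree$edge[, 2]))
      parent_rate <- stats::setNames(rep(base_rate,
                                         max(tree$edge)), NULL)
      for (k in seq_len(ne)) {
        e <- idx[k]
        par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
        r[e] <- parent_rate[par] * exp(stats::rnorm(1, -sigma^2 / 2, sigma))
        parent_rate[chi] <- r[e]
      }
      r
    })
  mu <- rates * tree$edge.length * n_sites
  x <- stats::rpois(ne, mu)
  phy <- tree
  phy$edge.length <- x / n_sites
  list(phylogram = phy, rates = rates)
}

#' Simulate a complete MIGseq study
#'
#' Convenience driver chaining the generators: species tree, zone
#' assignment, locus evolution, metadata (preservation type, collection
#' year), logistic dropout and per-(sample, locus) reads. One sample per
#' species. Herbarium specimens get ages of 17-109 years and silica-dried
#' ones 2-7 years, matching the age structure of typical mixed
#' herbarium/silica samplings.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]); the
#'   `simulate` block holds the generator parameters.
#' @return List with `tree`, `loci` (truth alignments), `metadata`,
#'   `zones` (per configuration), `presence_truth`, `presence` (after
#'   dropout), `reads` (list by sample of read-set data.frames tagged with
#'   their true locus) and `read_truth`.
#' @export
simulate_migseq <- function(config = pipeline_config()) {
  sc <- config$simulate
  seed0 <- config$master_seed
  tree <- simulate_species_tree(sc$n_species, sc$birth_rate, sc$root_age,
                                seed = derive_seed(seed0, "tree"))
  loci <- evolve_loci(tree, sc$n_loci, sc$subst_rate,
                      length_range = sc$length_range,
                      seed = derive_seed(seed0, "loci"))
  zones <- list(
    zones2 = assign_zones(tree, 2L, "clade"),
    zones4 = assign_zones(tree, min(4L, sc$n_species), "clade"),
    zones6 = assign_zones(tree, min(6L, sc$n_species), "clade"))
  set.seed(derive_seed(seed0, "metadata"))
  n <- sc$n_species
  herb <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(1 / 3, 2 / 3))
  age <- ifelse(herb, sample(17:109, n, replace = TRUE),
                sample(2:7, n, replace = TRUE))
  metadata <- data.frame(
    sample_id = tree$tip.label, species = tree$tip.label,
    preservation = ifelse(herb, "herbarium", "silica"),
    collection_year = 2020L - age, age = age,
    zone2 = unname(zones$zones2[tree$tip.label]),
    zone4 = unname(zones$zones4[tree$tip.label]),
    zone6 = unname(zones$zones6[tree$tip.label]),
    stringsAsFactors = FALSE)
  presence_truth <- matrix(1L, n, sc$n_loci,
                           dimnames = list(tree$tip.label,
                                           vapply(loci, `[[`, "", "id")))
  presence <- apply_dropout(presence_truth, metadata, sc$dropout,
                            seed = derive_seed(seed0, "dropout"))
  reads <- list(); read_truth <- list()
  for (s in tree$tip.label) {
    rs <- list(); rt <- list()
    for (j in seq_along(loci)) {
      if (presence[s, j] == 0L) next
      sim <- simulate_reads(loci[[j]]$seqs[[s]], sc$depth, sc$error_rate,
                            damage = list(p0_ct = sc$p0_ct, p0_ga = sc$p0_ga,
                                          decay = sc$decay),
                            mode = sc$mode,
                            seed = derive_seed(seed0,
                                               paste("reads", s, j)),
                            id_prefix = sprintf("%s_L%04d_", s, j))
      sim$reads$locus <- loci[[j]]$id
      rs[[length(rs) + 1L]] <- sim$reads
      if (nrow(sim$truth)) {
        sim$truth$locus <- loci[[j]]$id
        rt[[length(rt) + 1L]] <- sim$truth
      }
    }
    reads[[s]] <- if (length(rs)) do.call(rbind, rs) else
      data.frame(id = character(), seq = character(), qual = character(),
                 locus = character(), stringsAsFactors = FALSE)
    read_truth[[s]] <- if (length(rt)) do.call(rbind, rt) else NULL
  }
  list(tree = tree, loci = loci, metadata = metadata, zones = zones,
       presence_truth = presence_truth, presence = presence,
       reads = reads, read_truth = read_truth, config = config)
}
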