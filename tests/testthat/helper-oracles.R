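# Independent oracles and small generators used across the test files.
# These re-derive expected results by brute force or closed form and are
# deliberately kept separate from the package implementations they check.

# brute-force greedy centroid clustering over unique sequences: identical
# rule set as the clusterers (abundance then lexicographic order, ungapped
# left-anchored identity over the overlap) but written as a direct
# all-pairs scan
oracle_greedy_clusters <- function(seqs, counts, identity) {
  ord <- order(-counts, seqs)
  seqs <- seqs[ord]; counts <- counts[ord]
  centroids <- character(0)
  assign <- integer(length(seqs))
  ident <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    av <- strsplit(substr(a, 1, n), "")[[1]]
    bv <- strsplit(substr(b, 1, n), "")[[1]]
    mean(av == bv)
  }
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (ident(centroids[ci], seqs[i]) >= identity) { hit <- ci; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, seqs[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  list(seqs = seqs, counts = counts, assign = assign,
       n_clusters = length(centroids))
}

# independent per-site likelihood of the diploid h/e model, computed
# naively site by site (no pattern aggregation), for the grid oracle
oracle_het_error_loglik <- function(h, e, count_matrix) {
  bases <- 1:4
  total <- 0
  for (i in seq_len(nrow(count_matrix))) {
    n <- count_matrix[i, ]
    N <- sum(n)
    p_homo <- 0
    for (b in bases)
      p_homo <- p_homo + (1 - e)^n[b] * (e / 3)^(N - n[b]) / 4
    p_het <- 0
    for (b1 in 1:3) for (b2 in (b1 + 1):4) {
      nb <- n[b1] + n[b2]
      p_het <- p_het + ((1 - e) / 2 + e / 6)^nb * (e / 3)^(N - nb) / 6
    }
    total <- total + log((1 - h) * p_homo + h * p_het)
  }
  total
}

oracle_het_error_grid <- function(count_matrix, h_grid, e_grid) {
  ll <- matrix(NA_real_, length(h_grid), length(e_grid))
  for (i in seq_along(h_grid)) for (j in seq_along(e_grid))
    ll[i, j] <- oracle_het_error_loglik(h_grid[i], e_grid[j], count_matrix)
  idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  c(h = h_grid[idx[1]], e = e_grid[idx[2]])
}

# generator for diploid read clusters with known heterozygosity and error
simulate_het_clusters <- function(n_clusters, depth, len, h, e, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n_clusters), function(k) {
    a1 <- sample(bases, len, replace = TRUE)
    a2 <- a1
    het <- runif(len) < h
    a2[het] <- vapply(a1[het], function(b)
      sample(setdiff(bases, b), 1), character(1))
    reads <- vapply(seq_len(depth), function(r) {
      tmpl <- if (runif(1) < 0.5) a1 else a2
      err <- runif(len) < e
      tmpl[err] <- vapply(tmpl[err], function(b)
        sample(setdiff(bases, b), 1), character(1))
      paste(tmpl, collapse = "")
    }, character(1))
    tab <- table(reads)
    list(centroid = names(tab)[which.max(tab)],
         members = data.frame(seq = names(tab), count = as.integer(tab),
                              stringsAsFactors = FALSE),
         depth = depth)
  })
}

# exhaustive all-pairs nearest-feature scan (signed bedtools-style gap,
# ties by smaller feature start then class name order)
oracle_nearest <- function(loci, features) {
  classes <- c("CDS", "TE", "UTR5", "UTR3")
  crank <- stats::setNames(seq_along(classes), classes)
  out <- data.frame(name = loci$name, nearest_class = "none",
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    fi <- which(features$chrom == loci$chrom[i])
    if (length(fi) == 0L) next
    gaps <- numeric(length(fi))
    for (k in seq_along(fi)) {
      f <- features[fi[k], ]
      gaps[k] <- if (f$start >= loci$end[i]) f$start - loci$end[i]
        else if (f$end <= loci$start[i]) -(loci$start[i] - f$end)
        else 0
    }
    o <- order(abs(gaps), features$start[fi], crank[features$class[fi]])
    out$nearest_class[i] <- features$class[fi[o[1]]]
    out$distance[i] <- gaps[o[1]]
  }
  out
}

# independent single-rate (Langley-Fitch style) clock fit: Poisson branch
# likelihood with one global rate, node ages parameterized as fractions of
# the parent age, root age fixed; Nelder-Mead on its own objective code
oracle_clock_fit <- function(tree, n_sites, root_age) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  internal <- unique(pre[pre[, 2] > ntip, 2])
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  x <- pmax(tree$edge.length * n_sites, 1e-9)
  obj <- function(par) {
    fr <- stats::plogis(par[seq_along(internal)])
    r <- exp(par[length(internal) + 1L])
    ages <- numeric(ntip + tree$Nnode)
    ages[root] <- root_age
    for (k in seq_along(internal))
      ages[internal[k]] <- fr[k] * ages[parent_of[internal[k]]]
    tb <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
    if (any(tb <= 0)) return(1e10)
    mu <- r * tb * n_sites
    -sum(x * log(mu) - mu - lgamma(x + 1))
  }
  # initialize fractions from the phylogram node depths (proportional to
  # path lengths, the clock expectation)
  dep <- ape::node.depth.edgelength(tree)
  rel <- (max(dep) - dep) / max(max(dep) - dep[root], 1e-12)
  f0 <- vapply(internal, function(nd)
    min(max(rel[nd] / max(rel[parent_of[nd]], 1e-6), 0.05), 0.95),
    numeric(1))
  init <- c(stats::qlogis(f0), log(sum(tree$edge.length) /
                                   (root_age * nrow(tree$edge) / 2)))
  fit <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-14))
  fr <- stats::plogis(fit$par[seq_along(internal)])
  ages <- numeric(ntip + tree$Nnode)
  ages[root] <- root_age
  for (k in seq_along(internal))
    ages[internal[k]] <- fr[k] * ages[parent_of[internal[k]]]
  list(ages = ages, rate = exp(fit$par[length(internal) + 1L]),
       value = fit$value)
}

# random additive distance matrix from a random tree with positive branch
# lengths; returns both
random_additive_case <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# quick clade-structured zone divergence simulation used by the
# divergence tests: returns labeled pooled records
simulate_zone_records <- function(seed, n_species = 12, n_loci = 30,
                                  rate = 5e-4, root_age = 45) {
  tree <- simulate_species_tree(n_species, 0.15, root_age, seed = seed)
  loci <- evolve_loci(tree, n_loci, rate, length_range = c(150L, 250L),
                      seed = seed + 1L)
  zones <- assign_zones(tree, 2L, "clade")
  recs <- pool_pairwise_distances(loci)
  label_zone_pairs(recs, zone_config("zones2", as.list(zones)))
}

# record-level permutation of the (type, zones) labels
permute_labels <- function(labeled, seed) {
  set.seed(seed)
  idx <- sample.int(nrow(labeled))
  labeled$type <- labeled$type[idx]
  labeled$zones <- labeled$zones[idx]
  labeled
}
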