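# Presence-absence phylogenetics: binary locus matrix, binary distances,
# Saitou-Nei neighbor joining (implemented here), bootstrap supports over
# resampled loci, and SNP-matrix extraction for external ML programs.

#' Build the samples x loci presence-absence matrix
#'
#' @param loci Retained locus list (each with `id` and `seqs` named by
#'   sample).
#' @param samples Character vector of sample ids (rows); defaults to all
#'   samples observed in the loci.
#' @return Binary integer matrix (samples x loci). All-zero rows trigger a
#'   warning.
#' @export
build_presence_matrix <- function(loci, samples = NULL) {
  ids <- vapply(loci, `[[`, "", "id")
  if (is.null(samples))
    samples <- sort(unique(unlist(lapply(loci, function(l) names(l$seqs)))))
  m <- matrix(0L, length(samples), length(loci),
              dimnames = list(samples, ids))
  for (j in seq_along(loci))
    m[intersect(names(loci[[j]]$seqs), samples), j] <- 1L
  empty <- rownames(m)[rowSums(m) == 0L]
  if (length(empty) > 0L)
    warning("sample(s) present in no retained locus: ",
            paste(empty, collapse = ", "))
  m
}

#' Binary distance between presence-absence profiles
#'
#' @param m Binary samples x loci matrix.
#' @param metric `"mismatch"` (proportion of loci with differing
#'   presence; the default) or `"jaccard"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(m, metric = c("mismatch", "jaccard")) {
  metric <- match.arg(metric)
  if (metric == "mismatch") {
    d <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  } else {
    inter <- m %*% t(m)
    rs <- rowSums(m)
    un <- outer(rs, rs, "+") - inter
    d <- 1 - inter / un
    d[un == 0] <- 0
    diag(d) <- 0
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken by the lowest index pair), branch
#' lengths follow the standard two-point formulas, and negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch so path lengths are preserved. The result is the conventional
#' unrooted NJ tree with a basal trifurcation.
#'
#' @param d Symmetric distance matrix (zero diagonal, n >= 3) with
#'   dimnames, or a [stats::dist].
#' @param tol Asymmetry tolerance.
#' @return Unrooted [ape::phylo].
#' @export
nj_tree <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is not symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      sprintf("t%d", seq_len(n))
  labs <- rownames(d)
  # each active node is carried as a Newick subtree string
  sub <- labs
  D <- d
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (length(sub) > 3L) {
    m <- length(sub)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair among minima (row-major upper triangle)
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(la), sub[2], fmt(lb),
                 sub[3], fmt(lc))
  ape::read.tree(text = txt)
}

#' Bootstrap supports for the presence-absence NJ tree
#'
#' Loci (matrix columns) are resampled with replacement `n_reps` times;
#' the distance and NJ tree are recomputed per replicate and the support
#' of each internal edge of the reference tree is the percentage of
#' replicates containing that bipartition.
#'
#' @param m Binary samples x loci matrix.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param metric Distance metric passed to [binary_distance()].
#' @return The reference NJ [ape::phylo] with `node.label` set to
#'   percentage supports.
#' @export
bootstrap_support <- function(m, n_reps = 1000L, seed = 1L,
                              metric = "mismatch") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ref <- nj_tree(binary_distance(m, metric))
  set.seed(seed)
  boots <- lapply(seq_len(n_reps), function(b) {
    cols <- sample.int(ncol(m), replace = TRUE)
    nj_tree(binary_distance(m[, cols, drop = FALSE], metric))
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- round(100 * counts / n_reps, 1)
  ref
}

#' Extract the concatenated SNP matrix from locus alignments
#'
#' A column is a SNP when at least two distinct unambiguous bases (A, C,
#' G, T) occur among the non-missing samples; heterozygous IUPAC codes
#' are retained as-is in the output, and samples missing a locus receive
#' `N` for its columns.
#'
#' @param loci Locus list (aligned `seqs` named by sample).
#' @param samples Character vector of samples (rows); defaults to all.
#' @return List with `matrix` (samples x SNP character matrix) and `info`
#'   (`data.frame`: source `locus` and `position` per column).
#' @export
extract_snps <- function(loci, samples = NULL) {
  if (is.null(samples))
    samples <- sort(unique(unlist(lapply(loci, function(l) names(l$seqs)))))
  cols <- list(); info <- list()
  for (lc in loci) {
    sm <- seq_char_matrix(lc$seqs)
    present <- rownames(sm)
    for (p in seq_len(ncol(sm))) {
      col <- sm[, p]
      states <- unique(col[col %in% BASES])
      if (length(states) < 2L) next
      full <- stats::setNames(rep("N", length(samples)), samples)
      full[present] <- col
      cols[[length(cols) + 1L]] <- full
      info[[length(info) + 1L]] <-
        data.frame(locus = lc$id, position = p, stringsAsFactors = FALSE)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(), length(samples), 0,
           dimnames = list(samples, NULL))
  list(matrix = mat,
       info = if (length(info)) do.call(rbind, info) else
         data.frame(locus = character(), position = integer()))
}

#' Write a character matrix in relaxed PHYLIP format
#'
#' @param mat Samples x sites character matrix (dimnames required).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(mat, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(rownames(mat)[i],
                     paste(mat[i, ], collapse = "")), con)
  invisible(path)
}

#' Export a SNP matrix as FASTA
#'
#' @param snps Output of [extract_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps_fasta <- function(snps, path) {
  seqs <- apply(snps$matrix, 1L, paste, collapse = "")
  write_fasta(seqs, path)
}
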