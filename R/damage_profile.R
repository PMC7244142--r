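# Post-assembly DNA damage scoring: reads are aligned back onto their
# consensus locus and position-specific misincorporations are profiled
# from each read end (C>T from the 5' end, G>A from the 3' end), with a
# two-proportion test contrasting terminal against interior frequencies.

#' Align a read onto its consensus sequence
#'
#' End-anchored comparison (with the same scoring as the assembly module's
#' alignments when lengths differ); per aligned column the consensus base,
#' read base and the distances from the 5' and 3' read ends are recorded.
#' Reads aligning at identity below 0.5 are flagged unassigned and
#' excluded (`NULL` return).
#'
#' @param read Read sequence (character scalar).
#' @param consensus Consensus sequence.
#' @return `data.frame` with columns `cons`, `read`, `off5`, `off3` (both
#'   offsets 1-based from the respective read end), or `NULL` when
#'   unassigned.
#' @export
align_read_to_consensus <- function(read, consensus) {
  stopifnot(nchar(read) > 0L, nchar(consensus) > 0L)
  if (nchar(read) == nchar(consensus)) {
    rv <- strsplit(read, "", fixed = TRUE)[[1L]]
    cv <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(consensus),
      type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 0, gapExtension = 2)
    rv <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    cv <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    keep <- rv != "-" & cv != "-"
    rv <- rv[keep]; cv <- cv[keep]
  }
  if (length(rv) == 0L || mean(rv == cv) < 0.5) return(NULL)
  n <- length(rv)
  data.frame(cons = cv, read = rv, off5 = seq_len(n),
             off3 = rev(seq_len(n)), stringsAsFactors = FALSE)
}

#' Misincorporation profile from read-to-consensus calls
#'
#' Aggregates, for offsets 1..`w` from each read end, the number of
#' opportunities (consensus C at a 5' offset; consensus G at a 3' offset)
#' and the number of damage-type observations (C read as T; G read as A),
#' and their ratio.
#'
#' @param calls `data.frame` of per-column calls, the row-bound output of
#'   [align_read_to_consensus()] over all reads (>= 1 read).
#' @param w Window size in positions from each end (default 25).
#' @return `data.frame` of class `damage_profile` with columns `end`
#'   (`"5p"`/`"3p"`), `offset`, `opportunities`, `observations`,
#'   `frequency`.
#' @export
misincorporation_profile <- function(calls, w = 25L) {
  stopifnot(nrow(calls) >= 1L)
  prof <- do.call(rbind, lapply(seq_len(w), function(i) {
    c5 <- calls$off5 == i & calls$cons == "C"
    g3 <- calls$off3 == i & calls$cons == "G"
    data.frame(end = c("5p", "3p"), offset = i,
               opportunities = c(sum(c5), sum(g3)),
               observations = c(sum(c5 & calls$read == "T"),
                                sum(g3 & calls$read == "A")),
               stringsAsFactors = FALSE)
  }))
  prof$frequency <- ifelse(prof$opportunities > 0,
                           prof$observations / prof$opportunities, 0)
  prof <- prof[order(prof$end, prof$offset), ]
  rownames(prof) <- NULL
  class(prof) <- c("damage_profile", class(prof))
  prof
}

#' Test for elevated terminal damage
#'
#' Pools the damage frequency over terminal offsets (1..`terminal_k`, both
#' ends) and over interior offsets (>= `interior_from`) and contrasts them
#' with a two-proportion exact test (Fisher). A pronounced deamination
#' pattern yields a rate ratio well above 1 with a small p-value;
#' damage-free amplicon data should not reject.
#'
#' @param profile A `damage_profile` from [misincorporation_profile()].
#' @param terminal_k Last offset counted as terminal (default 3).
#' @param interior_from First offset counted as interior (default 11).
#' @return List with `ratio` (terminal/interior frequency; 1 when both are
#'   0, `Inf` when only the interior is 0), `p_value`, and the pooled
#'   counts.
#' @export
terminal_damage_test <- function(profile, terminal_k = 3L,
                                 interior_from = 11L) {
  term <- profile$offset <= terminal_k
  intr <- profile$offset >= interior_from
  t_opp <- sum(profile$opportunities[term])
  t_obs <- sum(profile$observations[term])
  i_opp <- sum(profile$opportunities[intr])
  i_obs <- sum(profile$observations[intr])
  if (t_opp < 30L || i_opp < 30L)
    stop("fewer than 30 opportunities in the terminal or interior window; ",
         "increase sequencing depth or the number of reads profiled")
  f_t <- t_obs / t_opp
  f_i <- i_obs / i_opp
  ratio <- if (f_t == 0 && f_i == 0) 1 else if (f_i == 0) Inf else f_t / f_i
  p <- stats::fisher.test(matrix(c(t_obs, t_opp - t_obs,
                                   i_obs, i_opp - i_obs), 2L))$p.value
  list(ratio = ratio, p_value = p,
       terminal = c(observations = t_obs, opportunities = t_opp),
       interior = c(observations = i_obs, opportunities = i_opp))
}

#' Profile damage for a read set against its loci
#'
#' Driver: aligns every read to the consensus of its locus and aggregates
#' the misincorporation profile.
#'
#' @param reads Read-set `data.frame` with a `locus` column naming the
#'   consensus each read derives from.
#' @param consensi Named character vector of consensus sequences by locus.
#' @param w Profile window (positions from each end).
#' @return A `damage_profile`.
#' @export
profile_damage <- function(reads, consensi, w = 25L) {
  stopifnot(!is.null(reads$locus))
  opp5 <- obs5 <- opp3 <- obs3 <- numeric(w)
  slow_calls <- list()
  for (loc in unique(reads$locus)) {
    cons <- consensi[[loc]]
    rs <- reads$seq[reads$locus == loc]
    eq <- nchar(rs) == nchar(cons)
    if (any(eq)) {
      # vectorized path: equal-length reads are end-anchored columnwise
      m <- seq_char_matrix(rs[eq])
      cv <- strsplit(cons, "", fixed = TRUE)[[1L]]
      L <- length(cv)
      ident <- rowMeans(m == matrix(cv, nrow(m), L, byrow = TRUE))
      m <- m[ident >= 0.5, , drop = FALSE]
      if (nrow(m) > 0L) {
        for (i in seq_len(min(w, L))) {
          if (cv[i] == "C") {
            opp5[i] <- opp5[i] + nrow(m)
            obs5[i] <- obs5[i] + sum(m[, i] == "T")
          }
          j <- L - i + 1L
          if (cv[j] == "G") {
            opp3[i] <- opp3[i] + nrow(m)
            obs3[i] <- obs3[i] + sum(m[, j] == "A")
          }
        }
      }
    }
    for (s in rs[!eq])
      slow_calls[[length(slow_calls) + 1L]] <-
        align_read_to_consensus(s, cons)
  }
  prof <- data.frame(
    end = rep(c("3p", "5p"), each = w), offset = rep(seq_len(w), 2L),
    opportunities = c(opp3, opp5), observations = c(obs3, obs5),
    stringsAsFactors = FALSE)
  if (length(slow_calls) > 0L) {
    calls <- do.call(rbind, slow_calls)
    extra <- misincorporation_profile(calls, w = w)
    prof$opportunities <- prof$opportunities + extra$opportunities
    prof$observations <- prof$observations + extra$observations
  }
  prof$frequency <- ifelse(prof$opportunities > 0,
                           prof$observations / prof$opportunities, 0)
  class(prof) <- c("damage_profile", class(prof))
  prof
}
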