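# Readers and writers for the on-disk formats the pipeline exchanges:
# FASTA, FASTQ (Sanger qualities), Newick, BED, GFF3, the sample-metadata
# TSV and the YAML pipeline configuration.
#
# Coordinate dialects: BED is 0-based half-open and is kept as-is; GFF3 is
# 1-based closed and is converted at the boundary. All internal interval
# tables are 0-based half-open.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record
#'   identifiers, order as in the file). Empty files yield an empty vector.
#' @details Identifiers must be unique and sequences non-empty and composed
#'   of IUPAC nucleotide codes (case-insensitive, `-` allowed); violations
#'   raise an error locating the offending record/character.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  # keep only the first whitespace-delimited token as the identifier
  ids <- sub("\\s.*$", "", ids)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA identifier: ", dup[[1L]])
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record: ", ids[which(nchar(seqs) == 0L)[1L]])
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly. Output is byte-deterministic.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)) || length(seqs) == 0L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path Path to a Sanger-quality FASTQ file.
#' @return A read-set `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", unname(names(x))),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read set to FASTQ
#'
#' @param reads Read-set `data.frame` with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L)
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con, sep = "\n")
  invisible(path)
}

#' Read a phylogeny from Newick text or file
#'
#' @param x Newick string (anything containing a `;`) or a file path.
#' @return An [ape::phylo] tree; internal node labels (supports) are kept.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- tryCatch(
    if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x)
    else ape::read.tree(x),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("Newick parse error: no tree found")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ", tr$tip.label[duplicated(tr$tip.label)][1L])
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead.
#' @return The Newick string (invisibly when written to file). Branch
#'   lengths are preserved to at least 1e-9.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read the sample-metadata table
#'
#' Reads the tab-separated specimen table with columns `sample_id`,
#' `species`, `preservation` (`herbarium` or `silica`), `collection_year`
#' and the three zone-configuration columns `zone2`, `zone4`, `zone6`.
#' Records with a missing zone code are kept but flagged (`zone_ok =
#' FALSE`) and a warning names them; they are excluded from zone analyses.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`, one row per sample, with an added logical
#'   `zone_ok` column.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("sample_id", "species", "preservation", "collection_year",
           "zone2", "zone4", "zone6")
  miss <- setdiff(req, names(md))
  if (length(miss) > 0L)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1L])
  bad <- setdiff(unique(md$preservation), c("herbarium", "silica"))
  if (length(bad) > 0L)
    stop("unknown preservation value: ", paste(bad, collapse = ", "),
         " (expected 'herbarium' or 'silica')")
  md$collection_year <- as.integer(md$collection_year)
  if (anyNA(md$collection_year)) stop("non-numeric collection_year")
  zc <- c("zone2", "zone4", "zone6")
  md$zone_ok <- !apply(is.na(md[zc]) | md[zc] == "", 1L, any)
  if (any(!md$zone_ok))
    warning("sample(s) with missing zone code excluded from zone analyses: ",
            paste(md$sample_id[!md$zone_ok], collapse = ", "))
  md
}

#' Read a BED file of locus intervals
#'
#' @param path Path to a BED (3+ column) file.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, as in BED) and `name` (generated when absent).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
        else sprintf("interval%05d", seq_along(gr))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
                    end = GenomicRanges::end(gr),
                    name = nm, stringsAsFactors = FALSE)
  if (any(out$start < 0L | out$end <= out$start))
    stop("invalid BED interval at line ",
         which(out$start < 0L | out$end <= out$start)[1L])
  out
}

#' Write intervals to BED
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and
#'   optionally `name` (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- intervals[c("chrom", "start", "end")]
  if (!is.null(intervals$name)) cols$name <- intervals$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic feature annotations from GFF3
#'
#' Feature types are mapped onto the four classes used by the genomic
#' context analyses: `CDS`, `TE` (any type containing
#' "transposable_element" or "transposon"), `UTR5` (`five_prime_UTR`) and
#' `UTR3` (`three_prime_UTR`); other types are dropped.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame` with `chrom`, `start`, `end` (converted to 0-based
#'   half-open) and `class`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  cls <- rep(NA_character_, length(type))
  cls[type == "CDS"] <- "CDS"
  cls[grepl("transposable_element|transposon", type)] <- "TE"
  cls[type == "five_prime_UTR"] <- "UTR5"
  cls[type == "three_prime_UTR"] <- "UTR3"
  keep <- !is.na(cls)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[keep],
             start = GenomicRanges::start(gr)[keep] - 1L,  # 1-based -> 0-based
             end = GenomicRanges::end(gr)[keep],
             class = cls[keep], stringsAsFactors = FALSE)
}

# ---- pipeline configuration ------------------------------------------------

default_config <- function() {
  list(
    master_seed = 1L,
    out_dir = ".",
    log_level = "info",
    simulate = list(n_species = 20L, birth_rate = 0.1, root_age = 45,
                    n_loci = 50L, length_range = c(300L, 800L),
                    subst_rate = 0.0005, depth = 20L, error_rate = 0.002,
                    mode = "amplicon", p0_ct = 0.3, p0_ga = 0.3, decay = 0.4,
                    dropout = c(intercept = 3, age = 0, herbarium = 0)),
    assembly = list(min_depth = 5L, max_alleles = 2L, max_N = 5L,
                    max_het = 8L, max_indels = 40L, min_taxa = 4L,
                    identity = 0.85, max_low_quality_bases = 50L,
                    low_quality_threshold = 20L),
    damage = list(window = 25L, terminal_k = 3L, interior_from = 11L),
    zones = list(configuration = "zones2"),
    dating = list(lambda = 0.01, n_sites = NULL,
                  cv_grid = 10^seq(5, -3))
  )
}

#' Create, read or write a pipeline configuration
#'
#' A configuration is a named list with a `master_seed` and one block of
#' options per pipeline stage; omitted entries are filled with defaults.
#' Configurations serialize losslessly to YAML.
#'
#' @param ... Named overrides, e.g. `master_seed = 7`,
#'   `assembly = list(min_taxa = 5)`. Unknown names are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  cfg <- default_config()
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L)
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      unknown <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(unknown) > 0L)
        stop("unknown option(s) in '", nm, "': ",
             paste(unknown, collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (!is.numeric(cfg$master_seed) || cfg$master_seed < 0)
    stop("master_seed must be a non-negative integer")
  cfg$master_seed <- as.integer(cfg$master_seed)
  # normalize vector-valued options (YAML deserializes them as lists)
  cfg$simulate$length_range <- as.integer(unlist(cfg$simulate$length_range))
  cfg$simulate$dropout <- unlist(cfg$simulate$dropout)
  cfg$dating$cv_grid <- as.numeric(unlist(cfg$dating$cv_grid))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path of the YAML configuration file.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  # YAML drops names of atomic vectors; store the dropout block as a map
  raw$simulate$dropout <- as.list(raw$simulate$dropout)
  yaml::write_yaml(raw, path)
  invisible(path)
}
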