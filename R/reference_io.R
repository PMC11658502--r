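#' Load a host/prey reference library
#'
#' Reads the ~100 bp 12S reference sequences (FASTA) together with a taxon
#' metadata table (TSV) and joins them into a `reference_library` object.
#' FASTA headers must carry the `taxon_id` used in the metadata table
#' (anything after the first whitespace in a header is ignored).
#'
#' The metadata table is tab-separated with a mandatory header row and
#' columns `taxon_id`, `scientific_name`, `common_name`, `role` (one of
#' `host_predator`, `prey`, `both`), `tier1`, `tier2`, `tier3`,
#' `mean_mass_kg` (may be empty). Tier labels group prey hierarchically,
#' e.g. brown accentor -> perching birds -> birds; the mapping
#' tier1 -> tier2 -> tier3 must be a function (one tier2/tier3 per tier1).
#'
#' @param fasta_path path to the reference FASTA file.
#' @param metadata_path path to the metadata TSV.
#' @return A `reference_library`: list with `records` (data.frame) and
#'   `sequences` (named uppercase character vector over A/C/G/T/N).
#' @export
load_reference <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty reference FASTA: ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  reference_library(setNames(toupper(as.character(seqs)), ids), meta)
}

#' Construct a reference library from in-memory objects
#'
#' @param sequences named character vector of reference sequences.
#' @param records metadata data.frame (see [load_reference()] for columns).
#' @return A validated `reference_library`.
#' @export
reference_library <- function(sequences, records) {
  required <- c("taxon_id", "scientific_name", "common_name", "role",
                "tier1", "tier2", "tier3", "mean_mass_kg")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[required]
  records$mean_mass_kg <- as.numeric(records$mean_mass_kg)
  if (anyDuplicated(records$taxon_id)) {
    stop("duplicate taxon_id in metadata: ",
         paste(unique(records$taxon_id[duplicated(records$taxon_id)]),
               collapse = ", "))
  }
  bad_role <- setdiff(records$role, c("host_predator", "prey", "both"))
  if (length(bad_role)) stop("unknown role value(s): ", paste(bad_role, collapse = ", "))
  orphans <- setdiff(names(sequences), records$taxon_id)
  if (length(orphans)) {
    stop("FASTA taxon id(s) absent from metadata: ", paste(orphans, collapse = ", "))
  }
  noseq <- setdiff(records$taxon_id, names(sequences))
  if (length(noseq)) {
    stop("metadata taxon id(s) without a reference sequence: ",
         paste(noseq, collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) stop("empty reference sequence(s)")
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("reference sequences must be over the alphabet A/C/G/T/N")
  }
  # tier1 -> (tier2, tier3) must be a function
  tmap <- unique(records[c("tier1", "tier2", "tier3")])
  if (anyDuplicated(tmap$tier1)) {
    stop("tier1 label(s) mapped to more than one tier2/tier3 group: ",
         paste(unique(tmap$tier1[duplicated(tmap$tier1)]), collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 sequences = sequences[records$taxon_id]),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("Reference library:", nrow(x$records), "taxa\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$records$role)),
                                table(x$records$role)), collapse = ", "), "\n")
  cat("  sequence lengths:", paste(range(nchar(x$sequences)), collapse = "-"),
      "bp\n")
  invisible(x)
}

#' Write a reference library to FASTA + metadata TSV
#'
#' Inverse of [load_reference()]; a write/load round trip reproduces the
#' library exactly.
#'
#' @param lib a `reference_library`.
#' @param fasta_path,metadata_path output paths.
#' @return `lib`, invisibly.
#' @export
write_reference <- function(lib, fasta_path, metadata_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(lib$sequences),
                              fasta_path)
  write.table(lib$records, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(lib)
}

# role helpers: "both" taxa (e.g. red fox) act as host candidates and as prey
host_capable <- function(lib) {
  lib$records$taxon_id[lib$records$role %in% c("host_predator", "both")]
}
prey_capable <- function(lib) {
  lib$records$taxon_id[lib$records$role %in% c("prey", "both")]
}

#' Load amplicon reads from FASTQ
#'
#' Reads are assumed single-ended (paired 250 bp reads fully span the ~100 bp
#' amplicon, so mates are expected to be pre-merged). The scat id for each
#' read is taken from the header prefix before the first `:`
#' (`<scat_id>:<read>` convention) unless a `manifest` maps read ids to
#' scats explicitly.
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @param manifest optional data.frame with columns `read_id`, `scat_id`
#'   overriding the header convention.
#' @param offset Phred offset (default 33).
#' @return data.frame with columns `read_id`, `scat_id`, `sequence`,
#'   `quality` (Phred string); attribute `offset` records the encoding.
#' @export
load_reads <- function(path, manifest = NULL, offset = 33L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record near line ", length(lines) %/% 4L * 4L + 1L,
         " of ", path)
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    b <- (i - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@")) {
      stop("malformed FASTQ header at line ", b + 1L, " of ", path)
    }
    if (!startsWith(lines[b + 3L], "+")) {
      stop("malformed FASTQ separator at line ", b + 3L, " of ", path)
    }
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L])) {
      stop("sequence/quality length mismatch at line ", b + 2L, " of ", path)
    }
  }
  # structural validation done line-by-line above; parse with Biostrings
  fq <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  read_id <- sub("\\s.*$", "", names(fq))
  if (!is.null(manifest)) {
    idx <- match(read_id, manifest$read_id)
    if (anyNA(idx)) {
      stop("read id(s) absent from manifest: ",
           paste(utils::head(read_id[is.na(idx)], 5L), collapse = ", "))
    }
    scat_id <- manifest$scat_id[idx]
  } else {
    scat_id <- sub(":.*$", "", read_id)
  }
  out <- data.frame(read_id = read_id, scat_id = scat_id,
                    sequence = toupper(as.character(fq)),
                    quality = as.character(S4Vectors::mcols(fq)$qualities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "offset") <- offset
  out
}

#' Write amplicon reads to FASTQ
#'
#' @param reads data.frame as returned by [load_reads()] / [simulate_scats()].
#' @param path output FASTQ path.
#' @return `reads`, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(reads)
}

#' Convert a Phred quality string to per-base error probabilities
#'
#' @param quality Phred-encoded quality string.
#' @param offset encoding offset (33 for Phred+33).
#' @return numeric vector of error probabilities, one per base.
#' @export
phred_to_error_prob <- function(quality, offset = 33L) {
  q <- utf8ToInt(quality) - offset
  10^(-q / 10)
}

#' Quality-trim a read (modified-Mott algorithm)
#'
#' For per-base error probabilities `p_i` and a quality score limit, the
#' retained window is the contiguous stretch maximizing
#' `sum(limit - p_i)` (Kadane scan); if every base exceeds the limit the
#' read becomes empty and is dropped downstream.
#'
#' @param sequence read sequence.
#' @param error_prob per-base error probabilities (same length), or `NULL`.
#' @param limit quality score limit in (0, 1); default 0.1.
#' @return list with `sequence` (trimmed), `start`, `end` (1-based inclusive
#'   window; `start > end` means empty), and `trimmed` flag.
#' @export
quality_trim <- function(sequence, error_prob, limit = 0.1) {
  stopifnot(limit > 0, limit < 1)
  if (is.null(error_prob)) {
    warning("read has no qualities; returned unchanged")
    return(list(sequence = sequence, start = 1L, end = nchar(sequence),
                trimmed = FALSE))
  }
  stopifnot(length(error_prob) == nchar(sequence))
  gains <- limit - error_prob
  best <- 0; best_s <- 1L; best_e <- 0L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(gains)) {
    if (cur <= 0) { cur <- 0; cur_s <- i }
    cur <- cur + gains[i]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  if (best_e < best_s) {
    return(list(sequence = "", start = 1L, end = 0L, trimmed = TRUE))
  }
  list(sequence = substr(sequence, best_s, best_e),
       start = as.integer(best_s), end = as.integer(best_e),
       trimmed = !(best_s == 1L && best_e == length(gains)))
}

#' Quality-trim a table of reads
#'
#' Applies [quality_trim()] to each read; zero-length reads are dropped.
#'
#' @param reads read data.frame (see [load_reads()]).
#' @param limit quality score limit, default 0.1.
#' @param offset Phred offset.
#' @return the trimmed read data.frame (quality strings trimmed in step);
#'   attribute `n_dropped` counts reads removed entirely.
#' @export
trim_reads <- function(reads, limit = 0.1, offset = attr(reads, "offset") %||% 33L) {
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    tr <- quality_trim(reads$sequence[i],
                       phred_to_error_prob(reads$quality[i], offset), limit)
    keep[i] <- nchar(tr$sequence) > 0L
    if (keep[i]) {
      reads$sequence[i] <- tr$sequence
      reads$quality[i] <- substr(reads$quality[i], tr$start, tr$end)
    }
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "offset") <- offset
  attr(out, "n_dropped") <- sum(!keep)
  out
}
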