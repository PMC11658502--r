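#' Alignment parameters for read-to-reference mapping
#'
#' Defaults are the vendor mapping parameters used throughout: mismatch
#' cost 2, insertion cost 3, deletion cost 3, length fraction 0.9,
#' similarity 0.94, with non-specific (tied) matches placed randomly under
#' a fixed seed. The match score is not part of that parameter set and
#' defaults to 1.
#'
#' `length_fraction` filters on the fraction of the read covered by the
#' alignment (aligned read bases / read length); `similarity` filters on
#' alignment identity (matching columns / aligned columns, gaps counted
#' as columns).
#'
#' @param match_score,mismatch_cost,insertion_cost,deletion_cost positive
#'   integer alignment scores/costs (linear gap model).
#' @param length_fraction minimum aligned fraction of the read, in (0, 1].
#' @param similarity minimum alignment identity, in (0, 1].
#' @param seed non-negative integer seed for random placement of
#'   non-specific matches.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match_score = 1L, mismatch_cost = 2L,
                             insertion_cost = 3L, deletion_cost = 3L,
                             length_fraction = 0.9, similarity = 0.94,
                             seed = 0L) {
  stopifnot(match_score > 0, mismatch_cost > 0, insertion_cost > 0,
            deletion_cost > 0,
            length_fraction > 0, length_fraction <= 1,
            similarity > 0, similarity <= 1, seed >= 0)
  structure(list(match_score = as.integer(match_score),
                 mismatch_cost = as.integer(mismatch_cost),
                 insertion_cost = as.integer(insertion_cost),
                 deletion_cost = as.integer(deletion_cost),
                 length_fraction = length_fraction,
                 similarity = similarity,
                 seed = as.integer(seed)),
            class = "alignment_params")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under a linear gap model: `+match_score` per
#' matching column, `-mismatch_cost` per mismatch, `-insertion_cost` per
#' read base inserted relative to the reference, `-deletion_cost` per
#' reference base missing from the read. The optimal score is always
#' >= 0; an all-zero matrix yields an empty alignment.
#'
#' @param query,target non-empty nucleotide strings.
#' @param params an [alignment_params()] object.
#' @return list with `score`, `matches`, `mismatches`, `insertions`,
#'   `deletions`, `aligned_cols`, `identity` (matches / aligned columns;
#'   `NA` for an empty alignment), `query_interval` and `target_interval`
#'   (0-based half-open), and `ref_aligned` (read bases projected onto the
#'   reference interval, `-` marking deleted reference bases).
#' @export
local_align <- function(query, target, params = alignment_params()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  r <- .sw_align_cpp(query, target, params$match_score, params$mismatch_cost,
                     params$insertion_cost, params$deletion_cost)
  list(score = r$score, matches = r$matches, mismatches = r$mismatches,
       insertions = r$insertions, deletions = r$deletions,
       aligned_cols = r$aligned_cols,
       identity = if (r$aligned_cols > 0) r$matches / r$aligned_cols else NA_real_,
       query_interval = c(r$q_start, r$q_end),
       target_interval = c(r$t_start, r$t_end),
       ref_aligned = r$ref_aligned)
}

# deterministic string hash onto [0, 1): Lehmer-style multiplicative mixing
# modulo the Mersenne prime 2^31 - 1 (all intermediates exact in doubles),
# used for per-read tie-break seeding
hash_unit <- function(s) {
  m <- 2147483647
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- ((h + b + 1) * 48271) %% m
  }
  for (k in 1:4) h <- (h * 48271 + 11) %% m # finalization rounds
  h / m
}

#' Map one read against a reference library
#'
#' Aligns the read to every reference sequence, discards hits failing the
#' `length_fraction` or `similarity` filters, and keeps the best-scoring
#' hit. Ties across taxa (non-specific matches) are resolved by drawing one
#' taxon uniformly at random, seeded on `(params$seed, read_id)` so the
#' outcome is reproducible and independent of read order.
#'
#' @param sequence read sequence (non-empty, post-trimming).
#' @param lib a `reference_library`.
#' @param params an [alignment_params()].
#' @param read_id read identifier (used only for tie-break seeding).
#' @return list with `taxon_id` (`NA` if unmapped), `status` (`"mapped"`,
#'   `"nonspecific_resolved"` or `"unmapped"`), `score`, `identity`,
#'   `mismatches`, `aligned_read_fraction`, `ref_start`/`ref_end` (0-based
#'   half-open on the chosen reference), `ref_aligned`, and `tied_taxa`
#'   (all taxa sharing the best score).
#' @export
map_read <- function(sequence, lib, params = alignment_params(),
                     read_id = "") {
  stopifnot(nchar(sequence) > 0)
  refs <- lib$sequences
  # fast path: a read identical to exactly one reference is its unique best
  # hit (references are distinct), with identity 1 and full coverage
  exact <- which(refs == sequence)
  if (length(exact) == 1L) {
    return(list(taxon_id = names(refs)[exact], status = "mapped",
                score = nchar(sequence) * params$match_score,
                identity = 1.0, mismatches = 0L,
                aligned_read_fraction = 1.0,
                ref_start = 0L, ref_end = nchar(sequence),
                ref_aligned = sequence, tied_taxa = names(refs)[exact]))
  }
  b <- .sw_batch_cpp(sequence, unname(refs), params$match_score,
                     params$mismatch_cost, params$insertion_cost,
                     params$deletion_cost)
  st <- b$stats
  qlen <- nchar(sequence)
  aligned_frac <- (st[, "q_end"] - st[, "q_start"]) / qlen
  identity <- ifelse(st[, "aligned_cols"] > 0,
                     st[, "matches"] / st[, "aligned_cols"], 0)
  pass <- aligned_frac >= params$length_fraction &
    identity >= params$similarity & st[, "score"] > 0
  if (!any(pass)) {
    return(list(taxon_id = NA_character_, status = "unmapped",
                score = 0L, identity = NA_real_, mismatches = NA_integer_,
                aligned_read_fraction = NA_real_,
                ref_start = NA_integer_, ref_end = NA_integer_,
                ref_aligned = NA_character_, tied_taxa = character(0)))
  }
  best <- max(st[pass, "score"])
  cand <- which(pass & st[, "score"] == best)
  if (length(cand) == 1L) {
    pick <- cand
    status <- "mapped"
  } else {
    # non-specific match: seeded uniform draw, order-independent
    u <- hash_unit(paste0(params$seed, ":", read_id))
    pick <- cand[1L + (floor(u * length(cand)) %% length(cand))]
    status <- "nonspecific_resolved"
  }
  list(taxon_id = names(refs)[pick], status = status,
       score = st[pick, "score"],
       identity = identity[pick],
       mismatches = st[pick, "mismatches"],
       aligned_read_fraction = aligned_frac[pick],
       ref_start = st[pick, "t_start"], ref_end = st[pick, "t_end"],
       ref_aligned = b$ref_aligned[pick],
       tied_taxa = names(refs)[cand])
}

#' Map a table of reads
#'
#' Vectorized driver over [map_read()].
#'
#' @param reads read data.frame with columns `read_id`, `scat_id`,
#'   `sequence`.
#' @param lib a `reference_library`.
#' @param params an [alignment_params()].
#' @return data.frame of mappings with columns `read_id`, `scat_id`,
#'   `taxon_id`, `status`, `score`, `identity`, `mismatches`,
#'   `aligned_read_fraction`, `ref_start`, `ref_end`, `ref_aligned`,
#'   `tied_taxa` (semicolon-joined).
#' @export
map_reads <- function(reads, lib, params = alignment_params()) {
  n <- nrow(reads)
  taxon_id <- character(n); status <- character(n)
  score <- integer(n); identity <- numeric(n); mismatches <- integer(n)
  frac <- numeric(n); ref_start <- integer(n); ref_end <- integer(n)
  ref_aligned <- character(n); tied <- character(n)
  for (i in seq_len(n)) {
    m <- map_read(reads$sequence[i], lib, params, read_id = reads$read_id[i])
    taxon_id[i] <- m$taxon_id; status[i] <- m$status
    score[i] <- m$score; identity[i] <- m$identity
    mismatches[i] <- m$mismatches; frac[i] <- m$aligned_read_fraction
    ref_start[i] <- m$ref_start; ref_end[i] <- m$ref_end
    ref_aligned[i] <- m$ref_aligned
    tied[i] <- paste(m$tied_taxa, collapse = ";")
  }
  data.frame(read_id = reads$read_id, scat_id = reads$scat_id,
             taxon_id = taxon_id, status = status, score = score,
             identity = identity, mismatches = mismatches,
             aligned_read_fraction = frac, ref_start = ref_start,
             ref_end = ref_end, ref_aligned = ref_aligned,
             tied_taxa = tied, stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a majority-rule consensus from reads mapped to one taxon
#'
#' At each reference position the plurality base among covering reads is
#' taken; an exact tie is coded `N`. Positions with zero depth are absent
#' from the consensus. Identity to the reference is computed over covered
#' positions only (an `N` never counts as a match).
#'
#' @param mappings mapping rows (see [map_reads()]) for a single taxon;
#'   must contain `ref_start`, `ref_end`, `ref_aligned`.
#' @param reference the reference sequence of that taxon.
#' @return list with `consensus` (string over covered positions),
#'   `covered` (0-based reference positions), `depth` (per-reference-position
#'   read depth), and `identity_to_reference`.
#' @export
build_consensus <- function(mappings, reference) {
  if (nrow(mappings) == 0L) stop("no mapped reads to build a consensus from")
  L <- nchar(reference)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (i in seq_len(nrow(mappings))) {
    s <- mappings$ref_start[i]
    bases <- strsplit(mappings$ref_aligned[i], "")[[1]]
    for (k in seq_along(bases)) {
      b <- bases[k]
      if (b %in% rownames(counts)) {
        counts[b, s + k] <- counts[b, s + k] + 1L
      }
    }
  }
  base_counts <- counts[1:4, , drop = FALSE]
  depth <- colSums(base_counts)
  covered <- which(depth > 0L)
  cons <- character(length(covered))
  for (j in seq_along(covered)) {
    col <- base_counts[, covered[j]]
    mx <- max(col)
    winners <- names(col)[col == mx]
    cons[j] <- if (length(winners) == 1L) winners else "N"
  }
  ref_bases <- strsplit(reference, "")[[1]][covered]
  ident <- if (length(covered)) mean(cons == ref_bases) else NA_real_
  list(consensus = paste(cons, collapse = ""),
       covered = covered - 1L,
       depth = as.integer(depth),
       identity_to_reference = ident)
}

#' De novo rescue of unmapped reads
#'
#' Reads that fail reference mapping are greedily clustered at
#' `>= assembly_similarity` pairwise alignment identity against each
#' cluster's founding read, then collapsed to a majority-rule consensus
#' per cluster (ties coded `N`). Because the amplicon is a single ~100 bp
#' locus, clustering plus pile-up stands in for overlap-layout assembly.
#' Contigs shorter than `min_contig` or supported by fewer than
#' `min_support` reads are discarded; the rest are ranked by
#' supporting-read count. Contigs supported by fewer than `low_coverage`
#' reads are flagged low-confidence.
#'
#' @param sequences character vector of unmapped read sequences.
#' @param min_contig minimum contig length (default 100).
#' @param min_support minimum supporting reads per contig (default 2;
#'   a lone read is not evidence of an assembled sequence).
#' @param assembly_similarity pairwise identity threshold (default 0.98).
#' @param low_coverage support threshold below which a contig is flagged
#'   `low_confidence` (default 10000, matching a conservative vendor
#'   default; effectively flags everything at amplicon scale).
#' @param params alignment parameters used for the identity computation.
#' @return data.frame with columns `contig`, `support`, `low_confidence`,
#'   ranked by support (may have zero rows).
#' @export
denovo_rescue <- function(sequences, min_contig = 100L, min_support = 2L,
                          assembly_similarity = 0.98,
                          low_coverage = 10000L,
                          params = alignment_params()) {
  sequences <- sequences[nchar(sequences) > 0L]
  if (length(sequences) == 0L) stop("no unmapped reads to assemble")
  reps <- character(0)
  members <- list()
  for (s in sequences) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      al <- local_align(s, reps[ci], params)
      min_len <- min(nchar(s), nchar(reps[ci]))
      if (al$aligned_cols > 0 &&
          al$matches / min_len >= assembly_similarity) {
        members[[ci]] <- c(members[[ci]], s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      members[[length(reps)]] <- s
    }
  }
  out <- list()
  for (ci in seq_along(reps)) {
    mem <- members[[ci]]
    maps <- do.call(rbind, lapply(mem, function(s) {
      al <- local_align(s, reps[ci], params)
      data.frame(ref_start = al$target_interval[1],
                 ref_end = al$target_interval[2],
                 ref_aligned = al$ref_aligned, stringsAsFactors = FALSE)
    }))
    cons <- build_consensus(maps, reps[ci])
    if (nchar(cons$consensus) >= min_contig && length(mem) >= min_support) {
      out[[length(out) + 1L]] <- data.frame(
        contig = cons$consensus, support = length(mem),
        low_confidence = length(mem) < low_coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), support = integer(0),
                      low_confidence = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$support), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Identify rescued contigs against the reference library
#'
#' Maps each contig back to the library at a stringent identity threshold;
#' contigs matching no reference stay unidentified (their scats carry an
#' "Undetermined" prey occurrence downstream).
#'
#' @param contigs data.frame from [denovo_rescue()].
#' @param lib a `reference_library`.
#' @param min_identity identity threshold, default 0.98.
#' @param params alignment parameters.
#' @return character vector of matched taxon ids (possibly empty),
#'   strongest-supported first, duplicates removed.
#' @export
match_contigs <- function(contigs, lib, min_identity = 0.98,
                          params = alignment_params()) {
  hits <- character(0)
  for (i in seq_len(nrow(contigs))) {
    m <- map_read(contigs$contig[i], lib,
                  alignment_params(match_score = params$match_score,
                                   mismatch_cost = params$mismatch_cost,
                                   insertion_cost = params$insertion_cost,
                                   deletion_cost = params$deletion_cost,
                                   length_fraction = params$length_fraction,
                                   similarity = min_identity,
                                   seed = params$seed),
                  read_id = paste0("contig", i))
    if (!is.na(m$taxon_id) && m$identity > min_identity) {
      hits <- c(hits, m$taxon_id)
    }
  }
  unique(hits)
}
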