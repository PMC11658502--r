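#' Tally mapped reads for one scat
#'
#' @param mappings mapping rows for a single scat (see [map_reads()]).
#' @return list with `tallies` (named integer vector of mapped-read counts
#'   per taxon, decreasing), `unmapped_fraction`, `n_reads`.
#' @export
tally_scat <- function(mappings) {
  if (nrow(mappings) == 0L) stop("no mappings for this scat")
  if (length(unique(mappings$scat_id)) > 1L) {
    stop("mappings span more than one scat: ",
         paste(unique(mappings$scat_id), collapse = ", "))
  }
  mapped <- mappings[mappings$status != "unmapped", , drop = FALSE]
  tallies <- sort(table(mapped$taxon_id), decreasing = TRUE)
  tallies <- setNames(as.integer(tallies), names(tallies))
  list(tallies = tallies,
       unmapped_fraction = 1 - nrow(mapped) / nrow(mappings),
       n_reads = nrow(mappings))
}

#' Classify a scat from its read tallies
#'
#' Decision cascade for host assignment:
#'
#' 1. If the single dominant taxon is a pure prey-role species (e.g. a
#'    deer scat picked up by mistake) and carries at least `min_host_reads`
#'    reads, the sample is `non_target`.
#' 2. If fewer than `min_host_reads` reads map to host-capable taxa the
#'    sample is `undetermined` (insufficient matching reads; degraded DNA).
#' 3. Exactly one host-capable candidate: `assigned`.
#' 4. Exactly two host-capable candidates with **no** reads on any other
#'    prey-capable taxon and `unmapped_fraction < 0.05`: intraguild
#'    predation — the candidate with the higher tally is the consumer, the
#'    other the consumed prey (an exact tie is `inconclusive`).
#' 5. Two candidates otherwise, or three or more: `inconclusive`.
#'
#' A host-capable taxon only counts as a candidate when its tally reaches
#' `min_host_frac` of mapped reads; this noise floor keeps a single stray
#' non-specifically placed read from turning a one-host scat into a
#' spurious two-host pattern. Taxa with role `both` (predators that are
#' also prey, e.g. foxes) are host-capable.
#'
#' @param tallies named mapped-read counts from [tally_scat()].
#' @param unmapped_fraction fraction of reads left unmapped.
#' @param lib a `reference_library`.
#' @param min_host_reads minimum total host-capable reads (default 50; the
#'   "insufficient reads" cut-off, configuration-exposed).
#' @param min_host_frac candidate noise floor as a fraction of mapped
#'   reads (default 0.02).
#' @return A `scat_call` list: `status` (one of `assigned`, `undetermined`,
#'   `inconclusive`, `non_target`, `unknown_prey`), `host_taxon`,
#'   `prey_occurrences`, `intraguild` (`NULL` or
#'   `list(consumer=, consumed=)`), `tallies`, `unmapped_fraction`.
#' @export
classify_scat <- function(tallies, unmapped_fraction, lib,
                          min_host_reads = 50L, min_host_frac = 0.02) {
  hosts <- host_capable(lib)
  preys <- prey_capable(lib)
  res <- structure(list(status = "undetermined", host_taxon = NA_character_,
                        prey_occurrences = character(0), intraguild = NULL,
                        tallies = tallies,
                        unmapped_fraction = unmapped_fraction),
                   class = "scat_call")
  if (length(tallies) == 0L || sum(tallies) == 0L) return(res)
  total_mapped <- sum(tallies)
  top <- names(tallies)[tallies == max(tallies)]
  # rule 1: a non-host animal dominates the sample outright
  if (length(top) == 1L && !(top %in% hosts) &&
      tallies[[top]] >= min_host_reads) {
    res$status <- "non_target"
    return(res)
  }
  host_reads <- sum(tallies[names(tallies) %in% hosts])
  if (host_reads < min_host_reads) return(res) # rule 2: undetermined
  floor_reads <- max(1, min_host_frac * total_mapped)
  cand <- names(tallies)[names(tallies) %in% hosts & tallies >= floor_reads]
  if (length(cand) == 0L) return(res)
  if (length(cand) == 1L) {
    res$status <- "assigned"
    res$host_taxon <- cand
    return(res)
  }
  if (length(cand) == 2L) {
    other_prey_reads <- sum(tallies[names(tallies) %in% preys &
                                      !(names(tallies) %in% cand)])
    if (other_prey_reads == 0L && unmapped_fraction < 0.05) {
      t1 <- tallies[[cand[1]]]; t2 <- tallies[[cand[2]]]
      if (t1 == t2) {
        res$status <- "inconclusive"
        return(res)
      }
      consumer <- cand[which.max(c(t1, t2))]
      consumed <- setdiff(cand, consumer)
      res$status <- "assigned"
      res$host_taxon <- consumer
      res$prey_occurrences <- consumed
      res$intraguild <- list(consumer = consumer, consumed = consumed)
      return(res)
    }
  }
  res$status <- "inconclusive"
  res
}

#' @export
print.scat_call <- function(x, ...) {
  cat("Scat call:", x$status)
  if (!is.na(x$host_taxon)) cat(" | host:", x$host_taxon)
  if (length(x$prey_occurrences)) {
    cat(" | prey:", paste(x$prey_occurrences, collapse = ", "))
  }
  if (!is.null(x$intraguild)) {
    cat(" | intraguild:", x$intraguild$consumer, "ate", x$intraguild$consumed)
  }
  cat("\n")
  invisible(x)
}

#' Call prey occurrences for an assigned scat
#'
#' Every non-host taxon with mapped reads becomes a prey candidate. A
#' candidate is accepted when its majority-rule consensus identity to its
#' reference exceeds `min_identity` (the ">98% similarity" rule). When the
#' same reads were placed non-specifically across several references, the
#' conflicting candidates are grouped (taxa linked by shared ties) and the
#' group keeps only the taxon with the most reads, tie-broken by the
#' fewest total mismatches. Candidates failing the identity threshold have
#' their reads routed to [denovo_rescue()]; contigs matching no reference
#' leave an `"Undetermined"` prey occurrence (a countable diet category).
#'
#' @param call a `scat_call` with status `assigned` (see [classify_scat()]).
#' @param mappings this scat's mapping rows.
#' @param lib a `reference_library`.
#' @param min_identity consensus identity threshold, default 0.98 (strict
#'   greater-than).
#' @param min_contig minimum rescue contig length, default 100.
#' @return the updated `scat_call`, with `prey_occurrences` filled in. An
#'   assigned scat whose candidate/unmapped reads resolve to nothing at all
#'   despite a substantial unmapped fraction is downgraded to
#'   `unknown_prey`.
#' @export
call_prey <- function(call, mappings, lib, min_identity = 0.98,
                      min_contig = 100L) {
  stopifnot(inherits(call, "scat_call"))
  if (call$status != "assigned") return(call)
  host <- call$host_taxon
  intraguild_prey <- call$prey_occurrences # consumed host, kept as-is
  mapped <- mappings[mappings$status != "unmapped", , drop = FALSE]
  cand_taxa <- setdiff(unique(mapped$taxon_id), c(host, intraguild_prey))
  stats_list <- list()
  rescue_seqs <- character(0)
  for (tx in cand_taxa) {
    rows <- mapped[mapped$taxon_id == tx, , drop = FALSE]
    cons <- build_consensus(rows, lib$sequences[[tx]])
    stats_list[[tx]] <- list(
      n_reads = nrow(rows),
      mismatches = sum(rows$mismatches, na.rm = TRUE),
      identity = cons$identity_to_reference,
      tied = unique(unlist(strsplit(rows$tied_taxa, ";", fixed = TRUE))))
  }
  accepted <- names(stats_list)[vapply(stats_list, function(s)
    isTRUE(s$identity > min_identity), logical(1))]
  failed <- setdiff(names(stats_list), accepted)
  # resolve conflict groups among accepted candidates: taxa linked by
  # shared non-specific ties compete for the same underlying reads
  if (length(accepted) > 1L) {
    # taxa a and b conflict when reads were tied between them (either tie
    # set of size > 1 names the other); merge into connected components
    conflicts <- function(a, b) {
      (length(stats_list[[a]]$tied) > 1L && b %in% stats_list[[a]]$tied) ||
        (length(stats_list[[b]]$tied) > 1L && a %in% stats_list[[b]]$tied)
    }
    groups <- list()
    for (tx in accepted) {
      linked <- which(vapply(groups, function(g)
        any(vapply(g, conflicts, logical(1), b = tx)), logical(1)))
      if (length(linked)) {
        merged <- c(unlist(groups[linked]), tx)
        groups[linked] <- NULL
        groups[[length(groups) + 1L]] <- merged
      } else {
        groups[[length(groups) + 1L]] <- tx
      }
    }
    accepted <- vapply(groups, function(g) {
      if (length(g) == 1L) return(g)
      n <- vapply(g, function(t2) stats_list[[t2]]$n_reads, numeric(1))
      g <- g[n == max(n)]
      if (length(g) > 1L) {
        mm <- vapply(g, function(t2) stats_list[[t2]]$mismatches, numeric(1))
        g <- g[order(mm)]
      }
      g[1]
    }, character(1))
  }
  # De novo rescue runs only when prey could not be discerned: either a
  # candidate failed the consensus-identity threshold, or the scat has no
  # prey call at all despite a substantial (>= 5%) unmapped fraction. A
  # handful of stray unmappable reads on an otherwise resolved scat is
  # background, not a missing prey item.
  no_prey_yet <- length(accepted) + length(intraguild_prey) == 0L
  attempt_rescue <- length(failed) > 0L ||
    (no_prey_yet && call$unmapped_fraction >= 0.05)
  undetermined <- FALSE
  if (attempt_rescue) {
    for (tx in failed) {
      rows <- mappings[!is.na(mappings$taxon_id) & mappings$taxon_id == tx, ,
                       drop = FALSE]
      rescue_seqs <- c(rescue_seqs, rows$sequence %||% character(0))
    }
    if ("sequence" %in% names(mappings)) {
      rescue_seqs <- c(rescue_seqs,
                       mappings$sequence[mappings$status == "unmapped"])
    }
    matched <- character(0)
    if (length(rescue_seqs)) {
      contigs <- tryCatch(
        denovo_rescue(rescue_seqs, min_contig = min_contig),
        error = function(e) NULL)
      matched <- if (!is.null(contigs) && nrow(contigs)) {
        match_contigs(contigs, lib, min_identity = min_identity)
      } else character(0)
      matched <- setdiff(matched, c(host, accepted, intraguild_prey))
    }
    if (length(matched)) {
      accepted <- c(accepted, matched)
    } else if (length(failed) > 0L) {
      undetermined <- TRUE
    }
  }
  prey <- unique(c(intraguild_prey, accepted))
  if (undetermined) prey <- c(prey, "Undetermined")
  if (length(prey) == 0L && call$unmapped_fraction > 0.05) {
    call$status <- "unknown_prey"
  }
  call$prey_occurrences <- setdiff(prey, host)
  call
}

#' Aggregate scat calls into a predator-by-prey diet matrix
#'
#' Occurrences are presence/absence per scat (each prey taxon counts at
#' most once per scat); intraguild consumed taxa count as prey occurrences
#' of their consumer; `"Undetermined"` is retained as a countable prey
#' row. Counts are stratified by season with an `Overall` slice equal to
#' the seasonal sum.
#'
#' @param calls list of `scat_call` objects (status `assigned`), each with
#'   a `scat_id` and `season` element attached (as produced by
#'   [run_pipeline()] or supplied manually).
#' @param seasons character vector of seasons parallel to `calls`
#'   (overrides any `season` element), values among
#'   `r paste(SEASONS, collapse=", ")`.
#' @param lib a `reference_library` (tier labels for prey rows).
#' @return A `diet_matrix`: list with `counts` (3-d array prey x predator
#'   x season incl. `Overall`), `scat_totals` (predator x season), `tiers`
#'   (tier lookup for prey rows).
#' @export
aggregate_calls <- function(calls, seasons = NULL, lib = NULL) {
  if (is.null(seasons)) {
    seasons <- vapply(calls, function(x) x$season %||% NA_character_,
                      character(1))
  }
  assigned <- vapply(calls, function(x) x$status == "assigned", logical(1))
  calls <- calls[assigned]
  seasons <- seasons[assigned]
  if (length(calls) && anyNA(seasons)) stop("missing season for assigned scat(s)")
  if (length(calls) && !all(seasons %in% SEASONS)) {
    stop("season values must be among: ", paste(SEASONS, collapse = ", "))
  }
  predators <- sort(unique(vapply(calls, function(x) x$host_taxon, character(1))))
  prey_items <- sort(unique(unlist(lapply(calls, function(x) x$prey_occurrences))))
  # keep Undetermined as the final row
  if ("Undetermined" %in% prey_items) {
    prey_items <- c(setdiff(prey_items, "Undetermined"), "Undetermined")
  }
  counts <- array(0L, dim = c(length(prey_items), length(predators),
                              length(SEASONS_ALL)),
                  dimnames = list(prey = prey_items, predator = predators,
                                  season = SEASONS_ALL))
  scat_totals <- matrix(0L, nrow = length(predators), ncol = length(SEASONS_ALL),
                        dimnames = list(predator = predators,
                                        season = SEASONS_ALL))
  for (i in seq_along(calls)) {
    h <- calls[[i]]$host_taxon
    s <- seasons[i]
    scat_totals[h, s] <- scat_totals[h, s] + 1L
    for (p in unique(calls[[i]]$prey_occurrences)) {
      counts[p, h, s] <- counts[p, h, s] + 1L
    }
  }
  counts[, , "Overall"] <- apply(counts[, , SEASONS, drop = FALSE], c(1, 2), sum)
  scat_totals[, "Overall"] <- rowSums(scat_totals[, SEASONS, drop = FALSE])
  tiers <- NULL
  if (!is.null(lib)) {
    rec <- lib$records
    idx <- match(prey_items, rec$taxon_id)
    tiers <- data.frame(tier1 = ifelse(is.na(idx), prey_items, rec$tier1[idx]),
                        tier2 = ifelse(is.na(idx), prey_items, rec$tier2[idx]),
                        tier3 = ifelse(is.na(idx), prey_items, rec$tier3[idx]),
                        row.names = prey_items, stringsAsFactors = FALSE)
  }
  diet_matrix(counts, scat_totals, tiers)
}

#' Construct a diet matrix
#'
#' @param counts 3-d integer array (prey x predator x season, seasons
#'   `r paste(SEASONS_ALL, collapse=", ")`); the `Overall` slice may be
#'   omitted and is then computed.
#' @param scat_totals predator x season matrix of scat counts (optional).
#' @param tiers optional data.frame (rownames = prey) with `tier1`,
#'   `tier2`, `tier3`.
#' @return A `diet_matrix`.
#' @export
diet_matrix <- function(counts, scat_totals = NULL, tiers = NULL) {
  stopifnot(length(dim(counts)) == 3L)
  have <- dimnames(counts)[[3]]
  bad <- setdiff(have, SEASONS_ALL)
  if (length(bad)) stop("unknown season slice(s): ", paste(bad, collapse = ", "))
  if (!identical(have, SEASONS_ALL)) {
    # normalize to the full four-season + Overall layout
    expanded <- array(0L, dim = c(dim(counts)[1:2], length(SEASONS_ALL)),
                      dimnames = c(dimnames(counts)[1:2],
                                   list(season = SEASONS_ALL)))
    for (s in intersect(have, SEASONS_ALL)) expanded[, , s] <- counts[, , s]
    if (!"Overall" %in% have) {
      expanded[, , "Overall"] <-
        apply(expanded[, , SEASONS, drop = FALSE], c(1, 2), sum)
    }
    counts <- expanded
  }
  if (any(counts < 0)) stop("diet counts must be non-negative")
  ov <- apply(counts[, , setdiff(dimnames(counts)[[3]], "Overall"),
                     drop = FALSE], c(1, 2), sum)
  if (!isTRUE(all.equal(as.vector(ov),
                        as.vector(counts[, , "Overall"])))) {
    stop("Overall slice must equal the sum of the season slices")
  }
  structure(list(counts = counts, scat_totals = scat_totals, tiers = tiers),
            class = "diet_matrix")
}

#' @export
print.diet_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat("Diet matrix:", d[1], "prey x", d[2], "predators x",
      d[3] - 1L, "seasons (+Overall)\n")
  cat("  total occurrences (Overall):", sum(x$counts[, , "Overall"]), "\n")
  invisible(x)
}

#' Write a calls table to TSV
#'
#' @param calls list of `scat_call` objects with `scat_id`/`season` set.
#' @param path output path.
#' @return the table, invisibly.
#' @export
write_calls <- function(calls, path) {
  tab <- do.call(rbind, lapply(calls, function(x) {
    data.frame(
      scat_id = x$scat_id %||% NA_character_,
      season = x$season %||% NA_character_,
      status = x$status,
      host = x$host_taxon,
      prey = paste(x$prey_occurrences, collapse = ";"),
      intraguild = if (is.null(x$intraguild)) "" else
        paste0(x$intraguild$consumer, ">", x$intraguild$consumed),
      n_mapped = sum(x$tallies),
      unmapped_fraction = x$unmapped_fraction,
      stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
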