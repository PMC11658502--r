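#' Pipeline run configuration
#'
#' @param reference_fasta,metadata_tsv reference library paths.
#' @param fastq path to the reads FASTQ.
#' @param manifest_tsv TSV with columns `scat_id`, `season`.
#' @param out_dir output directory (created if missing).
#' @param params an [alignment_params()].
#' @param min_host_reads,min_host_frac host-call thresholds
#'   (see [classify_scat()]).
#' @param prey_min_identity consensus identity threshold for prey calls.
#' @param biomass biomass model (see [biomass_model()]).
#' @param null_iterations,seed null-model iterations and global seed.
#' @param trim_limit quality score limit for read trimming.
#' @return a `run_config` list (paths are validated by [run_pipeline()]).
#' @export
run_config <- function(reference_fasta, metadata_tsv, fastq, manifest_tsv,
                       out_dir, params = alignment_params(),
                       min_host_reads = 50L, min_host_frac = 0.02,
                       prey_min_identity = 0.98,
                       biomass = biomass_model(),
                       null_iterations = 999L, seed = 1L,
                       trim_limit = 0.1) {
  structure(list(reference_fasta = reference_fasta,
                 metadata_tsv = metadata_tsv, fastq = fastq,
                 manifest_tsv = manifest_tsv, out_dir = out_dir,
                 params = params, min_host_reads = min_host_reads,
                 min_host_frac = min_host_frac,
                 prey_min_identity = prey_min_identity,
                 biomass = biomass, null_iterations = null_iterations,
                 seed = seed, trim_limit = trim_limit),
            class = "run_config")
}

#' Call one scat from its mapped reads
#'
#' Convenience wrapper chaining [tally_scat()], [classify_scat()] and
#' [call_prey()] for the mapping rows of a single scat.
#'
#' @param mappings mapping rows for one scat, including a `sequence`
#'   column for rescue.
#' @param lib a `reference_library`.
#' @param min_host_reads,min_host_frac,prey_min_identity thresholds.
#' @return a `scat_call` with `scat_id` attached.
#' @export
call_scat <- function(mappings, lib, min_host_reads = 50L,
                      min_host_frac = 0.02, prey_min_identity = 0.98) {
  t <- tally_scat(mappings)
  call <- classify_scat(t$tallies, t$unmapped_fraction, lib,
                        min_host_reads = min_host_reads,
                        min_host_frac = min_host_frac)
  call <- call_prey(call, mappings, lib, min_identity = prey_min_identity)
  call$scat_id <- mappings$scat_id[1]
  call
}

#' Run the full diet pipeline
#'
#' Reads and trims the FASTQ, maps every read to the reference library,
#' classifies each scat (host, prey occurrences, intraguild events),
#' aggregates a seasonal diet matrix, and writes the full set of result
#' tables to `out_dir`: calls, host composition, per-predator FOO and
#' biomass, diversity, Jaccard similarity + PCoA coordinates, Pianka
#' null-model report, and a provenance log echoing all parameters. Given
#' the same inputs and configuration the run is fully deterministic.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `calls`, `diet`, and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("reference_fasta", "metadata_tsv", "fastq", "manifest_tsv")) {
    if (!file.exists(config[[p]])) {
      stop("validation error: ", p, " does not exist: ", config[[p]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = logf)
  log_line("pipeline start; seed=", config$seed,
           " similarity=", config$params$similarity,
           " length_fraction=", config$params$length_fraction,
           " min_host_reads=", config$min_host_reads)

  lib <- load_reference(config$reference_fasta, config$metadata_tsv)
  manifest <- read.delim(config$manifest_tsv, stringsAsFactors = FALSE)
  reads <- load_reads(config$fastq)
  log_line("loaded ", nrow(reads), " reads, ", nrow(lib$records), " taxa")
  reads <- trim_reads(reads, limit = config$trim_limit)
  log_line("after trimming: ", nrow(reads), " reads (",
           attr(reads, "n_dropped"), " dropped)")

  params <- config$params
  params$seed <- config$seed
  mappings <- map_reads(reads, lib, params)
  mappings$sequence <- reads$sequence
  log_line("mapped: ", sum(mappings$status != "unmapped"), "/",
           nrow(mappings), " reads")

  calls <- lapply(split(mappings, mappings$scat_id), function(mm) {
    call <- call_scat(mm, lib, min_host_reads = config$min_host_reads,
                      min_host_frac = config$min_host_frac,
                      prey_min_identity = config$prey_min_identity)
    call$season <- manifest$season[match(call$scat_id, manifest$scat_id)]
    call
  })
  statuses <- vapply(calls, function(x) x$status, character(1))
  log_line("scat calls: ",
           paste(sprintf("%s=%d", names(table(statuses)), table(statuses)),
                 collapse = ", "))
  write_calls(calls, file.path(config$out_dir, "calls.tsv"))

  assigned <- calls[statuses == "assigned"]
  paths <- c(calls = file.path(config$out_dir, "calls.tsv"))
  diet <- NULL
  if (length(assigned)) {
    diet <- aggregate_calls(calls, lib = lib)
    hc <- host_composition(diet)
    write.table(data.frame(predator = names(hc), scats =
                             diet$scat_totals[, "Overall"],
                           percent = unname(hc)),
                file.path(config$out_dir, "host_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    # Table-1-style FOO layout: prey rows, predator x season columns
    foo_tab <- NULL
    bio_tab <- NULL
    div_tab <- NULL
    for (pred in dimnames(diet$counts)$predator) {
      for (season in SEASONS_ALL) {
        row <- diet$counts[, pred, season]
        if (sum(row) == 0) next
        foo <- compute_foo(diet, pred, season)
        lab <- paste(pred, substr(season, 1, 3), sep = ".")
        col <- setNames(data.frame(round(foo, 1)), lab)
        foo_tab <- if (is.null(foo_tab)) col else cbind(foo_tab, col)
        bio <- tryCatch(compute_biomass(diet, pred, season, lib,
                                        config$biomass),
                        error = function(e) NULL)
        if (!is.null(bio)) {
          full <- setNames(rep(NA_real_, nrow(foo_tab)), rownames(foo_tab))
          full[names(bio)] <- round(bio, 1)
          bcol <- setNames(data.frame(full), lab)
          bio_tab <- if (is.null(bio_tab)) bcol else cbind(bio_tab, bcol)
        }
        if (season == "Overall") {
          dv <- tryCatch(diet_diversity(diet, pred), error = function(e) NULL)
          if (!is.null(dv)) {
            div_tab <- rbind(div_tab, data.frame(
              predator = pred, richness = dv$richness,
              shannon = round(dv$shannon, 4),
              simpson = round(dv$simpson, 4)))
          }
        }
      }
    }
    write.table(cbind(prey = rownames(foo_tab), foo_tab),
                file.path(config$out_dir, "foo.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bio_tab)) {
      write.table(cbind(prey = rownames(bio_tab), bio_tab),
                  file.path(config$out_dir, "biomass.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
    if (!is.null(div_tab)) {
      write.table(div_tab, file.path(config$out_dir, "diversity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # guild statistics need >= 2 predators
    pres <- presence_matrix(diet)
    if (nrow(pres) >= 2L && ncol(pres) >= 2L) {
      jac <- jaccard_matrix(pres)
      write.table(cbind(predator = rownames(jac), as.data.frame(round(jac, 3))),
                  file.path(config$out_dir, "jaccard.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ord <- diet_pcoa(1 - jac)
      write.table(cbind(predator = rownames(ord$coordinates),
                        as.data.frame(round(ord$coordinates, 4))),
                  file.path(config$out_dir, "pcoa.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      foo_mat <- t(diet$counts[, , "Overall"])
      foo_mat <- foo_mat[, colnames(foo_mat) != "Undetermined", drop = FALSE]
      keep <- rowSums(foo_mat) > 0
      foo_mat <- foo_mat[keep, , drop = FALSE]
      if (nrow(foo_mat) >= 2L) {
        nm <- niche_null_model(foo_mat, iterations = config$null_iterations,
                               seed = config$seed)
        pianka_rep <- data.frame(comparison = "guild",
                                 observed = nm$observed_index,
                                 null_mean = mean(nm$simulated),
                                 p_upper = nm$p_upper)
        preds <- rownames(foo_mat)
        for (i in seq_along(preds)) {
          for (j in seq_along(preds)) {
            if (i < j) {
              nmp <- niche_null_model(foo_mat[c(i, j), , drop = FALSE],
                                      iterations = config$null_iterations,
                                      seed = config$seed)
              pianka_rep <- rbind(pianka_rep, data.frame(
                comparison = paste(preds[i], preds[j], sep = "-"),
                observed = nmp$observed_index,
                null_mean = mean(nmp$simulated),
                p_upper = nmp$p_upper))
            }
          }
        }
        write.table(pianka_rep, file.path(config$out_dir, "pianka.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    paths <- c(paths, foo = file.path(config$out_dir, "foo.tsv"))
  }
  # mapping table export
  write.table(mappings[c("read_id", "scat_id", "taxon_id", "status",
                         "score", "identity", "mismatches", "ref_start",
                         "ref_end")],
              file.path(config$out_dir, "mappings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  log_line("pipeline done; outputs in ", config$out_dir)
  invisible(list(calls = calls, diet = diet, mappings = mappings,
                 out_dir = config$out_dir))
}

#' Simulate a scat study to disk
#'
#' Thin wrapper over [simulate_scats()] that writes the FASTQ, manifest,
#' reference FASTA/metadata and truth tables of a scenario to a
#' directory, ready for [run_pipeline()].
#'
#' @param scenario a [guild_scenario()].
#' @param n_scats number of scats.
#' @param out_dir output directory.
#' @param seed RNG seed (same seed, byte-identical outputs).
#' @return invisibly, the [simulate_scats()] result plus file paths.
#' @export
simulate_scat_study <- function(scenario, n_scats, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_scats(scenario, n_scats, seed = seed)
  paths <- list(
    fastq = file.path(out_dir, "reads.fastq"),
    manifest = file.path(out_dir, "manifest.tsv"),
    reference_fasta = file.path(out_dir, "reference.fasta"),
    metadata = file.path(out_dir, "taxa.tsv"),
    truth = file.path(out_dir, "truth_scats.tsv"))
  write_reads(sim$reads, paths$fastq)
  write.table(sim$manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_reference(scenario$library, paths$reference_fasta, paths$metadata)
  write.table(sim$truth$scats, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sim, list(paths = paths)))
}
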