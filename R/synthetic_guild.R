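#' Simulate a reference library of divergent marker sequences
#'
#' Sequences are evolved from a random ancestor by per-site substitution
#' and accepted by rejection sampling so that every pair differs at
#' `>= min_divergence` of positions (position-wise identity
#' `<= 1 - min_divergence`). This keeps the 0.94 mapping and 0.98 prey
#' thresholds discriminative between taxa.
#'
#' @param n_taxa number of taxa.
#' @param length sequence length in bp (default 100, the 12S V5 amplicon
#'   scale).
#' @param min_divergence minimum pairwise divergence (default 0.05).
#' @param seed RNG seed.
#' @param roles optional role vector per taxon (default: all `"prey"`).
#' @param prefix taxon id prefix.
#' @return a `reference_library` with placeholder metadata (synthetic
#'   taxa `t01`, `t02`, ...; masses drawn log-uniform 0.05-100 kg).
#' @export
simulate_references <- function(n_taxa, length = 100L, min_divergence = 0.05,
                                seed = NULL, roles = NULL, prefix = "t") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_taxa >= 1L, length >= 10L, min_divergence > 0,
            min_divergence < 0.75)
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, length, replace = TRUE)
  mut_rate <- min(0.9, 1.5 * min_divergence)
  seqs <- character(0)
  attempts <- 0L
  while (base::length(seqs) < n_taxa) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n_taxa) {
      stop("min_divergence ", min_divergence, " not achievable for ",
           n_taxa, " taxa at length ", length)
    }
    cand <- ancestor
    flip <- runif(length) < mut_rate
    cand[flip] <- vapply(which(flip), function(i)
      sample(setdiff(bases, ancestor[i]), 1L), character(1))
    cand <- paste(cand, collapse = "")
    ok <- all(vapply(seqs, function(s)
      hamming_identity(s, cand) <= 1 - min_divergence, logical(1)))
    if (ok) seqs <- c(seqs, cand)
  }
  ids <- sprintf("%s%02d", prefix, seq_len(n_taxa))
  names(seqs) <- ids
  if (is.null(roles)) roles <- rep("prey", n_taxa)
  records <- data.frame(
    taxon_id = ids,
    scientific_name = paste("Synthetica", ids),
    common_name = paste("synthetic taxon", ids),
    role = roles,
    tier1 = ids,
    tier2 = ids,
    tier3 = ifelse(seq_len(n_taxa) %% 2 == 0, "group_a", "group_b"),
    mean_mass_kg = signif(exp(runif(n_taxa, log(0.05), log(100))), 3),
    stringsAsFactors = FALSE)
  reference_library(seqs, records)
}

# position-wise identity of two equal-length sequences
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Define a synthetic guild scenario
#'
#' Bundles the generative model for a predator guild study: a reference
#' library, per-predator diet probability vectors, and the read-emission
#' model. Defaults describe a realistic one-year scat survey of a
#' four-predator guild: most reads in a scat come from the depositing
#' host (fraction 0.85), 0-3 prey taxa per scat (zero-truncated
#' Poisson(0.8) capped at 3, ~1.45 prey/scat), per-base sequencing error
#' 0.005, occasional degraded scats (too few reads to call a host) and
#' rare two-predator (intraguild) scats.
#'
#' @param library a `reference_library`; predators are its host-capable
#'   taxa, prey its prey-capable taxa.
#' @param diets predators x prey matrix of diet probabilities (rows sum
#'   to 1).
#' @param predator_weights host composition of the scat collection
#'   (default uniform).
#' @param lambda_prey rate of the zero-truncated Poisson prey count.
#' @param prey_cap maximum prey taxa per scat (default 3).
#' @param reads_meanlog,reads_sdlog log-normal reads-per-scat parameters
#'   (default meanlog log(200), sdlog 0.4).
#' @param host_read_fraction fraction of a scat's reads from the host.
#' @param error_rate per-base substitution error probability.
#' @param degradation_prob probability a scat is degraded (emits very few
#'   reads).
#' @param intraguild_prob probability a scat is an intraguild-predation
#'   event (two hosts, no other prey).
#' @param junk_fraction fraction of unmappable (off-target) reads.
#' @param quality_char Phred+33 quality character written for every base
#'   (default `"F"`, Q37).
#' @return a `guild_scenario` list.
#' @export
guild_scenario <- function(library, diets,
                           predator_weights = NULL,
                           lambda_prey = 0.8, prey_cap = 3L,
                           reads_meanlog = log(200), reads_sdlog = 0.4,
                           host_read_fraction = 0.85,
                           error_rate = 0.005,
                           degradation_prob = 0.05,
                           intraguild_prob = 0.02,
                           junk_fraction = 0.01,
                           quality_char = "F") {
  predators <- rownames(diets)
  prey <- colnames(diets)
  stopifnot(all(predators %in% host_capable(library)),
            all(prey %in% library$records$taxon_id),
            all(abs(rowSums(diets) - 1) < 1e-8), all(diets >= 0),
            host_read_fraction > 0, host_read_fraction < 1,
            error_rate >= 0, error_rate < 1,
            degradation_prob >= 0, degradation_prob <= 1,
            intraguild_prob >= 0, intraguild_prob <= 1,
            junk_fraction >= 0, junk_fraction < 1)
  if (is.null(predator_weights)) {
    predator_weights <- setNames(rep(1 / length(predators), length(predators)),
                                 predators)
  }
  structure(list(library = library, diets = diets,
                 predator_weights = predator_weights,
                 lambda_prey = lambda_prey, prey_cap = as.integer(prey_cap),
                 reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
                 host_read_fraction = host_read_fraction,
                 error_rate = error_rate,
                 degradation_prob = degradation_prob,
                 intraguild_prob = intraguild_prob,
                 junk_fraction = junk_fraction,
                 quality_char = quality_char),
            class = "guild_scenario")
}

#' The default four-predator / twelve-prey study scenario
#'
#' A 16-taxon synthetic library (4 host predators, two of which are also
#' prey to larger predators; 12 prey taxa) with concentrated,
#' small-mammal-dominated diet vectors of the kind observed in montane
#' predator guilds: each predator has one dominant prey plus a short tail.
#'
#' @param seed RNG seed for the library simulation.
#' @param ... overrides passed on to [guild_scenario()].
#' @return a `guild_scenario`.
#' @export
default_scenario <- function(seed = 20260101L, ...) {
  roles <- c("host_predator", "host_predator", "both", "both",
             rep("prey", 12))
  lib <- simulate_references(16L, length = 100L, min_divergence = 0.05,
                             seed = seed, roles = roles)
  predators <- lib$records$taxon_id[1:4]
  prey <- lib$records$taxon_id[5:16]
  diets <- rbind(
    # apex 1: ungulate-style dominant prey, moderate tail
    c(0.55, 0.14, 0.10, 0.08, 0.05, 0.03, 0.02, 0.01, 0.01, 0.01, 0, 0),
    # apex 2: one dominant prey, short tail
    c(0.10, 0.62, 0.12, 0.06, 0.04, 0.03, 0.02, 0.01, 0, 0, 0, 0),
    # mesocarnivore 1: strongly specialised (pika-like dominance)
    c(0.03, 0.02, 0.80, 0.06, 0.04, 0.02, 0.02, 0.01, 0, 0, 0, 0),
    # mesocarnivore 2: generalist but still dominated
    c(0.05, 0.04, 0.55, 0.12, 0.08, 0.06, 0.04, 0.03, 0.02, 0.01, 0, 0))
  dimnames(diets) <- list(predators, prey)
  guild_scenario(lib, diets, ...)
}

# zero-truncated Poisson capped at `cap`
rztpois_capped <- function(n, lambda, cap) {
  x <- qpois_trunc(runif(n), lambda)
  pmin(x, cap)
}
qpois_trunc <- function(u, lambda) {
  p0 <- exp(-lambda)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

# introduce iid substitution errors into a sequence
add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  flip <- which(runif(length(chars)) < rate)
  for (i in flip) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

random_sequence <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Simulate scats and their amplicon reads
#'
#' For each scat: draw the depositing host from the predator weights;
#' with probability `intraguild_prob` emit an intraguild scat (reads from
#' two host-capable taxa, no other prey, < 5% junk reads); with
#' probability `degradation_prob` emit a degraded scat (< `degraded_max`
#' reads); otherwise draw a prey count from the capped zero-truncated
#' Poisson, sample that many distinct prey by the host's diet vector,
#' and allocate `host_read_fraction` of the scat's reads to the host and
#' the rest equally among prey. Every read is a copy of its taxon's
#' reference with iid substitution errors; a `junk_fraction` of reads is
#' replaced by random unmappable sequence.
#'
#' @param scenario a [guild_scenario()].
#' @param n_scats number of scats.
#' @param seed RNG seed (identical seeds give identical reads and truth).
#' @param seasons season labels sampled uniformly per scat (default the
#'   four survey months).
#' @param degraded_max maximum read count of a degraded scat (default 20).
#' @return list with `reads` (data.frame `read_id`, `scat_id`,
#'   `sequence`, `quality`), `manifest` (`scat_id`, `season`), and
#'   `truth` (list: `scats` data.frame with true host/prey/status per
#'   scat, and `diet` the realized true `diet_matrix`).
#' @export
simulate_scats <- function(scenario, n_scats, seed = NULL,
                           seasons = SEASONS, degraded_max = 20L) {
  stopifnot(inherits(scenario, "guild_scenario"), n_scats >= 1L)
  if (!is.null(seed)) set.seed(seed)
  lib <- scenario$library
  predators <- rownames(scenario$diets)
  reflen <- nchar(lib$sequences)
  reads_list <- vector("list", n_scats)
  truth_list <- vector("list", n_scats)
  calls_truth <- vector("list", n_scats)
  for (s in seq_len(n_scats)) {
    scat_id <- sprintf("scat%04d", s)
    season <- sample(seasons, 1L)
    host <- sample(predators, 1L, prob = scenario$predator_weights[predators])
    intraguild <- runif(1) < scenario$intraguild_prob
    degraded <- !intraguild && runif(1) < scenario$degradation_prob
    n_reads <- max(1L, round(rlnorm(1, scenario$reads_meanlog,
                                    scenario$reads_sdlog)))
    if (degraded) n_reads <- sample.int(degraded_max, 1L)
    if (intraguild) {
      consumed <- sample(setdiff(predators, host), 1L)
      n_host <- round(n_reads * scenario$host_read_fraction)
      src <- c(rep(host, n_host), rep(consumed, n_reads - n_host))
      prey_taxa <- consumed
    } else {
      n_prey <- rztpois_capped(1L, scenario$lambda_prey, scenario$prey_cap)
      dv <- scenario$diets[host, ]
      n_prey <- min(n_prey, sum(dv > 0))
      prey_taxa <- if (n_prey > 0)
        sample(colnames(scenario$diets), n_prey, prob = dv) else character(0)
      n_host <- if (length(prey_taxa)) {
        round(n_reads * scenario$host_read_fraction)
      } else n_reads
      src <- rep(host, n_host)
      if (length(prey_taxa)) {
        alloc <- rep(floor((n_reads - n_host) / length(prey_taxa)),
                     length(prey_taxa))
        rem <- (n_reads - n_host) - sum(alloc)
        if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
        alloc <- pmax(alloc, 1L) # every true prey leaves at least one read
        src <- c(src, rep(prey_taxa, alloc))
      }
    }
    # junk reads replace a random subset (never on intraguild scats'
    # mapped fraction guarantee: the rate stays < 5%)
    is_junk <- runif(length(src)) < scenario$junk_fraction
    seqs <- character(length(src))
    for (i in seq_along(src)) {
      seqs[i] <- if (is_junk[i]) {
        random_sequence(100L)
      } else {
        add_errors(lib$sequences[[src[i]]], scenario$error_rate)
      }
    }
    reads_list[[s]] <- data.frame(
      read_id = sprintf("%s:read%05d", scat_id, seq_along(seqs)),
      scat_id = scat_id,
      sequence = seqs,
      quality = vapply(nchar(seqs), function(L)
        strrep(scenario$quality_char, L), character(1)),
      stringsAsFactors = FALSE)
    truth_list[[s]] <- data.frame(
      scat_id = scat_id, season = season, host = host,
      prey = paste(setdiff(prey_taxa, character(0)), collapse = ";"),
      intraguild = intraguild, degraded = degraded,
      n_reads = length(src), stringsAsFactors = FALSE)
    calls_truth[[s]] <- structure(
      list(status = if (degraded) "undetermined" else "assigned",
           host_taxon = host,
           prey_occurrences = prey_taxa,
           intraguild = if (intraguild)
             list(consumer = host, consumed = prey_taxa) else NULL,
           tallies = setNames(integer(0), character(0)),
           unmapped_fraction = mean(is_junk),
           scat_id = scat_id, season = season),
      class = "scat_call")
  }
  reads <- do.call(rbind, reads_list)
  attr(reads, "offset") <- 33L
  truth_scats <- do.call(rbind, truth_list)
  truth_diet <- aggregate_calls(calls_truth, lib = lib)
  list(reads = reads,
       manifest = truth_scats[c("scat_id", "season")],
       truth = list(scats = truth_scats, calls = calls_truth,
                    diet = truth_diet))
}

#' Random diet count matrix (null-model calibration input)
#'
#' Each predator row is an independent symmetric Dirichlet draw converted
#' to counts by a multinomial sample, giving exchangeable resource
#' columns — the reference input for type-I-error studies of
#' [niche_null_model()].
#'
#' @param n_predators,n_prey dimensions (>= 2 each).
#' @param concentration symmetric Dirichlet concentration (default 1).
#' @param total occurrences per row (default 100).
#' @param seed RNG seed.
#' @return integer matrix predators x prey.
#' @export
random_diet_matrix <- function(n_predators, n_prey, concentration = 1,
                               total = 100L, seed = NULL) {
  stopifnot(n_predators >= 2L, n_prey >= 2L, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n_predators, n_prey,
                dimnames = list(paste0("pred", seq_len(n_predators)),
                                paste0("prey", seq_len(n_prey))))
  for (i in seq_len(n_predators)) {
    g <- rgamma(n_prey, shape = concentration)
    out[i, ] <- as.integer(rmultinom(1, total, g / sum(g)))
  }
  out
}
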