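# Small in-code fixtures shared across tests.

# A hand-built six-taxon library: two pure predators, one predator that is
# also prey (fox-like), three prey. Sequences are 100 bp and mutually
# divergent well past the mapping thresholds.
tiny_library <- function() {
  set.seed(424242)
  base <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  seqs <- c(
    wolf = base,
    leopard = mutate_seq(base, 12),
    fox = mutate_seq(base, 24),
    pika = mutate_seq(base, 36),
    vole = mutate_seq(base, 48),
    snowcock = mutate_seq(base, 60))
  records <- data.frame(
    taxon_id = names(seqs),
    scientific_name = paste("Genus", names(seqs)),
    common_name = names(seqs),
    role = c("host_predator", "host_predator", "both", "prey", "prey", "prey"),
    tier1 = names(seqs),
    tier2 = c("canids", "felids", "canids", "small mammals", "small mammals",
              "birds"),
    tier3 = c("carnivores", "carnivores", "carnivores", "mammals", "mammals",
              "birds"),
    mean_mass_kg = c(35, 40, 4.5, 0.15, 0.03, 3.0),
    stringsAsFactors = FALSE)
  reference_library(seqs, records)
}

# mapping rows for synthetic reads drawn as exact/mutated copies of library
# taxa: convenience for scat-call tests
make_scat_mappings <- function(lib, composition, scat_id = "s1",
                               n_junk = 0L, seed = 1) {
  set.seed(seed)
  rows <- list()
  idx <- 1L
  for (tx in names(composition)) {
    for (r in seq_len(composition[[tx]])) {
      rows[[idx]] <- data.frame(
        read_id = sprintf("%s:read%04d", scat_id, idx), scat_id = scat_id,
        taxon_id = tx, status = "mapped", score = 100L, identity = 1,
        mismatches = 0L, aligned_read_fraction = 1,
        ref_start = 0L, ref_end = 100L, ref_aligned = lib$sequences[[tx]],
        tied_taxa = tx, sequence = lib$sequences[[tx]],
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  for (r in seq_len(n_junk)) {
    rows[[idx]] <- data.frame(
      read_id = sprintf("%s:junk%04d", scat_id, r), scat_id = scat_id,
      taxon_id = NA_character_, status = "unmapped", score = 0L,
      identity = NA_real_, mismatches = NA_integer_,
      aligned_read_fraction = NA_real_, ref_start = NA_integer_,
      ref_end = NA_integer_, ref_aligned = NA_character_, tied_taxa = "",
      sequence = random_dna(100), stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small deterministic diet matrix: 2 predators x 3 prey x seasons
toy_diet_matrix <- function() {
  counts <- array(0L, dim = c(3, 2, 4),
                  dimnames = list(prey = c("pika", "vole", "snowcock"),
                                  predator = c("wolf", "fox"),
                                  season = c("March", "July", "September",
                                             "December")))
  counts["pika", "wolf", "March"] <- 5L
  counts["vole", "wolf", "March"] <- 3L
  counts["snowcock", "wolf", "July"] <- 2L
  counts["pika", "fox", "March"] <- 7L
  counts["vole", "fox", "December"] <- 1L
  scat_totals <- matrix(
    c(6L, 2L, 0L, 0L, 8L,
      5L, 0L, 0L, 1L, 6L), nrow = 2, byrow = TRUE,
    dimnames = list(predator = c("wolf", "fox"),
                    season = c("March", "July", "September", "December",
                               "Overall")))
  tiers <- data.frame(
    tier1 = c("pika", "vole", "snowcock"),
    tier2 = c("small mammals", "small mammals", "birds"),
    tier3 = c("mammals", "mammals", "birds"),
    row.names = c("pika", "vole", "snowcock"), stringsAsFactors = FALSE)
  diet_matrix(counts, scat_totals, tiers)
}
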