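test_that("local alignment matches hand cases and the DP oracle", {
  # self-alignment: perfect score and identity
  a <- local_align("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 8L)
  expect_equal(a$identity, 1)
  expect_equal(a$query_interval, c(0L, 8L))
  # no positive-scoring cell
  b <- local_align("AAAA", "TTTT")
  expect_equal(b$score, 0L)
  expect_equal(b$aligned_cols, 0L)
  # one-substitution case against the oracle
  o <- sw_oracle("ACGTTCGT", "ACGTACGT")
  c1 <- local_align("ACGTTCGT", "ACGTACGT")
  expect_equal(c1$score, o$score)
  expect_equal(c1$matches, o$matches)
  expect_equal(c1$mismatches, o$mismatches)
  expect_equal(c1$identity, o$matches / o$aligned_cols)
})

test_that("aligner agrees with the brute-force oracle on random pairs", {
  set.seed(1234)
  for (i in 1:60) {
    qlen <- sample(20:110, 1)
    tlen <- sample(60:110, 1)
    t <- random_dna(tlen)
    # mix of related and unrelated queries so gaps and mismatches occur
    q <- if (i %% 2 == 0) {
      mutate_seq(substr(t, 1, min(qlen, tlen)), sample(0:8, 1))
    } else {
      random_dna(qlen)
    }
    o <- sw_oracle(q, t)
    a <- local_align(q, t)
    expect_equal(a$score, o$score, info = paste("pair", i))
    expect_equal(a$matches, o$matches, info = paste("pair", i))
    expect_equal(a$mismatches, o$mismatches, info = paste("pair", i))
    expect_equal(a$aligned_cols, o$aligned_cols, info = paste("pair", i))
    expect_equal(a$target_interval, c(o$t_start, o$t_end),
                 info = paste("pair", i))
  }
})

test_that("aligner score matches Biostrings pairwiseAlignment", {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE)
  set.seed(5678)
  for (i in 1:20) {
    t <- random_dna(80)
    q <- if (i %% 2 == 0) mutate_seq(t, sample(1:10, 1)) else random_dna(50)
    ours <- local_align(q, t)$score
    theirs <- Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 3, scoreOnly = TRUE)
    if (theirs < 0) {
      # Biostrings reports a negative score where no positive local
      # alignment exists; ours is defined as 0 there
      expect_equal(ours, 0L)
    } else {
      expect_equal(ours, as.integer(theirs))
    }
  }
})

test_that("map_read applies similarity and length-fraction filters", {
  lib <- tiny_library()
  # perfect read maps with identity 1
  m <- map_read(lib$sequences[["pika"]], lib, read_id = "r1")
  expect_equal(m$taxon_id, "pika")
  expect_equal(m$status, "mapped")
  expect_equal(m$identity, 1)
  expect_equal(m$aligned_read_fraction, 1)
  # 7 substitutions in 100 bp: best identity 0.93 < 0.94 -> unmapped
  set.seed(11)
  read7 <- mutate_seq(lib$sequences[["pika"]], 7)
  m7 <- map_read(read7, lib, read_id = "r2")
  # oracle recomputation of the identity against the threshold
  o <- sw_oracle(read7, lib$sequences[["pika"]])
  if (o$matches / o$aligned_cols < 0.94) {
    expect_equal(m7$status, "unmapped")
    expect_true(is.na(m7$taxon_id))
  }
  # 5 substitutions passes (0.95 >= 0.94) when alignment stays full-length
  set.seed(12)
  read5 <- mutate_seq(lib$sequences[["pika"]], 5)
  o5 <- sw_oracle(read5, lib$sequences[["pika"]])
  m5 <- map_read(read5, lib, read_id = "r3")
  if (o5$matches / o5$aligned_cols >= 0.94 &&
      (o5$q_end - o5$q_start) / 100 >= 0.9) {
    expect_equal(m5$taxon_id, "pika")
  }
})

test_that("non-specific ties resolve deterministically by seed", {
  # two identical references force a tie
  seqs <- tiny_library()$sequences[c("pika", "vole")]
  seqs[["vole"]] <- seqs[["pika"]]
  rec <- tiny_library()$records
  rec <- rec[rec$taxon_id %in% c("pika", "vole"), ]
  lib2 <- reference_library(seqs, rec)
  p <- alignment_params(seed = 7L)
  picks <- vapply(1:20, function(i)
    map_read(seqs[["pika"]], lib2, p, read_id = "readX")$taxon_id,
    character(1))
  expect_length(unique(picks), 1L) # same read+seed -> same resolution
  m <- map_read(seqs[["pika"]], lib2, p, read_id = "readX")
  expect_equal(m$status, "nonspecific_resolved")
  expect_setequal(m$tied_taxa, c("pika", "vole"))
  # across many read ids both taxa are drawn
  many <- vapply(sprintf("read%03d", 1:40), function(rid)
    map_read(seqs[["pika"]], lib2, p, read_id = rid)$taxon_id, character(1))
  expect_setequal(unique(many), c("pika", "vole"))
})

test_that("lowering the similarity threshold never unmaps reads", {
  lib <- tiny_library()
  set.seed(303)
  reads <- vapply(1:30, function(i)
    mutate_seq(lib$sequences[[sample(6, 1)]], sample(0:8, 1)), character(1))
  n_mapped <- function(sim) {
    sum(vapply(seq_along(reads), function(i)
      map_read(reads[i], lib, alignment_params(similarity = sim),
               read_id = paste0("r", i))$status != "unmapped", logical(1)))
  }
  counts <- vapply(c(0.98, 0.94, 0.90, 0.80), n_mapped, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("consensus takes plurality bases, codes ties N, conserves depth", {
  lib <- tiny_library()
  ref <- lib$sequences[["pika"]]
  mk_row <- function(seq) data.frame(
    ref_start = 0L, ref_end = nchar(seq), ref_aligned = seq,
    stringsAsFactors = FALSE)
  # three identical error-free reads reproduce the reference
  maps <- do.call(rbind, replicate(3, mk_row(ref), simplify = FALSE))
  cons <- build_consensus(maps, ref)
  expect_equal(cons$consensus, ref)
  expect_equal(cons$identity_to_reference, 1)
  expect_equal(sum(cons$depth), 3L * nchar(ref)) # depth conservation

  # 2 vs 2 tie at one position -> N
  alt <- ref
  substr(alt, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(ref, 10, 10))[1]
  maps <- rbind(mk_row(ref), mk_row(ref), mk_row(alt), mk_row(alt))
  cons <- build_consensus(maps, ref)
  expect_equal(substr(cons$consensus, 10, 10), "N")

  # 10 reads sharing one substitution: consensus carries it,
  # identity = (covered - 1) / covered
  maps <- do.call(rbind, replicate(10, mk_row(alt), simplify = FALSE))
  cons <- build_consensus(maps, ref)
  expect_equal(substr(cons$consensus, 10, 10), substr(alt, 10, 10))
  expect_equal(cons$identity_to_reference,
               (nchar(ref) - 1) / nchar(ref))

  expect_error(build_consensus(maps[0, ], ref), "no mapped reads")
})

test_that("de novo rescue clusters read families and majority-rules sites", {
  set.seed(21)
  fam1 <- random_dna(110)
  fam2 <- random_dna(110)
  # 50 copies of one sequence -> one contig equal to it
  contigs <- denovo_rescue(rep(fam1, 50))
  expect_equal(nrow(contigs), 1L)
  expect_equal(contigs$contig, fam1)
  expect_equal(contigs$support, 50L)
  expect_true(contigs$low_confidence) # far below the 10k coverage bar
  # two disjoint families -> two contigs
  contigs <- denovo_rescue(c(rep(fam1, 25), rep(fam2, 25)))
  expect_equal(nrow(contigs), 2L)
  expect_setequal(contigs$contig, c(fam1, fam2))
  # 50/50 split at one site -> N
  alt <- fam1
  substr(alt, 55, 55) <- setdiff(c("A", "C", "G", "T"),
                                 substr(fam1, 55, 55))[1]
  contigs <- denovo_rescue(c(rep(fam1, 10), rep(alt, 10)))
  expect_equal(nrow(contigs), 1L)
  expect_equal(substr(contigs$contig, 55, 55), "N")
  # short reads never reach min_contig
  expect_equal(nrow(denovo_rescue(rep(substr(fam1, 1, 60), 20))), 0L)
  expect_error(denovo_rescue(character(0)), "no unmapped reads")
})
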