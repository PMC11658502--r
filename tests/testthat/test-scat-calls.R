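test_that("tally_scat counts reads per taxon and conserves totals", {
  lib <- tiny_library()
  mm <- make_scat_mappings(lib, c(wolf = 90, pika = 10))
  t <- tally_scat(mm)
  expect_equal(t$tallies[["wolf"]], 90L)
  expect_equal(t$tallies[["pika"]], 10L)
  expect_equal(t$unmapped_fraction, 0)
  mm2 <- make_scat_mappings(lib, c(wolf = 50), n_junk = 50)
  t2 <- tally_scat(mm2)
  expect_equal(t2$unmapped_fraction, 0.5)
  expect_equal(sum(t2$tallies) + 50L, t2$n_reads) # conservation
  expect_error(tally_scat(mm[0, ]), "no mappings")
})

test_that("classification cascade covers every tally pattern", {
  lib <- tiny_library()
  classify <- function(tallies, unmapped = 0) {
    classify_scat(tallies, unmapped, lib, min_host_reads = 50L)
  }
  # one clear host
  r <- classify(c(wolf = 500, pika = 40))
  expect_equal(r$status, "assigned")
  expect_equal(r$host_taxon, "wolf")
  # intraguild: two hosts, no prey reads, unmapped < 5%, consumer = larger
  r <- classify(c(wolf = 600, fox = 350), unmapped = 0.03)
  expect_equal(r$status, "assigned")
  expect_equal(r$intraguild$consumer, "wolf")
  expect_equal(r$intraguild$consumed, "fox")
  expect_equal(r$prey_occurrences, "fox")
  # two hosts with prey reads present -> inconclusive
  r <- classify(c(wolf = 600, fox = 350, pika = 30))
  expect_equal(r$status, "inconclusive")
  # two hosts, clean, but too much unmapped -> inconclusive
  r <- classify(c(wolf = 600, fox = 350), unmapped = 0.10)
  expect_equal(r$status, "inconclusive")
  # tied two-host pattern cannot name a consumer
  r <- classify(c(wolf = 300, fox = 300), unmapped = 0.01)
  expect_equal(r$status, "inconclusive")
  # three host species -> inconclusive
  r <- classify(c(wolf = 300, fox = 300, leopard = 200))
  expect_equal(r$status, "inconclusive")
  # too few host reads -> undetermined
  r <- classify(c(wolf = 4))
  expect_equal(r$status, "undetermined")
  # dominant non-host animal -> non-target scat
  r <- classify(c(vole = 800, wolf = 10))
  expect_equal(r$status, "non_target")
  # empty tallies -> undetermined
  r <- classify(setNames(integer(0), character(0)))
  expect_equal(r$status, "undetermined")

  # property: the cascade is total over random tally patterns
  set.seed(77)
  taxa <- lib$records$taxon_id
  for (i in 1:100) {
    k <- sample(0:4, 1)
    tal <- setNames(sample(0:900, k, replace = TRUE), sample(taxa, k))
    out <- classify(tal, runif(1, 0, 0.2))
    expect_true(out$status %in% c("assigned", "undetermined", "inconclusive",
                                  "non_target"))
  }
})

test_that("a stray nonspecific host read does not break a one-host scat", {
  lib <- tiny_library()
  r <- classify_scat(c(wolf = 500, pika = 60, fox = 1), 0.01, lib,
                     min_host_reads = 50L, min_host_frac = 0.02)
  expect_equal(r$status, "assigned")
  expect_equal(r$host_taxon, "wolf")
})

test_that("call_prey applies the >98% consensus rule and tie-breaks", {
  lib <- tiny_library()
  mm <- make_scat_mappings(lib, c(wolf = 200, pika = 40))
  call <- classify_scat(tally_scat(mm)$tallies, 0, lib)
  call <- call_prey(call, mm, lib)
  expect_equal(call$prey_occurrences, "pika")

  # candidate below the identity bar is excluded (and rescue finds nothing
  # better: its reads re-map to the same weak reference)
  far <- mutate_seq(lib$sequences[["pika"]], 3) # identity 0.97 to pika ref
  mm_bad <- make_scat_mappings(lib, c(wolf = 200))
  bad_rows <- make_scat_mappings(lib, c(pika = 40))
  bad_rows$ref_aligned <- far
  bad_rows$sequence <- far
  bad_rows$identity <- 0.97
  bad_rows$mismatches <- 3L
  mm_bad <- rbind(mm_bad, bad_rows)
  call <- classify_scat(tally_scat(mm_bad)$tallies, 0, lib)
  call <- call_prey(call, mm_bad, lib)
  expect_false("pika" %in% call$prey_occurrences)
  expect_true("Undetermined" %in% call$prey_occurrences)

  # conflicting references for the same reads: higher read count wins,
  # ties broken by fewer mismatches
  mm_conf <- make_scat_mappings(lib, c(wolf = 200, pika = 40, vole = 40))
  mm_conf$tied_taxa[mm_conf$taxon_id %in% c("pika", "vole")] <- "pika;vole"
  mm_conf$mismatches[mm_conf$taxon_id == "pika"] <- 1L
  mm_conf$mismatches[mm_conf$taxon_id == "vole"] <- 3L
  call <- classify_scat(tally_scat(mm_conf)$tallies, 0, lib)
  call <- call_prey(call, mm_conf, lib)
  expect_equal(call$prey_occurrences, "pika")
  # unequal read counts: the larger set wins regardless of mismatches
  mm_conf2 <- make_scat_mappings(lib, c(wolf = 200, pika = 30, vole = 50))
  mm_conf2$tied_taxa[mm_conf2$taxon_id %in% c("pika", "vole")] <- "pika;vole"
  call <- classify_scat(tally_scat(mm_conf2)$tallies, 0, lib)
  call <- call_prey(call, mm_conf2, lib)
  expect_equal(call$prey_occurrences, "vole")
})

test_that("aggregate_calls builds seasonal diet matrices that conserve", {
  mk_call <- function(host, prey, season, scat_id) {
    structure(list(status = "assigned", host_taxon = host,
                   prey_occurrences = prey, intraguild = NULL,
                   tallies = c(setNames(100L, host)), unmapped_fraction = 0,
                   scat_id = scat_id, season = season),
              class = "scat_call")
  }
  # the published beech-marten pattern: 8 occurrences across 6 scats
  calls <- list(
    mk_call("marten", c("pika", "weasel"), "September", "m1"),
    mk_call("marten", c("pika", "bunting"), "September", "m2"),
    mk_call("marten", "pika", "September", "m3"),
    mk_call("marten", c("pika", "snowcock"), "September", "m4"),
    mk_call("marten", "pika", "September", "m5"),
    mk_call("marten", character(0), "September", "m6"),
    mk_call("wolf", "pika", "March", "w1"))
  dm <- aggregate_calls(calls)
  expect_equal(sum(dm$counts[, "marten", "Overall"]), 8L)
  expect_equal(dm$counts["pika", "marten", "Overall"], 5L)
  expect_equal(dm$counts["weasel", "marten", "Overall"], 1L)
  expect_equal(dm$scat_totals["marten", "Overall"], 6L)
  # season slices sum to overall
  expect_equal(apply(dm$counts[, , c("March", "July", "September",
                                     "December")], c(1, 2), sum),
               dm$counts[, , "Overall"])
  # empty input -> empty matrix
  dm0 <- aggregate_calls(list())
  expect_equal(dim(dm0$counts)[1:2], c(0L, 0L))
  # intraguild consumed taxa count as consumer prey occurrences
  ig <- mk_call("wolf", "fox", "March", "w2")
  ig$intraguild <- list(consumer = "wolf", consumed = "fox")
  dm2 <- aggregate_calls(c(calls, list(ig)))
  expect_equal(dm2$counts["fox", "wolf", "Overall"], 1L)
})
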