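#' Host composition of the scat collection
#'
#' The share of scats belonging to each host predator: `s / S * 100`,
#' with `s` the scats of one host and `S` all assigned scats.
#'
#' @param scat_totals named vector of per-predator scat counts, or a
#'   `diet_matrix` (its `Overall` scat totals are used).
#' @return named percentage vector summing to 100.
#' @export
host_composition <- function(scat_totals) {
  if (inherits(scat_totals, "diet_matrix")) {
    scat_totals <- scat_totals$scat_totals[, "Overall"]
  }
  S <- sum(scat_totals)
  if (S <= 0) stop("no assigned scats")
  scat_totals / S * 100
}

# extract one predator/season prey-count row from a diet_matrix
diet_row <- function(matrix, predator, season = "Overall") {
  stopifnot(inherits(matrix, "diet_matrix"))
  if (!predator %in% dimnames(matrix$counts)$predator) {
    stop("unknown predator: ", predator)
  }
  sub <- matrix$counts[, predator, season, drop = FALSE]
  setNames(as.vector(sub), dimnames(sub)[[1]])
}

#' Frequency of occurrence (FOO)
#'
#' Each prey item's occurrence count `r` divided by the predator's total
#' prey occurrences `R`, as a percentage (`r / R * 100`). The denominator
#' is total prey occurrences — including `"Undetermined"` occurrences —
#' not the scat count.
#'
#' @param matrix a `diet_matrix`.
#' @param predator predator taxon id (column).
#' @param season season slice, default `"Overall"`.
#' @return named percentage vector over prey items, summing to 100.
#' @export
compute_foo <- function(matrix, predator, season = "Overall") {
  row <- diet_row(matrix, predator, season)
  R <- sum(row)
  if (R == 0) {
    stop("no prey occurrences for ", predator, " in ", season)
  }
  row / R * 100
}

#' Feeding-trial biomass model
#'
#' Linear regression from wolf feeding trials relating mean prey mass `X`
#' (kg) to the prey mass represented by one collectable scat,
#' `Y = 0.439 + 0.008 * X` (kg per scat).
#'
#' Two contribution modes are provided. `per_scat_mass` multiplies `Y` by
#' the occurrence count (the stated procedure); `mass_weighted`
#' additionally weights by prey mass (`Y * X * n`), which lets large prey
#' dominate the percentage as biomass intuitively should.
#'
#' @param intercept,slope regression coefficients (defaults 0.439, 0.008).
#' @param mode `"per_scat_mass"` or `"mass_weighted"`.
#' @return A `biomass_model` list.
#' @export
biomass_model <- function(intercept = 0.439, slope = 0.008,
                          mode = c("per_scat_mass", "mass_weighted")) {
  structure(list(intercept = intercept, slope = slope,
                 mode = match.arg(mode)),
            class = "biomass_model")
}

#' Biomass contribution percentages
#'
#' Applies the [biomass_model()] to one predator/season row of a diet
#' matrix. `"Undetermined"` occurrences carry no mass and are excluded;
#' any other prey with occurrences but no `mean_mass_kg` is an error.
#'
#' @param matrix a `diet_matrix`.
#' @param predator,season row selector as in [compute_foo()].
#' @param masses named vector of mean adult masses (kg) per prey item, or
#'   a `reference_library` (masses pulled from its records by tier1 label
#'   falling back to taxon id).
#' @param model a [biomass_model()].
#' @return named percentage vector over prey items with mass, summing
#'   to 100.
#' @export
compute_biomass <- function(matrix, predator, season = "Overall",
                            masses, model = biomass_model()) {
  row <- diet_row(matrix, predator, season)
  row <- row[names(row) != "Undetermined"]
  row <- row[row > 0]
  if (length(row) == 0L) stop("no identified prey occurrences for ", predator)
  if (inherits(masses, "reference_library")) {
    rec <- masses$records
    m <- setNames(rec$mean_mass_kg, rec$taxon_id)
    m2 <- setNames(rec$mean_mass_kg, rec$tier1)
    masses <- ifelse(names(row) %in% names(m), m[names(row)], m2[names(row)])
    names(masses) <- names(row)
  } else {
    masses <- masses[names(row)]
  }
  if (anyNA(masses)) {
    stop("missing mean mass for prey item(s): ",
         paste(names(row)[is.na(masses)], collapse = ", "))
  }
  y <- model$intercept + model$slope * masses
  contrib <- switch(model$mode,
                    per_scat_mass = y * row,
                    mass_weighted = y * masses * row)
  contrib / sum(contrib) * 100
}

#' Dietary diversity indices
#'
#' Richness (number of prey items), Shannon-Wiener `H' = -sum p ln p`
#' (higher = more diverse) and Simpson `D = sum p^2` (lower = more
#' diverse). `"Undetermined"` occurrences are excluded by default.
#'
#' @param row named prey-count vector, or a `diet_matrix` with `predator`
#'   (and optionally `season`) given.
#' @param predator,season selectors when `row` is a `diet_matrix`.
#' @param drop_undetermined exclude the `"Undetermined"` category
#'   (default TRUE).
#' @return list with `richness`, `shannon`, `simpson`.
#' @export
diet_diversity <- function(row, predator = NULL, season = "Overall",
                           drop_undetermined = TRUE) {
  if (inherits(row, "diet_matrix")) row <- diet_row(row, predator, season)
  if (drop_undetermined) row <- row[names(row) != "Undetermined"]
  row <- row[row > 0]
  if (length(row) == 0L) stop("empty diet row")
  list(richness = length(row),
       shannon = unname(vegan::diversity(row, index = "shannon")),
       simpson = unname(1 - vegan::diversity(row, index = "simpson")))
}

#' Mean prey species per scat
#'
#' @param prey_counts integer vector of per-scat prey species counts for
#'   one predator (identified prey; an empty scat contributes 0), or a
#'   list of assigned `scat_call`s.
#' @param drop_undetermined exclude `"Undetermined"` occurrences from the
#'   per-scat counts (default TRUE).
#' @return list with `mean` and `sd` (sample standard deviation, n-1).
#' @export
mean_prey_per_scat <- function(prey_counts, drop_undetermined = TRUE) {
  if (is.list(prey_counts) && !is.data.frame(prey_counts)) {
    prey_counts <- vapply(prey_counts, function(x) {
      p <- x$prey_occurrences
      if (drop_undetermined) p <- setdiff(p, "Undetermined")
      length(p)
    }, integer(1))
  }
  if (length(prey_counts) == 0L) stop("no assigned scats")
  list(mean = mean(prey_counts),
       sd = if (length(prey_counts) > 1L) sd(prey_counts) else 0)
}

#' Incidence-based sample coverage and rarefaction
#'
#' Sample completeness from per-scat prey incidence: with `n` sampling
#' units and `f1`, `f2` the numbers of prey taxa seen in exactly one and
#' two units,
#' `C_hat = 1 - (f1/U) * ((n-1) f1 / ((n-1) f1 + 2 f2))`
#' where `U` is the total incidence count. Rarefied richness for `m <= n`
#' units is the hypergeometric expectation
#' `E[S(m)] = sum_i (1 - choose(n - Q_i, m) / choose(n, m))` with `Q_i`
#' the incidence frequency of taxon `i`.
#'
#' @param incidence binary matrix (sampling units x taxa) or a vector of
#'   per-taxon incidence frequencies with `n_units` supplied.
#' @param n_units number of sampling units when `incidence` is a
#'   frequency vector.
#' @return list with `observed_richness`, `coverage`, and `rarefaction`
#'   (data.frame `m`, `expected_richness` for `m = 1..n`).
#' @export
sample_coverage <- function(incidence, n_units = NULL) {
  if (is.matrix(incidence)) {
    n <- nrow(incidence)
    Q <- colSums(incidence > 0)
  } else {
    if (is.null(n_units)) stop("n_units required for a frequency vector")
    n <- n_units
    Q <- incidence
  }
  Q <- Q[Q > 0]
  if (n < 1L) stop("need at least one sampling unit")
  U <- sum(Q)
  f1 <- sum(Q == 1)
  f2 <- sum(Q == 2)
  coverage <- if (f1 == 0) {
    1
  } else if (n > 1 || f2 > 0) {
    1 - (f1 / U) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  } else {
    1 - f1 / U # n = 1, all singletons -> 0
  }
  rare <- data.frame(
    m = seq_len(n),
    expected_richness = vapply(seq_len(n), function(m) {
      sum(1 - exp(lchoose(n - Q, m) - lchoose(n, m)))
    }, numeric(1)))
  list(observed_richness = length(Q), coverage = coverage,
       rarefaction = rare)
}

#' Group a diet matrix by taxonomic tier
#'
#' Prey rows are collapsed to their secondary ("group", e.g. perching
#' birds) or tertiary ("category", e.g. birds) tier; counts are summed
#' within groups, so row totals are conserved and FOO commutes with
#' grouping.
#'
#' @param matrix a `diet_matrix` carrying a `tiers` table.
#' @param level `"tier1"` (identity), `"tier2"` or `"tier3"`.
#' @return a grouped `diet_matrix`.
#' @export
group_tiers <- function(matrix, level = c("tier1", "tier2", "tier3")) {
  level <- match.arg(level)
  if (level == "tier1") return(matrix)
  if (is.null(matrix$tiers)) stop("diet matrix carries no tier table")
  labels <- matrix$tiers[dimnames(matrix$counts)$prey, level]
  if (anyNA(labels)) stop("tier map is not total over prey items")
  groups <- unique(labels)
  counts <- array(0L, dim = c(length(groups), dim(matrix$counts)[2:3]),
                  dimnames = c(list(prey = groups),
                               dimnames(matrix$counts)[2:3]))
  for (g in groups) {
    sel <- matrix$counts[labels == g, , , drop = FALSE]
    counts[g, , ] <- apply(sel, c(2, 3), sum)
  }
  tiers <- unique(matrix$tiers[c(level, "tier3")])
  tiers_df <- data.frame(tier1 = groups, tier2 = groups, tier3 = groups,
                         row.names = groups, stringsAsFactors = FALSE)
  diet_matrix(counts, matrix$scat_totals, tiers_df)
}
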