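#' Published guild FOO table (example data)
#'
#' The per-predator, per-season frequency-of-occurrence table of a
#' four-season scat survey of a Qinghai-Tibetan Plateau predator guild
#' (Tibetan wolf TW, snow leopard SL, Eurasian lynx EL, Tibetan fox TF,
#' red fox RF, Pallas's cat PC), shipped as a worked example for the
#' presence/absence similarity functions. Columns are
#' `<predator>.<season>` with seasons `O` (overall), `M`, `J`, `S`, `D`
#' (March, July, September, December); rows are prey items plus an
#' `Undetermined` category.
#'
#' @return data.frame of FOO percentages with prey rownames.
#' @export
guild_foo_table <- function() {
  path <- system.file("extdata", "table1_foo.tsv", package = "scatdiet")
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- tab$prey
  tab$prey <- NULL
  tab
}

#' Presence sets from a FOO table column
#'
#' A prey item is present when its FOO is positive; the `Undetermined`
#' category is excluded (it names no taxon).
#'
#' @param foo_table data.frame as from [guild_foo_table()].
#' @param column column name, e.g. `"TW.O"`.
#' @return character vector of present prey items.
#' @export
foo_presence_set <- function(foo_table, column) {
  stopifnot(column %in% colnames(foo_table))
  items <- rownames(foo_table)[foo_table[[column]] > 0]
  setdiff(items, "Undetermined")
}
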