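# Direct-synthesis fragment accounting: contiguous synthesis spans under
# firewall placements, distinct-fragment counts, and placement comparison.
#
# A span is a maximal run of consecutive bins whose consensus strategy is
# DIRECT_SYNTHESIS, split wherever a firewall sits on a junction inside the
# run. Every bin combination across a span must be synthesized as its own
# fragment, so a span contributes the product of its bin sizes; splitting a
# span turns that product into a sum of smaller products.

#' Direct-synthesis spans of a design
#'
#' Computes the maximal runs of consecutive bins with consensus strategy
#' `DIRECT_SYNTHESIS`, split at every bin whose `firewall_after` flag is set
#' inside a run. Fragment identity is by variant combination (which part was
#' picked per bin), not by sequence string equality, so duplicated sequences
#' across variants still count separately. A firewall on a bin outside any
#' direct-synthesis run is recorded on the design but contributes nothing
#' (a warning is issued).
#'
#' @param design A `dna_design`.
#' @return A `data.frame` with one row per span: `first_bin`, `last_bin`,
#'   `n_bins`, `fragment_count` (product of bin sizes over the span).
#' @export
synthesis_spans <- function(design) {
  stopifnot(inherits(design, "dna_design"))
  nb <- length(design$bins)
  empty <- data.frame(first_bin = integer(), last_bin = integer(),
                      n_bins = integer(), fragment_count = numeric(),
                      stringsAsFactors = FALSE)
  if (!nb) return(empty)
  ds <- vapply(seq_len(nb), function(b)
    bin_consensus_strategy(design, b) == "DIRECT_SYNTHESIS", logical(1L))
  fw <- vapply(design$bins, function(b) isTRUE(b$firewall_after), logical(1L))
  idle <- which(fw & !ds)
  if (length(idle))
    dd_warn("dd_idle_firewall_warning",
            "firewall(s) after bin(s) %s sit outside any direct-synthesis run and have no effect",
            paste(idle, collapse = ", "))
  sizes <- bin_sizes(design)
  spans <- list()
  b <- 1L
  while (b <= nb) {
    if (!ds[b]) { b <- b + 1L; next }
    first <- b
    # extend while next bin is DS and no firewall blocks the junction
    while (b < nb && ds[b + 1L] && !fw[b]) b <- b + 1L
    spans[[length(spans) + 1L]] <- data.frame(
      first_bin = first, last_bin = b, n_bins = b - first + 1L,
      fragment_count = prod(as.numeric(sizes[first:b])),
      stringsAsFactors = FALSE)
    b <- b + 1L
  }
  if (!length(spans)) return(empty)
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}

#' Total distinct direct-synthesis fragments
#'
#' Sums each span's fragment count (the product of its bin sizes). This is
#' the number of distinct DNA fragments that would have to be purchased to
#' realize every combination by direct synthesis.
#'
#' @param design A `dna_design`.
#' @return A list with `total` (numeric) and `spans` (the
#'   [synthesis_spans()] table).
#' @export
count_fragments <- function(design) {
  spans <- synthesis_spans(design)
  list(total = sum(spans$fragment_count), spans = spans)
}

#' Compare firewall placements by synthesis-fragment cost
#'
#' Evaluates each candidate placement (a logical `firewall_after` vector, one
#' entry per bin) on the same design and tabulates the resulting fragment
#' totals, flagging the minimum — the quantitative version of "is this
#' firewall where it should be?".
#'
#' @param design A `dna_design`.
#' @param placements A list of logical vectors, each of length equal to the
#'   bin count. Names, when present, label the rows.
#' @return A `data.frame` with `placement`, `firewalls` (compact `0/1`
#'   string), `total`, `is_minimum`.
#' @export
compare_firewall_placements <- function(design, placements) {
  stopifnot(inherits(design, "dna_design"), is.list(placements))
  nb <- length(design$bins)
  labels <- names(placements) %||% rep("", length(placements))
  labels[!nzchar(labels)] <-
    sprintf("placement_%d", which(!nzchar(labels)))
  totals <- numeric(length(placements))
  for (i in seq_along(placements)) {
    v <- placements[[i]]
    if (!is.logical(v) || length(v) != nb)
      dd_stop("dd_structure_error",
              "placement %d must be a logical vector of length %d (the bin count)",
              i, nb)
    d2 <- design
    for (b in seq_len(nb)) d2$bins[[b]]$firewall_after <- v[b]
    totals[i] <- suppressWarnings(count_fragments(d2)$total)
  }
  data.frame(placement = labels,
             firewalls = vapply(placements, function(v)
               paste(as.integer(v), collapse = ""), character(1L)),
             total = totals,
             is_minimum = totals == min(totals),
             stringsAsFactors = FALSE)
}

#' Export a firewall-placement cost table as CSV
#'
#' Writes one row per placement with its span ranges, per-span fragment
#' counts, and total.
#'
#' @param design A `dna_design`.
#' @param placements As for [compare_firewall_placements()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_cost_csv <- function(design, placements, path) {
  tab <- compare_firewall_placements(design, placements)
  nb <- length(design$bins)
  tab$spans <- vapply(placements, function(v) {
    d2 <- design
    for (b in seq_len(nb)) d2$bins[[b]]$firewall_after <- v[b]
    sp <- suppressWarnings(synthesis_spans(d2))
    paste(sprintf("%d-%d:%g", sp$first_bin, sp$last_bin, sp$fragment_count),
          collapse = ";")
  }, character(1L))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
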