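# Combinatorial enumeration (Cartesian product over bins, leftmost bin
# slowest), rule filtering with an elimination report, and scar-less
# in-silico assembly of constructs into annotated sequences.

bin_sizes <- function(design) {
  vapply(design$bins, function(b) length(b$part_ids), integer(1L))
}

check_enumerable <- function(design) {
  if (!length(design$bins))
    dd_stop("dd_structure_error", "design has no bins")
  sz <- bin_sizes(design)
  if (any(sz == 0L))
    dd_stop("dd_structure_error", "bin %d is empty", which(sz == 0L)[1L])
  sz
}

#' Number of Cartesian combinations of a design
#'
#' The product of bin sizes, computed without materializing any construct,
#' so library-scale designs (tens of thousands of combinations and beyond)
#' count instantly.
#'
#' @param design A `dna_design`.
#' @return A numeric count.
#' @export
n_constructs <- function(design) {
  prod(as.numeric(check_enumerable(design)))
}

# Bin slot indices of the construct with the given lexicographic rank
# (1-based; leftmost bin varies slowest).
construct_slots <- function(sizes, rank) {
  k <- length(sizes)
  idx <- integer(k)
  r <- rank - 1
  for (j in k:1) {
    idx[j] <- as.integer(r %% sizes[j]) + 1L
    r <- r %/% sizes[j]
  }
  idx
}

make_construct <- function(design, slots, rank) {
  ids <- vapply(seq_along(slots), function(b)
    design$bins[[b]]$part_ids[slots[b]], character(1L))
  structure(list(part_ids = ids,
                 part_names = vapply(design$parts[ids], function(p) p$name,
                                     character(1L)),
                 index = rank),
            class = "dna_construct")
}

#' @export
print.dna_construct <- function(x, ...) {
  cat(sprintf("<construct #%d> %s\n", x$index,
              paste(x$part_names, collapse = " - ")))
  invisible(x)
}

#' Enumerate all constructs of a design
#'
#' Yields every Cartesian combination (one part per bin) in deterministic
#' lexicographic order with the leftmost bin varying slowest — the order that
#' fixes construct numbering. Materialization is guarded: use
#' [n_constructs()] to count large designs lazily, or [construct_iterator()]
#' to stream them.
#'
#' @param design A `dna_design`.
#' @param limit Refuse to materialize more than this many constructs.
#' @return A list of `dna_construct` objects.
#' @export
enumerate_constructs <- function(design, limit = 1e5) {
  sizes <- check_enumerable(design)
  N <- prod(as.numeric(sizes))
  if (N > limit)
    dd_stop("dd_structure_error",
            "%s constructs exceed the materialization limit (%s); use n_constructs() or construct_iterator()",
            format(N, big.mark = ","), format(limit, big.mark = ","))
  lapply(seq_len(N), function(r)
    make_construct(design, construct_slots(sizes, r), r))
}

#' Streaming construct iterator
#'
#' Returns a closure yielding one construct per call in enumeration order and
#' `NULL` when exhausted, so arbitrarily large designs can be walked without
#' materializing the product.
#'
#' @param design A `dna_design`.
#' @return A function `function() -> dna_construct | NULL`.
#' @export
construct_iterator <- function(design) {
  sizes <- check_enumerable(design)
  N <- prod(as.numeric(sizes))
  r <- 0
  function() {
    if (r >= N) return(NULL)
    r <<- r + 1
    make_construct(design, construct_slots(sizes, r), r)
  }
}

#' Filter the enumeration by the design's rules
#'
#' A construct is kept iff every rule evaluates `TRUE` on its part-name
#' multiset. The report's `per_rule_eliminations` counts, for each rule, the
#' combinations violating that rule irrespective of the other rules, so the
#' per-rule sums may exceed the total eliminated when violations overlap.
#'
#' @param design A `dna_design`.
#' @param keep_constructs Materialize the kept constructs (set `FALSE` to
#'   only count on large designs).
#' @param chunk_size Constructs evaluated per batch.
#' @return A list with `report` (fields `total`, `kept`, `eliminated`,
#'   `per_rule_eliminations`) and `constructs` (kept constructs, or `NULL`).
#' @export
filter_by_rules <- function(design, keep_constructs = TRUE,
                            chunk_size = 10000L) {
  sizes <- check_enumerable(design)
  bad_ops <- unlist(lapply(design$rules, function(r)
    setdiff(c(r$operand1, if (is.character(r$operand2)) r$operand2),
            part_names(design))))
  if (length(bad_ops))
    dd_stop("dd_operand_error",
            "rule operand(s) not on the canvas: %s",
            paste(unique(bad_ops), collapse = ", "))
  N <- prod(as.numeric(sizes))
  rules <- unname(design$rules)
  per_rule <- stats::setNames(numeric(length(rules)),
                              vapply(rules, function(r) r$name, character(1L)))
  kept <- 0
  kept_list <- list()
  r0 <- 0
  while (r0 < N) {
    ranks <- seq(r0 + 1, min(r0 + chunk_size, N))
    slots <- t(vapply(ranks, function(r) construct_slots(sizes, r),
                      integer(length(sizes))))
    # part-name matrix, one row per construct in the chunk
    mat <- vapply(seq_along(sizes), function(b) {
      ids <- design$bins[[b]]$part_ids[slots[, b]]
      vapply(design$parts[ids], function(p) p$name, character(1L))
    }, character(length(ranks)))
    if (length(ranks) == 1L) mat <- matrix(mat, nrow = 1L)
    ok <- rep(TRUE, length(ranks))
    for (j in seq_along(rules)) {
      rj <- rules[[j]]
      n1 <- rowSums(mat == rj$operand1)
      sat <- switch(rj$operator,
        WITH = n1 == 0L | rowSums(mat == rj$operand2) >= 1L,
        NOTWITH = !(n1 >= 1L & rowSums(mat == rj$operand2) >= 1L),
        NOTMORETHAN = n1 <= rj$operand2)
      per_rule[j] <- per_rule[j] + sum(!sat)
      ok <- ok & sat
    }
    kept <- kept + sum(ok)
    if (keep_constructs && any(ok)) {
      kept_list <- c(kept_list, lapply(ranks[ok], function(r)
        make_construct(design, construct_slots(sizes, r), r)))
    }
    r0 <- r0 + length(ranks)
  }
  list(report = list(total = N, kept = kept, eliminated = N - kept,
                     per_rule_eliminations = as.list(per_rule)),
       constructs = if (keep_constructs) kept_list else NULL)
}

glyph_to_feature_key <- function(glyph) {
  switch(glyph,
         promoter = "promoter", rbs = "RBS", cds = "CDS",
         terminator = "terminator", origin_of_replication = "rep_origin",
         signal_peptide = "sig_peptide", "misc_feature")
}

#' Assemble one construct scar-lessly
#'
#' Concatenates each selected part's extracted (and, where flagged,
#' reverse-complemented) sequence in bin order with no intervening bases.
#' Source features fully contained in a part are propagated at their offset
#' (features truncated at a part boundary are not carried into the
#' assembly), and one spanning feature per part (labelled with the part
#' name) is added so fusion joints remain inspectable. Topology follows the
#' design flag; circular assemblies close the final junction without added
#' bases.
#'
#' @param design A `dna_design`.
#' @param construct A `dna_construct` from [enumerate_constructs()] /
#'   [filter_by_rules()].
#' @param name Name for the assembled sequence.
#' @return An [annotated_sequence()].
#' @export
assemble_construct <- function(design, construct,
                               name = sprintf("construct_%d", construct$index)) {
  stopifnot(inherits(design, "dna_design"), inherits(construct, "dna_construct"))
  residues <- character(length(construct$part_ids))
  feats <- list()
  offset <- 0L
  for (i in seq_along(construct$part_ids)) {
    p <- design$parts[[construct$part_ids[i]]]
    ext <- tryCatch(
      extract_region(design$sources[[p$source_name]], p$start, p$stop,
                     p$reverse),
      error = function(e) dd_stop("dd_range_error",
        "part '%s': %s", p$name, conditionMessage(e)))
    residues[i] <- ext$residues
    ft <- ext$features
    if (nrow(ft)) {
      ft <- ft[!grepl(" \\(truncated\\)$", ft$label), , drop = FALSE]
      ft$start <- ft$start + offset
      ft$end <- ft$end + offset
      feats[[length(feats) + 1L]] <- ft
    }
    feats[[length(feats) + 1L]] <- data.frame(
      label = p$name, type = glyph_to_feature_key(p$glyph),
      start = offset + 1L, end = offset + seq_length(ext),
      strand = if (p$reverse) "-" else "+", stringsAsFactors = FALSE)
    offset <- offset + seq_length(ext)
  }
  ftab <- do.call(rbind, feats)
  annotated_sequence(name, paste(residues, collapse = ""),
                     circular = design$topology == "circular",
                     features = feature_table(ftab$label, ftab$type,
                                              ftab$start, ftab$end,
                                              ftab$strand))
}

#' Sequential names for kept constructs
#'
#' Zero-padded sequential names in enumeration order: the index is padded to
#' the width of the final index, so names sort in enumeration order.
#'
#' @param x A list of constructs, or an integer count.
#' @param prefix Name prefix (e.g. `"pRDR0000"`).
#' @return Character vector of names, in order.
#' @export
name_constructs <- function(x, prefix) {
  n <- if (is.numeric(x)) as.integer(x) else length(x)
  if (n < 1L) return(character())
  paste0(prefix, formatC(seq_len(n), width = nchar(as.character(n)),
                         flag = "0"))
}

#' Export an enumeration report as CSV
#'
#' One row per Cartesian combination: the construct name (kept constructs
#' are named sequentially; eliminated ones are blank), the selected part per
#' bin, the kept flag, and the names of the rules the combination violates.
#'
#' @param design A `dna_design`.
#' @param path Output CSV path.
#' @param prefix Name prefix for kept constructs.
#' @return The path, invisibly.
#' @export
export_enumeration_csv <- function(design, path, prefix = "construct_") {
  sizes <- check_enumerable(design)
  all <- enumerate_constructs(design)
  rules <- unname(design$rules)
  viol <- vapply(all, function(co) {
    bad <- vapply(rules, function(r) !evaluate_rule(r, co$part_names),
                  logical(1L))
    paste(vapply(rules[bad], function(r) r$name, character(1L)), collapse = ";")
  }, character(1L))
  kept <- !nzchar(viol)
  nm <- character(length(all))
  nm[kept] <- name_constructs(sum(kept), prefix)
  tab <- data.frame(construct = nm, stringsAsFactors = FALSE)
  for (b in seq_along(sizes)) {
    tab[[sprintf("bin%d_%s", b, design$bins[[b]]$label)]] <-
      vapply(all, function(co) co$part_names[b], character(1L))
  }
  tab$kept <- ifelse(kept, "TRUE", "FALSE")
  tab$violated_rules <- viol
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
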