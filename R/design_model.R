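# The design model: parts cut from registered sources, ordered combinatorial
# bins, per-bin assembly metadata (firewalls, forced overhangs), linked
# repeated parts, and correct-by-construction validation diagnostics.

#' @name vocabularies
#' @title Controlled vocabularies
#' @description
#' `STRATEGY_VOCAB` lists the forced assembly strategies in their fixed
#' tie-break order (used by [bin_consensus_strategy()]); `"none"` is the
#' absence of a forced strategy and is not part of the order. `GLYPH_VOCAB`
#' lists the SBOLv-style part category tags.
#' @export
STRATEGY_VOCAB <- c("PCR", "DIGEST", "DIRECT_SYNTHESIS",
                    "EMBEDDED_IN_PRIMER_FORWARD", "EMBEDDED_IN_PRIMER_REVERSE")

#' @rdname vocabularies
#' @export
GLYPH_VOCAB <- c("promoter", "rbs", "cds", "terminator",
                 "origin_of_replication", "signal_peptide", "tag", "scar",
                 "user_defined", "generic")

PART_NAME_RE <- "^[A-Za-z0-9_-]+$"

#' Create an empty design
#'
#' A design is the ordered 5'->3' list of bins (left to right), the set of
#' registered source sequences, the part definitions, and the design rules.
#' All design-model functions are functional: they return the updated design.
#'
#' @param topology Output topology of assembled constructs, `"circular"`
#'   (default) or `"linear"`.
#' @return An object of class `dna_design`.
#' @export
new_design <- function(topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  structure(list(topology = topology,
                 sources = list(),
                 parts = list(),       # definitions keyed by definition_id
                 bins = list(),        # each: label, part_ids, firewall_after, forced_overhang
                 rules = list(),       # keyed by rule name, in creation order
                 assembly_method = NA_character_,
                 seed = NA_integer_,   # provenance: generator seed, if any
                 next_def = 1L),
            class = "dna_design")
}

#' @export
print.dna_design <- function(x, ...) {
  sizes <- vapply(x$bins, function(b) length(b$part_ids), integer(1L))
  cat(sprintf("<dna_design> %s, %d bin(s) [%s], %d part definition(s), %d rule(s)\n",
              x$topology, length(x$bins), paste(sizes, collapse = ","),
              length(x$parts), length(x$rules)))
  invisible(x)
}

#' Register a source sequence with a design
#' @param design A [new_design()].
#' @param source An [annotated_sequence()].
#' @return The updated design.
#' @export
add_source <- function(design, source) {
  stopifnot(inherits(design, "dna_design"),
            inherits(source, "annotated_sequence"))
  design$sources[[source$name]] <- source
  design
}

#' Append an empty bin to a design
#' @param design A `dna_design`.
#' @param label Bin label (defaults to `bin<k>`).
#' @return The updated design.
#' @export
add_bin <- function(design, label = NULL) {
  stopifnot(inherits(design, "dna_design"))
  label <- label %||% sprintf("bin%d", length(design$bins) + 1L)
  design$bins[[length(design$bins) + 1L]] <-
    list(label = label, part_ids = character(),
         firewall_after = FALSE, forced_overhang = NA_integer_)
  design
}

part_names <- function(design) {
  vapply(design$parts, function(p) p$name, character(1L))
}

find_def <- function(design, name) {
  ids <- names(design$parts)[part_names(design) == name]
  if (!length(ids)) NULL else ids[[1L]]
}

#' Look up a part definition by name
#' @param design A `dna_design`.
#' @param name Part name.
#' @return The part definition (a list with fields `name`, `source_name`,
#'   `start`, `stop`, `reverse`, `glyph`, `forced_strategy`, `definition_id`).
#' @export
get_part <- function(design, name) {
  id <- find_def(design, name)
  if (is.null(id)) dd_stop("dd_operand_error", "no part named '%s'", name)
  design$parts[[id]]
}

check_part_fields <- function(design, name, source_name, start, stop,
                              forced_strategy, glyph) {
  if (!is_string(name) || !nzchar(name))
    dd_stop("dd_name_error", "part name must be a non-empty string")
  if (!grepl(PART_NAME_RE, name)) {
    bad <- unique(strsplit(gsub("[A-Za-z0-9_-]", "", name), "")[[1L]])
    dd_stop("dd_name_error",
            "part name '%s' contains prohibited character(s): %s",
            name, paste(sQuote(bad), collapse = ", "))
  }
  src <- design$sources[[source_name]]
  if (is.null(src))
    dd_stop("dd_reference_error", "unknown source '%s' for part '%s'",
            source_name, name)
  L <- seq_length(src)
  for (v in list(list(start, "start"), list(stop, "stop"))) {
    if (!is_count(v[[1L]]) || v[[1L]] < 1 || v[[1L]] > L)
      dd_stop("dd_range_error",
              "part '%s': %s = %s outside [1, %d] of source '%s' (%d bp)",
              name, v[[2L]], format(v[[1L]]), L, source_name, L)
  }
  if (start > stop && !src$circular)
    dd_stop("dd_topology_error",
            "part '%s': start (%d) > stop (%d) on linear source '%s'",
            name, start, stop, source_name)
  if (!forced_strategy %in% c("none", STRATEGY_VOCAB))
    dd_stop("dd_value_error", "unknown forced strategy '%s'", forced_strategy)
  if (!glyph %in% GLYPH_VOCAB)
    dd_stop("dd_value_error", "unknown glyph category '%s'", glyph)
  invisible(TRUE)
}

#' Define a new part
#'
#' A part is a named, oriented region of a registered source sequence.
#' Correct-by-construction: out-of-range coordinates, duplicate names and
#' prohibited name characters are rejected at creation time, so an invalid
#' part can never enter a design. A freshly created part is peripheral
#' (unbinned) unless `bin` is given.
#'
#' @param design A `dna_design`.
#' @param name Unique part name, charset `[A-Za-z0-9_-]`.
#' @param source An [annotated_sequence()] (registered on the fly) or the
#'   name of an already-registered source.
#' @param start,stop 1-based inclusive positions in the source;
#'   `start > stop` selects the origin-wrapping region of a circular source.
#' @param reverse Associate the part with the reverse complement.
#' @param glyph Part category tag, one of `GLYPH_VOCAB`.
#' @param forced_strategy Forced assembly strategy, `"none"` or one of
#'   `STRATEGY_VOCAB`.
#' @param bin Optional bin index to place the part into.
#' @return The updated design.
#' @export
create_part <- function(design, name, source, start, stop, reverse = FALSE,
                        glyph = "generic", forced_strategy = "none",
                        bin = NULL) {
  stopifnot(inherits(design, "dna_design"))
  if (inherits(source, "annotated_sequence")) {
    design <- add_source(design, source)
    source_name <- source$name
  } else {
    source_name <- source
  }
  if (name %in% part_names(design))
    dd_stop("dd_uniqueness_error", "a part named '%s' already exists", name)
  check_part_fields(design, name, source_name, start, stop,
                    forced_strategy, glyph)
  id <- sprintf("def%04d", design$next_def)
  design$next_def <- design$next_def + 1L
  design$parts[[id]] <- list(name = name, source_name = source_name,
                             start = as.integer(start), stop = as.integer(stop),
                             reverse = isTRUE(reverse), glyph = glyph,
                             forced_strategy = forced_strategy,
                             definition_id = id)
  if (!is.null(bin)) design <- replicate_part(design, name, bin)
  design
}

check_bin_index <- function(design, bin_index) {
  if (!is_count(bin_index) || bin_index < 1 || bin_index > length(design$bins))
    dd_stop("dd_structure_error", "bin index %s out of range (design has %d bins)",
            format(bin_index), length(design$bins))
  as.integer(bin_index)
}

#' Place an instance of a part into a bin
#'
#' All instances of a part share its single definition: editing the
#' definition through [edit_part_definition()] updates every placed instance
#' in unison (the linked-repeated-parts model).
#'
#' @param design A `dna_design`.
#' @param name Name of an existing part.
#' @param bin_index Target bin (1-based, left to right).
#' @param digest_first_bin Enforce the optional DIGEST-in-first-bin gate.
#' @return The updated design.
#' @export
replicate_part <- function(design, name, bin_index, digest_first_bin = TRUE) {
  stopifnot(inherits(design, "dna_design"))
  id <- find_def(design, name)
  if (is.null(id)) dd_stop("dd_operand_error", "no part named '%s'", name)
  bin_index <- check_bin_index(design, bin_index)
  if (digest_first_bin &&
      design$parts[[id]]$forced_strategy == "DIGEST" && bin_index == 1L)
    dd_stop("dd_digest_first_bin_error",
            "part '%s' forces DIGEST and cannot be placed in the first bin", name)
  design$bins[[bin_index]]$part_ids <-
    c(design$bins[[bin_index]]$part_ids, id)
  design
}

#' Remove one placed instance of a part from a bin
#'
#' Removing an instance never touches the shared definition or any other
#' instance.
#'
#' @param design A `dna_design`.
#' @param name Part name.
#' @param bin_index Bin holding the instance.
#' @return The updated design.
#' @export
remove_part_instance <- function(design, name, bin_index) {
  bin_index <- check_bin_index(design, bin_index)
  id <- find_def(design, name)
  if (is.null(id)) dd_stop("dd_operand_error", "no part named '%s'", name)
  ids <- design$bins[[bin_index]]$part_ids
  hit <- which(ids == id)
  if (!length(hit))
    dd_stop("dd_structure_error", "part '%s' has no instance in bin %d",
            name, bin_index)
  design$bins[[bin_index]]$part_ids <- ids[-hit[1L]]
  design
}

#' Edit a part definition (all instances update in unison)
#'
#' Applies a set of field updates to a part definition atomically: every
#' update is validated against the resulting state first, and on any failure
#' the design is returned unchanged (the error carries the diagnostic).
#' Renaming a part also renames it inside every rule that references it, so
#' rules can never dangle after a rename.
#'
#' @param design A `dna_design`.
#' @param name Current part name.
#' @param updates Named list drawn from `name`, `source_name`, `start`,
#'   `stop`, `reverse`, `glyph`, `forced_strategy`.
#' @param digest_first_bin Enforce the optional DIGEST-in-first-bin gate.
#' @return The updated design.
#' @export
edit_part_definition <- function(design, name, updates,
                                 digest_first_bin = TRUE) {
  stopifnot(inherits(design, "dna_design"), is.list(updates))
  id <- find_def(design, name)
  if (is.null(id)) dd_stop("dd_operand_error", "no part named '%s'", name)
  allowed <- c("name", "source_name", "start", "stop", "reverse", "glyph",
               "forced_strategy")
  bad <- setdiff(names(updates), allowed)
  if (length(bad))
    dd_stop("dd_value_error", "unknown part field(s): %s",
            paste(bad, collapse = ", "))
  p <- design$parts[[id]]
  new <- utils::modifyList(p, updates)
  if (new$name != p$name && new$name %in% part_names(design))
    dd_stop("dd_uniqueness_error", "a part named '%s' already exists", new$name)
  check_part_fields(design, new$name, new$source_name, new$start, new$stop,
                    new$forced_strategy, new$glyph)
  # DIGEST-first-bin gate applies to definitions already placed in bin 1
  if (digest_first_bin &&
      new$forced_strategy == "DIGEST" && length(design$bins) &&
      id %in% design$bins[[1L]]$part_ids)
    dd_stop("dd_digest_first_bin_error",
            "part '%s' is placed in the first bin and cannot force DIGEST",
            new$name)
  new$start <- as.integer(new$start); new$stop <- as.integer(new$stop)
  new$reverse <- isTRUE(new$reverse)
  design$parts[[id]] <- new
  if (new$name != p$name && length(design$rules)) {
    design$rules <- lapply(design$rules, function(r) {
      if (identical(r$operand1, p$name)) r$operand1 <- new$name
      if (identical(r$operand2, p$name)) r$operand2 <- new$name
      r
    })
  }
  design
}

#' Set the direct-synthesis firewall flag on a bin
#'
#' A firewall on bin `i` prevents a synthesized DNA fragment from extending
#' through the assembly junction to the right of that bin, splitting the
#' direct-synthesis span there (see [synthesis_spans()]).
#'
#' @param design A `dna_design`.
#' @param bin_index Bin index.
#' @param value Logical flag.
#' @return The updated design.
#' @export
set_firewall <- function(design, bin_index, value = TRUE) {
  bin_index <- check_bin_index(design, bin_index)
  design$bins[[bin_index]]$firewall_after <- isTRUE(value)
  design
}

#' Set the forced relative overhang/overlap position for a bin's right junction
#'
#' Treated as opaque metadata handed to downstream assembly design.
#'
#' @param design A `dna_design`.
#' @param bin_index Bin index.
#' @param value Integer offset, or `NA` to clear.
#' @return The updated design.
#' @export
set_forced_overhang <- function(design, bin_index, value) {
  bin_index <- check_bin_index(design, bin_index)
  if (!is.na(value) && !is_count(value))
    dd_stop("dd_value_error", "forced overhang must be an integer or NA")
  design$bins[[bin_index]]$forced_overhang <- as.integer(value)
  design
}

#' Declare the intended assembly-method arity
#'
#' `"single"` for one-construct methods, `"combinatorial"` for library
#' methods; [validate_design()] warns (`W_METHOD_ARITY`) when the declared
#' arity disagrees with whether the design is combinatorial.
#'
#' @param design A `dna_design`.
#' @param method `"single"`, `"combinatorial"`, or `NA` to clear.
#' @return The updated design.
#' @export
set_assembly_method <- function(design, method) {
  if (!is.na(method) && !method %in% c("single", "combinatorial"))
    dd_stop("dd_value_error",
            "assembly method must be 'single', 'combinatorial' or NA")
  design$assembly_method <- method
  design
}

#' Is the design combinatorial?
#' @param design A `dna_design`.
#' @return `TRUE` when any bin holds more than one part.
#' @export
is_combinatorial <- function(design) {
  any(vapply(design$bins, function(b) length(b$part_ids) > 1L, logical(1L)))
}

#' Extract the sequence of a part
#' @param design A `dna_design`.
#' @param name Part name.
#' @return The part's [annotated_sequence()] (linear, oriented).
#' @export
part_sequence <- function(design, name) {
  p <- get_part(design, name)
  extract_region(design$sources[[p$source_name]], p$start, p$stop, p$reverse)
}

#' Consensus assembly strategy of a bin
#'
#' The bin strategy is derived, never set directly: it is the most frequent
#' non-`"none"` forced strategy among the bin's member parts, with ties
#' broken by the fixed `STRATEGY_VOCAB` order
#' (PCR < DIGEST < DIRECT_SYNTHESIS < EMBEDDED_IN_PRIMER_FORWARD <
#' EMBEDDED_IN_PRIMER_REVERSE). It is `"none"` when no member forces a
#' strategy.
#'
#' @param design A `dna_design`.
#' @param bin_index Bin index.
#' @return A strategy string.
#' @export
bin_consensus_strategy <- function(design, bin_index) {
  bin_index <- check_bin_index(design, bin_index)
  ids <- design$bins[[bin_index]]$part_ids
  if (!length(ids))
    dd_stop("dd_structure_error", "bin %d is empty", bin_index)
  forced <- vapply(design$parts[ids], function(p) p$forced_strategy,
                   character(1L))
  forced <- forced[forced != "none"]
  if (!length(forced)) return("none")
  tab <- table(factor(forced, levels = STRATEGY_VOCAB))
  STRATEGY_VOCAB[which.max(tab)]   # which.max takes the first = vocab order
}

#' Indicator attributes for placed part instances
#'
#' A textual surrogate for the canvas indicator lights: per placed instance,
#' whether the part has associated rules (`has_rules`), whether it forces the
#' bin's consensus strategy (`forces_consensus`), and whether it breaks it
#' (`breaks_consensus`).
#'
#' @param design A `dna_design`.
#' @return A `data.frame` with one row per placed instance.
#' @export
part_indicators <- function(design) {
  rows <- list()
  ruled <- unique(unlist(lapply(design$rules, function(r)
    c(r$operand1, if (is.character(r$operand2)) r$operand2))))
  for (b in seq_along(design$bins)) {
    ids <- design$bins[[b]]$part_ids
    if (!length(ids)) next
    consensus <- bin_consensus_strategy(design, b)
    for (id in ids) {
      p <- design$parts[[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = p$name, bin = b,
        has_rules = p$name %in% ruled,
        forces_consensus = p$forced_strategy != "none" &&
          p$forced_strategy == consensus,
        breaks_consensus = p$forced_strategy != "none" &&
          p$forced_strategy != consensus,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(name = character(), bin = integer(),
                      has_rules = logical(), forces_consensus = logical(),
                      breaks_consensus = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

diag_row <- function(code, severity, subject, message) {
  data.frame(code = code, severity = severity, subject = subject,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a design
#'
#' Runs the full correct-by-construction diagnostic suite and returns every
#' finding. A design with zero error-severity diagnostics is guaranteed to
#' enumerate and assemble without raising. Diagnostic codes are stable
#' identifiers: `E_EMPTY_DESIGN`, `E_EMPTY_BIN`, `E_BAD_NAME`, `E_DUP_NAME`,
#' `E_RANGE`, `E_RULE_OPERAND_MISSING`, `E_RULE_DUP_NAME`, `E_RULE_COUNT`,
#' `E_DIGEST_FIRST_BIN` (toggleable, on by default), `W_STRATEGY_MISMATCH`,
#' `W_METHOD_ARITY`.
#'
#' @param design A `dna_design`.
#' @param digest_first_bin Enable the DIGEST-in-first-bin check.
#' @return A `data.frame` of diagnostics (`code`, `severity`, `subject`,
#'   `message`); zero rows means a clean design.
#' @export
validate_design <- function(design, digest_first_bin = TRUE) {
  stopifnot(inherits(design, "dna_design"))
  d <- list()
  push <- function(...) d[[length(d) + 1L]] <<- diag_row(...)

  if (!length(design$bins)) {
    push("E_EMPTY_DESIGN", "error", "<design>", "design has no bins")
  }
  nm <- part_names(design)
  dup <- unique(nm[duplicated(nm)])
  for (x in dup)
    push("E_DUP_NAME", "error", x,
         sprintf("part name '%s' used by more than one definition", x))
  for (id in names(design$parts)) {
    p <- design$parts[[id]]
    if (!grepl(PART_NAME_RE, p$name))
      push("E_BAD_NAME", "error", p$name,
           sprintf("part name '%s' contains prohibited characters", p$name))
    src <- design$sources[[p$source_name]]
    if (is.null(src)) {
      push("E_RANGE", "error", p$name,
           sprintf("part '%s' references unknown source '%s'",
                   p$name, p$source_name))
    } else {
      L <- seq_length(src)
      if (p$start < 1L || p$start > L || p$stop < 1L || p$stop > L)
        push("E_RANGE", "error", p$name,
             sprintf("part '%s' coordinates [%d, %d] outside [1, %d] of '%s'",
                     p$name, p$start, p$stop, L, p$source_name))
      else if (p$start > p$stop && !src$circular)
        push("E_RANGE", "error", p$name,
             sprintf("part '%s' wraps the origin of linear source '%s'",
                     p$name, p$source_name))
    }
  }
  for (b in seq_along(design$bins)) {
    ids <- design$bins[[b]]$part_ids
    if (!length(ids)) {
      push("E_EMPTY_BIN", "error", design$bins[[b]]$label,
           sprintf("bin %d ('%s') holds no parts", b, design$bins[[b]]$label))
      next
    }
    consensus <- bin_consensus_strategy(design, b)
    for (id in ids) {
      p <- design$parts[[id]]
      if (p$forced_strategy != "none" && p$forced_strategy != consensus)
        push("W_STRATEGY_MISMATCH", "warning", p$name,
             sprintf("part '%s' forces %s but bin %d consensus is %s",
                     p$name, p$forced_strategy, b, consensus))
      if (digest_first_bin && b == 1L && p$forced_strategy == "DIGEST")
        push("E_DIGEST_FIRST_BIN", "error", p$name,
             sprintf("part '%s' forces DIGEST in the first bin", p$name))
    }
  }
  rn <- vapply(design$rules, function(r) r$name, character(1L))
  for (x in unique(rn[duplicated(rn)]))
    push("E_RULE_DUP_NAME", "error", x,
         sprintf("rule name '%s' is duplicated", x))
  for (r in design$rules) {
    ops <- c(r$operand1, if (is.character(r$operand2)) r$operand2)
    for (o in ops) {
      if (!o %in% nm)
        push("E_RULE_OPERAND_MISSING", "error", r$name,
             sprintf("rule '%s' references unknown part '%s'", r$name, o))
    }
    if (r$operator == "NOTMORETHAN" &&
        (!is_count(r$operand2) || r$operand2 < 1))
      push("E_RULE_COUNT", "error", r$name,
           sprintf("rule '%s': NOTMORETHAN count must be a positive integer",
                   r$name))
  }
  if (!is.na(design$assembly_method)) {
    comb <- is_combinatorial(design)
    if (comb && design$assembly_method == "single")
      push("W_METHOD_ARITY", "warning", "<design>",
           "design is combinatorial but the declared assembly method is single-construct")
    if (!comb && design$assembly_method == "combinatorial")
      push("W_METHOD_ARITY", "warning", "<design>",
           "design is single-construct but the declared assembly method is combinatorial")
  }
  if (!length(d))
    return(data.frame(code = character(), severity = character(),
                      subject = character(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, d)
  rownames(out) <- NULL
  out
}

#' Error-severity subset of a diagnostics table
#' @param diagnostics Output of [validate_design()].
#' @return The rows with `severity == "error"`.
#' @export
design_errors <- function(diagnostics) {
  diagnostics[diagnostics$severity == "error", , drop = FALSE]
}
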