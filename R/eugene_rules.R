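# Design-specification rule subset: NOTMORETHAN / WITH / NOTWITH rules,
# per-construct evaluation, per-part listing, and rules-file import/export.
#
# Supported rules-file dialect (one statement per line):
#   Rule <name>(<operand1> <OPERATOR> <operand2|count>);
# with `//` comment lines; operator keywords are case-insensitive.

RULE_OPERATORS <- c("NOTMORETHAN", "WITH", "NOTWITH")

RULE_LINE_RE <- paste0(
  "^Rule\\s+([A-Za-z0-9_-]+)\\s*\\(\\s*([A-Za-z0-9_-]+)\\s+",
  "([A-Za-z]+)\\s+([A-Za-z0-9_-]+)\\s*\\)\\s*;?\\s*$")

#' Add a design-specification rule
#'
#' Attaches a rule to the design. Operands are constrained to parts presently
#' on the canvas, so a rule can never reference a mistyped or non-existent
#' part name. `WITH` is directional: the presence of `operand1` in a
#' construct requires `operand2` (not vice versa). `NOTWITH` forbids
#' co-occurrence. `NOTMORETHAN` caps the copy number of `operand1` at the
#' integer `operand2`.
#'
#' @param design A `dna_design`.
#' @param name Unique rule name, charset `[A-Za-z0-9_-]`.
#' @param operator One of `"NOTMORETHAN"`, `"WITH"`, `"NOTWITH"`.
#' @param operand1 A part name on the canvas.
#' @param operand2 A part name (`WITH`/`NOTWITH`) or a positive integer copy
#'   count (`NOTMORETHAN`).
#' @return The updated design.
#' @export
add_rule <- function(design, name, operator, operand1, operand2) {
  stopifnot(inherits(design, "dna_design"))
  if (!is_string(name) || !grepl(PART_NAME_RE, name))
    dd_stop("dd_name_error", "invalid rule name '%s'", format(name))
  operator <- toupper(operator)
  if (!operator %in% RULE_OPERATORS)
    dd_stop("dd_value_error", "unsupported operator '%s' (supported: %s)",
            operator, paste(RULE_OPERATORS, collapse = ", "))
  if (name %in% names(design$rules))
    dd_stop("dd_uniqueness_error", "a rule named '%s' already exists", name)
  nm <- part_names(design)
  if (!operand1 %in% nm)
    dd_stop("dd_operand_error",
            "operand 1 '%s' is not a part on the canvas", operand1)
  if (operator == "NOTMORETHAN") {
    if (!is_count(operand2) || operand2 < 1)
      dd_stop("dd_value_error",
              "NOTMORETHAN count must be a positive integer, got %s",
              format(operand2))
    operand2 <- as.integer(operand2)
  } else {
    if (!is_string(operand2) || !operand2 %in% nm)
      dd_stop("dd_operand_error",
              "operand 2 '%s' is not a part on the canvas", format(operand2))
  }
  design$rules[[name]] <- list(name = unname(name), operator = operator,
                               operand1 = unname(operand1),
                               operand2 = unname(operand2))
  design
}

#' Evaluate a rule on one construct
#'
#' A pure predicate on the construct's part-name multiset (one part per bin;
#' repeated parts contribute repeated names).
#'
#' @param rule A rule as stored on a design (list with `operator`,
#'   `operand1`, `operand2`).
#' @param construct_parts Character vector of the construct's part names.
#' @return `TRUE` when the construct satisfies the rule.
#' @export
evaluate_rule <- function(rule, construct_parts) {
  n1 <- sum(construct_parts == rule$operand1)
  switch(rule$operator,
    WITH = n1 == 0L || sum(construct_parts == rule$operand2) >= 1L,
    NOTWITH = !(n1 >= 1L && sum(construct_parts == rule$operand2) >= 1L),
    NOTMORETHAN = n1 <= rule$operand2,
    dd_stop("dd_value_error", "unsupported operator '%s'", rule$operator))
}

#' List the rules associated with a part
#'
#' Returns, in creation order, every rule in which the part appears as either
#' operand — the canvas answer to "which of my thousands of rules touch this
#' part?".
#'
#' @param design A `dna_design`.
#' @param name A part name on the canvas.
#' @return A list of rules (possibly empty).
#' @export
rules_for_part <- function(design, name) {
  if (!name %in% part_names(design))
    dd_stop("dd_operand_error", "no part named '%s'", name)
  keep <- vapply(design$rules, function(r) {
    identical(r$operand1, name) ||
      (is.character(r$operand2) && identical(r$operand2, name))
  }, logical(1L))
  unname(design$rules[keep])
}

format_rule <- function(rule) {
  sprintf("Rule %s(%s %s %s);", rule$name, rule$operand1, rule$operator,
          format(rule$operand2))
}

#' Export the design's rules as a rules file
#'
#' One statement per line in the supported dialect; re-importing the exported
#' text classifies every line as `identical`.
#'
#' @param design A `dna_design`.
#' @param path Optional file path; when given the text is also written there.
#' @return Character vector of rule lines, invisibly when `path` is given.
#' @export
export_rules_file <- function(design, path = NULL) {
  lines <- vapply(unname(design$rules), format_rule, character(1L))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

free_rule_name <- function(design, name) {
  if (!name %in% names(design$rules)) return(name)
  k <- 1L
  repeat {
    cand <- sprintf("%s_%d", name, k)
    if (!cand %in% names(design$rules)) return(cand)
    k <- k + 1L
  }
}

#' Import a rules file into a design
#'
#' Classifies every input line and returns both the updated design and an
#' import record per line: `imported` (new rule added), `identical` (same
#' name and same operator/operands as an existing rule; no change),
#' `renamed_conflict` (name clash with different content; imported under an
#' auto-generated alternative name `<name>_k`), or `ignored` (comments,
#' blanks, unparseable statements, unsupported operators, operands not on the
#' canvas — with a reason).
#'
#' @param design A `dna_design`.
#' @param text Rules-file content as a character vector of lines or a single
#'   string.
#' @param path Alternatively, a path to a rules file.
#' @return A list with `design` (updated) and `records` (a `data.frame` with
#'   `line_number`, `raw_text`, `status`, `resolved_name`, `reason`).
#' @export
import_rules_file <- function(design, text = NULL, path = NULL) {
  stopifnot(inherits(design, "dna_design"))
  if (is.null(text)) {
    if (is.null(path)) dd_stop("dd_value_error", "need text or path")
    text <- readLines(path, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  nm_parts <- part_names(design)
  recs <- vector("list", length(text))
  rec <- function(i, status, resolved = "", reason = "") {
    data.frame(line_number = i, raw_text = text[i], status = status,
               resolved_name = resolved, reason = reason,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(text)) {
    ln <- trimws(text[i])
    if (!nzchar(ln)) { recs[[i]] <- rec(i, "ignored", reason = "blank line"); next }
    if (startsWith(ln, "//")) { recs[[i]] <- rec(i, "ignored", reason = "comment"); next }
    m <- regmatches(ln, regexec(RULE_LINE_RE, ln))[[1L]]
    if (!length(m)) {
      recs[[i]] <- rec(i, "ignored", reason = "unparseable statement"); next
    }
    name <- m[2L]; op1 <- m[3L]; operator <- toupper(m[4L]); op2raw <- m[5L]
    if (!operator %in% RULE_OPERATORS) {
      recs[[i]] <- rec(i, "ignored",
                       reason = sprintf("invalid operator '%s'", m[4L])); next
    }
    if (!op1 %in% nm_parts) {
      recs[[i]] <- rec(i, "ignored",
                       reason = sprintf("operand '%s' not present in the current design", op1))
      next
    }
    if (operator == "NOTMORETHAN") {
      if (!grepl("^[0-9]+$", op2raw) || as.integer(op2raw) < 1L) {
        recs[[i]] <- rec(i, "ignored",
                         reason = sprintf("invalid NOTMORETHAN count '%s'", op2raw))
        next
      }
      op2 <- as.integer(op2raw)
    } else {
      if (!op2raw %in% nm_parts) {
        recs[[i]] <- rec(i, "ignored",
                         reason = sprintf("operand '%s' not present in the current design", op2raw))
        next
      }
      op2 <- op2raw
    }
    existing <- design$rules[[name]]
    if (!is.null(existing)) {
      if (identical(existing$operator, operator) &&
          identical(existing$operand1, op1) && identical(existing$operand2, op2)) {
        recs[[i]] <- rec(i, "identical", resolved = name)
        next
      }
      new_name <- free_rule_name(design, name)
      design <- add_rule(design, new_name, operator, op1, op2)
      recs[[i]] <- rec(i, "renamed_conflict", resolved = new_name,
                       reason = sprintf("name '%s' already used with different content", name))
      next
    }
    design <- add_rule(design, name, operator, op1, op2)
    recs[[i]] <- rec(i, "imported", resolved = name)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(line_number = integer(), raw_text = character(),
               status = character(), resolved_name = character(),
               reason = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(design = design, records = records)
}
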