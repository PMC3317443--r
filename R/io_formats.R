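# Design-document serialization (versioned JSON and XML renderings of the
# same schema) and j5-style CSV + sequence-bundle interchange.
#
# Bundle layout written by export_j5_bundle():
#   <dir>/parts.csv   Part Name, Part Source, Reverse Complement, Start BP, End BP
#   <dir>/order.csv   long format: ">"-prefixed bin rows carrying the
#                     per-bin firewall flag, forced assembly strategy and
#                     forced relative overhang, each followed by one row per
#                     member part name
#   <dir>/rules.eug   rules file in the supported dialect
#   <dir>/sequences/  one GenBank file per referenced source
# import_j5_bundle() accepts that layout, with sequences either in a
# directory or in a .zip archive; sources are resolved by the GenBank record
# display ID, never by file name.

DESIGN_SCHEMA_VERSION <- "1.0"

design_to_list <- function(design) {
  list(
    schema_version = DESIGN_SCHEMA_VERSION,
    topology = design$topology,
    assembly_method = design$assembly_method,
    seed = design$seed,
    sources = lapply(unname(design$sources), function(s) list(
      name = s$name, circular = s$circular, residues = s$residues,
      features = s$features)),
    parts = lapply(unname(design$parts), function(p)
      p[c("definition_id", "name", "source_name", "start", "stop",
          "reverse", "glyph", "forced_strategy")]),
    bins = lapply(design$bins, function(b) list(
      label = b$label, part_ids = as.list(b$part_ids),
      firewall_after = b$firewall_after,
      forced_overhang = b$forced_overhang)),
    rules = lapply(unname(design$rules), function(r)
      r[c("name", "operator", "operand1", "operand2")]))
}

design_from_list <- function(x, where = "design document") {
  need <- function(field, env = x) {
    if (is.null(env[[field]]))
      dd_stop("dd_schema_error", "%s: missing required field '%s'",
              where, field)
    env[[field]]
  }
  ver <- need("schema_version")
  if (!identical(as.character(ver), DESIGN_SCHEMA_VERSION))
    dd_stop("dd_version_error", "%s: unknown schema_version '%s' (supported: %s)",
            where, ver, DESIGN_SCHEMA_VERSION)
  topology <- x$topology
  if (is.null(topology)) {
    dd_warn("dd_default_warning",
            "%s: missing topology flag; defaulting to circular", where)
    topology <- "circular"
  }
  design <- new_design(topology)
  for (s in x$sources %||% list()) {
    ft <- s$features
    ft <- if (is.null(ft) || (is.data.frame(ft) && !nrow(ft)) ||
              (!is.data.frame(ft) && !length(ft))) feature_table()
          else if (is.data.frame(ft)) feature_table(ft$label, ft$type,
                                                    ft$start, ft$end, ft$strand)
          else {
            m <- do.call(rbind, lapply(ft, as.data.frame,
                                       stringsAsFactors = FALSE))
            feature_table(m$label, m$type, m$start, m$end, m$strand)
          }
    design <- add_source(design, annotated_sequence(
      need("name", s), need("residues", s),
      circular = isTRUE(s$circular), features = ft))
  }
  # deserialization is purely structural: field presence and types are
  # schema-checked here, while semantic findings (ranges, duplicate names,
  # rule operands, DIGEST placement) stay diagnostics of validate_design(),
  # so a defective document can still be loaded and inspected
  id_map <- character()
  for (p in x$parts %||% list()) {
    id <- sprintf("def%04d", design$next_def)
    design$next_def <- design$next_def + 1L
    design$parts[[id]] <- list(
      name = as.character(need("name", p)),
      source_name = as.character(need("source_name", p)),
      start = as.integer(need("start", p)),
      stop = as.integer(need("stop", p)),
      reverse = isTRUE(p$reverse),
      glyph = as.character(p$glyph %||% "generic"),
      forced_strategy = as.character(p$forced_strategy %||% "none"),
      definition_id = id)
    id_map[[as.character(need("definition_id", p))]] <- id
  }
  for (b in x$bins %||% list()) {
    design <- add_bin(design, b$label %||% NULL)
    bi <- length(design$bins)
    for (ref in unlist(b$part_ids %||% list())) {
      id <- id_map[[as.character(ref)]]
      if (is.null(id) || is.na(id))
        dd_stop("dd_schema_error", "%s: bin '%s' references unknown part id '%s'",
                where, b$label %||% bi, ref)
      design$bins[[bi]]$part_ids <- c(design$bins[[bi]]$part_ids, id)
    }
    design$bins[[bi]]$firewall_after <- isTRUE(b$firewall_after)
    ov <- b$forced_overhang
    design$bins[[bi]]$forced_overhang <-
      if (is.null(ov) || !length(ov) || is.na(ov[[1L]])) NA_integer_
      else as.integer(ov[[1L]])
  }
  for (r in x$rules %||% list()) {
    nm <- as.character(need("name", r))
    op <- as.character(need("operator", r))
    op2 <- need("operand2", r)
    design$rules[[nm]] <- list(
      name = nm, operator = op,
      operand1 = as.character(need("operand1", r)),
      operand2 = if (op == "NOTMORETHAN") as.integer(op2)
                 else as.character(op2))
  }
  am <- x$assembly_method
  design$assembly_method <-
    if (is.null(am) || !length(am) || is.na(am[[1L]])) NA_character_
    else as.character(am[[1L]])
  sd <- x$seed
  design$seed <-
    if (is.null(sd) || !length(sd) || is.na(sd[[1L]])) NA_integer_
    else as.integer(sd[[1L]])
  design
}

#' Save a design document
#'
#' Serializes the full design (sources inline, parts, bins with firewalls
#' and overhangs, rules, topology, glyph tags) to the package's versioned
#' schema, as JSON or XML depending on the file extension. Saving is refused
#' while the design carries error-severity diagnostics.
#'
#' @param design A `dna_design`.
#' @param path Output path ending in `.json` or `.xml`.
#' @return The path, invisibly.
#' @export
save_design <- function(design, path) {
  stopifnot(inherits(design, "dna_design"))
  errs <- design_errors(validate_design(design))
  if (nrow(errs))
    stop(errorCondition(
      paste0("design has validation errors; fix before saving:\n",
             paste(sprintf("  %s %s: %s", errs$code, errs$subject,
                           errs$message), collapse = "\n")),
      class = c("dd_validation_error", "dnadesign_error", "error"),
      diagnostics = errs))
  ext <- tolower(tools::file_ext(path))
  x <- design_to_list(design)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", dataframe = "rows")
  } else if (ext == "xml") {
    doc <- xml2::xml_new_root("dnadesign",
                              schema_version = DESIGN_SCHEMA_VERSION,
                              topology = design$topology)
    if (!is.na(design$assembly_method))
      xml2::xml_set_attr(doc, "assembly_method", design$assembly_method)
    if (!is.na(design$seed))
      xml2::xml_set_attr(doc, "seed", as.character(design$seed))
    srcs <- xml2::xml_add_child(doc, "sources")
    for (s in x$sources) {
      sn <- xml2::xml_add_child(srcs, "source", name = s$name,
                                circular = tolower(as.character(s$circular)))
      xml2::xml_add_child(sn, "residues", s$residues)
      for (i in seq_len(nrow(s$features))) {
        f <- s$features[i, ]
        xml2::xml_add_child(sn, "feature", label = f$label, type = f$type,
                            start = as.character(f$start),
                            end = as.character(f$end), strand = f$strand)
      }
    }
    pn <- xml2::xml_add_child(doc, "parts")
    for (p in x$parts) {
      xml2::xml_add_child(pn, "part", id = p$definition_id, name = p$name,
                          source = p$source_name,
                          start = as.character(p$start),
                          stop = as.character(p$stop),
                          reverse = tolower(as.character(p$reverse)),
                          glyph = p$glyph, forced_strategy = p$forced_strategy)
    }
    bn <- xml2::xml_add_child(doc, "bins")
    for (b in x$bins) {
      el <- xml2::xml_add_child(bn, "bin", label = b$label,
                                firewall_after = tolower(as.character(b$firewall_after)))
      if (!is.na(b$forced_overhang))
        xml2::xml_set_attr(el, "forced_overhang",
                           as.character(b$forced_overhang))
      for (ref in unlist(b$part_ids)) xml2::xml_add_child(el, "member", ref = ref)
    }
    rl <- xml2::xml_add_child(doc, "rules")
    for (r in x$rules) {
      xml2::xml_add_child(rl, "rule", name = r$name, operator = r$operator,
                          operand1 = r$operand1,
                          operand2 = as.character(r$operand2))
    }
    xml2::write_xml(doc, path)
  } else {
    dd_stop("dd_value_error", "unknown design-file extension '.%s' (use .json or .xml)", ext)
  }
  invisible(path)
}

xml_to_design_list <- function(doc) {
  root <- xml2::xml_root(doc)
  attr_or_null <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else v
  }
  list(
    schema_version = attr_or_null(root, "schema_version"),
    topology = attr_or_null(root, "topology"),
    assembly_method = attr_or_null(root, "assembly_method") %||% NA_character_,
    seed = attr_or_null(root, "seed") %||% NA_integer_,
    sources = lapply(xml2::xml_find_all(root, "./sources/source"), function(s) {
      fts <- xml2::xml_find_all(s, "./feature")
      list(name = xml2::xml_attr(s, "name"),
           circular = xml2::xml_attr(s, "circular") == "true",
           residues = xml2::xml_text(xml2::xml_find_first(s, "./residues")),
           features = if (!length(fts)) feature_table() else feature_table(
             xml2::xml_attr(fts, "label"), xml2::xml_attr(fts, "type"),
             as.integer(xml2::xml_attr(fts, "start")),
             as.integer(xml2::xml_attr(fts, "end")),
             xml2::xml_attr(fts, "strand")))
    }),
    parts = lapply(xml2::xml_find_all(root, "./parts/part"), function(p) list(
      definition_id = xml2::xml_attr(p, "id"),
      name = xml2::xml_attr(p, "name"),
      source_name = xml2::xml_attr(p, "source"),
      start = as.integer(xml2::xml_attr(p, "start")),
      stop = as.integer(xml2::xml_attr(p, "stop")),
      reverse = xml2::xml_attr(p, "reverse") == "true",
      glyph = xml2::xml_attr(p, "glyph"),
      forced_strategy = xml2::xml_attr(p, "forced_strategy"))),
    bins = lapply(xml2::xml_find_all(root, "./bins/bin"), function(b) {
      ov <- xml2::xml_attr(b, "forced_overhang")
      list(label = xml2::xml_attr(b, "label"),
           firewall_after = xml2::xml_attr(b, "firewall_after") == "true",
           forced_overhang = if (is.na(ov)) NA_integer_ else as.integer(ov),
           part_ids = as.list(xml2::xml_attr(
             xml2::xml_find_all(b, "./member"), "ref")))
    }),
    rules = lapply(xml2::xml_find_all(root, "./rules/rule"), function(r) {
      op <- xml2::xml_attr(r, "operator")
      op2 <- xml2::xml_attr(r, "operand2")
      list(name = xml2::xml_attr(r, "name"), operator = op,
           operand1 = xml2::xml_attr(r, "operand1"),
           operand2 = if (op == "NOTMORETHAN") as.integer(op2) else op2)
    }))
}

#' Load a design document
#'
#' Reads a `.json` or `.xml` design document saved by [save_design()].
#' Loading is atomic — a file that fails the schema checks yields no partial
#' design — and purely structural: semantic findings (ranges, duplicate
#' names, rule operands) are reported by [validate_design()] on the loaded
#' design rather than blocking the load, so defective documents can still be
#' inspected. A missing topology flag defaults to circular with a warning.
#'
#' @param path Path to a design document.
#' @return A `dna_design`.
#' @export
load_design <- function(path) {
  if (!file.exists(path)) dd_stop("dd_io_error", "no such file: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    tryCatch(jsonlite::read_json(path),
             error = function(e) dd_stop("dd_schema_error",
               "'%s' is not a valid design document: %s", path,
               conditionMessage(e)))
  } else if (ext == "xml") {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) dd_stop("dd_schema_error",
                      "'%s' is not a valid design document: %s", path,
                      conditionMessage(e)))
    xml_to_design_list(doc)
  } else {
    dd_stop("dd_value_error", "unknown design-file extension '.%s'", ext)
  }
  design_from_list(x, where = sprintf("'%s'", path))
}

## ---- j5-style bundle -------------------------------------------------------

PARTS_CSV_HEADER <- c("Part Name", "Part Source", "Reverse Complement",
                      "Start BP", "End BP")
ORDER_CSV_HEADER <- c("Bin/Part", "Direct Synthesis Firewall",
                      "Forced Assembly Strategy", "Forced Relative Overhang")

sanitize_filename <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

binned_defs <- function(design) {
  unique(unlist(lapply(design$bins, function(b) b$part_ids)))
}

#' Export a design as a j5-style bundle
#'
#' Writes the parts CSV, the bin-order CSV, the rules file and one GenBank
#' file per referenced source into `dir` (layout documented in this module).
#' Export is the correct-by-construction gate: it is refused with the full
#' diagnostic list while the design has error-severity diagnostics. Parts
#' peripheral to the collection (defined but unbinned) are not exported.
#' Source display IDs are taken from the sequence records, never from file
#' names.
#'
#' @param design A `dna_design`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths (`parts_csv`,
#'   `order_csv`, `rules`, `sequence_dir`).
#' @export
export_j5_bundle <- function(design, dir) {
  stopifnot(inherits(design, "dna_design"))
  errs <- design_errors(validate_design(design))
  if (nrow(errs))
    stop(errorCondition(
      paste0("design has validation errors; export refused:\n",
             paste(sprintf("  %s %s: %s", errs$code, errs$subject,
                           errs$message), collapse = "\n")),
      class = c("dd_validation_error", "dnadesign_error", "error"),
      diagnostics = errs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq_dir <- file.path(dir, "sequences")
  dir.create(seq_dir, showWarnings = FALSE)

  defs <- binned_defs(design)
  parts <- design$parts[defs]
  ptab <- data.frame(
    a = vapply(parts, function(p) p$name, character(1L)),
    b = vapply(parts, function(p) p$source_name, character(1L)),
    c = vapply(parts, function(p) ifelse(p$reverse, "TRUE", "FALSE"),
               character(1L)),
    d = vapply(parts, function(p) p$start, integer(1L)),
    e = vapply(parts, function(p) p$stop, integer(1L)),
    stringsAsFactors = FALSE)
  names(ptab) <- PARTS_CSV_HEADER
  parts_csv <- file.path(dir, "parts.csv")
  utils::write.csv(ptab, parts_csv, row.names = FALSE, quote = FALSE)

  order_lines <- paste(ORDER_CSV_HEADER, collapse = ",")
  for (bi in seq_along(design$bins)) {
    b <- design$bins[[bi]]
    ov <- if (is.na(b$forced_overhang)) "" else as.character(b$forced_overhang)
    strat <- bin_consensus_strategy(design, bi)
    order_lines <- c(order_lines,
                     sprintf(">%s,%s,%s,%s", b$label,
                             ifelse(b$firewall_after, "TRUE", "FALSE"),
                             strat, ov))
    for (id in b$part_ids)
      order_lines <- c(order_lines,
                       sprintf("%s,,,", design$parts[[id]]$name))
  }
  order_csv <- file.path(dir, "order.csv")
  writeLines(order_lines, order_csv)

  rules_path <- file.path(dir, "rules.eug")
  export_rules_file(design, rules_path)

  used_sources <- unique(vapply(parts, function(p) p$source_name,
                                character(1L)))
  for (sn in used_sources)
    write_genbank(design$sources[[sn]],
                  file.path(seq_dir, paste0(sanitize_filename(sn), ".gb")))
  invisible(list(parts_csv = parts_csv, order_csv = order_csv,
                 rules = rules_path, sequence_dir = seq_dir))
}

read_strict_csv <- function(path, expected_header) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    dd_stop("dd_format_error", "'%s' is empty", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  # historical files misspell "Reverse Complement" as "Reverse Compliment"
  header[header == "Reverse Compliment"] <- "Reverse Complement"
  if (!identical(trimws(header), expected_header))
    dd_stop("dd_format_error",
            "'%s': unexpected header '%s' (expected '%s')", path,
            paste(header, collapse = ","),
            paste(expected_header, collapse = ","))
  lines[-1L]
}

load_bundle_sources <- function(sequences) {
  paths <- if (length(sequences) == 1L && dir.exists(sequences)) {
    list.files(sequences, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
  } else if (length(sequences) == 1L && grepl("\\.zip$", sequences)) {
    tmp <- tempfile("j5seqs")
    utils::unzip(sequences, exdir = tmp)
    list.files(tmp, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE,
               recursive = TRUE)
  } else {
    sequences
  }
  seqs <- lapply(paths, read_genbank)
  # resolved by record display ID, never by file name
  stats::setNames(seqs, vapply(seqs, function(s) s$name, character(1L)))
}

#' Import a j5-style bundle as a minimal design
#'
#' Rebuilds a design from the parts CSV, order CSV, optional rules file and
#' the sequence files (a directory or a `.zip` of GenBank records). Sources
#' are matched by the record display ID, never by file name. Because CSVs
#' carry no SBOLv icon information, every imported part gets the `generic`
#' glyph. Out-of-range coordinates — the classic hand-edited-spreadsheet
#' failure — are hard errors naming the offending row, and the finished
#' design must validate cleanly or the import fails with the diagnostics.
#'
#' @param parts_csv Path to the parts CSV.
#' @param order_csv Path to the bin-order CSV.
#' @param sequences A directory, a `.zip`, or a vector of GenBank paths.
#' @param rules Optional path to a rules file.
#' @param topology Output topology of the imported design.
#' @return A `dna_design`.
#' @export
import_j5_bundle <- function(parts_csv, order_csv, sequences, rules = NULL,
                             topology = "circular") {
  sources <- load_bundle_sources(sequences)
  design <- new_design(topology)
  for (s in sources) design <- add_source(design, s)

  rows <- read_strict_csv(parts_csv, PARTS_CSV_HEADER)
  part_rows <- list()
  for (i in seq_along(rows)) {
    if (!nzchar(trimws(rows[i]))) next
    f <- trimws(strsplit(rows[i], ",", fixed = TRUE)[[1L]])
    if (length(f) != 5L)
      dd_stop("dd_format_error", "'%s' row %d: expected 5 fields, got %d",
              parts_csv, i + 1L, length(f))
    if (is.null(design$sources[[f[2L]]]))
      dd_stop("dd_reference_error",
              "part '%s': source display ID '%s' not found among the bundled sequences",
              f[1L], f[2L])
    if (!toupper(f[3L]) %in% c("TRUE", "FALSE"))
      dd_stop("dd_format_error", "'%s' row %d: bad boolean '%s'",
              parts_csv, i + 1L, f[3L])
    if (!grepl("^[0-9]+$", f[4L]) || !grepl("^[0-9]+$", f[5L]))
      dd_stop("dd_format_error", "'%s' row %d: non-numeric coordinates",
              parts_csv, i + 1L)
    design <- create_part(design, f[1L], f[2L],
                          as.integer(f[4L]), as.integer(f[5L]),
                          reverse = toupper(f[3L]) == "TRUE",
                          glyph = "generic")
  }

  rows <- read_strict_csv(order_csv, ORDER_CSV_HEADER)
  bi <- 0L
  bin_strategy <- "none"
  for (i in seq_along(rows)) {
    if (!nzchar(trimws(rows[i]))) next
    f <- strsplit(rows[i], ",", fixed = TRUE)[[1L]]
    f <- c(trimws(f), rep("", 4L - length(f)))
    if (startsWith(f[1L], ">")) {
      design <- add_bin(design, sub("^>", "", f[1L]))
      bi <- length(design$bins)
      design$bins[[bi]]$firewall_after <- toupper(f[2L]) == "TRUE"
      bin_strategy <- if (f[3L] %in% STRATEGY_VOCAB) f[3L] else "none"
      if (nzchar(f[4L]))
        design$bins[[bi]]$forced_overhang <- as.integer(f[4L])
    } else {
      if (bi == 0L)
        dd_stop("dd_format_error",
                "'%s' row %d: part row before any '>' bin row", order_csv, i + 1L)
      if (!f[1L] %in% part_names(design))
        dd_stop("dd_reference_error",
                "'%s' row %d: part '%s' not defined in the parts CSV",
                order_csv, i + 1L, f[1L])
      design <- replicate_part(design, f[1L], bi, digest_first_bin = FALSE)
      # the order CSV carries strategy per bin; re-apply it to members whose
      # definition does not already force one
      id <- find_def(design, f[1L])
      if (bin_strategy != "none" &&
          design$parts[[id]]$forced_strategy == "none")
        design$parts[[id]]$forced_strategy <- bin_strategy
    }
  }

  if (!is.null(rules)) {
    design <- import_rules_file(design, path = rules)$design
  }
  errs <- design_errors(validate_design(design))
  if (nrow(errs))
    stop(errorCondition(
      paste0("imported bundle does not form a valid design:\n",
             paste(sprintf("  %s %s: %s", errs$code, errs$subject,
                           errs$message), collapse = "\n")),
      class = c("dd_validation_error", "dnadesign_error", "error"),
      diagnostics = errs))
  design
}
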