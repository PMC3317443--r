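# Annotated DNA sequences: construction, reverse complement, region
# extraction on linear/circular sources, and GenBank flat-file I/O.

DNA_ALPHABET_RE <- "^[ACGTNacgtn]*$"

#' Feature table constructor
#'
#' Builds the feature table carried by an [annotated_sequence()]. Coordinates
#' are 1-based inclusive; on a circular sequence a feature may wrap the origin,
#' in which case `start > end`.
#'
#' @param label Character vector of display labels.
#' @param type Character vector of GenBank feature keys (e.g. `"CDS"`,
#'   `"misc_feature"`).
#' @param start,end Integer vectors of 1-based inclusive positions.
#' @param strand Character vector, `"+"` (forward) or `"-"` (reverse).
#' @return A `data.frame` with columns `label`, `type`, `start`, `end`,
#'   `strand`.
#' @export
feature_table <- function(label = character(), type = character(),
                          start = integer(), end = integer(),
                          strand = character()) {
  n <- max(length(label), length(type), length(start), length(end),
           length(strand))
  if (n == 0L) {
    return(data.frame(label = character(), type = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ft <- data.frame(label = as.character(label), type = as.character(type),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  bad <- !ft$strand %in% c("+", "-")
  if (any(bad)) dd_stop("dd_value_error", "strand must be '+' or '-'")
  ft
}

#' Annotated DNA sequence
#'
#' The source material parts are cut from: a named DNA string, a circular
#' topology flag, and a table of positioned features. Residue case is
#' preserved; comparisons elsewhere in the package are case-insensitive.
#'
#' @param name Display identifier.
#' @param residues DNA string over `A`,`C`,`G`,`T`,`N` (either case).
#' @param circular Logical topology flag; `TRUE` for plasmid-like sources.
#' @param features A [feature_table()].
#' @return An object of class `annotated_sequence`.
#' @export
annotated_sequence <- function(name, residues, circular = FALSE,
                               features = feature_table()) {
  if (!is_string(name) || !nzchar(name))
    dd_stop("dd_name_error", "sequence name must be a non-empty string")
  if (!is_string(residues) || !nzchar(residues))
    dd_stop("dd_invalid_source_error", "sequence '%s' has no residues", name)
  if (!grepl(DNA_ALPHABET_RE, residues))
    dd_stop("dd_alphabet_error",
            "sequence '%s' contains non-DNA characters (allowed: ACGTN)", name)
  L <- nchar(residues)
  features <- feature_table(features$label, features$type, features$start,
                            features$end, features$strand)
  if (nrow(features)) {
    out_of_range <- features$start < 1L | features$start > L |
      features$end < 1L | features$end > L
    if (any(out_of_range))
      dd_stop("dd_range_error",
              "feature '%s' outside [1, %d] on sequence '%s'",
              features$label[which(out_of_range)[1L]], L, name)
    wraps <- features$start > features$end
    if (any(wraps) && !isTRUE(circular))
      dd_stop("dd_topology_error",
              "feature '%s' wraps the origin but sequence '%s' is linear",
              features$label[which(wraps)[1L]], name)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(name = name, residues = residues,
                 circular = isTRUE(circular), features = features),
            class = "annotated_sequence")
}

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> %s: %d bp, %s, %d feature(s)\n",
              x$name, seq_length(x), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Sequence length in base pairs
#' @param seq An [annotated_sequence()].
#' @return Integer length.
#' @export
seq_length <- function(seq) nchar(seq$residues)

#' Case-preserving reverse complement of a DNA string
#' @param x A DNA string over `ACGTN` (either case).
#' @return The reverse complement, with residue case preserved per position.
#' @export
revcomp_string <- function(x) {
  if (!grepl(DNA_ALPHABET_RE, x))
    dd_stop("dd_alphabet_error", "non-DNA characters in string")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Reverse complement of an annotated sequence
#'
#' Residues are reverse-complemented (case preserved); each feature is
#' mirrored (`start' = L - end + 1`, `end' = L - start + 1`) with its strand
#' flipped, and the feature table is re-sorted by start.
#'
#' @param seq An [annotated_sequence()].
#' @return The reverse-complemented `annotated_sequence`.
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "annotated_sequence"))
  L <- seq_length(seq)
  ft <- seq$features
  if (nrow(ft)) {
    new_start <- L - ft$end + 1L
    new_end <- L - ft$start + 1L
    ft$start <- new_start
    ft$end <- new_end
    ft$strand <- ifelse(ft$strand == "+", "-", "+")
  }
  annotated_sequence(seq$name, revcomp_string(seq$residues),
                     circular = seq$circular, features = ft)
}

# Positions (source coordinates, in read order) covered by a window that may
# wrap the origin of a circular source.
window_positions <- function(start, stop, L) {
  if (start <= stop) start:stop else c(start:L, 1:stop)
}

feature_positions <- function(fstart, fend, L) {
  if (fstart <= fend) fstart:fend else c(fstart:L, 1:fend)
}

#' Extract a region from a source sequence
#'
#' Returns the contiguous region read 5'->3' from `start` through `stop`
#' (1-based inclusive). On a circular source `start > stop` selects the
#' origin-wrapping window through position `L` then `1`. Features fully inside
#' the window are remapped to region coordinates; features partially
#' overlapping are truncated to the window and their label suffixed with
#' `" (truncated)"`. If `reverse`, the extracted region is
#' reverse-complemented. The result is always linear.
#'
#' @param source An [annotated_sequence()].
#' @param start,stop 1-based inclusive positions in the source.
#' @param reverse Reverse-complement the extracted region.
#' @return A linear `annotated_sequence` for the region.
#' @export
extract_region <- function(source, start, stop, reverse = FALSE) {
  stopifnot(inherits(source, "annotated_sequence"))
  L <- seq_length(source)
  for (v in list(c(start, "start"), c(stop, "stop"))) {
    p <- as.numeric(v[[1L]])
    if (!is_count(p) || p < 1 || p > L)
      dd_stop("dd_range_error",
              "%s = %s outside [1, %d] on source '%s' (%d bp)",
              v[[2L]], v[[1L]], L, source$name, L)
  }
  start <- as.integer(start); stop <- as.integer(stop)
  if (start > stop && !source$circular)
    dd_stop("dd_topology_error",
            "start (%d) > stop (%d) on linear source '%s'",
            start, stop, source$name)
  win <- window_positions(start, stop, L)
  chars <- strsplit(source$residues, "", fixed = TRUE)[[1L]]
  residues <- paste(chars[win], collapse = "")
  # region offset of each source position (0 where outside the window)
  offset_of <- integer(L)
  offset_of[win] <- seq_along(win)

  ft <- source$features
  out <- feature_table()
  if (nrow(ft)) {
    rows <- vector("list", nrow(ft))
    for (i in seq_len(nrow(ft))) {
      fpos <- feature_positions(ft$start[i], ft$end[i], L)
      offs <- offset_of[fpos]
      offs <- sort(offs[offs > 0L])
      if (!length(offs)) next
      full <- length(offs) == length(fpos)
      # maximal contiguous runs in region coordinates (a partially covered
      # feature can split across the two window arms)
      runs <- split(offs, cumsum(c(1L, diff(offs) != 1L)))
      rows[[i]] <- do.call(rbind, lapply(runs, function(r) {
        data.frame(label = if (full) ft$label[i]
                   else paste0(ft$label[i], " (truncated)"),
                   type = ft$type[i], start = min(r), end = max(r),
                   strand = ft$strand[i], stringsAsFactors = FALSE)
      }))
    }
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows)) {
      m <- do.call(rbind, rows)
      out <- feature_table(m$label, m$type, m$start, m$end, m$strand)
    }
  }
  res <- annotated_sequence(
    sprintf("%s:%d..%d%s", source$name, start, stop, if (reverse) "(rc)" else ""),
    residues, circular = FALSE, features = out)
  if (reverse) reverse_complement(res) else res
}

## ---- GenBank flat-file I/O -------------------------------------------------

format_location <- function(start, end, strand, L, circular) {
  loc <- if (start <= end) sprintf("%d..%d", start, end)
         else sprintf("join(%d..%d,1..%d)", start, L, end)
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

parse_location <- function(loc, line_no) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    body <- sub("^join\\((.*)\\)$", "\\1", loc)
    spans <- strsplit(body, ",", fixed = TRUE)[[1L]]
    m <- regmatches(spans, regexec("^([0-9]+)\\.\\.([0-9]+)$", spans))
    if (length(spans) != 2L || any(vapply(m, length, 1L) != 3L))
      dd_stop("dd_format_error",
              "line %d: unsupported join() location '%s'", line_no, loc)
    # origin-wrapping pair a..L,1..b collapses to start > end
    a <- as.integer(m[[1L]][2L]); b <- as.integer(m[[2L]][3L])
    if (as.integer(m[[2L]][2L]) != 1L)
      dd_stop("dd_format_error",
              "line %d: join() location '%s' does not wrap the origin",
              line_no, loc)
    return(list(start = a, end = b, strand = strand))
  }
  m <- regmatches(loc, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", loc))[[1L]]
  if (!length(m))
    dd_stop("dd_format_error", "line %d: cannot parse location '%s'",
            line_no, loc)
  a <- as.integer(m[2L])
  b <- if (nzchar(m[4L] %||% "")) as.integer(m[4L]) else a
  list(start = a, end = b, strand = strand)
}

#' Write an annotated sequence as a GenBank flat file
#'
#' Emits a minimal standard-compliant record (LOCUS/DEFINITION/FEATURES/
#' ORIGIN). The LOCUS line declares `circular` or `linear` topology; reverse-
#' strand features use `complement()` locations and origin-wrapping features
#' use `join(a..L,1..b)`.
#'
#' @param seq An [annotated_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path) {
  stopifnot(inherits(seq, "annotated_sequence"))
  L <- seq_length(seq)
  lines <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN %s",
            seq$name, L, if (seq$circular) "circular" else "linear",
            toupper(format(Sys.Date(), "%d-%b-%Y"))),
    sprintf("DEFINITION  %s", seq$name),
    "FEATURES             Location/Qualifiers")
  ft <- seq$features
  for (i in seq_len(nrow(ft))) {
    loc <- format_location(ft$start[i], ft$end[i], ft$strand[i], L,
                           seq$circular)
    lines <- c(lines,
               sprintf("     %-16s%s", ft$type[i], loc),
               sprintf("                     /label=\"%s\"", ft$label[i]))
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(seq$residues, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) dd_stop("dd_io_error", "cannot write GenBank file '%s'", path)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Parses a minimal GenBank record: the LOCUS name becomes the sequence name,
#' LOCUS topology sets the circular flag (linear when absent), every feature
#' is captured with its strand and 1-based coordinates, and the ORIGIN block
#' supplies the residues. A missing DEFINITION line is tolerated. The feature
#' label is taken from the first of `/label`, `/gene`, `/product`, `/note`,
#' falling back to the feature key.
#'
#' @param path Path to a GenBank file.
#' @return An [annotated_sequence()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path))
    dd_stop("dd_io_error", "no such file: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i))
    dd_stop("dd_format_error", "line 1: no LOCUS line in '%s'", path)
  locus <- strsplit(trimws(lines[locus_i[1L]]), "[[:space:]]+")[[1L]]
  if (length(locus) < 2L)
    dd_stop("dd_format_error", "line %d: malformed LOCUS line", locus_i[1L])
  name <- locus[2L]
  circular <- any(tolower(locus) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (!length(origin_i))
    dd_stop("dd_invalid_source_error", "no ORIGIN sequence block in '%s'", path)
  seq_end <- if (length(end_i)) end_i[1L] - 1L else length(lines)
  seq_lines <- lines[seq(origin_i[1L] + 1L, seq_end)]
  residues <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(residues))
    dd_stop("dd_invalid_source_error", "empty ORIGIN sequence in '%s'", path)
  if (!grepl(DNA_ALPHABET_RE, residues))
    dd_stop("dd_format_error",
            "line %d: non-DNA characters in ORIGIN block", origin_i[1L] + 1L)

  # features between the FEATURES header and ORIGIN
  feat_i <- grep("^FEATURES", lines)
  ft <- feature_table()
  if (length(feat_i)) {
    block <- seq(feat_i[1L] + 1L, origin_i[1L] - 1L)
    cur <- NULL
    rows <- list()
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      lab <- cur$quals[["label"]] %||% cur$quals[["gene"]] %||%
        cur$quals[["product"]] %||% cur$quals[["note"]] %||% cur$type
      data.frame(label = lab, type = cur$type, start = cur$loc$start,
                 end = cur$loc$end, strand = cur$loc$strand,
                 stringsAsFactors = FALSE)
    }
    for (j in block) {
      ln <- lines[j]
      if (!nzchar(trimws(ln))) next
      if (grepl("^ {5}[^ ]", ln)) {            # new feature line
        rows[[length(rows) + 1L]] <- flush(cur)
        key <- trimws(substr(ln, 1L, 21L))
        loc <- trimws(substring(ln, 22L))
        cur <- list(type = key, loc = parse_location(loc, j), quals = list())
      } else if (!is.null(cur)) {              # qualifier / continuation
        q <- regmatches(ln, regexec("^\\s*/([A-Za-z_]+)=\"?([^\"]*)\"?\\s*$",
                                    ln))[[1L]]
        if (length(q) == 3L) cur$quals[[q[2L]]] <- q[3L]
      }
    }
    rows[[length(rows) + 1L]] <- flush(cur)
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows)) {
      m <- do.call(rbind, rows)
      ft <- feature_table(m$label, m$type, m$start, m$end, m$strand)
    }
  }
  annotated_sequence(name, residues, circular = circular, features = ft)
}
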