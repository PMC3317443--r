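# Seeded synthetic-design generator: random annotated sources cut into one
# part per (bin, slot), with named presets reproducing the canonical design
# shapes used throughout the documentation and tests — a GFP-localization
# style 6-bin collection ("prdr_like") and a 38x38 barcode/gene
# direct-synthesis library ("barcode_gene3").

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a source carrying the part region plus flanking context and 1-3 features
# placed inside the part region
random_source <- function(name, part_len, circular = FALSE) {
  flank <- sample(10:40, 2L)
  L <- part_len + sum(flank)
  nfeat <- sample(1:3, 1L)
  fstart <- sort(sample(seq_len(max(part_len - 6L, 1L)), nfeat)) + flank[1L]
  fend <- pmin(fstart + sample(3:12, nfeat, replace = TRUE), flank[1L] + part_len)
  ft <- feature_table(label = sprintf("%s_feat%d", name, seq_len(nfeat)),
                      type = "misc_feature", start = fstart, end = fend,
                      strand = sample(c("+", "-"), nfeat, replace = TRUE))
  list(seq = annotated_sequence(paste0(name, "_src"), random_dna(L),
                                circular = circular, features = ft),
       start = flank[1L] + 1L, stop = flank[1L] + part_len)
}

prdr_part_plan <- function() {
  # 6-bin, 9-part GFP-localization style collection: backbone / signal
  # peptide variants / linker variants / reporter CDS / degradation-tag
  # variants / terminator; 1*2*2*1*2*1 = 8 combinations
  list(
    list(bin = "backbone", parts = "vector_backbone",
         glyph = "origin_of_replication"),
    list(bin = "signal", parts = c("sig1", "sig2"), glyph = "signal_peptide"),
    list(bin = "linker", parts = c("long", "short"), glyph = "tag"),
    list(bin = "reporter", parts = "gfpuv", glyph = "cds"),
    list(bin = "deg_tag", parts = c("tag_lva", "tag_asv"), glyph = "tag"),
    list(bin = "term", parts = "terminator1", glyph = "terminator"))
}

#' Generate a seeded synthetic design
#'
#' Builds a complete, validating design from scratch: one random annotated
#' source per (bin, slot), one part cut from each, uniquely named, with every
#' bin populated in order. Deterministic given `(arguments, seed)`.
#'
#' Presets reproduce canonical shapes:
#' \describe{
#'   \item{`"prdr_like"`}{the 6-bin, 9-part collection with bin sizes
#'     `[1,2,2,1,2,1]` (8 combinations) and the part names `sig1`/`sig2`,
#'     `long`/`short`, `tag_lva`/`tag_asv` used in the worked rule examples;
#'     `bin_sizes` is ignored.}
#'   \item{`"barcode_gene3"`}{two consecutive `DIRECT_SYNTHESIS` bins of 38
#'     barcode variants and 38 gene variants (no firewall set), the
#'     firewall-cost worked example.}
#' }
#'
#' @param bin_sizes Integer vector of parts per bin (ignored by presets that
#'   fix the shape).
#' @param part_length_range Min/max part length in bp.
#' @param seed Integer seed; generation is reproducible given the same seed.
#' @param preset `NULL`, `"prdr_like"`, or `"barcode_gene3"`.
#' @param topology Output topology of the design.
#' @return A validating `dna_design`.
#' @export
#' @details The generator seed is recorded on the design (`design$seed`) and
#'   travels with saved design documents for provenance.
generate_design <- function(bin_sizes = c(1L, 2L, 2L, 1L, 2L, 1L),
                            part_length_range = c(60L, 240L),
                            seed = 1L, preset = NULL,
                            topology = "circular") {
  if (!is.null(preset) &&
      !preset %in% c("prdr_like", "barcode_gene3"))
    dd_stop("dd_value_error", "unknown preset '%s'", preset)
  if (is.null(preset)) {
    if (!length(bin_sizes) || any(!vapply(bin_sizes, is_count, logical(1L))) ||
        any(bin_sizes < 1L))
      dd_stop("dd_value_error", "bin_sizes must be positive integers")
  }
  if (length(part_length_range) != 2L || part_length_range[1L] < 1L ||
      part_length_range[2L] < part_length_range[1L])
    dd_stop("dd_value_error", "invalid part_length_range")
  design <- with_seed(seed, {
    design <- new_design(topology)
    if (identical(preset, "prdr_like")) {
      for (entry in prdr_part_plan()) {
        design <- add_bin(design, entry$bin)
        bi <- length(design$bins)
        for (nm in entry$parts) {
          src <- random_source(nm, sample(part_length_range[1L]:part_length_range[2L], 1L))
          design <- create_part(design, nm, src$seq, src$start, src$stop,
                                glyph = entry$glyph, bin = bi)
        }
      }
    } else if (identical(preset, "barcode_gene3")) {
      plan <- list(list(bin = "barcode", prefix = "barcode", n = 38L,
                        len = c(20L, 30L)),
                   list(bin = "gene3", prefix = "gene3_v", n = 38L,
                        len = part_length_range))
      for (entry in plan) {
        design <- add_bin(design, entry$bin)
        bi <- length(design$bins)
        for (k in seq_len(entry$n)) {
          nm <- sprintf("%s%02d", entry$prefix, k)
          src <- random_source(nm, sample(entry$len[1L]:entry$len[2L], 1L))
          design <- create_part(design, nm, src$seq, src$start, src$stop,
                                forced_strategy = "DIRECT_SYNTHESIS",
                                glyph = if (entry$bin == "gene3") "cds" else "generic",
                                bin = bi)
        }
      }
    } else {
      for (b in seq_along(bin_sizes)) {
        design <- add_bin(design)
        for (s in seq_len(bin_sizes[b])) {
          nm <- sprintf("bin%d_part%d", b, s)
          src <- random_source(nm, sample(part_length_range[1L]:part_length_range[2L], 1L))
          design <- create_part(design, nm, src$seq, src$start, src$stop,
                                glyph = sample(GLYPH_VOCAB, 1L), bin = b)
        }
      }
    }
    design
  })
  design$seed <- as.integer(seed)
  design
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n_codons, no_stop = TRUE) {
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      c3 <- random_dna(3L)
      if (!no_stop || !c3 %in% STOP_CODONS) break
    }
    out[i] <- c3
  }
  paste(out, collapse = "")
}

#' Generate an in-frame fusion fixture
#'
#' A linear 4-bin design (signal peptide / linker / CDS / tag) in which every
#' part length is divisible by 3, the fusion starts with ATG, no part
#' contains an internal stop codon in the fusion frame, and the final codon
#' of the last part is a stop — so the assembled construct forms one
#' uninterrupted open reading frame and a translation oracle can verify
#' in-frame assembly. Reverse-orienting any coding part breaks the frame
#' detectably.
#'
#' @param seed Integer seed.
#' @return A validating linear `dna_design` with one part per bin.
#' @export
generate_frame_fixture <- function(seed = 1L) {
  design <- with_seed(seed, {
    design <- new_design("linear")
    plan <- list(
      list(name = "sigpep", glyph = "signal_peptide", codons = 8L,
           first = "ATG"),
      list(name = "linker", glyph = "tag", codons = 5L),
      list(name = "payload_cds", glyph = "cds", codons = 60L),
      list(name = "cterm_tag", glyph = "tag", codons = 6L, last = "TAA"))
    for (entry in plan) {
      body <- random_codons(entry$codons -
                              (!is.null(entry$first)) - (!is.null(entry$last)))
      residues <- paste0(entry$first %||% "", body, entry$last %||% "")
      src <- annotated_sequence(
        paste0(entry$name, "_src"), residues, circular = FALSE,
        features = feature_table(entry$name, "CDS", 1L, nchar(residues), "+"))
      design <- add_bin(design, entry$name)
      design <- create_part(design, entry$name, src, 1L, nchar(residues),
                            glyph = entry$glyph, bin = length(design$bins))
    }
    design
  })
  design$seed <- as.integer(seed)
  design
}
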