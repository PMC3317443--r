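# Shared test helpers: small builders and independent oracles.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a linear/circular source with k features at random positions
rand_annotated <- function(n, k = 0L, circular = FALSE, name = "src") {
  ft <- if (k > 0L) {
    st <- sample(seq_len(n), k, replace = TRUE)
    en <- pmin(st + sample(0:9, k, replace = TRUE), n)
    feature_table(sprintf("f%d", seq_len(k)), "misc_feature", st, en,
                  sample(c("+", "-"), k, replace = TRUE))
  } else feature_table()
  annotated_sequence(name, rand_dna(n), circular = circular, features = ft)
}

# independent per-base reverse complement (lookup table, no chartr)
oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")
  paste(rev(unname(map[strsplit(x, "")[[1]]])), collapse = "")
}

# rotation oracle for circular extraction: rotate so `start` is first, slice
oracle_rotate_slice <- function(residues, start, wlen) {
  L <- nchar(residues)
  rotated <- paste0(substr(residues, start, L), substr(residues, 1, start - 1))
  substr(rotated, 1, wlen)
}

# independent rule predicate written directly from the operator definitions
oracle_rule_ok <- function(op, o1, o2, construct_names) {
  cnt <- function(x) length(which(construct_names == x))
  if (op == "WITH") return(!(cnt(o1) > 0 && cnt(o2) == 0))
  if (op == "NOTWITH") return(!(cnt(o1) > 0 && cnt(o2) > 0))
  if (op == "NOTMORETHAN") return(cnt(o1) <= o2)
  stop("bad operator")
}

# the 6-bin worked design plus its co-localization rule
prdr_design_with_rule <- function(seed = 7) {
  d <- generate_design(preset = "prdr_like", seed = seed)
  add_rule(d, "rule3", "WITH", "short", "sig1")
}

# a tiny two-part design over one shared source
tiny_design <- function(src_len = 60, seed = 11) {
  set.seed(seed)
  src <- rand_annotated(src_len, k = 2L, name = "pSrc")
  d <- new_design("linear")
  d <- add_source(d, src)
  d <- add_bin(d, "a")
  d <- add_bin(d, "b")
  d <- create_part(d, "left", "pSrc", 1, floor(src_len / 2), bin = 1)
  d <- create_part(d, "right", "pSrc", floor(src_len / 2) + 1, src_len, bin = 2)
  d
}

find_def_test <- function(design, name) {
  ids <- names(design$parts)
  ids[vapply(design$parts, function(p) p$name == name, logical(1))][1]
}

run_cli <- function(args) {
  script <- system.file("cli", "dnadesign.R", package = "dnadesign")
  res <- suppressWarnings(system2(
    "Rscript", c(shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(res, "status") %||% 0L, output = paste(res, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
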