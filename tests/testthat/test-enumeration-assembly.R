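# Cartesian enumeration, rule filtering against a brute-force oracle, and
# scar-less assembly.

test_that("enumeration yields the product of bin sizes in lexicographic order", {
  d <- generate_design(preset = "prdr_like", seed = 7)
  all <- enumerate_constructs(d)
  expect_length(all, 8)
  expect_equal(vapply(all, function(co) co$index, numeric(1)), 1:8)
  # leftmost bin varies slowest: bin 2 (sig1/sig2) flips every 4th construct
  sig <- vapply(all, function(co) co$part_names[2], character(1))
  expect_equal(sig, rep(c("sig1", "sig2"), each = 4))
  # all-singleton design
  d1 <- generate_design(bin_sizes = c(1, 1, 1), seed = 1,
                        part_length_range = c(20, 30))
  expect_length(enumerate_constructs(d1), 1)
  expect_equal(n_constructs(d1), 1)
  # empty bin is a structure error
  expect_error(n_constructs(add_bin(d)), class = "dd_structure_error")
})

test_that("library-scale products are counted lazily, not materialized", {
  d <- generate_design(bin_sizes = rep(38, 3), seed = 5,
                       part_length_range = c(20, 30))
  expect_equal(n_constructs(d), 38^3)
  expect_equal(n_constructs(d), 54872)
  expect_error(enumerate_constructs(d, limit = 1000),
               class = "dd_structure_error")
  # the streaming iterator walks the same order without materializing
  it <- construct_iterator(d)
  first <- it(); second <- it()
  expect_equal(first$index, 1)
  expect_equal(second$index, 2)
  expect_equal(first$part_names[1:2], second$part_names[1:2])
})

test_that("rule filtering matches a brute-force per-combination oracle", {
  set.seed(30)
  for (trial in 1:30) {
    sizes <- sample(1:3, sample(2:4, 1), replace = TRUE)
    d <- generate_design(bin_sizes = sizes, seed = 1000 + trial,
                         part_length_range = c(15, 30))
    nm <- vapply(d$parts, function(p) p$name, character(1))
    nrules <- sample(0:4, 1)
    rules <- list()
    for (k in seq_len(nrules)) {
      op <- sample(c("WITH", "NOTWITH", "NOTMORETHAN"), 1)
      ops <- sample(nm, min(2, length(nm)), replace = length(nm) < 2)
      o2 <- if (op == "NOTMORETHAN") sample(1:2, 1) else ops[2]
      d <- add_rule(d, sprintf("r%d", k), op, ops[1], o2)
      rules[[k]] <- list(op = op, o1 = ops[1], o2 = o2)
    }
    res <- filter_by_rules(d)
    # oracle: expand the full product and evaluate every rule on every row
    grids <- lapply(d$bins, function(b)
      vapply(d$parts[b$part_ids], function(p) p$name, character(1)))
    grid <- rev(expand.grid(rev(grids), stringsAsFactors = FALSE))
    keep <- vapply(seq_len(nrow(grid)), function(i) {
      row <- unlist(grid[i, ], use.names = FALSE)
      all(vapply(rules, function(r)
        oracle_rule_ok(r$op, r$o1, r$o2, row), logical(1)))
    }, logical(1))
    expect_equal(res$report$total, nrow(grid))
    expect_equal(res$report$kept, sum(keep))
    expect_equal(vapply(res$constructs, function(co) co$index, numeric(1)),
                 as.numeric(which(keep)))
  }
})

test_that("adding a rule never increases the kept count (monotone filtering)", {
  d <- generate_design(preset = "prdr_like", seed = 7)
  kept <- n_constructs(d)
  rules <- list(list("a", "WITH", "short", "sig1"),
                list("b", "NOTWITH", "tag_lva", "sig2"),
                list("c", "NOTMORETHAN", "gfpuv", 1))
  for (r in rules) {
    d <- add_rule(d, r[[1]], r[[2]], r[[3]], r[[4]])
    now <- filter_by_rules(d, keep_constructs = FALSE)$report$kept
    expect_lte(now, kept)
    kept <- now
  }
})

test_that("assembly concatenates scar-lessly with the design topology", {
  d <- generate_design(preset = "prdr_like", seed = 7)
  co <- enumerate_constructs(d)[[1]]
  asm <- assemble_construct(d, co)
  expect_true(asm$circular)
  parts_cat <- paste(vapply(co$part_names, function(n)
    part_sequence(d, n)$residues, character(1)), collapse = "")
  expect_equal(asm$residues, parts_cat)
  # single-part design assembles to that part's sequence
  d1 <- new_design("linear")
  d1 <- add_source(d1, annotated_sequence("s", "ACGTACGTACGT"))
  d1 <- add_bin(d1)
  d1 <- create_part(d1, "only", "s", 3, 10, bin = 1)
  asm1 <- assemble_construct(d1, enumerate_constructs(d1)[[1]])
  expect_equal(asm1$residues, part_sequence(d1, "only")$residues)
  expect_false(asm1$circular)
})

test_that("assembled length is the sum of part lengths across random designs", {
  set.seed(31)
  for (trial in 1:25) {
    sizes <- sample(1:3, sample(1:4, 1), replace = TRUE)
    d <- generate_design(bin_sizes = sizes, seed = 2000 + trial,
                         part_length_range = c(15, 60))
    cos <- enumerate_constructs(d)
    co <- cos[[sample(length(cos), 1)]]
    asm <- assemble_construct(d, co)
    expect_equal(seq_length(asm),
                 sum(vapply(co$part_names, function(n)
                   seq_length(part_sequence(d, n)), integer(1))))
  }
})

test_that("assembled annotations are the contained features plus one span per part", {
  set.seed(32)
  d <- generate_design(bin_sizes = c(2, 2), seed = 77,
                       part_length_range = c(40, 80))
  co <- enumerate_constructs(d)[[1]]
  asm <- assemble_construct(d, co)
  contained <- sum(vapply(co$part_names, function(n) {
    ft <- part_sequence(d, n)$features
    sum(!grepl(" \\(truncated\\)$", ft$label))
  }, numeric(1)))
  expect_equal(nrow(asm$features), contained + length(co$part_names))
  # the per-part span features tile the assembly in order
  spans <- asm$features[asm$features$label %in% co$part_names, ]
  spans <- spans[order(spans$start), ]
  expect_equal(spans$label, unname(co$part_names))
  expect_equal(spans$start[1], 1L)
  expect_equal(spans$end[nrow(spans)], seq_length(asm))
})

test_that("the frame fixture assembles to one uninterrupted reading frame", {
  library(Biostrings)
  d <- generate_frame_fixture(seed = 1)
  co <- enumerate_constructs(d)[[1]]
  asm <- assemble_construct(d, co)
  expect_equal(seq_length(asm) %% 3, 0)
  aa <- as.character(translate(DNAString(asm$residues)))
  expect_equal(substr(aa, 1, 1), "M")
  # no internal stop; the construct ends on its single stop codon
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  # negative control: reverse-orienting the CDS breaks the frame detectably
  d2 <- edit_part_definition(d, "payload_cds", list(reverse = TRUE))
  asm2 <- assemble_construct(d2, enumerate_constructs(d2)[[1]])
  aa2 <- as.character(translate(DNAString(asm2$residues)))
  expect_true(grepl("\\*", substr(aa2, 1, nchar(aa2) - 1)))
})

test_that("construct names are sequential, zero-padded and order-preserving", {
  expect_equal(name_constructs(8, "pRDR0000"),
               sprintf("pRDR0000%d", 1:8))
  expect_equal(name_constructs(1, "only_"), "only_1")
  nm <- name_constructs(12, "pj5_000")
  expect_equal(nm[1], "pj5_00001")
  expect_equal(nm[12], "pj5_00012")
  expect_false(is.unsorted(nm))
  expect_equal(anyDuplicated(nm), 0)
  d <- prdr_design_with_rule()
  kept <- filter_by_rules(d)$constructs
  expect_equal(name_constructs(kept, "pRDR0000"), sprintf("pRDR0000%d", 1:6))
})

test_that("the enumeration report exports as CSV with kept flags and violations", {
  td <- withr::local_tempdir()
  d <- prdr_design_with_rule()
  p <- file.path(td, "report.csv")
  export_enumeration_csv(d, p, prefix = "pRDR0000")
  tab <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$kept), 6)
  expect_equal(sum(tab$violated_rules == "rule3"), 2)
  expect_equal(tab$construct[tab$kept][1], "pRDR00001")
})
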