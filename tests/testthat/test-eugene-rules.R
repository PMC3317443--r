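# Rule creation with operand validation, per-construct evaluation semantics,
# per-part listing, and rules-file import/export.

test_that("add_rule validates operands, names and counts", {
  d <- prdr_design_with_rule()
  # the mistyped-operand trap: 'ispA' when only 'ispA-O' exists
  d2 <- generate_design(bin_sizes = c(1, 1), seed = 4)
  d2 <- edit_part_definition(d2, "bin1_part1", list(name = "ispA-O"))
  expect_error(add_rule(d2, "cap", "NOTMORETHAN", "ispA", 1),
               class = "dd_operand_error")
  d2 <- add_rule(d2, "cap", "NOTMORETHAN", "ispA-O", 1)
  expect_length(rules_for_part(d2, "ispA-O"), 1)
  # duplicate rule name
  expect_error(add_rule(d, "rule3", "NOTWITH", "long", "sig2"),
               class = "dd_uniqueness_error")
  # count must be a positive integer
  expect_error(add_rule(d2, "zero", "NOTMORETHAN", "ispA-O", 0),
               class = "dd_value_error")
  expect_error(add_rule(d2, "op", "MAYBEWITH", "ispA-O", 1),
               class = "dd_value_error")
})

test_that("rule evaluation follows the operator semantics", {
  with_rule <- list(name = "r", operator = "WITH",
                    operand1 = "short", operand2 = "sig1")
  # short present with sig2 instead of sig1 -> violated
  expect_false(evaluate_rule(with_rule, c("sig2", "short", "gfp", "std_tag")))
  expect_true(evaluate_rule(with_rule, c("sig1", "short", "gfp")))
  # vacuous antecedent: no 'short' anywhere
  expect_true(evaluate_rule(with_rule, c("sig2", "long", "gfp")))
  notwith <- list(name = "r", operator = "NOTWITH",
                  operand1 = "a", operand2 = "b")
  expect_false(evaluate_rule(notwith, c("a", "b")))
  expect_true(evaluate_rule(notwith, c("a", "c")))
  cap <- list(name = "r", operator = "NOTMORETHAN",
              operand1 = "ispA-O", operand2 = 1L)
  expect_false(evaluate_rule(cap, c("ispA-O", "x", "ispA-O")))
  expect_true(evaluate_rule(cap, c("ispA-O", "x")))
})

test_that("WITH is directional: operand1's presence requires operand2", {
  d <- generate_design(preset = "prdr_like", seed = 7)
  # short WITH sig1 eliminates exactly the 2 short+sig2 combinations of 8
  da <- add_rule(d, "rule3", "WITH", "short", "sig1")
  ra <- filter_by_rules(da)
  expect_equal(ra$report$total, 8)
  expect_equal(ra$report$eliminated, 2)
  elim_a <- setdiff(seq_len(8),
                    vapply(ra$constructs, function(co) co$index, numeric(1)))
  # the symmetric direction eliminates 2 *different* combinations
  db <- add_rule(d, "rule3r", "WITH", "sig1", "short")
  rb <- filter_by_rules(db)
  expect_equal(rb$report$eliminated, 2)
  elim_b <- setdiff(seq_len(8),
                    vapply(rb$constructs, function(co) co$index, numeric(1)))
  expect_length(intersect(elim_a, elim_b), 0)
  # their conjunction eliminates 4
  dc <- add_rule(da, "rule3r", "WITH", "sig1", "short")
  expect_equal(filter_by_rules(dc)$report$eliminated, 4)
})

test_that("rules_for_part lists exactly the rules touching a part", {
  d <- prdr_design_with_rule()
  r <- rules_for_part(d, "sig1")
  expect_length(r, 1)
  expect_equal(r[[1]]$name, "rule3")
  expect_length(rules_for_part(d, "gfpuv"), 0)
  expect_error(rules_for_part(d, "nosuch"), class = "dd_operand_error")
  # set-cover property: every rule appears once per distinct operand
  set.seed(10)
  d2 <- generate_design(bin_sizes = c(3, 3, 3), seed = 10,
                        part_length_range = c(20, 40))
  nm <- vapply(d2$parts, function(p) p$name, character(1))
  for (k in 1:60) {
    op <- sample(c("WITH", "NOTWITH", "NOTMORETHAN"), 1)
    ops <- sample(nm, 2)
    d2 <- add_rule(d2, sprintf("r%03d", k), op, ops[1],
                   if (op == "NOTMORETHAN") sample(1:3, 1) else ops[2])
  }
  per_part <- lapply(nm, function(p) vapply(rules_for_part(d2, p),
                                            function(r) r$name, character(1)))
  tallied <- table(unlist(per_part))
  for (r in d2$rules) {
    ops <- unique(c(r$operand1, if (is.character(r$operand2)) r$operand2))
    expect_equal(as.integer(tallied[[r$name]]), length(ops))
  }
})

test_that("rules files export one canonical line per rule and re-import as identical", {
  d <- prdr_design_with_rule()
  lines <- export_rules_file(d)
  expect_equal(lines, "Rule rule3(short WITH sig1);")
  expect_equal(export_rules_file(new_design()), character(0))
  res <- import_rules_file(d, text = lines)
  expect_equal(res$records$status, "identical")
  expect_length(res$design$rules, 1)
  # lossless round trip of a large random rule set
  set.seed(20)
  d2 <- generate_design(bin_sizes = c(3, 3, 3), seed = 20,
                        part_length_range = c(20, 40))
  nm <- vapply(d2$parts, function(p) p$name, character(1))
  for (k in 1:50) {
    op <- sample(c("WITH", "NOTWITH", "NOTMORETHAN"), 1)
    ops <- sample(nm, 2)
    d2 <- add_rule(d2, sprintf("r%03d", k), op, ops[1],
                   if (op == "NOTMORETHAN") sample(1:5, 1) else ops[2])
  }
  blank <- d2; blank$rules <- list()
  res2 <- import_rules_file(blank, text = export_rules_file(d2))
  expect_true(all(res2$records$status == "imported"))
  expect_identical(res2$design$rules, d2$rules)
})

test_that("import classifies comments, conflicts and bad lines per the dialog colours", {
  d <- prdr_design_with_rule()
  txt <- c("// linker constraints",
           "",
           "Rule rule3(short WITH sig1);",
           "Rule rule3(long NOTWITH sig1);",
           "Rule r9(short MAYBEWITH sig1);",
           "Rule r10(ispA NOTMORETHAN 1);",
           "Rule r11(short NOTMORETHAN 0);",
           "total gibberish")
  res <- import_rules_file(d, text = txt)
  rec <- res$records
  expect_equal(nrow(rec), length(txt))
  expect_equal(rec$status,
               c("ignored", "ignored", "identical", "renamed_conflict",
                 "ignored", "ignored", "ignored", "ignored"))
  expect_equal(rec$resolved_name[4], "rule3_1")
  expect_match(rec$reason[1], "comment")
  expect_match(rec$reason[5], "operator")
  expect_match(rec$reason[6], "ispA")
  expect_match(rec$reason[7], "count")
  # design gained exactly the renamed rule
  expect_setequal(names(res$design$rules), c("rule3", "rule3_1"))
  expect_equal(res$design$rules[["rule3_1"]]$operator, "NOTWITH")
  # operator keywords are case-insensitive
  res2 <- import_rules_file(d, text = "Rule lc(long with sig2);")
  expect_equal(res2$records$status, "imported")
  expect_equal(res2$design$rules[["lc"]]$operator, "WITH")
})

test_that("rule filtering is order-independent and equals per-rule intersection", {
  d <- generate_design(preset = "prdr_like", seed = 13)
  d1 <- add_rule(d, "a", "WITH", "short", "sig1")
  d1 <- add_rule(d1, "b", "NOTWITH", "tag_lva", "sig2")
  d2 <- add_rule(d, "b", "NOTWITH", "tag_lva", "sig2")
  d2 <- add_rule(d2, "a", "WITH", "short", "sig1")
  k1 <- vapply(filter_by_rules(d1)$constructs, function(co) co$index, numeric(1))
  k2 <- vapply(filter_by_rules(d2)$constructs, function(co) co$index, numeric(1))
  expect_equal(k1, k2)
  # kept set = intersection of single-rule kept sets
  da <- add_rule(d, "a", "WITH", "short", "sig1")
  db <- add_rule(d, "b", "NOTWITH", "tag_lva", "sig2")
  ka <- vapply(filter_by_rules(da)$constructs, function(co) co$index, numeric(1))
  kb <- vapply(filter_by_rules(db)$constructs, function(co) co$index, numeric(1))
  expect_equal(k1, intersect(ka, kb))
})
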