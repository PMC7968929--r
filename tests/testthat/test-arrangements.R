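test_that("enumeration yields 48 order/orientation permutations and 6 all-forward orders", {
  full <- enumerate_arrangements(TRUE)
  fwd <- enumerate_arrangements(FALSE)
  expect_length(full, 48L)
  expect_length(fwd, 6L)

  labels <- vapply(full, function(a) a$label, character(1))
  expect_false(anyDuplicated(labels) > 0)

  # every gene appears in every slot, in both orientations
  for (slot in 1:3) {
    genes <- vapply(full, function(a) a$slots$gene[slot], character(1))
    oris <- vapply(full, function(a) a$slots$orientation[slot], character(1))
    expect_setequal(unique(genes), c("lacI", "tetR", "cI"))
    expect_setequal(unique(oris), c("forward", "reverse"))
  }
  expect_true(all(vapply(fwd, function(a)
    all(a$slots$orientation == "forward"), logical(1))))

  # the generalized helper: 1 gene, 2 orientations -> 2 arrangements
  expect_length(readthru:::enumerate_slot_sets("x", TRUE), 2L)
  expect_length(readthru:::enumerate_slot_sets("x", FALSE), 1L)
})

test_that("flip is an involution with no fixed points", {
  full <- enumerate_arrangements(TRUE)
  for (a in full) {
    fl <- flip_arrangement(a)
    expect_identical(flip_arrangement(fl)$label, a$label)
    expect_false(fl$label == a$label)
  }
  fl <- flip_arrangement(parse_label("TLC"))
  expect_identical(fl$slots$gene, c("cI", "lacI", "tetR"))
  expect_identical(unique(fl$slots$orientation), "reverse")
})

test_that("orientation pairs partition the 48-set into 24 disjoint flip pairs", {
  full <- enumerate_arrangements(TRUE)
  pairs <- orientation_pairs(full)
  expect_length(pairs, 24L)

  members <- unlist(lapply(pairs, function(p)
    c(p[[1]]$label, p[[2]]$label)))
  expect_length(members, 48L)
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, vapply(full, function(a) a$label, character(1)))

  for (p in pairs) {
    expect_identical(flip_arrangement(p[[1]])$label, p[[2]]$label)
  }
  tlc_pair <- Filter(function(p) any(c(p[[1]]$label, p[[2]]$label) == "TLC"),
                     pairs)[[1]]
  expect_setequal(c(tlc_pair[[1]]$label, tlc_pair[[2]]$label),
                  c("TLC", "C_rL_rT_r"))

  expect_error(orientation_pairs(full[-1]), "not closed under flip")
})

test_that("labels parse and format as mutual inverses", {
  a <- parse_label("TLC")
  expect_identical(a$slots$gene, c("tetR", "lacI", "cI"))
  expect_identical(unique(a$slots$orientation), "forward")

  b <- parse_label("LT_rC_r")
  expect_identical(b$slots$gene, c("lacI", "tetR", "cI"))
  expect_identical(b$slots$orientation, c("forward", "reverse", "reverse"))

  for (a in enumerate_arrangements(TRUE)) {
    expect_identical(format_label(parse_label(a$label)), a$label)
  }
})

test_that("malformed labels are rejected naming the offending token", {
  expect_error(parse_label("XLT"), "unknown gene letter 'X'")
  expect_error(parse_label("TTC"), "duplicate gene letter 'T'")
  expect_error(parse_label("TL"), "malformed")
  expect_error(parse_label("TLCC"), "malformed|duplicate")
})

test_that("terminator specs validate rates and multiply in tandem", {
  expect_error(terminator("T1", 1.5), "\\[0, 1\\]")
  expect_error(terminator("T1", -0.1), "\\[0, 1\\]")

  d <- double_terminator(terminator("Tcrp", 0.5), terminator("T1", 0.5))
  expect_equal(d$readthrough_rate, 0.25)
  expect_lt(d$readthrough_rate, 0.5)

  # NA rates resolve against the model mu before multiplying
  d2 <- double_terminator(terminator("T1"), terminator("T2"), mu = 0.6)
  expect_equal(d2$readthrough_rate, 0.36)
  expect_error(double_terminator(terminator("T1"), terminator("T2")),
               "mu needed")
})
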