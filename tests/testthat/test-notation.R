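test_that("epitope names parse into base sequence and modifications", {
  p <- parse_epitope_name("GILGFVFTL + OTH(L9)")
  expect_equal(p$base_sequence, "GILGFVFTL")
  expect_equal(p$mods$code, "OTH")
  expect_equal(p$mods$residue, "L")
  expect_equal(p$mods$position, 9L)

  p2 <- parse_epitope_name("GILGFVFTV + OTH(V9)")
  expect_equal(p2$base_sequence, "GILGFVFTV")
  expect_equal(p2$mods$position, 9L)

  p3 <- parse_epitope_name("SIINFEKL")
  expect_equal(p3$base_sequence, "SIINFEKL")
  expect_equal(nrow(p3$mods), 0L)
})

test_that("both multi-modification annotation shapes normalise identically", {
  a <- parse_epitope_name("ACDEFGHIK + PHOS(C2), OTH(K9)")
  b <- parse_epitope_name("ACDEFGHIK + PHOS(C2),OTH(K9)")
  expect_identical(a, b)
  one_group <- parse_epitope_name("ACDEFGHIK + PHOS(C2, K9)")
  expect_equal(one_group$mods$position, c(2L, 9L))
  expect_equal(one_group$mods$code, c("PHOS", "PHOS"))
})

test_that("inconsistent, out-of-range, duplicate and malformed names error", {
  expect_error(parse_epitope_name("GILGFVFTL + OTH(V9)"), "inconsistent")
  expect_error(parse_epitope_name("GILGFVFTL + OTH(L12)"), "out of range")
  expect_error(parse_epitope_name("GILGFVFTL + OTH(L9), PHOS(L9)"), "duplicate")
  expect_error(parse_epitope_name("GILGFVFTL + OTH L9"), "malformed")
  expect_error(parse_epitope_name("GILGFVFTL + o(L9)"), "malformed")
  expect_error(parse_epitope_name(""), "non-empty")
  expect_error(parse_epitope_name("GILGFVF"), "length")        # 7-mer
  expect_error(parse_epitope_name("GILGFVFTLGILG"), "length")  # 13-mer
})

test_that("lowercase sequences are upcased with a warning", {
  expect_warning(p <- parse_epitope_name("gilgfvftl + OTH(L9)"), "upcased")
  expect_equal(p$base_sequence, "GILGFVFTL")
})

test_that("tokenize marks modified positions and preserves order and length", {
  p <- parse_epitope_name("GILGFVFTL + OTH(L9)")
  expect_equal(tokenize(p),
               c("G", "I", "L", "G", "F", "V", "F", "T", "L-OTH"))
  expect_equal(tokenize(parse_epitope_name("SIINFEKL")),
               c("S", "I", "I", "N", "F", "E", "K", "L"))
  p3 <- parse_epitope_name("ACDEFGHIK + PHOS(C2), OTH(K9)")
  expect_equal(tokenize(p3),
               c("A", "C-PHOS", "D", "E", "F", "G", "H", "I", "K-OTH"))
  expect_true(all(is_ncaa_token(c("L-OTH", "C-PHOS"))))
  expect_false(any(is_ncaa_token(c("L", "C"))))
})

test_that("render/parse round-trips and tokenize is position-stable", {
  set.seed(7)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  codes <- c("OTH", "PHOS", "ME1", "AC", "X2Y")
  for (i in 1:25) {
    len <- sample(8:11, 1)
    base <- sample(aa, len, replace = TRUE)
    n_mods <- sample(0:2, 1)
    pos <- sort(sample.int(len, n_mods))
    mods <- data.frame(code = sample(codes, n_mods, replace = TRUE),
                       residue = base[pos], position = pos,
                       stringsAsFactors = FALSE)
    pep <- structure(list(base_sequence = paste(base, collapse = ""),
                          mods = mods), class = "modified_peptide")
    rendered <- render_epitope_name(pep)
    reparsed <- parse_epitope_name(rendered)
    expect_equal(reparsed$base_sequence, pep$base_sequence)
    expect_equal(reparsed$mods$code, pep$mods$code)
    expect_equal(reparsed$mods$position, pep$mods$position)
    # stripping the codes from tokens reproduces the base sequence
    expect_equal(paste(sub("-.*$", "", tokenize(pep)), collapse = ""),
                 pep$base_sequence)
    expect_length(tokenize(pep), len)
  }
})

test_that("parsing is whitespace-invariant", {
  variants <- c("GILGFVFTL + OTH(L9)",
                "GILGFVFTL+OTH(L9)",
                "GILGFVFTL  +  OTH( L9 )",
                " GILGFVFTL + OTH(L9) ")
  parsed <- lapply(variants, parse_epitope_name)
  for (p in parsed[-1]) expect_identical(p, parsed[[1]])
})

test_that("peptide list files read one name per line, skipping comments", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# header comment", "GILGFVFTL + OTH(L9)", "", "SIINFEKL"), path)
  peps <- read_peptide_list(path)
  expect_length(peps, 2L)
  expect_equal(peps[[1]]$base_sequence, "GILGFVFTL")
  expect_equal(names(peps)[2], "SIINFEKL")
})
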