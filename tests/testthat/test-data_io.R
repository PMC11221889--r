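test_that("mutation strings parse into chain/wt/pos/mt rows", {
  m <- parse_mutation_string("A:Y32W")
  expect_equal(m$chain, "A")
  expect_equal(m$wt, "Y")
  expect_equal(m$pos, 32L)
  expect_equal(m$mt, "W")

  m3 <- parse_mutation_string("A:S56M, A:L97W ,A:T99V")
  expect_equal(nrow(m3), 3L)
  expect_equal(m3$wt, c("S", "L", "T"))
  expect_equal(m3$pos, c(56L, 97L, 99L))
  expect_equal(m3$mt, c("M", "W", "V"))

  sk <- parse_mutation_string("YA32W", style = "skempi")
  expect_equal(sk, parse_mutation_string("A:Y32W"))
})

test_that("malformed mutation tokens are rejected with the token named", {
  expect_error(parse_mutation_string("A:32W"), "A:32W")
  expect_error(parse_mutation_string("Y32W"), "malformed")
  expect_error(parse_mutation_string("A:Y32Y"), "identical")
  expect_error(parse_mutation_string("A:B32W"), "invalid residue")
  expect_error(parse_mutation_string(""), "empty")
})

test_that("apply_mutations substitutes and guards wild-type identity", {
  expect_equal(apply_mutations(c(A = "AYC"), parse_mutation_string("A:Y2W")),
               c(A = "AWC"))
  muts0 <- parse_mutation_string("A:Y2W")[0, ]
  expect_equal(apply_mutations(c(A = "AYC"), muts0), c(A = "AYC"))
  expect_error(apply_mutations(c(A = "AYC"), parse_mutation_string("A:G2W")),
               "expected 'G', found 'Y'")
  expect_error(apply_mutations(c(A = "AYC"), parse_mutation_string("A:Y9W")),
               "out of range")
  expect_error(apply_mutations(c(A = "AYC"), parse_mutation_string("B:Y2W")),
               "unknown chain")
})

test_that("mutation application round-trips under wt/mt reversal", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      chains <- c(H = paste(sample(seqddg:::AA_ALPHABET, 30, TRUE),
                            collapse = ""),
                  A = paste(sample(seqddg:::AA_ALPHABET, 20, TRUE),
                            collapse = ""))
      pos <- sample(1:20, 3)
      ch <- sample(c("H", "A"), 3, TRUE)
      wt <- vapply(seq_len(3), function(i)
        substr(chains[[ch[i]]], pos[i], pos[i]), character(1))
      mt <- vapply(wt, function(w)
        sample(setdiff(seqddg:::AA_ALPHABET, w), 1), character(1))
      fwd <- data.frame(chain = ch, wt = wt, pos = pos, mt = mt)
      fwd <- fwd[!duplicated(fwd[c("chain", "pos")]), ]
      mutated <- apply_mutations(chains, fwd)
      rev <- data.frame(chain = fwd$chain, wt = fwd$mt, pos = fwd$pos,
                        mt = fwd$wt)
      expect_equal(apply_mutations(mutated, rev), chains)
    }
  })
})

test_that("FASTA reading uppercases, keeps order, and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ac", "de", ">b desc", "WWW"), f)
  got <- read_fasta(f)
  expect_equal(got, c(a = "ACDE", b = "WWW"))

  writeLines(c(">a", "AC-E"), f)
  expect_error(read_fasta(f), "illegal residue")
  writeLines(c(">a", "ACD", ">a", "ACD"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("canonical CSV round-trips a generated dataset deterministically", {
  gen <- small_dataset()
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(gen$dataset, f)
  ds1 <- load_dataset(f, "synthetic", quiet = TRUE)
  ds2 <- load_dataset(f, "synthetic", quiet = TRUE)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
  expect_equal(ds1$ddg, gen$dataset$ddg)
  expect_equal(ds1$mutations, gen$dataset$mutations)
  expect_equal(nrow(ds1), 8L)
  expect_equal(length(unique(ds1$complex_id)), 2L)
})

test_that("every loaded record passes the wild-type-identity invariant", {
  gen <- small_dataset(n_complexes = 3L, mutations_per_complex = 5L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(gen$dataset, f)
  ds <- load_dataset(f, "synthetic", quiet = TRUE)
  for (i in seq_len(nrow(ds))) {
    rec <- dataset_record(ds, i)
    chains <- c(rec$ab_chains, rec$ag_chains)
    for (k in seq_len(nrow(rec$mutations))) {
      mu <- rec$mutations[k, ]
      expect_equal(substr(chains[[mu$chain]], mu$pos, mu$pos), mu$wt)
    }
  }
})

test_that("invalid rows are reported with their row number", {
  gen <- small_dataset()
  df <- as.data.frame(gen$dataset)
  df$mutations[3] <- "H:W1W"  # wt == mt
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(load_dataset(f, "synthetic", quiet = TRUE), "row 3")
  expect_warning(ds <- load_dataset(f, "synthetic", strict = FALSE,
                                    quiet = TRUE), "row 3")
  expect_equal(nrow(ds), nrow(df) - 1L)
})

test_that("per-chain offsets map author numbering onto sequence positions", {
  df <- data.frame(complex_id = "CX", ab_chains = "H", ag_chains = "A",
                   ab_seq = "AYC", ag_seq = "MKT",
                   mutations = "H:Y32W", ddg = 1.0,
                   offsets = "H:30;A:0", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  ds <- load_dataset(f, "synthetic", quiet = TRUE)
  expect_equal(dataset_record(ds, 1)$mutations$pos, 2L)
})

test_that("abbind and skempi dialect configs drive column mapping", {
  df <- data.frame("#PDB" = "1ABC", ab_chains = "H;L", ag_chains = "A",
                   ab_seq = "AYC;MK", ag_seq = "WWTM",
                   Mutation = "L:K2R", "ddG(kcal/mol)" = -0.5,
                   check.names = FALSE, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  ds <- load_dataset(f, "abbind", quiet = TRUE)
  expect_equal(attr(ds, "provenance"), "abbind")
  rec <- dataset_record(ds, 1)
  expect_equal(names(rec$ab_chains), c("H", "L"))
  expect_equal(rec$ddg, -0.5)

  df2 <- data.frame("#Pdb" = "1CSE", ab_chains = "I", ag_chains = "E",
                    ab_seq = "KYTM", ag_seq = "AAC",
                    "Mutation(s)_cleaned" = "YI2F", ddG = 0.7,
                    check.names = FALSE, stringsAsFactors = FALSE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(df2, f2, sep = ";", row.names = FALSE, qmethod = "double")
  ds2 <- load_dataset(f2, "skempi", quiet = TRUE)
  expect_equal(dataset_record(ds2, 1)$mutations,
               parse_mutation_string("I:Y2F"))
})
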