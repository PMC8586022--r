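test_that("kmer enumeration covers the alphabet power deterministically", {
  expect_length(enumerate_kmers(alpha_dna(), 6), 4096)
  expect_length(enumerate_kmers(alpha_dna("5mC"), 6), 15625)
  expect_identical(enumerate_kmers(alphabet("A", "DNA"), 1), "A")
  k3 <- enumerate_kmers(alpha_dna(), 3)
  expect_identical(k3[1:5], c("AAA", "AAT", "AAC", "AAG", "ATA"))
  expect_false(anyDuplicated(k3) > 0)
  expect_identical(k3, enumerate_kmers(alpha_dna(), 3))  # stable
  # declared base order, not ASCII order, drives the enumeration
  expect_identical(enumerate_kmers(alphabet(c("G", "A"), "DNA"), 2),
                   c("GG", "GA", "AG", "AA"))
})

test_that("alphabet validation enforces type and symbol rules", {
  expect_error(alphabet(c("A", "Z"), "DNA"), "unknown base")
  expect_error(alphabet(c("A", "A"), "DNA"), "unique")
  expect_error(alphabet(c("A", "U"), "DNA"), "RNA")
  expect_error(alphabet(c("A", "T"), "RNA"), "DNA")
  expect_error(enumerate_kmers(alpha_dna(), 0), "positive")
})

test_that("kmer string round trip handles modified bases and dialects", {
  sym <- kmer_symbols("GT[5mC]AGA")
  expect_identical(drop(sym), c("G", "T", "5mC", "A", "G", "A"))
  expect_identical(symbols_to_kmer(sym), "GT[5mC]AGA")
  expect_identical(drop(kmer_symbols("GTMAGA", dialect = "nanopolish")),
                   c("G", "T", "5mC", "A", "G", "A"))
  expect_identical(symbols_to_kmer(sym, dialect = "nanopolish"), "GTMAGA")
  expect_error(kmer_symbols("G[5m"), "unterminated")
  expect_error(kmer_symbols(c("AAA", "AATT")), "mixed")
})

test_that("random_split uses floor and is seed-reproducible", {
  rna <- enumerate_kmers(alpha_rna(), 5)
  dna <- enumerate_kmers(alpha_dna(), 6)
  expect_length(random_split(rna, 0.95, 7)$train, 972)
  expect_length(random_split(dna, 0.25, 7)$train, 1024)
  s1 <- random_split(dna, 0.40, 123)
  s2 <- random_split(dna, 0.40, 123)
  expect_identical(s1$train, s2$train)
  expect_false(identical(s1$train, random_split(dna, 0.40, 124)$train))
  expect_error(random_split(dna, 1.2, 1), "fraction")
  expect_error(random_split(character(0), 0.5, 1), "empty")
})

test_that("dropout-style splits match closed-form counts and brute force", {
  for (k in 2:4) {
    alpha <- alpha_rna()
    B <- length(alpha$bases)
    all_k <- enumerate_kmers(alpha, k)
    bd <- base_dropout_split(alpha, k, "G")
    expect_length(bd$train, (B - 1)^k)
    expect_identical(sort(c(bd$train, bd$test)), sort(all_k))
    expect_length(intersect(bd$train, bd$test), 0)
    expect_false(any(grepl("G", bd$train, fixed = TRUE)))
    pd <- position_dropout_split(alpha, k, "C", 1)
    expect_length(pd$test, B^(k - 1))
    expect_true(all(substr(pd$test, 1, 1) == "C"))
    expect_identical(sort(c(pd$train, pd$test)), sort(all_k))
    cb <- combination_split(alpha, k, "A", "U")
    expect_length(cb$train, 2 * (B - 1)^k - (B - 2)^k)
    expect_identical(sort(c(cb$train, cb$test)), sort(all_k))
    has_both <- grepl("A", all_k, fixed = TRUE) & grepl("U", all_k, fixed = TRUE)
    expect_identical(sort(cb$test), sort(all_k[has_both]))
  }
  expect_error(base_dropout_split(alpha_dna(), 6, "U"), "not in alphabet")
  expect_error(position_dropout_split(alpha_dna(), 6, "A", 7), "position")
  expect_error(combination_split(alpha_dna(), 6, "A", "A"), "differ")
  # k = 1 degenerate cases
  expect_identical(base_dropout_split(alpha_dna(), 1, "A")$test, "A")
  expect_identical(position_dropout_split(alpha_dna(), 1, "A", 1)$test, "A")
})

test_that("imputation split covers the universe at every fraction", {
  canon <- enumerate_kmers(alpha_dna(), 3)
  ext <- enumerate_kmers(alpha_dna("5mC"), 3)
  modif <- setdiff(ext, canon)
  s0 <- imputation_split(canon, modif, 0, 1)
  expect_identical(sort(s0$train), sort(canon))  # de novo design
  expect_identical(sort(s0$test), sort(modif))
  s1 <- imputation_split(canon, modif, 1, 1)
  expect_length(s1$test, 0)
  s <- imputation_split(canon, modif, 0.3, 5)
  expect_length(s$train, length(canon) + floor(0.3 * length(modif)))
  expect_identical(sort(c(s$train, s$test)), sort(ext))
  expect_identical(s$train, imputation_split(canon, modif, 0.3, 5)$train)
  expect_error(imputation_split(canon, ext, 0.5, 1), "overlap")
  expect_error(imputation_split(canon, modif, 1.5, 1), "fraction")
})

test_that("count_containing matches brute-force enumeration", {
  for (k in 2:4) {
    alpha <- alpha_dna("5mC")
    kmers <- enumerate_kmers(alpha, k)
    sym <- kmer_symbols(kmers)
    for (b in c("A", "5mC")) {
      expect_identical(count_containing(alpha, k, b),
                       sum(rowSums(sym == b) > 0))
      for (m in 0:k)
        expect_identical(count_containing(alpha, k, b, exactly = m),
                         sum(rowSums(sym == b) == m))
    }
  }
  expect_error(count_containing(alpha_dna(), 6, "5mC"), "not in alphabet")
})
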