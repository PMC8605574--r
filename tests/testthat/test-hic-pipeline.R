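test_that("digestion cuts at the first motif base", {
  a <- DNAStringSet(c(chr1 = "AAAGATCAAA"))
  rm <- digest_genome(a)
  expect_equal(rm$frag_start$chr1, c(0L, 3L))   # fragments [0,3) [3,10)
  expect_equal(rm$n_fragments, 2L)

  a2 <- DNAStringSet(c(chr1 = "GATCGATC"))
  rm2 <- digest_genome(a2)
  expect_equal(rm2$frag_start$chr1, c(0L, 4L))  # [0,4) [4,8): cut at 0 is the end

  a3 <- DNAStringSet(c(chr1 = "AAAAAAAA"))
  expect_equal(digest_genome(a3)$n_fragments, 1L)
})

test_that("fragment assignment matches a linear-scan oracle", {
  a <- random_assembly(c(chrA = 30000L, chrB = 20000L), seed = 50L)
  rm <- digest_genome(a)
  # cut-site position belongs to the downstream fragment; position 0 to the first
  cut1 <- rm$frag_start$chrA[2]
  expect_equal(assign_fragment(rm, "chrA", cut1), 2L)
  expect_equal(assign_fragment(rm, "chrA", 0L), 1L)
  expect_error(assign_fragment(rm, "chrA", 30000L), "out of bounds")

  withr::with_seed(9, {
    ch <- sample(c("chrA", "chrB"), 2000, replace = TRUE)
    pos <- floor(runif(2000) * (chrom_lengths(a)[ch] - 1))
  })
  got <- assign_fragment(rm, ch, pos)
  oracle <- vapply(seq_along(ch), function(i) {
    st <- rm$frag_start[[ch[i]]]
    j <- max(which(st <= pos[i]))
    rm$offset[[ch[i]]] + j
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("pair classification distinguishes the three product classes", {
  a <- DNAStringSet(c(chr1 = paste0(strrep("A", 100), "GATC", strrep("A", 100),
                                    "GATC", strrep("A", 100))))
  rm <- digest_genome(a)     # fragments [0,100) [100,204) [204,308)
  pairs <- data.frame(
    chrom1 = "chr1", pos1 = c(10L, 10L, 10L, 10L, 110L),
    strand1 = c("+", "+", "-", "+", "+"),
    chrom2 = "chr1", pos2 = c(150L, 50L, 50L, 50L, 250L),
    strand2 = c("-", "-", "+", "+", "+"), stringsAsFactors = FALSE)
  out <- classify_pairs(pairs, rm)
  # different fragments -> valid; same fragment inward (+/-) -> non_ligation;
  # same fragment outward (-/+) or equal strands -> self_ligation
  expect_equal(out$pairs$class,
               c("valid", "non_ligation", "self_ligation", "self_ligation",
                 "valid"))
  expect_equal(unname(out$census),
               c(2L, 2L, 1L)[match(names(out$census),
                                   c("valid", "self_ligation", "non_ligation"))])
})

test_that("classification census matches the generator's construction", {
  cfg <- small_config(seed = 61L, n_pairs = 1000)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  rm <- digest_genome(g$assembly)
  out <- classify_pairs(h$pairs, rm)
  # truth: class is determined by fragment identity and strands
  f1 <- assign_fragment(rm, h$pairs$chrom1, h$pairs$pos1)
  f2 <- assign_fragment(rm, h$pairs$chrom2, h$pairs$pos2)
  expect_equal(sum(out$census), 1000L)
  expect_equal(unname(out$census[["valid"]]), sum(f1 != f2))
})

test_that("proportional binning splits reads by base overlap", {
  a <- c(chr1 = 1000L)
  # 75-bp read fully inside bin 1
  p1 <- data.frame(chrom1 = "chr1", pos1 = 10L, strand1 = "+",
                   chrom2 = "chr1", pos2 = 500L, strand2 = "+",
                   stringsAsFactors = FALSE)
  cm <- bin_pairs(p1, a, bin_size = 100L, read_len = 75L)
  expect_equal(cm$matrix[1, 6], 1)
  expect_equal(matrix_mass(cm), 1)

  # read [70, 145): 30 bp in bin 1, 45 bp in bin 2 -> 0.4 / 0.6
  p2 <- data.frame(chrom1 = "chr1", pos1 = 70L, strand1 = "+",
                   chrom2 = "chr1", pos2 = 500L, strand2 = "+",
                   stringsAsFactors = FALSE)
  cm2 <- bin_pairs(p2, a, bin_size = 100L, read_len = 75L)
  expect_equal(cm2$matrix[1, 6], 0.4)
  expect_equal(cm2$matrix[2, 6], 0.6)

  # minus-strand 5' end at 144 spans [70, 145) as well
  p3 <- p2; p3$pos1 <- 144L; p3$strand1 <- "-"
  cm3 <- bin_pairs(p3, a, bin_size = 100L, read_len = 75L)
  expect_equal(cm3$matrix[1, 6], 0.4)
})

test_that("binning conserves total mass and is order-invariant", {
  cfg <- small_config(seed = 62L, n_pairs = 10000)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  cm <- bin_pairs(h$pairs, g$assembly)
  expect_equal(matrix_mass(cm), 10000, tolerance = 1e-9)
  expect_true(isSymmetric(cm$matrix))

  withr::with_seed(3, perm <- sample.int(nrow(h$pairs)))
  cm2 <- bin_pairs(h$pairs[perm, ], g$assembly)
  expect_equal(cm2$matrix, cm$matrix, tolerance = 1e-9)
})

test_that("balancing normalizes marginals, preserves symmetry, masks zero rows", {
  ones <- contact_matrix(matrix(1, 2, 2), c(chr1 = 20L), 10L)
  b <- balance_matrix(ones)
  expect_equal(b$matrix, matrix(0.5, 2, 2))

  m <- matrix(c(4, 1, 0, 1, 3, 0, 0, 0, 0), 3, 3)
  cm <- contact_matrix(m, c(chr1 = 30L), 10L)
  b <- balance_matrix(cm)
  expect_true(b$mask[3])
  expect_equal(b$matrix[3, ], rep(0, 3))
  rs <- rowSums(b$matrix[1:2, 1:2])
  expect_lt(max(abs(rs - 1)), 1e-8)
  expect_true(isSymmetric(b$matrix))

  # idempotence: balancing a balanced matrix returns it unchanged
  b2 <- balance_matrix(b)
  expect_identical(b2$matrix, b$matrix)
})

test_that("balancing agrees with a long-run naive alternating oracle", {
  withr::with_seed(77, {
    n <- 50
    m <- matrix(runif(n * n, 0.1, 2), n, n)
    m <- m + t(m)
  })
  cm <- contact_matrix(m, c(chr1 = 500L), 10L)
  b <- balance_matrix(cm, tol = 1e-12, max_iter = 10000)
  oracle <- brute_balance(m, iters = 5000)
  expect_lt(max(abs(b$matrix - oracle)), 1e-6)
})

test_that("non-convergence is reported, not hidden", {
  withr::with_seed(5, {
    m <- matrix(runif(64, 1e-4, 10), 8, 8)
    m <- m + t(m)
  })
  cm <- contact_matrix(m, c(chr1 = 80L), 10L)
  expect_warning(b <- balance_matrix(cm, tol = 1e-12, max_iter = 2L),
                 "did not converge")
  expect_false(b$balance$converged)
})

test_that("contact probability accessor is symmetric and NA on masked bins", {
  m <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 0), 3, 3)
  b <- balance_matrix(contact_matrix(m, c(chr1 = 30L), 10L))
  expect_equal(contact_probability(b, 1, 2), contact_probability(b, 2, 1))
  expect_equal(contact_probability(b, 1, 1), b$matrix[1, 1])
  expect_true(is.na(contact_probability(b, 1, 3)))
  raw <- contact_matrix(m, c(chr1 = 30L), 10L)
  expect_error(contact_probability(raw, 1, 2), "not balanced")
})

test_that("contact matrices round trip through the text format", {
  cfg <- small_config(seed = 63L, n_pairs = 5000)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  b <- balance_matrix(bin_pairs(h$pairs, g$assembly))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(b, f)
  back <- read_contact_matrix(f)
  expect_equal(back$matrix, b$matrix, tolerance = 1e-15)
  expect_identical(back$mask, b$mask)
  expect_identical(back$state, "balanced")
  expect_identical(back$bin_size, b$bin_size)
})

test_that("the balanced map correlates with the generator's ground truth", {
  cfg <- synthetic_config(seed = 64L, n_chrom = 6L, n_pairs = 4e5)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  cl <- classify_pairs(h$pairs, digest_genome(g$assembly))
  emp <- balance_matrix(bin_pairs(cl$pairs[cl$pairs$class == "valid", ],
                                  g$assembly))
  tr <- h$truth; tr$state <- "raw"
  trb <- balance_matrix(tr)
  ok <- !emp$mask
  ut <- upper.tri(emp$matrix) & outer(ok, ok)
  expect_gt(cor(emp$matrix[ut], trb$matrix[ut]), 0.9)
})
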