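test_that("generators are deterministic given one config", {
  cfg <- small_config(seed = 5L)
  g1 <- make_genome(cfg); g2 <- make_genome(cfg)
  expect_identical(as.character(g1$assembly), as.character(g2$assembly))
  expect_identical(g1$ntbs, g2$ntbs)

  t1 <- make_chip_replicates(g1$assembly, g1$ntbs, cfg, n_reps = 2)
  t2 <- make_chip_replicates(g2$assembly, g2$ntbs, cfg, n_reps = 2)
  expect_identical(t1, t2)

  cfg$n_pairs <- 2000
  h1 <- make_hic_pairs(g1$assembly, g1$ntbs, cfg)
  h2 <- make_hic_pairs(g2$assembly, g2$ntbs, cfg)
  expect_identical(h1$pairs, h2$pairs)
  expect_identical(h1$planted, h2$planted)
})

test_that("planted genome has the configured background and site GC", {
  cfg <- synthetic_config(seed = 2L, n_chrom = 5L, chrom_length_bp = 200000L,
                          n_ntbs = 20L)
  g <- make_genome(cfg)
  expect_equal(gc_content(NULL, g$assembly), 0.38, tolerance = 0.01)  # 1 Mb
  expect_equal(gc_content(g$ntbs, g$assembly), 0.52, tolerance = 0.02)
  # planted sites avoid the telomere windows
  tel <- telomere_windows(g$assembly, cfg$telomere_window_bp)
  expect_equal(count_site_overlaps(g$ntbs, tel), 0L)
  # sites occupy distinct contact-map bins
  mid <- (start(g$ntbs) - 1 + end(g$ntbs)) %/% 2
  bins <- paste(seqnames(g$ntbs), mid %/% cfg$bin_size)
  expect_equal(anyDuplicated(bins), 0L)
})

test_that("feature tracks hit exactly the requested overlap count", {
  cfg <- small_config(seed = 3L)
  g <- make_genome(cfg)
  for (k in c(0L, 3L, 8L)) {
    fe <- make_feature_track(g$ntbs, g$assembly, n_features = 20L,
                             n_overlapping = k, seed = 99L)
    expect_length(fe, 20L)
    expect_equal(count_site_overlaps(g$ntbs, fe), k)
    expect_equal(count_site_overlaps(fe, g$ntbs), k)
  }
  expect_error(make_feature_track(g$ntbs, g$assembly, 5L, 9L))
})

test_that("probe tracks carry planted peaks subject to per-replicate dropout", {
  cfg <- small_config(seed = 8L, replicate_detect_prob = 1)
  g <- make_genome(cfg)
  tracks <- make_chip_replicates(g$assembly, g$ntbs, cfg, n_reps = 3)
  amp <- cfg$peak_amplitude * cfg$noise_sd
  for (tr in tracks) {
    gr <- GRanges(tr$chrom, IRanges(tr$start + 1L, tr$end))
    inside <- overlapsAny(gr, g$ntbs)
    # with detect_prob 1 every planted probe is elevated in every replicate
    expect_gt(min(tapply(tr$log2_ratio[inside],
                         subjectHits(findOverlaps(gr[inside], g$ntbs)), mean)),
              amp / 2)
    expect_lt(abs(mean(tr$log2_ratio[!inside])), 0.02)
  }

  flat <- make_chip_replicates(g$assembly, g$ntbs,
                               small_config(seed = 8L, peak_amplitude = 0),
                               n_reps = 2)
  expect_equal(sd(flat[[1]]$log2_ratio), cfg$noise_sd, tolerance = 0.05)
  expect_lt(abs(mean(flat[[1]]$log2_ratio)), 0.02)
})

test_that("probe tracks round trip through the tab-delimited format", {
  cfg <- small_config(seed = 4L)
  g <- make_genome(cfg)
  tracks <- make_chip_replicates(g$assembly, g$ntbs, cfg, n_reps = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_probe_tracks(tracks, f)
  back <- read_probe_tracks(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$log2_ratio, tracks[[1]]$log2_ratio)
  expect_equal(back[[2]]$start, tracks[[2]]$start)
})

test_that("healing counts follow the binomial model", {
  expect_equal(make_healing_counts(c(TG80 = 1), 200, seed = 1)$resistant, 200L)
  expect_equal(make_healing_counts(c(N80 = 0), 200, seed = 1)$resistant, 0L)
  # freq 0.125, n = 400: within +/- 2 sd of the binomial mean (50 +/- 13)
  x <- make_healing_counts(c(site = 0.125), 400, seed = 7)$resistant
  expect_gte(x, 37L); expect_lte(x, 63L)
})

test_that("Hi-C pair generator emits the exact pair count and truth labels", {
  cfg <- small_config(seed = 6L, n_pairs = 3000)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  expect_equal(nrow(h$pairs), 3000L)
  expect_equal(sum(h$planted), ceiling(0.14 * length(g$ntbs)))
  expect_named(h$planted, names(g$ntbs))

  h0 <- make_hic_pairs(g$assembly, g$ntbs,
                       small_config(seed = 6L, n_pairs = 1000,
                                    planted_tel_fraction = 0))
  expect_equal(sum(h0$planted), 0L)

  # pairs survive classification as predominantly valid products
  cl <- classify_pairs(h$pairs, digest_genome(g$assembly))
  expect_gte(cl$census[["valid"]] / nrow(h$pairs), 0.95)

  # strong decay limit: contacts collapse toward the diagonal
  steep <- make_hic_pairs(g$assembly, g$ntbs,
                          small_config(seed = 6L, n_pairs = 5000,
                                       decay_exponent = 4))
  intra_dist <- function(h) {
    same <- h$pairs$chrom1 == h$pairs$chrom2
    mean(abs(h$pairs$pos1 - h$pairs$pos2)[same])
  }
  expect_lt(intra_dist(steep), intra_dist(h))
  d <- with(steep$pairs[steep$pairs$chrom1 == steep$pairs$chrom2, ],
            abs(pos1 - pos2))
  expect_gt(mean(d <= cfg$bin_size), 0.5)
})

test_that("pair tables round trip through the BEDPE-like format", {
  cfg <- small_config(seed = 6L, n_pairs = 500)
  g <- make_genome(cfg)
  h <- make_hic_pairs(g$assembly, g$ntbs, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(h$pairs, f)
  expect_identical(read_pairs(f), h$pairs[, c("chrom1", "pos1", "strand1",
                                              "chrom2", "pos2", "strand2")])
})
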