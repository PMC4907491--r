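test_that("a 41-bp reference yields exactly its single eligible position", {
  ref <- simulate_reference(41, seed = 6)
  cfg <- pool_config(strata = c("0" = 1), seed = 1)
  pool <- build_pool(ref, list(), cfg)
  expect_equal(nrow(pool$instances), 1L)
  expect_equal(pool$instances$pos, 20L)
  expect_equal(pool$instances$freq, 0L)
  expect_equal(pool$instances$window, ref$seq)
})

test_that("exhausted strata yield fewer instances with a warning", {
  ref <- simulate_reference(200, seed = 2)
  track <- read_start_track(ref$name, positions = 50L, counts = 3L)
  cfg <- pool_config(strata = c("0" = 5, "11+" = 5), seed = 1)
  expect_warning(pool <- build_pool(ref, track, cfg), "11\\+")
  expect_equal(sum(pool$instances$stratum == "11+"), 0L)
  expect_equal(sum(pool$instances$stratum == "0"), 5L)
})

test_that("per-stratum counts equal min(requested, available) by exhaustive scan", {
  sim <- simulate_biased(length = 50000, beta = 0, n_reads = 10000, seed = 17)
  cfg <- pool_config(scale = 0.1, seed = 5)
  pool <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))

  # independent brute-force enumeration of every position's class
  freq <- integer(50000)
  freq[sim$track$positions + 1L] <- sim$track$counts
  chars <- strsplit(sim$ref$seq, "")[[1]]
  eligible <- vapply(21:(50000 - 20), function(p1) {
    !any(chars[(p1 - 20):(p1 + 20)] == "N")
  }, logical(1))
  avail_freq <- freq[21:(50000 - 20)][eligible]
  cls <- ifelse(avail_freq >= 11, "11+", as.character(avail_freq))
  avail <- table(cls)

  got <- table(pool$instances$stratum)
  for (s in names(cfg$strata)) {
    expect_equal(tab_count(got, s), min(cfg$strata[[s]], tab_count(avail, s)),
                 label = paste("stratum", s))
  }
})

test_that("pool windows match the reference substring exactly", {
  sim <- simulate_biased(length = 5000, beta = 5, n_reads = 2000, seed = 23)
  cfg <- pool_config(strata = c("0" = 50, "1" = 20, "11+" = 10), seed = 9)
  pool <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))
  expect_true(all(nchar(pool$instances$window) == 41L))
  for (i in seq_len(nrow(pool$instances))) {
    p <- pool$instances$pos[i]
    expect_equal(pool$instances$window[i], substr(sim$ref$seq, p - 19, p + 21))
  }
  # window center is the base at the selected position (the 21st feature)
  centers <- substr(pool$instances$window, 21, 21)
  at_pos <- substr(rep(sim$ref$seq, nrow(pool$instances)),
                   pool$instances$pos + 1, pool$instances$pos + 1)
  expect_equal(centers, at_pos)
})

test_that("pooling is deterministic given the seed", {
  sim <- simulate_biased(length = 10000, beta = 2, n_reads = 5000, seed = 3)
  cfg <- pool_config(scale = 0.02, seed = 42)
  p1 <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))
  p2 <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))
  expect_identical(p1$instances, p2$instances)
})

test_that("global distributions match hand enumeration", {
  expect_equal(unname(global_distribution(reference_sequence("x", "ACGT"), 1)$freqs),
               rep(0.25, 4))
  d2 <- global_distribution(reference_sequence("x", "AAAA"), 2)
  expect_equal(unname(d2$freqs["AA"]), 1)
  expect_equal(sum(d2$freqs), 1)
  # ACGTACGT tetramers: ACGT x2, CGTA, GTAC, TACG of 5 total
  d4 <- global_distribution(reference_sequence("x", "ACGTACGT"), 4)
  expect_equal(unname(d4$freqs["ACGT"]), 2 / 5)
  expect_equal(unname(d4$freqs["CGTA"]), 1 / 5)
  expect_equal(unname(d4$freqs["GTAC"]), 1 / 5)
  expect_equal(unname(d4$freqs["TACG"]), 1 / 5)
  expect_error(global_distribution(reference_sequence("x", "NNNN"), 1),
               "no countable")
})

test_that("distance table reproduces closed-form displacements", {
  # identical local and global distributions: distance 0
  pool <- make_pool(strrep("A", 41), freqs = 0)
  gm <- kmer_distribution(1, c(A = 1, C = 0, G = 0, T = 0) + 1e-12)
  gd <- kmer_distribution(2, stats::setNames(c(1, rep(0, 15)) + 1e-12,
                                             startbias_all_kmers(2)))
  tab <- pool_distance_table(pool, gm, gd)
  expect_equal(tab$distance[tab$group == "0"], 0, tolerance = 1e-6)

  # local mono (1,0,0,0) vs global (0,1,0,0), di terms equal: sqrt(2)
  gm2 <- kmer_distribution(1, c(A = 0, C = 1, G = 0, T = 0) + 1e-12)
  tab2 <- pool_distance_table(pool, gm2, gd)
  expect_equal(tab2$distance[tab2$group == "0"], sqrt(2), tolerance = 1e-6)

  # mono displacement (0.5,0.5,0,0) vs uniform with identical di: 0.5
  pool3 <- make_pool(c(strrep("A", 41), strrep("C", 41)), freqs = c(0, 0))
  gm3 <- uniform_distribution(1)
  gd3 <- kmer_distribution(2, stats::setNames(
    c(0.5, rep(0, 4), 0.5, rep(0, 10)), startbias_all_kmers(2)))
  tab3 <- pool_distance_table(pool3, gm3, gd3)
  expect_equal(tab3$distance[tab3$group == "0"], 0.5, tolerance = 1e-9)

  # empty groups carry a missing marker
  expect_true(is.na(tab$distance[tab$group == "11+"]))
})

test_that("GC table matches hand counts", {
  pool <- make_pool(strrep("G", 41), freqs = 0)
  expect_equal(pool_gc_table(pool)$gc[1], 1)
  pool2 <- make_pool(paste(rep(c("A", "T"), length.out = 41), collapse = ""), 0)
  expect_equal(pool_gc_table(pool2)$gc[1], 0)
  # two windows with 20 and 21 G+C of 41 each: 41/82 = 0.5
  w1 <- paste0(strrep("G", 20), strrep("A", 21))
  w2 <- paste0(strrep("C", 21), strrep("T", 20))
  pool3 <- make_pool(c(w1, w2), c(0, 0))
  expect_equal(pool_gc_table(pool3)$gc[1], 0.5)
})

test_that("group distances grow with bias and shrink to zero without it", {
  # beta > 0: group distance non-decreasing across 0 -> 1-5 -> 6-10 -> 11+
  # on average over seeds; beta = 0: all groups near zero
  dist_by_group <- function(beta, seed) {
    sim <- simulate_biased(length = 50000, order = 2, beta = beta,
                           n_reads = 1e5, seed = seed)
    pool <- suppressWarnings(build_pool(sim$ref, sim$track,
                                        pool_config(scale = 0.1, seed = seed)))
    tab <- pool_distance_table(pool, global_distribution(sim$ref, 1),
                               global_distribution(sim$ref, 2))
    stats::setNames(tab$distance, tab$group)
  }
  biased <- rowMeans(vapply(1:3, function(s) dist_by_group(20, s), numeric(4)))
  expect_true(all(diff(biased) >= 0))

  # groups small enough to be dominated by sampling noise are excluded:
  # the null distance only converges to 0 as the group grows
  sim <- simulate_biased(length = 50000, order = 2, beta = 0,
                         n_reads = 1e5, seed = 4)
  pool <- suppressWarnings(build_pool(sim$ref, sim$track,
                                      pool_config(scale = 0.1, seed = 4)))
  tab <- pool_distance_table(pool, global_distribution(sim$ref, 1),
                             global_distribution(sim$ref, 2))
  big <- tab$n >= 100
  expect_true(any(big))
  expect_true(all(tab$distance[big] < 0.05))
})

test_that("pool TSV round-trips", {
  sim <- simulate_biased(length = 3000, beta = 4, n_reads = 2000, seed = 12)
  cfg <- pool_config(strata = c("0" = 30, "1" = 10, "11+" = 10), seed = 2)
  pool <- suppressWarnings(build_pool(sim$ref, sim$track, cfg))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(pool, f)
  back <- read_pool_tsv(f)
  expect_equal(back$instances$pos, pool$instances$pos)
  expect_equal(back$instances$window, pool$instances$window)
  expect_equal(back$instances$freq, pool$instances$freq)
})
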