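test_that("simulate_genome is seeded, composition-true, and validated", {
  g1 <- simulate_genome(10000, gc = 0.5, seed = 3)
  g2 <- simulate_genome(10000, gc = 0.5, seed = 3)
  expect_identical(g1$seq, g2$seq)
  g3 <- simulate_genome(10000, gc = 0.5, seed = 4)
  expect_false(identical(g1$seq, g3$seq))
  # empirical GC within the binomial 99% CI of 0.5
  gc <- gc_content(g1)
  ci <- qnorm(0.995) * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(gc - 0.5), ci)
  expect_error(simulate_genome(10000, gc = 0), "strictly between")
  expect_error(simulate_genome(10000, gc = 1), "strictly between")
})

test_that("default_model encodes the dyad-proximal bias symmetrically", {
  m <- default_model()
  expect_gt(m$weights["G", "-3"], m$weights["A", "-3"])
  expect_equal(m$weights["G", "-3"], m$weights["C", "3"])
  expect_equal(m$weights["A", "-1"], m$weights["T", "1"])
  expect_true(is_rotationally_symmetric(m))
  expect_error(default_model(h = 2), "h must be >= 3")
})

test_that("the best-scoring central hexamers are exactly the GNATNC family", {
  # enumeration oracle over all 4^6 hexamers at offsets -3..+3
  m <- default_model(h = 3)
  bases <- c("A", "C", "G", "T")
  hexes <- do.call(expand.grid, rep(list(bases), 6))
  offs <- as.character(c(-3, -2, -1, 1, 2, 3))
  score <- rep(1, nrow(hexes))
  for (j in 1:6) {
    score <- score * m$weights[cbind(as.character(hexes[[j]]), offs[j])]
  }
  argmax <- which(score == max(score))
  hex_str <- apply(hexes, 1, paste, collapse = "")
  matches_gnatnc <- grepl("^G[ACGT]AT[ACGT]C$", hex_str)
  expect_identical(sort(hex_str[argmax]), sort(hex_str[matches_gnatnc]))
  expect_length(argmax, 16L)
})

test_that("site_probabilities matches a hand brute-force product", {
  g <- toy_genome(c(t = "GGATCCAAGATC"))  # 12 nt, h = 3: dyads 3..9
  m <- default_model(h = 3)
  p <- site_probabilities(g, m)[["t"]]
  chars <- strsplit(g$seq[["t"]], "", fixed = TRUE)[[1]]
  brute <- rep(0, 12)
  for (gd in 3:9) {
    idx <- c(gd - 2, gd - 1, gd, gd + 1, gd + 2, gd + 3)
    offs <- as.character(c(-3, -2, -1, 1, 2, 3))
    brute[gd] <- prod(m$weights[cbind(chars[idx], offs)])
  }
  brute <- brute / sum(brute)
  expect_equal(p, brute, tolerance = 1e-12)
  expect_equal(sum(p), 1)
})

test_that("uniform weights give uniform probabilities over valid dyads", {
  g <- simulate_genome(2000, seed = 5)
  M <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- cleavage_model(M)
  p <- site_probabilities(g, m)[["chrS"]]
  valid <- p > 0
  expect_equal(which(valid), 3:1997)
  expect_equal(unique(round(p[valid], 15)), round(1 / 1995, 15))
})

test_that("simulate_breaks conserves N and respects window bounds", {
  g <- simulate_genome(5000, seed = 6)
  m <- default_model()
  tr <- simulate_breaks(g, m, 1000, seed = 7)
  expect_equal(sum(tr$count), 1000)
  expect_true(all(tr$dyad >= m$h & tr$dyad <= 5000 - m$h))
  tr2 <- simulate_breaks(g, m, 1000, seed = 7)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("pure background is uniform over dyads", {
  g <- simulate_genome(50000, seed = 8)
  m <- default_model(beta = 1)
  tr <- simulate_breaks(g, m, 10000, seed = 9)
  counts <- rep(0L, 50000)
  counts[tr$dyad] <- tr$count
  valid <- 10:(50000 - 10)
  bins <- cut(valid, breaks = 50)
  binned <- tapply(counts[valid], bins, sum)
  p <- as.numeric(table(bins)) / length(valid)
  gof <- chisq.test(binned, p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("planted preference concentrates breaks at GNATNC dyads", {
  g <- simulate_genome(50000, seed = 10)
  m <- default_model(beta = 0)
  tr <- simulate_breaks(g, m, 5000, seed = 11)
  match_dyads <- scan_iupac(g, "GNATNC")$dyad
  frac_breaks <- sum(tr$count[tr$dyad %in% match_dyads]) / sum(tr$count)
  # genome-wide density of GNATNC-matching dyads, by brute force
  dens <- length(iupac_scan_oracle(g$seq[["chrS"]], "GNATNC")) /
    (50000 - 19)
  expect_gt(frac_breaks, dens)
  expect_gt(frac_breaks, 5 * dens)  # strongly, not marginally
})

test_that("simulate_tracks realizes the 2-nt 5'-overhang end geometry", {
  g <- toy_genome(c(p = strrep("ACGT", 25)))
  m0 <- default_model(h = 3, phi = 0)
  truth <- structure(data.frame(seqname = "p", dyad = 50L, count = 7L),
                     class = c("sim_truth", "data.frame"),
                     N = 7L, seed = 1L, model = m0)
  tr <- simulate_tracks(truth, g, seed = 2)
  expect_equal(tr$top[["p"]][50], 7)
  expect_equal(tr$bottom[["p"]][51], 7)
  expect_equal(sum(unlist(tr$top)) + sum(unlist(tr$bottom)), 14)

  # phi = 1, shift = 1: every end shifted by incomplete fill-in
  m1 <- default_model(h = 3, phi = 1, shift = 1)
  attr(truth, "model") <- m1
  tr1 <- simulate_tracks(truth, g, seed = 2)
  expect_equal(tr1$top[["p"]][51], 7)
  expect_equal(tr1$bottom[["p"]][50], 7)
  expect_equal(tr1$top[["p"]][50], 0)
})

test_that("count conservation holds through simulate_tracks", {
  for (circ in c(TRUE, FALSE)) {
    g <- simulate_genome(3000, seed = 12, circular = circ)
    m <- default_model(phi = 0.4)
    truth <- simulate_breaks(g, m, 2000, seed = 13)
    tr <- suppressWarnings(simulate_tracks(truth, g, seed = 14))
    total <- sum(unlist(tr$top)) + sum(unlist(tr$bottom))
    expect_equal(total, tr$total_mapped)
    if (circ) expect_equal(total, 2 * 2000)  # circular: nothing can drop
    else expect_lte(2 * 2000 - total, 4)     # linear-edge drops only
  }
})

test_that("ends shifted off a linear sequence are dropped with a warning", {
  g <- toy_genome(c(p = strrep("A", 20)))
  m <- cleavage_model(matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"),
                                                      NULL)),
                      phi = 1, shift = 25L)
  truth <- structure(data.frame(seqname = "p", dyad = 10L, count = 3L),
                     class = c("sim_truth", "data.frame"),
                     N = 3L, seed = 1L, model = m)
  expect_warning(tr <- simulate_tracks(truth, g, seed = 3), "dropped")
  expect_lt(tr$total_mapped, 6)
})

test_that("a symmetric model propagates rotational symmetry to composition", {
  # expected composition of top-strand windows at planted dyads is invariant
  # under reverse complement (symmetric model, symmetric base frequencies)
  d <- sim_dataset(N = 20000L, beta = 0, phi = 0, seed = 21L)
  pk <- structure(data.frame(seqname = d$truth$seqname, pos = d$truth$dyad,
                             strand = "top", signal = 1),
                  class = c("peak_set", "data.frame"))
  w <- suppressMessages(oriented_windows(pk, d$genome, h = 10))
  f <- base_composition(w)$fractions
  n <- length(w)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:10) {
    for (b in c("A", "C", "G", "T")) {
      f1 <- f[b, as.character(-k)]
      f2 <- f[comp[[b]], as.character(k)]
      se <- sqrt(f1 * (1 - f1) / n + f2 * (1 - f2) / n)
      expect_lt(abs(f1 - f2), 3 * se + 1e-12)
    }
  }
})

test_that("simulate_control replicates: same seed identical, total 2N", {
  g <- simulate_genome(20000, seed = 15)
  a <- simulate_control(g, 5000, seed = 16)
  b <- simulate_control(g, 5000, seed = 16)
  expect_identical(a$top, b$top)
  expect_identical(a$bottom, b$bottom)
  expect_equal(a$total_mapped, 10000)
  expect_equal(replicate_correlation(normalize_rpm(a), normalize_rpm(b)), 1)
})

test_that("cleavage_model validates its inputs", {
  M <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(cleavage_model(M * 0), "positive")
  expect_error(cleavage_model(M, beta = 1.5), "\\[0, 1\\]")
  expect_error(cleavage_model(matrix(1, 4, 5,
    dimnames = list(c("A", "C", "G", "T"), NULL))), "offsets")
  asym <- M; asym["G", 1] <- 2
  expect_false(is_rotationally_symmetric(cleavage_model(asym)))
})
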