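peakset <- function(seqname, pos, strand, signal = 1) {
  structure(data.frame(seqname = seqname, pos = pos, strand = strand,
                       signal = rep_len(signal, length(pos))),
            class = c("peak_set", "data.frame"))
}

test_that("top-strand windows put the assigned base at offset -1", {
  g <- toy_genome(c(p = "AAAGGATCCTTT"))
  pk <- peakset("p", 7L, "top")
  w <- oriented_windows(pk, g, h = 3)
  # genomic [q-2, q+3] = [5, 10] = "GATCCT"; dyad pair (7, 8)
  expect_identical(unname(w[1]), "GATCCT")
  # offset -1 base is the genomic base at q
  expect_identical(substr(w[1], 3, 3), substr(g$seq[["p"]], 7, 7))
})

test_that("bottom-strand windows are reverse-complemented around (q, q-1)", {
  g <- toy_genome(c(p = "AAAGGATCCTTT"))
  pk <- peakset("p", 6L, "bottom")
  w <- oriented_windows(pk, g, h = 3)
  # genomic [3, 8] = "AGGATC", reverse complement = "GATCCT";
  # offset -1 = complement of base at q=6 ("A" -> "T")
  expect_identical(unname(w[1]), "GATCCT")
  expect_identical(substr(w[1], 3, 3),
                   chartr("ACGT", "TGCA", substr(g$seq[["p"]], 6, 6)))
})

test_that("re-orienting a bottom window twice is an involution", {
  set.seed(12)
  g <- toy_genome(c(p = random_seq(200)))
  pk <- peakset("p", 100L, "bottom")
  w <- oriented_windows(pk, g, h = 8)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w[1], "")[[1]]),
                                     collapse = ""))
  expect_identical(chartr("ACGT", "TGCA",
                          paste(rev(strsplit(rc, "")[[1]]), collapse = "")),
                   unname(w[1]))
})

test_that("edge and N windows are dropped with a logged count", {
  g <- toy_genome(c(p = paste0(strrep("A", 30), "N", strrep("A", 30))))
  pk <- peakset("p", c(2L, 28L, 45L), c("top", "top", "top"))
  expect_message(w <- oriented_windows(pk, g, h = 10), "dropped 2")
  expect_length(w, 1L)
  expect_equal(attr(w, "n_dropped"), 2L)
  # circular wrap instead of dropping
  gc_ <- toy_genome(c(p = strrep("ACGT", 20)), circular = TRUE)
  pkc <- peakset("p", 2L, "top")
  expect_length(oriented_windows(pkc, gc_, h = 10), 1L)
  expect_error(oriented_windows(peakset(character(), integer(), character()),
                                g), "empty")
})

test_that("base_composition counts fractions per offset", {
  w <- c("ACGTAA", "AGGTAC")
  p <- base_composition(w)
  expect_equal(p$fractions["A", "-3"], 1)
  expect_equal(p$fractions["C", "-2"], 0.5)
  expect_equal(p$fractions["G", "-2"], 0.5)
  expect_equal(unname(colSums(p$fractions)), rep(1, 6))
  expect_equal(p$n, 2)
  expect_error(base_composition(c("ACGT", "AC")), "length")
  expect_error(base_composition(character()), "at least one")
})

test_that("logo scores follow the per-letter relative entropy closed form", {
  w <- c("GG", "GG")  # f_G = 1 at both offsets
  p <- logo_scores(base_composition(w), background_gc = 0.5)
  expect_equal(p$scores["G", "-1"], log2(1 / 0.25))  # 2 bits
  expect_equal(p$scores["A", "-1"], 0)               # f = 0 contributes 0
  # f = q gives all-zero scores
  wq <- c("AC", "CA", "GT", "TG")
  pq <- logo_scores(base_composition(wq), background_gc = 0.5)
  expect_equal(max(abs(pq$scores)), 0)
  # higher background GC shrinks the G score
  hi <- logo_scores(base_composition(w), background_gc = 0.8)
  expect_lt(hi$scores["G", "-1"], p$scores["G", "-1"])
  expect_error(logo_scores(base_composition(w), 0), "strictly between")
})

test_that("averaged_profile is a delta at -1 for a delta top peak", {
  g <- toy_genome(c(p = strrep("A", 100)))
  tr <- make_track(g, top = list(p = c(`50` = 120)), units = "RPM")
  pk <- peakset("p", 50L, "top", 120)
  prof <- averaged_profile(pk, tr, h = 5)
  expect_equal(prof["oriented_top", "-1"], 120)
  expect_equal(sum(prof), 120)

  zero <- make_track(g, units = "RPM")
  expect_equal(sum(averaged_profile(pk, zero, h = 5)), 0)
  raw <- make_track(g, units = "raw_counts")
  expect_error(averaged_profile(pk, raw), "RPM")
  expect_error(averaged_profile(peakset(character(), integer(), character()),
                                tr), "empty")
})

test_that("bottom-strand peaks flip and strand-swap in averaged profiles", {
  g <- toy_genome(c(p = strrep("A", 100)))
  # break at dyad 50: top end at 50, bottom end at 51
  tr <- make_track(g, top = list(p = c(`50` = 10)),
                   bottom = list(p = c(`51` = 10)), units = "RPM")
  pk_top <- peakset("p", 50L, "top", 10)
  pk_bot <- peakset("p", 51L, "bottom", 10)
  pt <- averaged_profile(pk_top, tr, h = 5)
  pb <- averaged_profile(pk_bot, tr, h = 5)
  # seen from either end the oriented geometry is the same
  expect_equal(pt["oriented_top", "-1"], 10)
  expect_equal(pt["oriented_bottom", "1"], 10)
  expect_equal(pb["oriented_top", "-1"], 10)
  expect_equal(pb["oriented_bottom", "1"], 10)
})

test_that("simulated defaults put the oriented maxima at -1 and +1", {
  d <- sim_dataset(N = 5000L, beta = 0, phi = 0, seed = 101L)
  pk <- top_peaks(call_peaks(d$rpm, threshold = 100), 50)
  prof <- averaged_profile(pk, d$rpm, h = 10)
  offs <- colnames(prof)
  expect_identical(offs[which.max(prof["oriented_top", ])], "-1")
  expect_identical(offs[which.max(prof["oriented_bottom", ])], "1")
})

test_that("planted bias is recovered in logo scores around strong peaks", {
  d <- sim_dataset(N = 20000L, beta = 0, phi = 0, seed = 111L)
  # >= 8 reads: well above what a single-mismatch site accumulates here
  pk <- call_peaks(d$rpm, threshold = 8 * 1e6 / d$track$total_mapped)
  w <- suppressMessages(oriented_windows(pk, d$genome, h = 10))
  p <- logo_scores(base_composition(w), gc_content(d$genome))
  s <- p$scores
  expect_identical(rownames(s)[which.max(s[, "-3"])], "G")
  expect_identical(rownames(s)[which.max(s[, "-1"])], "A")
  expect_identical(rownames(s)[which.max(s[, "1"])], "T")
  expect_identical(rownames(s)[which.max(s[, "3"])], "C")
  far <- as.character(c(-10:-6, 6:10))
  expect_gt(min(s["G", "-3"], s["A", "-1"], s["T", "1"], s["C", "3"]),
            max(abs(s[, far])))
})

test_that("composition profiles serialize to TSV", {
  p <- logo_scores(base_composition(c("ACGTAC", "ACGTAC")), 0.45)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  lines <- readLines(f)
  expect_match(lines[1], "n=2")
  expect_match(lines[2], "background_gc=0.45")
  df <- utils::read.table(f, header = TRUE, comment.char = "#")
  expect_equal(nrow(df), 6)
  expect_true(all(c("f_A", "s_G") %in% names(df)))
})
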