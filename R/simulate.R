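#' Cleavage preference model
#'
#' A rotationally symmetric position-weight model of intrinsic cleavage-site
#' preference around the dyad axis, plus the nuisance parameters of the
#' library simulation: the background fraction `beta` (breaks placed
#' uniformly over valid dyads, emulating a catalytically dead control's
#' random background), the incomplete fill-in failure rate `phi`, and the
#' artifact shift `shift` in nt.
#'
#' @param weights 4 x 2h positive matrix, rownames `A,C,G,T`, columns the
#'   no-zero offsets `-h..-1, +1..+h`.
#' @param beta Background fraction in `[0, 1]`.
#' @param phi Fill-in failure rate in `[0, 1]`.
#' @param shift Artifact shift in nt (default 1).
#' @return A `cleavage_model`.
#' @export
cleavage_model <- function(weights, beta = 0.05, phi = 0.1, shift = 1L) {
  if (!is.matrix(weights) || !identical(rownames(weights), c("A", "C", "G", "T"))) {
    stop("weights must be a matrix with rownames A,C,G,T")
  }
  if (ncol(weights) %% 2L != 0L) stop("weights must cover offsets -h..-1,+1..+h")
  h <- ncol(weights) %/% 2L
  if (any(weights <= 0)) stop("all weights must be positive")
  if (beta < 0 || beta > 1 || phi < 0 || phi > 1) {
    stop("beta and phi must lie in [0, 1]")
  }
  offsets <- offset_labels(h)
  colnames(weights) <- as.character(offsets)
  structure(list(weights = weights, h = h, offsets = offsets,
                 beta = beta, phi = phi, shift = as.integer(shift)),
            class = "cleavage_model")
}

#' Test rotational symmetry of a model
#'
#' A model is rotationally symmetric when `M[b, +k] == M[complement(b), -k]`
#' for every base and offset, the signature expected of two protomers
#' engaging two half-sites.
#'
#' @param model A [cleavage_model()].
#' @return Logical.
#' @export
is_rotationally_symmetric <- function(model) {
  M <- model$weights
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:model$h) {
    for (b in rownames(M)) {
      if (!isTRUE(all.equal(M[b, as.character(k)],
                            M[comp[[b]], as.character(-k)]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Default cleavage preference model
#'
#' Unit weights everywhere except an elevated weight for G at -3, A at -1,
#' T at +1 and C at +3 — a rotationally symmetric encoding of the observed
#' composition bias whose best-scoring central hexamer (offsets -3..+3) is
#' exactly the GNATNC family.
#'
#' @param h Half-width in nt (default 10; must be >= 3).
#' @param boost Weight for the four preferred cells (default 4).
#' @param beta,phi,shift Passed to [cleavage_model()]; defaults 0.05, 0.1, 1.
#' @return A [cleavage_model()].
#' @export
default_model <- function(h = 10L, boost = 4, beta = 0.05, phi = 0.1,
                          shift = 1L) {
  if (h < 3L) stop("h must be >= 3")
  M <- matrix(1, nrow = 4, ncol = 2L * h,
              dimnames = list(c("A", "C", "G", "T"),
                              as.character(offset_labels(h))))
  M["G", "-3"] <- boost
  M["A", "-1"] <- boost
  M["T", "1"] <- boost
  M["C", "3"] <- boost
  cleavage_model(M, beta = beta, phi = phi, shift = shift)
}

#' Simulate an i.i.d. random genome
#'
#' Residues drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length Sequence length in nt.
#' @param gc G+C fraction, strictly inside (0, 1).
#' @param circular Circularity flag.
#' @param seed Integer seed (determinism contract: same seed, same genome).
#' @param name Sequence name.
#' @return A [genome_sequence()] with one sequence.
#' @export
simulate_genome <- function(length, gc = 0.45, circular = FALSE, seed = 1L,
                            name = "chrS") {
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (length < 12L) stop("length too short")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- with_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  genome_sequence(stats::setNames(s, name), circular = circular)
}

valid_dyads <- function(genome, h) {
  # dyad g is valid when the window at offsets -h..+h fits the sequence
  lapply(names(genome$seq), function(nm) {
    len <- nchar(genome$seq[[nm]])
    if (genome$circular[[nm]]) {
      seq_len(len)
    } else {
      if (len < 2L * h) stop("sequence '", nm, "' shorter than the ",
                             2L * h, "-nt scoring window")
      h:(len - h)
    }
  }) |> stats::setNames(names(genome$seq))
}

#' Per-dyad cleavage probabilities
#'
#' Scores each valid dyad as the product over offsets of the model weight of
#' the genomic base at that offset (windows containing N score zero), then
#' normalizes scores to probabilities over all valid dyads in the genome.
#'
#' @param genome A [genome_sequence()].
#' @param model A [cleavage_model()].
#' @return Named list (per sequence) of per-position probability vectors;
#'   invalid dyads have probability 0. Probabilities sum to 1 genome-wide.
#' @export
site_probabilities <- function(genome, model) {
  h <- model$h
  logM <- log(model$weights)
  vd <- valid_dyads(genome, h)
  scores <- lapply(names(genome$seq), function(nm) {
    len <- nchar(genome$seq[[nm]])
    chars <- seq_chars(genome, nm)
    g <- vd[[nm]]
    ls <- numeric(length(g))
    for (j in seq_along(model$offsets)) {
      o <- model$offsets[j]
      idx <- offset_to_position(g, rep(o, length(g)))
      if (genome$circular[[nm]]) idx <- wrap_index(idx, len)
      b <- chars[idx]
      wj <- logM[, j][b]          # NA for N
      wj[is.na(wj)] <- -Inf
      ls <- ls + wj
    }
    out <- rep(-Inf, len)
    out[g] <- ls
    out
  })
  names(scores) <- names(genome$seq)
  mx <- max(unlist(scores, use.names = FALSE))
  if (!is.finite(mx)) stop("no scoreable dyad (all windows contain N?)")
  probs <- lapply(scores, function(s) exp(s - mx))
  tot <- sum(unlist(probs, use.names = FALSE))
  lapply(probs, function(p) p / tot)
}

#' Simulate planted double-strand breaks
#'
#' Each of `N` DSBs is a background break with probability `beta` (dyad
#' uniform over valid positions) and otherwise is drawn from
#' [site_probabilities()]. Counts are aggregated per dyad into a ground-truth
#' table.
#'
#' @param genome A [genome_sequence()].
#' @param model A [cleavage_model()].
#' @param N Number of DSBs.
#' @param seed Integer seed.
#' @return A `sim_truth` data.frame (`seqname`, `dyad`, `count`) with the
#'   model, N and seed attached as attributes.
#' @export
simulate_breaks <- function(genome, model, N, seed = 1L) {
  if (N < 1L) stop("N must be >= 1")
  p <- site_probabilities(genome, model)
  vd <- valid_dyads(genome, model$h)
  # global indexing across sequences
  nms <- names(genome$seq)
  valid_global <- do.call(rbind, lapply(nms, function(nm) {
    data.frame(seqname = nm, dyad = vd[[nm]])
  }))
  pv <- unlist(lapply(nms, function(nm) p[[nm]][vd[[nm]]]), use.names = FALSE)
  if (nrow(valid_global) == 0L) stop("no valid dyads")
  draw <- with_seed(seed, {
    nbg <- stats::rbinom(1L, N, model$beta)
    i_bg <- if (nbg > 0L) sample.int(nrow(valid_global), nbg, replace = TRUE)
            else integer()
    i_sig <- if (N - nbg > 0L) sample.int(nrow(valid_global), N - nbg,
                                          replace = TRUE, prob = pv)
             else integer()
    c(i_bg, i_sig)
  })
  tab <- table(draw)
  idx <- as.integer(names(tab))
  sites <- data.frame(seqname = valid_global$seqname[idx],
                      dyad = valid_global$dyad[idx],
                      count = as.integer(tab))
  sites <- sites[order(sites$seqname, sites$dyad), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("sim_truth", "data.frame"),
            N = N, seed = seed, model = model)
}

#' Simulate strand-specific 5'-end count tracks from planted breaks
#'
#' Each DSB at dyad `g` leaves a 2-nt 5' overhang whose fill-in yields one
#' top-strand 5'-end count at `g` and one bottom-strand count at `g + 1`.
#' Independently per end, with probability `phi` (from the truth's model) the
#' fill-in is incomplete and the end is shifted: the top end to `g + shift`,
#' the bottom end to `(g + 1) - shift`. Ends shifted off a linear sequence
#' are dropped with a warning, never silently. Total raw counts equal `2N`
#' minus any such drops.
#'
#' @param truth A `sim_truth` from [simulate_breaks()].
#' @param genome The [genome_sequence()] the truth was simulated on.
#' @param seed Integer seed for the per-end artifact draws.
#' @return A raw-count `strand_track`.
#' @export
simulate_tracks <- function(truth, genome, seed = 1L) {
  model <- attr(truth, "model")
  phi <- model$phi; s <- model$shift
  track <- strand_track(genome)
  dropped <- 0L
  placed <- 0L
  shifts <- with_seed(seed, {
    list(top = stats::rbinom(nrow(truth), truth$count, phi),
         bottom = stats::rbinom(nrow(truth), truth$count, phi))
  })
  add <- function(nm, strand, pos, n) {
    len <- track$lengths[[nm]]
    if (genome$circular[[nm]]) {
      pos <- wrap_index(pos, len)
    } else if (pos < 1L || pos > len) {
      dropped <<- dropped + n
      warning(sprintf("dropped %d %s-strand end(s) shifted off linear '%s'",
                      n, strand, nm), call. = FALSE)
      return(invisible())
    }
    track[[strand]][[nm]][pos] <<- track[[strand]][[nm]][pos] + n
    placed <<- placed + n
  }
  for (i in seq_len(nrow(truth))) {
    nm <- truth$seqname[i]; g <- truth$dyad[i]; cnt <- truth$count[i]
    kt <- shifts$top[i]; kb <- shifts$bottom[i]
    if (cnt - kt > 0L) add(nm, "top", g, cnt - kt)
    if (kt > 0L) add(nm, "top", g + s, kt)
    if (cnt - kb > 0L) add(nm, "bottom", g + 1L, cnt - kb)
    if (kb > 0L) add(nm, "bottom", g + 1L - s, kb)
  }
  track$total_mapped <- placed
  track
}

#' Simulate a pure-background control map
#'
#' Emulates a catalytically dead control: `N` top-strand and `N`
#' bottom-strand read 5'-ends placed uniformly and independently over each
#' strand (2N raw counts in total). Unlike genuine cleavage, the background
#' has no end-pairing geometry, so control maps carry no strand
#' cross-correlation offset — the dead-enzyme control's defining property.
#'
#' @param genome A [genome_sequence()].
#' @param N Read-end pairs to place (total raw counts = 2N).
#' @param seed Integer seed.
#' @return A raw-count `strand_track`.
#' @export
simulate_control <- function(genome, N, seed = 1L) {
  if (N < 1L) stop("N must be >= 1")
  track <- strand_track(genome)
  lens <- track$lengths
  tot <- sum(lens)
  with_seed(seed, {
    for (strand in c("top", "bottom")) {
      pos <- sample.int(tot, N, replace = TRUE)
      cum <- cumsum(lens)
      si <- findInterval(pos - 1L, c(0L, cum))  # sequence index per draw
      off <- pos - c(0L, cum)[si]
      for (j in seq_along(lens)) {
        sel <- si == j
        if (any(sel)) {
          nm <- names(lens)[j]
          track[[strand]][[nm]] <- track[[strand]][[nm]] +
            tabulate(off[sel], nbins = lens[[j]])
        }
      }
    }
  })
  track$total_mapped <- 2L * N
  track
}

#' Write simulation ground truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  model <- attr(truth, "model")
  write_tsv_commented(
    as.data.frame(truth), path,
    header = c(
      sprintf("sim_truth N=%d seed=%d", attr(truth, "N"), attr(truth, "seed")),
      sprintf("model h=%d beta=%g phi=%g shift=%d",
              model$h, model$beta, model$phi, model$shift)))
}
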